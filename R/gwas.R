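#' Hardy-Weinberg equilibrium test
#'
#' Default is the exact conditional test: given the observed allele counts,
#' the distribution of the heterozygote count under Hardy-Weinberg
#' equilibrium is computed in closed form, and the two-sided p-value is the
#' total probability of all heterozygote counts no more probable than the
#' observed one. A 1-df chi-square goodness-of-fit test against the
#' expected genotype proportions is available via `method = "chisq"`;
#' it is anti-conservative for extreme tables at small counts, which is
#' why the exact test is the default. Monomorphic variants return p = 1.
#' The test is invariant to swapping the allele labels.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (vectorized): major homozygotes,
#'   heterozygotes, minor homozygotes.
#' @param method `"exact"` (default) or `"chisq"`.
#' @return P-value(s) in `(0, 1]`.
#' @export
#' @examples
#' hwe_test(25, 50, 25)
#' hwe_test(50, 0, 50)
hwe_test <- function(n_aa, n_ab, n_bb, method = c("exact", "chisq")) {
  method <- match.arg(method)
  k <- max(length(n_aa), length(n_ab), length(n_bb))
  n_aa <- rep_len(n_aa, k); n_ab <- rep_len(n_ab, k); n_bb <- rep_len(n_bb, k)
  if (any(c(n_aa, n_ab, n_bb) < 0, na.rm = TRUE)) {
    abort("genotype counts must be non-negative.")
  }
  if (any(c(n_aa, n_ab, n_bb) != round(c(n_aa, n_ab, n_bb)), na.rm = TRUE)) {
    abort("genotype counts must be integers.")
  }
  vapply(seq_len(k), function(i) {
    a <- n_aa[i]; h <- n_ab[i]; b <- n_bb[i]
    if (anyNA(c(a, h, b))) return(NA_real_)
    n <- a + h + b
    if (n == 0) abort("total genotype count must be positive.")
    n_al <- 2 * a + h  # copies of the A allele
    if (n_al == 0 || n_al == 2 * n) return(1)
    if (method == "chisq") {
      p_hat <- n_al / (2 * n)
      e <- n * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
      stat <- sum((c(a, h, b) - e)^2 / e)
      return(pchisq(stat, df = 1, lower.tail = FALSE))
    }
    ## exact: heterozygote counts compatible with the allele counts
    hets <- seq(n_al %% 2, min(n_al, 2 * n - n_al), by = 2)
    lp <- lgamma(n + 1) - lgamma((n_al - hets) / 2 + 1) - lgamma(hets + 1) -
      lgamma((2 * n - n_al - hets) / 2 + 1) + hets * log(2) +
      lgamma(n_al + 1) + lgamma(2 * n - n_al + 1) - lgamma(2 * n + 1)
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    p_obs <- pr[hets == h]
    min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
  }, numeric(1))
}

#' Per-variant QC metrics from a dosage matrix
#'
#' @param dosages Samples-by-variants numeric matrix in `[0, 2]` with `NA`
#'   for missing genotypes.
#' @return Tibble `variant_id, maf, missingness, hwe_p` (HWE from rounded
#'   hard calls, exact test).
#' @export
compute_variant_metrics <- function(dosages) {
  af <- colMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  missingness <- colMeans(is.na(dosages))
  hard <- round(dosages)
  cnt <- function(g) colSums(hard == g, na.rm = TRUE)
  hwe_p <- hwe_test(cnt(0), cnt(1), cnt(2))
  tibble(
    variant_id = colnames(dosages) %||% sprintf("var%04d", seq_along(maf)),
    maf = unname(maf), missingness = unname(missingness),
    hwe_p = unname(hwe_p)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variant QC filters
#'
#' Retains variants with minor allele frequency strictly above `maf_min`,
#' missingness strictly below `miss_max`, imputation quality strictly above
#' `r2_min`, and an HWE p-value of at least `hwe_min`. Filters whose metric
#' column is absent from the table are skipped (and reported as skipped).
#' The per-filter exclusion counts are attached as attribute `"report"`.
#'
#' @param variants Tibble with `variant_id` and any of `maf`,
#'   `missingness`, `imputation_r2`, `hwe_p`.
#' @param maf_min,miss_max,r2_min,hwe_min Thresholds (defaults 0.05, 0.02,
#'   0.6, 1e-5).
#' @return The retained rows, with attribute `"report"` (tibble
#'   `filter, n_excluded, applied`).
#' @export
filter_variants <- function(variants, maf_min = 0.05, miss_max = 0.02,
                            r2_min = 0.6, hwe_min = 1e-5) {
  rules <- list(
    maf = function(d) d$maf > maf_min,
    missingness = function(d) d$missingness < miss_max,
    imputation_r2 = function(d) d$imputation_r2 > r2_min,
    hwe = function(d) d$hwe_p >= hwe_min
  )
  cols <- c(maf = "maf", missingness = "missingness",
            imputation_r2 = "imputation_r2", hwe = "hwe_p")
  keep <- rep(TRUE, nrow(variants))
  report <- purrr::imap(rules, function(rule, nm) {
    if (!cols[[nm]] %in% names(variants)) {
      return(tibble(filter = nm, n_excluded = NA_integer_, applied = FALSE))
    }
    pass <- rule(variants)
    pass[is.na(pass)] <- FALSE
    keep <<- keep & pass
    tibble(filter = nm, n_excluded = sum(!pass), applied = TRUE)
  }) %>% bind_rows()
  out <- variants[keep, ]
  attr(out, "report") <- report
  out
}

#' Per-variant association scan with genomic-inflation estimate
#'
#' Ordinary least-squares regression of the outcome on each variant's
#' additive dosage plus shared covariates, with Wald p-values. Missing
#' dosages are dropped per variant. The genomic inflation factor is the
#' median of the per-variant Wald chi-square statistics divided by the
#' null chi-square(1) median (0.45494); a value near 1 indicates no
#' systematic inflation.
#'
#' @param data Tibble with `sample_id`, the outcome and covariates, in the
#'   same order as the rows of `dosages`.
#' @param dosages Samples-by-variants dosage matrix (rownames matched to
#'   `data$sample_id` when present).
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of adjustment columns.
#' @return Object of class `"gwas_scan"`: per-variant results (`tidy()`)
#'   and `lambda_gc` (`glance()`). Constant-dosage variants are skipped
#'   with a warning.
#' @export
gwas_scan <- function(data, dosages, outcome, covariates = NULL) {
  if (!is.null(rownames(dosages))) {
    if (!all(data$sample_id %in% rownames(dosages))) {
      abort("dosage matrix is missing some samples in `data`.")
    }
    dosages <- dosages[data$sample_id, , drop = FALSE]
  } else if (nrow(dosages) != nrow(data)) {
    abort("dosage matrix rows do not match `data`.")
  }
  cols <- c(outcome, covariates)
  cc <- complete.cases(data[cols])
  data <- data[cc, ]
  dosages <- dosages[cc, , drop = FALSE]
  y <- data[[outcome]]
  xmat <- if (length(covariates)) {
    model.matrix(stats::reformulate(covariates), data = data)
  } else {
    matrix(1, nrow(data), 1)
  }
  vids <- colnames(dosages) %||% sprintf("var%04d", seq_len(ncol(dosages)))
  res <- purrr::map(seq_len(ncol(dosages)), function(j) {
    d <- dosages[, j]
    ok <- !is.na(d)
    if (sum(ok) < ncol(xmat) + 2 || var(d[ok]) == 0) {
      return(tibble(variant_id = vids[j], slope = NA_real_, se = NA_real_,
                    p = NA_real_))
    }
    xj <- cbind(xmat[ok, , drop = FALSE], dose = d[ok])
    fit <- stats::lm.fit(xj, y[ok])
    cf <- fit$coefficients
    if (anyNA(cf)) {
      return(tibble(variant_id = vids[j], slope = NA_real_, se = NA_real_,
                    p = NA_real_))
    }
    rdf <- fit$df.residual
    sigma2 <- sum(fit$residuals^2) / rdf
    xtxinv <- tryCatch(solve(crossprod(xj)), error = function(e) NULL)
    if (is.null(xtxinv)) {
      return(tibble(variant_id = vids[j], slope = NA_real_, se = NA_real_,
                    p = NA_real_))
    }
    se <- sqrt(sigma2 * xtxinv[length(cf), length(cf)])
    tstat <- cf[["dose"]] / se
    tibble(variant_id = vids[j], slope = cf[["dose"]], se = se,
           p = 2 * stats::pt(abs(tstat), rdf, lower.tail = FALSE))
  }) %>% bind_rows()
  n_skip <- sum(is.na(res$p))
  if (n_skip) warn(sprintf("%d variant(s) skipped (constant or rank-deficient).", n_skip))
  chisq <- qnorm(res$p[!is.na(res$p)] / 2, lower.tail = FALSE)^2
  lambda <- median(chisq) / qchisq(0.5, df = 1)
  structure(
    list(results = res, lambda_gc = lambda,
         n_samples = nrow(data), n_variants = ncol(dosages)),
    class = "gwas_scan"
  )
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat(sprintf("<gwas_scan> %d variants, %d samples, lambda_GC = %.3f\n",
              x$n_variants, x$n_samples, x$lambda_gc))
  invisible(x)
}

#' Greedy clumping into loci with independent signals
#'
#' Sorts genome-wide-significant variants by ascending p-value; the best
#' remaining variant leads a new locus, which absorbs every significant
#' variant on the same chromosome within `window_bp`. Among the absorbed
#' variants, those with squared dosage correlation below `r2_threshold` to
#' the lead are counted as additional independent signals of the locus.
#'
#' @param scan A [gwas_scan()] object (or its `tidy()` tibble).
#' @param variants Tibble `variant_id, chrom, pos`.
#' @param dosages Samples-by-variants dosage matrix (for r-squared;
#'   missing values pairwise-deleted).
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param r2_threshold Independence threshold (default 0.1).
#' @param window_bp Locus window around the lead (default 1e6).
#' @return Tibble `locus, lead_variant, chrom, pos, p, n_signals, signals`
#'   (semicolon-joined independent-signal ids, lead included).
#' @export
clump_signals <- function(scan, variants, dosages, p_threshold = 5e-8,
                          r2_threshold = 0.1, window_bp = 1e6) {
  res <- if (inherits(scan, "gwas_scan")) scan$results else scan
  sig <- res %>%
    dplyr::filter(!is.na(.data$p), .data$p < p_threshold) %>%
    dplyr::inner_join(variants[c("variant_id", "chrom", "pos")],
                      by = "variant_id") %>%
    arrange(.data$p)
  loci <- list()
  while (nrow(sig)) {
    lead <- sig[1, ]
    in_window <- sig$chrom == lead$chrom &
      abs(sig$pos - lead$pos) <= window_bp
    members <- sig[in_window, ]
    extra <- members %>%
      dplyr::filter(.data$variant_id != lead$variant_id) %>%
      dplyr::filter(purrr::map_lgl(.data$variant_id, function(v) {
        r <- stats::cor(dosages[, lead$variant_id], dosages[, v],
                        use = "pairwise.complete.obs")
        !is.na(r) && r^2 < r2_threshold
      }))
    loci[[length(loci) + 1]] <- tibble(
      locus = length(loci) + 1L,
      lead_variant = lead$variant_id, chrom = lead$chrom, pos = lead$pos,
      p = lead$p, n_signals = 1L + nrow(extra),
      signals = paste(c(lead$variant_id, extra$variant_id), collapse = ";")
    )
    sig <- sig[!in_window, ]
  }
  bind_rows(loci)
}
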