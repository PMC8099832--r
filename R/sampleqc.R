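#' Per-sample standard deviation of autosomal L2R (SDL2R)
#'
#' The sample standard deviation of a sample's autosomal L2R values; high
#' values flag excessive genotyping-intensity noise.
#'
#' @param intensities Probe-intensity tibble (autosomal rows are used).
#' @return Tibble `sample_id, sdl2r`; samples with fewer than two autosomal
#'   probes get `NA`.
#' @export
compute_sdl2r <- function(intensities) {
  probe_l2r(intensities) %>%
    dplyr::filter(.data$panel == "autosomal") %>%
    group_by(.data$sample_id) %>%
    summarise(
      sdl2r = if (sum(!is.na(.data$l2r)) >= 2) sd(.data$l2r, na.rm = TRUE)
              else NA_real_,
      .groups = "drop"
    ) %>%
    arrange(.data$sample_id)
}

#' B-allele-frequency phase concordance
#'
#' Given B-allele frequencies at phased heterozygous sites (ordered by
#' position) and the phase of the alternate allele, computes the
#' phase-aligned deviation `e_i = s_i * (BAF_i - 0.5)` with `s_i = +1` when
#' the alternate allele lies on haplotype A and `-1` otherwise, and returns
#' the fraction of consecutive pairs `(e_i, e_{i+1})` sharing the same
#' non-zero sign. Pairs containing an exactly-zero deviation are skipped.
#' A clean sample has independent deviation signs (concordance near 0.5);
#' contamination or mosaicism produces runs of like signs (concordance
#' near 1).
#'
#' @param baf B-allele frequencies in `[0, 1]`, ordered by position.
#' @param hap_a_alt Logical, `TRUE` when the alternate allele is on
#'   haplotype A at that site.
#' @return Concordance fraction, or `NA` if fewer than two usable sites.
#' @export
#' @examples
#' compute_baf_concordance(c(0.55, 0.45, 0.56, 0.44), c(TRUE, FALSE, TRUE, FALSE))
compute_baf_concordance <- function(baf, hap_a_alt) {
  stopifnot(length(baf) == length(hap_a_alt))
  ok <- !is.na(baf) & !is.na(hap_a_alt)
  e <- ifelse(hap_a_alt[ok], 1, -1) * (baf[ok] - 0.5)
  if (length(e) < 2) return(NA_real_)
  s <- sign(e)
  a <- s[-length(s)]
  b <- s[-1]
  usable <- a != 0 & b != 0
  if (!any(usable)) return(NA_real_)
  mean(a[usable] == b[usable])
}

#' Per-sample BAF phase concordance for a site table
#'
#' @param baf_table Tibble `sample_id, pos, baf, hap_a_alt`.
#' @return Tibble `sample_id, baf_concordance`.
#' @export
baf_concordance_by_sample <- function(baf_table) {
  baf_table %>%
    arrange(.data$sample_id, .data$pos) %>%
    group_by(.data$sample_id) %>%
    summarise(
      baf_concordance = compute_baf_concordance(.data$baf, .data$hap_a_alt),
      .groups = "drop"
    )
}

#' Apply sample exclusion rules
#'
#' Flags samples for exclusion when any of the following holds: SDL2R at or
#' above the threshold (fixed 0.36 by default, or mean + 2 SD of the cohort
#' in adaptive mode), BAF phase concordance above 0.52, genotype call rate
#' below 99%, or any upstream genotype-QC flag (`sex_anomaly`,
#' `het_outlier`, `!ancestry_pass`, `!unrelated_pass`) present in the
#' input. Rules whose metric column is absent are skipped; a missing value
#' in a present metric column excludes the sample with reason
#' `missing_metric`.
#'
#' @param metrics Tibble with `sample_id` and any of `sdl2r`,
#'   `baf_concordance`, `call_rate`, and the upstream flags.
#' @param sdl2r_max Fixed SDL2R exclusion threshold (exclude when
#'   `sdl2r >= sdl2r_max`). Default 0.36.
#' @param sdl2r_mode `"fixed"` or `"adaptive"` (mean + 2 SD of the cohort).
#' @param baf_max Exclude when `baf_concordance > baf_max` (default 0.52).
#' @param call_rate_min Exclude when `call_rate < call_rate_min`
#'   (default 0.99).
#' @return `metrics` with logical `excluded` and a semicolon-joined
#'   `exclusion_reasons` column (empty string when retained).
#' @export
apply_exclusions <- function(metrics, sdl2r_max = 0.36,
                             sdl2r_mode = c("fixed", "adaptive"),
                             baf_max = 0.52, call_rate_min = 0.99) {
  sdl2r_mode <- match.arg(sdl2r_mode)
  n <- nrow(metrics)
  reasons <- vector("list", n)
  add_reason <- function(hit, label) {
    hit[is.na(hit)] <- FALSE
    for (i in which(hit)) reasons[[i]] <<- c(reasons[[i]], label)
    invisible(NULL)
  }
  miss_rule <- function(x) is.na(x)

  if ("sdl2r" %in% names(metrics)) {
    thr <- if (sdl2r_mode == "adaptive") {
      mean(metrics$sdl2r, na.rm = TRUE) + 2 * sd(metrics$sdl2r, na.rm = TRUE)
    } else sdl2r_max
    add_reason(metrics$sdl2r >= thr, "sdl2r")
    add_reason(miss_rule(metrics$sdl2r), "missing_metric")
  }
  if ("baf_concordance" %in% names(metrics)) {
    add_reason(metrics$baf_concordance > baf_max, "baf_concordance")
    add_reason(miss_rule(metrics$baf_concordance), "missing_metric")
  }
  if ("call_rate" %in% names(metrics)) {
    add_reason(metrics$call_rate < call_rate_min, "call_rate")
    add_reason(miss_rule(metrics$call_rate), "missing_metric")
  }
  flag_cols <- c(sex_anomaly = FALSE, het_outlier = FALSE,
                 ancestry_pass = TRUE, unrelated_pass = TRUE)
  for (fc in names(flag_cols)) {
    if (fc %in% names(metrics)) {
      v <- metrics[[fc]]
      hit <- if (flag_cols[[fc]]) !v else v
      add_reason(hit, fc)
      add_reason(miss_rule(v), "missing_metric")
    }
  }
  reasons <- lapply(reasons, unique)
  metrics %>%
    mutate(
      excluded = lengths(reasons) > 0,
      exclusion_reasons = purrr::map_chr(reasons, paste, collapse = ";")
    )
}
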