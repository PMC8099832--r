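#' Log2 intensity ratio
#'
#' The log R ratio (L2R) of a probe is the log2-transformed ratio of the
#' observed probe intensity to its reference intensity; it is the basic
#' per-probe proxy for relative DNA quantity.
#'
#' @param observed,reference Strictly positive intensities (vectorized).
#' @param probe_id,sample_id Optional identifiers used in error messages.
#' @return `log2(observed / reference)`.
#' @export
#' @examples
#' compute_l2r(1000, 500)
compute_l2r <- function(observed, reference, probe_id = NULL, sample_id = NULL) {
  bad <- which(!is.finite(observed) | !is.finite(reference) |
                 observed <= 0 | reference <= 0)
  if (length(bad)) {
    lab <- bad[1]
    ctx <- c(
      if (!is.null(probe_id)) sprintf("probe %s", probe_id[min(lab, length(probe_id))]),
      if (!is.null(sample_id)) sprintf("sample %s", sample_id[min(lab, length(sample_id))])
    )
    abort(sprintf(
      "Non-positive or non-finite intensity at position %d%s.",
      lab, if (length(ctx)) paste0(" (", paste(ctx, collapse = ", "), ")") else ""
    ))
  }
  log2(observed / reference)
}

#' Add an `l2r` column to a probe-intensity table
#'
#' Accepts either a table that already carries `l2r` (returned unchanged,
#' validated) or one with `observed_intensity` and `reference_intensity`
#' columns, from which L2R is derived via [compute_l2r()].
#'
#' @param intensities Tibble with `sample_id`, `probe_id`, `panel` and
#'   either `l2r` or the two intensity columns.
#' @return The input with a numeric `l2r` column.
#' @export
probe_l2r <- function(intensities) {
  need <- c("sample_id", "probe_id", "panel")
  miss <- setdiff(need, names(intensities))
  if (length(miss)) abort(paste0("intensities is missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(intensities[c("sample_id", "probe_id")])) {
    abort("duplicated (sample_id, probe_id) pairs in intensities.")
  }
  if ("l2r" %in% names(intensities)) return(intensities)
  if (!all(c("observed_intensity", "reference_intensity") %in% names(intensities))) {
    abort("intensities must carry `l2r` or observed/reference intensity columns.")
  }
  dplyr::mutate(intensities, l2r = compute_l2r(
    .data$observed_intensity, .data$reference_intensity,
    probe_id = .data$probe_id, sample_id = .data$sample_id
  ))
}

mt_wide <- function(intensities) {
  mt <- dplyr::filter(probe_l2r(intensities), .data$panel == "MT")
  tidyr::pivot_wider(mt[c("sample_id", "probe_id", "l2r")],
                     names_from = "probe_id", values_from = "l2r")
}

#' Fit coverage-calibrated probe weights
#'
#' Calibrates the array against whole-exome sequencing: stage 1 regresses
#' each calibration sample's normalized mitochondrial coverage jointly on
#' all MT probe L2R values; probes whose coefficient is significant at
#' `alpha` are selected; stage 2 refits the regression on the selected
#' probes only, and those refitted coefficients become the per-probe
#' weights. Probes that are not selected get weight 0. An intercept is
#' always included and absorbed (not a probe weight).
#'
#' @param intensities Probe-intensity tibble (MT panel rows are used).
#' @param coverage Tibble `sample_id, normalized_mt_coverage`; only samples
#'   present here enter the calibration fit.
#' @param alpha Probe-selection significance threshold (default 0.05).
#' @param scale_coverage If `TRUE`, z-score the coverage before fitting;
#'   off by default since downstream plate standardization absorbs scale.
#' @return A tibble of class `"probe_weights"` with columns
#'   `probe_id, weight, se, p_value, selected` (`se` is the stage-2
#'   standard error, selected probes only) and the stage-2 intercept as
#'   attribute `"intercept"`.
#' @export
fit_probe_weights <- function(intensities, coverage, alpha = 0.05,
                              scale_coverage = FALSE) {
  wide <- mt_wide(intensities)
  dat <- dplyr::inner_join(coverage, wide, by = "sample_id")
  probes <- setdiff(names(wide), "sample_id")
  keep <- complete.cases(dat[probes]) & is.finite(dat$normalized_mt_coverage)
  if (any(!keep)) {
    inform(sprintf("fit_probe_weights: dropping %d calibration row(s) with missing values.",
                   sum(!keep)))
    dat <- dat[keep, ]
  }
  if (nrow(dat) <= length(probes) + 1) {
    abort("calibration subset must have more samples than probes.")
  }
  y <- dat$normalized_mt_coverage
  if (scale_coverage) y <- as.numeric(scale(y))
  x <- as.matrix(dat[probes])

  fit1 <- lm(y ~ x)
  cf1 <- coef(fit1)
  if (anyNA(cf1)) {
    bad <- probes[is.na(cf1[-1])]
    abort(paste0("rank-deficient probe design; collinear probe(s): ",
                 paste(bad, collapse = ", ")))
  }
  p1 <- summary(fit1)$coefficients[-1, "Pr(>|t|)"]
  selected <- p1 < alpha
  if (!any(selected)) {
    abort("no probe passed selection; use a larger calibration set or relax alpha.")
  }

  fit2 <- lm(y ~ x[, selected, drop = FALSE])
  cf2 <- coef(fit2)
  if (anyNA(cf2)) abort("rank-deficient design in the stage-2 refit.")
  w <- setNames(numeric(length(probes)), probes)
  w[selected] <- cf2[-1]
  se <- setNames(rep(NA_real_, length(probes)), probes)
  se[selected] <- summary(fit2)$coefficients[-1, "Std. Error"]

  out <- tibble(
    probe_id = probes,
    weight = unname(w),
    se = unname(se),
    p_value = unname(p1),
    selected = unname(selected)
  )
  attr(out, "intercept") <- unname(cf2[1])
  attr(out, "n_calibration") <- nrow(dat)
  class(out) <- c("probe_weights", class(out))
  out
}

#' Weighted-median mtDNA abundance estimate (raw mL2RMT)
#'
#' Multiplies each selected MT probe's L2R by its calibration weight and
#' takes the per-sample median of the weighted values. Even-count medians
#' use the mean-of-the-middle-two convention. Unweighted variants are
#' provided for comparison: `"unweighted_all"` is the plain median over all
#' MT probes and `"unweighted_subset"` the plain median over a configured
#' probe subset.
#'
#' @param intensities Probe-intensity tibble (MT panel rows are used).
#' @param weights A [fit_probe_weights()] table (required for
#'   `method = "weighted"`).
#' @param method One of `"weighted"`, `"unweighted_all"`,
#'   `"unweighted_subset"`.
#' @param subset_probes Probe ids for `"unweighted_subset"`.
#' @return Tibble `sample_id, ml2rmt_raw, method`; samples with no usable
#'   probe get `NA` and a warning.
#' @export
compute_ml2rmt <- function(intensities, weights = NULL,
                           method = c("weighted", "unweighted_all",
                                      "unweighted_subset"),
                           subset_probes = NULL) {
  method <- match.arg(method)
  mt <- dplyr::filter(probe_l2r(intensities), .data$panel == "MT")
  if (method == "weighted") {
    if (is.null(weights)) abort("`weights` is required for method = \"weighted\".")
    sel <- dplyr::filter(weights, .data$selected)
    if (!nrow(sel)) abort("no selected probes in `weights`.")
    mt <- dplyr::inner_join(mt, sel[c("probe_id", "weight")], by = "probe_id") %>%
      mutate(wl2r = .data$weight * .data$l2r)
  } else if (method == "unweighted_subset") {
    if (is.null(subset_probes)) {
      abort("`subset_probes` is required for method = \"unweighted_subset\".")
    }
    mt <- dplyr::filter(mt, .data$probe_id %in% subset_probes) %>%
      mutate(wl2r = .data$l2r)
  } else {
    mt <- mutate(mt, wl2r = .data$l2r)
  }
  out <- mt %>%
    group_by(.data$sample_id) %>%
    summarise(ml2rmt_raw = median(.data$wl2r, na.rm = TRUE), .groups = "drop") %>%
    mutate(method = method)
  all_ids <- unique(probe_l2r(intensities)$sample_id)
  lost <- setdiff(all_ids, out$sample_id)
  flagged <- union(lost, out$sample_id[is.nan(out$ml2rmt_raw)])
  if (length(flagged)) {
    warn(sprintf("%d sample(s) had no usable probe; estimate set to missing.",
                 length(flagged)))
    out <- bind_rows(out, tibble(sample_id = lost, ml2rmt_raw = NA_real_,
                                 method = method))
  }
  out$ml2rmt_raw[is.nan(out$ml2rmt_raw)] <- NA_real_
  arrange(out, .data$sample_id)
}

#' Median autosomal abundance (mL2Rauto)
#'
#' Per-sample summary of all autosomal L2R values; a proxy for the total
#' quantity of hybridized DNA, used as a covariate to absorb DNA-quality
#' differences. Defaults to the median (symmetry with mL2RMT); the mean is
#' available via `stat`.
#'
#' @param intensities Probe-intensity tibble (autosomal panel rows used).
#' @param stat `"median"` (default) or `"mean"`.
#' @return Tibble `sample_id, ml2rauto_raw`.
#' @export
compute_ml2rauto <- function(intensities, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  fn <- if (stat == "median") median else mean
  probe_l2r(intensities) %>%
    dplyr::filter(.data$panel == "autosomal") %>%
    group_by(.data$sample_id) %>%
    summarise(ml2rauto_raw = fn(.data$l2r, na.rm = TRUE), .groups = "drop") %>%
    arrange(.data$sample_id)
}

#' Standardize abundance estimates within genotyping plates
#'
#' Rescales a raw per-sample estimate to mean zero and sample SD one within
#' each genotyping plate, removing plate-level intensity shifts. Plates
#' with zero spread or a single non-missing sample cannot be standardized:
#' their values are set to missing with a warning.
#'
#' @param estimates Tibble with `sample_id` and the raw column.
#' @param plates Tibble `sample_id, plate_id` (e.g. the phenotype table).
#' @param value Name of the raw column (default `"ml2rmt_raw"`).
#' @param out Name of the standardized column (default drops `_raw`).
#' @return `estimates` with the standardized column and `plate_id` added.
#' @export
standardize_by_plate <- function(estimates, plates = NULL, value = "ml2rmt_raw",
                                 out = sub("_raw$", "", value)) {
  if (!value %in% names(estimates)) {
    abort(sprintf("column `%s` not found in estimates.", value))
  }
  if ("plate_id" %in% names(estimates)) {
    dat <- estimates
  } else {
    if (is.null(plates)) abort("`plates` is required when estimates lack plate_id.")
    dat <- dplyr::left_join(estimates,
                            dplyr::distinct(plates[c("sample_id", "plate_id")]),
                            by = "sample_id")
  }
  if (anyNA(dat$plate_id)) abort("some samples have no plate assignment.")
  dat <- dat %>%
    group_by(.data$plate_id) %>%
    mutate(
      .n_ok = sum(!is.na(.data[[value]])),
      .mu = mean(.data[[value]], na.rm = TRUE),
      .sd = sd(.data[[value]], na.rm = TRUE),
      !!sym(out) := dplyr::case_when(
        .data$.n_ok < 2 ~ NA_real_,
        .data$.sd == 0 ~ NA_real_,
        TRUE ~ (.data[[value]] - .data$.mu) / .data$.sd
      )
    ) %>%
    ungroup()
  degenerate <- dat %>%
    dplyr::filter(.data$.n_ok < 2 | .data$.sd == 0) %>%
    dplyr::distinct(.data$plate_id) %>%
    pull()
  if (length(degenerate)) {
    warn(paste0("plate(s) with zero spread or a single usable sample set to missing: ",
                paste(degenerate, collapse = ", ")))
  }
  dplyr::select(dat, -dplyr::all_of(c(".n_ok", ".mu", ".sd")))
}
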