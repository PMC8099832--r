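#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with the standard monotonicity
#' enforcement; values are capped at 1 and `NA`s are propagated.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order as the input.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p_values) {
  ok <- p_values[!is.na(p_values)]
  if (any(ok < 0 | ok > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p_values, method = "BH")
}

fit_checked_lm <- function(df, formula, context) {
  fit <- lm(formula, data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(sprintf("rank-deficient design in %s; aliased column(s): %s",
                  context, paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  fit
}

#' Per-SD linear associations
#'
#' For each exposure (and optionally within each level of a stratifying
#' column), standardizes the exposure to z-scores over the analysis subset
#' and fits an ordinary least-squares regression of the outcome on the
#' standardized exposure plus covariates. Reported slopes are therefore
#' "per SD of exposure"; confidence intervals are Wald 95% intervals and
#' q-values are Benjamini-Hochberg across all rows returned by the call.
#'
#' @param data Tibble with one row per sample.
#' @param outcome Name of the outcome column.
#' @param exposures Character vector of exposure column names.
#' @param covariates Character vector of adjustment columns (factors such
#'   as genotyping batch are expanded to indicators).
#' @param strata Optional name of a stratifying column (e.g. sex or MT
#'   haplogroup); `NULL` analyses all samples together.
#' @return Tibble with columns
#'   `outcome, exposure, stratum, slope, ci_low, ci_high, p_value, q_value, n`.
#' @export
linear_association <- function(data, outcome, exposures, covariates = NULL,
                               strata = NULL) {
  levels <- if (is.null(strata)) "all" else
    sort(unique(stats::na.omit(data[[strata]])))
  rows <- purrr::map(levels, function(lv) {
    sub <- if (is.null(strata)) data else
      dplyr::filter(data, .data[[strata]] == lv)
    purrr::map(exposures, function(ex) {
      cols <- c(outcome, ex, covariates)
      cc <- sub[complete.cases(sub[cols]), cols]
      if (nrow(cc) < length(cols) + 2) {
        abort(sprintf("too few complete cases for exposure `%s` in stratum `%s`.",
                      ex, as.character(lv)))
      }
      df <- data.frame(.y = cc[[outcome]],
                       .z = as.numeric(standardize_exposure(cc[[ex]])))
      for (cv in covariates) df[[cv]] <- cc[[cv]]
      fml <- stats::reformulate(c(".z", covariates), response = ".y")
      fit <- fit_checked_lm(df, fml, sprintf("association of %s ~ %s", outcome, ex))
      sm <- summary(fit)$coefficients
      est <- sm[".z", "Estimate"]
      se <- sm[".z", "Std. Error"]
      tcrit <- stats::qt(0.975, fit$df.residual)
      tibble(
        outcome = outcome, exposure = ex, stratum = as.character(lv),
        slope = est, ci_low = est - tcrit * se, ci_high = est + tcrit * se,
        p_value = sm[".z", "Pr(>|t|)"], n = nrow(df)
      )
    }) %>% bind_rows()
  }) %>% bind_rows()
  mutate(rows, q_value = bh_fdr(.data$p_value))
}

#' Two-lines breakpoint test
#'
#' Detects sign-reversing (U- or inverted-U-shaped) relationships by
#' fitting separate covariate-adjusted regressions of `y` on `x` below and
#' above each candidate cutoff, selecting the cutoff that minimizes the
#' total residual sum of squares, and reporting both segment slopes with
#' their p-values at the selected cutoff. The U-shape flag is raised when
#' both slopes are individually significant at `alpha` and have opposite
#' signs.
#'
#' @param data Tibble with one row per observation.
#' @param x,y Names of the running variable and outcome columns.
#' @param covariates Optional adjustment columns, shared by both segments
#'   (each segment is fit separately).
#' @param cutoffs Candidate cutoffs; default is a 1-unit grid over the
#'   observed range of `x`, restricted to cutoffs leaving at least
#'   `min_per_side` observations on each side.
#' @param min_per_side Minimum observations per segment. The default,
#'   `NULL`, uses 10% of the observations (never fewer than 10): keeping
#'   the candidate cutoffs away from the edges prevents tiny, unstable
#'   segments from being selected, which would otherwise inflate the
#'   U-shape flag's false-positive rate under weak-slope monotone inputs.
#' @param alpha Per-segment significance level for the U-shape flag.
#' @return An object of class `"two_lines"`; see [tidy.two_lines()] and
#'   [glance.two_lines()].
#' @export
two_lines_test <- function(data, x, y, covariates = NULL, cutoffs = NULL,
                           min_per_side = NULL, alpha = 0.05) {
  cols <- c(x, y, covariates)
  cc <- data[complete.cases(data[cols]), cols]
  xv <- cc[[x]]
  if (is.null(min_per_side)) min_per_side <- max(10, ceiling(0.1 * length(xv)))
  if (is.null(cutoffs)) {
    cutoffs <- seq(ceiling(min(xv)), floor(max(xv)), by = 1)
  }
  ok <- vapply(cutoffs, function(cf) {
    sum(xv <= cf) >= min_per_side && sum(xv > cf) >= min_per_side
  }, logical(1))
  cutoffs <- cutoffs[ok]
  if (!length(cutoffs)) {
    abort("no candidate cutoff leaves both sides adequately populated.")
  }
  fml <- stats::reformulate(c(x, covariates), response = y)
  seg_fit <- function(rows) fit_checked_lm(cc[rows, ], fml, "two-lines segment")
  rss <- vapply(cutoffs, function(cf) {
    lo <- xv <= cf
    sum(resid(seg_fit(lo))^2) + sum(resid(seg_fit(!lo))^2)
  }, numeric(1))
  best <- cutoffs[which.min(rss)]
  lo <- xv <= best
  f_lo <- seg_fit(lo)
  f_hi <- seg_fit(!lo)
  stat <- function(fit) {
    sm <- summary(fit)$coefficients
    c(slope = sm[x, "Estimate"], p = sm[x, "Pr(>|t|)"])
  }
  s_lo <- stat(f_lo)
  s_hi <- stat(f_hi)
  u_flag <- !is.na(s_lo["p"]) && !is.na(s_hi["p"]) &&
    s_lo["p"] < alpha && s_hi["p"] < alpha &&
    sign(s_lo["slope"]) * sign(s_hi["slope"]) == -1
  structure(
    list(
      cutoff = best,
      slope_below = unname(s_lo["slope"]), slope_above = unname(s_hi["slope"]),
      p_below = unname(s_lo["p"]), p_above = unname(s_hi["p"]),
      u_shape_flag = unname(u_flag),
      n_below = sum(lo), n_above = sum(!lo),
      alpha = alpha,
      grid = tibble(cutoff = cutoffs, rss = rss),
      x = x, y = y, covariates = covariates,
      data = cc[c(x, y)]
    ),
    class = "two_lines"
  )
}

#' @export
print.two_lines <- function(x, ...) {
  cat(sprintf("<two_lines> cutoff %g (%s): slope below %+.4g (p=%.3g), above %+.4g (p=%.3g)\n",
              x$cutoff, x$x, x$slope_below, x$p_below, x$slope_above, x$p_above))
  cat(sprintf("  U-shape flag: %s (n = %d / %d)\n",
              x$u_shape_flag, x$n_below, x$n_above))
  invisible(x)
}
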