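#' Rockwood accumulation-of-deficits frailty index
#'
#' The frailty index is the fraction of health deficits present among the
#' deficits assessed: `sum(items == 1) / number of answered items`. An
#' individual answering fewer than `min_answered` items (default 39, i.e.
#' an 80% floor on 49 items) gets a missing index rather than an estimate
#' from too few items.
#'
#' @param items A numeric vector of deficit indicators in `{0, 1, NA}`, or
#'   a matrix / data frame with one row per individual and one column per
#'   item.
#' @param min_answered Minimum number of answered items (default 39).
#' @return A fraction in `[0, 1]` per individual, `NA` where too few items
#'   were answered.
#' @export
#' @examples
#' frailty_index(c(rep(1, 5), rep(0, 44)))
frailty_index <- function(items, min_answered = 39) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (!is.matrix(items)) items <- matrix(items, nrow = 1)
  storage.mode(items) <- "double"
  vals <- items[!is.na(items)]
  if (length(vals) && !all(vals %in% c(0, 1))) {
    abort("deficit items must be 0, 1 or missing.")
  }
  answered <- rowSums(!is.na(items))
  fi <- rowSums(items == 1, na.rm = TRUE) / answered
  fi[answered < min_answered] <- NA_real_
  unname(fi)
}

#' Split a distribution into tertiles
#'
#' Cutoffs are the empirical 33.333% and 66.667% quantiles under the
#' linear-interpolation convention (`type = 7`); boundary values are
#' assigned to the lower group. On a standard normal distribution the lower
#' cutoff converges to \eqn{\Phi^{-1}(1/3) \approx -0.431}.
#'
#' @param values Numeric vector with at least 3 non-missing values.
#' @return A list of class `"tertiles"`: `spec` (tibble
#'   `lower_cutoff, upper_cutoff`) and `labels` (factor `T1`/`T2`/`T3`,
#'   `NA` preserved).
#' @export
#' @examples
#' tertile_discretize(1:9)
tertile_discretize <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 3) abort("need at least 3 non-missing values.")
  if (max(x) == min(x)) abort("all values identical; tertiles are undefined.")
  q <- unname(quantile(x, c(1, 2) / 3, type = 7))
  if (q[1] >= q[2]) {
    abort("tertile cutoffs coincide (heavily tied data); tertiles are undefined.")
  }
  labels <- factor(
    dplyr::case_when(
      is.na(values) ~ NA_character_,
      values <= q[1] ~ "T1",
      values <= q[2] ~ "T2",
      TRUE ~ "T3"
    ),
    levels = c("T1", "T2", "T3")
  )
  structure(
    list(spec = tibble(lower_cutoff = q[1], upper_cutoff = q[2]),
         labels = labels),
    class = "tertiles"
  )
}

#' @export
print.tertiles <- function(x, ...) {
  cat(sprintf("<tertiles> cutoffs: %.4g / %.4g; sizes: %s\n",
              x$spec$lower_cutoff, x$spec$upper_cutoff,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Standardize an exposure to z-scores
#'
#' Centers and scales by the sample mean and SD of the analysis subset, so
#' regression slopes on the result are "per SD" effects. The centering and
#' scaling constants are attached as attributes `"center"` and `"scale"`
#' for back-transformation.
#'
#' @param values Numeric vector; missing values are ignored in the
#'   constants and propagated in the output.
#' @return Z-scored numeric vector with attributes `center` and `scale`.
#' @export
standardize_exposure <- function(values) {
  mu <- mean(values, na.rm = TRUE)
  s <- sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) abort("exposure has zero or undefined SD.")
  structure((values - mu) / s, center = mu, scale = s)
}
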