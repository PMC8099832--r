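#' Tidy a two-lines fit
#'
#' @param x A [two_lines_test()] object.
#' @param ... Unused.
#' @return One row per segment: `segment, slope, p_value, n`.
#' @method tidy two_lines
#' @export
tidy.two_lines <- function(x, ...) {
  tibble(
    segment = c("below", "above"),
    cutoff = x$cutoff,
    slope = c(x$slope_below, x$slope_above),
    p_value = c(x$p_below, x$p_above),
    n = c(x$n_below, x$n_above)
  )
}

#' One-row summary of a two-lines fit
#'
#' @param x A [two_lines_test()] object.
#' @param ... Unused.
#' @method glance two_lines
#' @export
glance.two_lines <- function(x, ...) {
  tibble(
    cutoff = x$cutoff,
    slope_below = x$slope_below, slope_above = x$slope_above,
    p_below = x$p_below, p_above = x$p_above,
    u_shape_flag = x$u_shape_flag,
    n_below = x$n_below, n_above = x$n_above
  )
}

#' Per-variant results of an association scan
#'
#' @param x A [gwas_scan()] object.
#' @param ... Unused.
#' @method tidy gwas_scan
#' @export
tidy.gwas_scan <- function(x, ...) x$results

#' One-row summary of an association scan
#'
#' @param x A [gwas_scan()] object.
#' @param ... Unused.
#' @return `lambda_gc, n_variants, n_samples`.
#' @method glance gwas_scan
#' @export
glance.gwas_scan <- function(x, ...) {
  tibble(lambda_gc = x$lambda_gc, n_variants = x$n_variants,
         n_samples = x$n_samples)
}

#' Probe-weight table as a plain tibble
#'
#' @param x A [fit_probe_weights()] result.
#' @param ... Unused.
#' @method tidy probe_weights
#' @export
tidy.probe_weights <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "probe_weights")
  attr(out, "intercept") <- NULL
  attr(out, "n_calibration") <- NULL
  out
}

#' One-row summary of a probe-weight fit
#'
#' @param x A [fit_probe_weights()] result.
#' @param ... Unused.
#' @method glance probe_weights
#' @export
glance.probe_weights <- function(x, ...) {
  tibble(
    n_probes = nrow(x),
    n_selected = sum(x$selected),
    intercept = attr(x, "intercept"),
    n_calibration = attr(x, "n_calibration")
  )
}
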