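#' Manhattan-style plot of an association scan
#'
#' @param object A [gwas_scan()] object.
#' @param variants Optional tibble `variant_id, chrom, pos` for genomic
#'   ordering; without it variants are plotted in input order.
#' @param p_threshold,suggestive Reference lines (defaults 5e-8 and 1e-5).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gwas_scan
#' @export
autoplot.gwas_scan <- function(object, variants = NULL, p_threshold = 5e-8,
                               suggestive = 1e-5, ...) {
  res <- dplyr::filter(object$results, !is.na(.data$p))
  if (!is.null(variants)) {
    res <- dplyr::inner_join(res, variants[c("variant_id", "chrom", "pos")],
                             by = "variant_id") %>%
      arrange(.data$chrom, .data$pos) %>%
      mutate(x = dplyr::row_number(), chrom = factor(.data$chrom))
  } else {
    res <- mutate(res, x = dplyr::row_number(), chrom = factor(1))
  }
  ggplot2::ggplot(res, ggplot2::aes(x = .data$x, y = -log10(.data$p),
                                    colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        colour = "red", linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(suggestive),
                        colour = "blue", linetype = 3) +
    ggplot2::labs(x = "variant", y = expression(-log[10](italic(p))),
                  subtitle = sprintf("lambda[GC] == %.3f", object$lambda_gc)) +
    ggplot2::theme_minimal()
}

#' Plot a two-lines breakpoint fit
#'
#' Scatter of the (possibly subsampled) observations with separate linear
#' fits below and above the selected cutoff.
#'
#' @param object A [two_lines_test()] object.
#' @param max_points Subsample cap for the scatter layer (default 2000).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot two_lines
#' @export
autoplot.two_lines <- function(object, max_points = 2000, ...) {
  d <- object$data
  names(d) <- c("x", "y")
  d$side <- ifelse(d$x <= object$cutoff, "below", "above")
  shown <- if (nrow(d) > max_points) d[sample.int(nrow(d), max_points), ] else d
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = shown, alpha = 0.2, size = 0.6) +
    ggplot2::geom_smooth(ggplot2::aes(group = .data$side),
                         method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red") +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = 2) +
    ggplot2::labs(x = object$x, y = object$y,
                  subtitle = sprintf("cutoff = %g; slopes %+0.3g / %+0.3g",
                                     object$cutoff, object$slope_below,
                                     object$slope_above)) +
    ggplot2::theme_minimal()
}

#' Plot PheWAS results
#'
#' One point per phecode and contrast at -log10(p), triangles up for odds
#' ratios above 1 and down otherwise; the dashed line marks the largest p
#' with q < 0.05 (when any).
#'
#' @param object A [run_phewas()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phewas_result
#' @export
autoplot.phewas_result <- function(object, ...) {
  d <- as_tibble(object) %>%
    mutate(direction = ifelse(.data$odds_ratio > 1, "increased", "reduced"))
  sig <- d$p_value[d$q_value < 0.05]
  pl <- ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$phecode),
                                        y = -log10(.data$p_value),
                                        shape = .data$direction,
                                        colour = .data$contrast)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(increased = 24, reduced = 25)) +
    ggplot2::labs(x = "phecode", y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
  if (length(sig)) {
    pl <- pl + ggplot2::geom_hline(yintercept = -log10(max(sig)),
                                   colour = "red", linetype = 2)
  }
  pl
}

#' Plot calibrated probe weights
#'
#' @param object A [fit_probe_weights()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot probe_weights
#' @export
autoplot.probe_weights <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$weight,
                               y = -log10(.data$p_value),
                               colour = .data$selected)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "stage-2 weight", y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
}
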