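#' Plot a fitted cline
#'
#' Observed per-population allele frequencies (point size proportional to
#' the number of alleles sampled) with the fitted cline curve and a rug at
#' the estimated centre.
#'
#' @param object A [fit_cline()] result.
#' @param n_grid Grid points for the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cline_fit <- function(object, n_grid = 201, ...) {
  obs <- dplyr::filter(object$data, .data$n > 0) |>
    dplyr::mutate(freq = .data$k / .data$n)
  rng <- range(object$data$distance)
  pad <- 0.05 * diff(rng)
  curve <- cline_curve(object$params, rng[1] - pad, rng[2] + pad, n = n_grid)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$distance, y = .data$freq)) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(y = .data$frequency),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_vline(xintercept = object$params$center,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "Transect distance (km)", y = "Allele frequency",
                  size = "Alleles\nsampled",
                  title = object$locus %||% NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ordered-pair cline-shape comparison
#'
#' Deviance matrix as tiles (data marker in rows, shape marker in
#' columns); pairs below the Bonferroni-corrected critical deviance -- not
#' significantly different in shape -- are outlined.
#'
#' @param object A [compare_clines()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cline_comparison <- function(object, ...) {
  td <- tidy(object) |>
    dplyr::mutate(
      data_marker = factor(.data$data_marker, levels = rev(object$markers)),
      shape_marker = factor(.data$shape_marker, levels = object$markers))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$shape_marker,
                                   y = .data$data_marker)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$D), colour = "white") +
    ggplot2::geom_tile(data = dplyr::filter(td, !.data$significant),
                       fill = NA, colour = "dodgerblue", linewidth = 0.9) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", .data$D)),
                       size = 3, colour = "grey20") +
    ggplot2::scale_fill_gradient(low = "aliceblue", high = "firebrick") +
    ggplot2::labs(x = "Shape source", y = "Data source", fill = "D",
                  subtitle = sprintf("critical D = %.2f (df = %d, per-test alpha = %.2g)",
                                     object$critical_D, object$df,
                                     object$alpha_per_test)) +
    ggplot2::theme_minimal()
}
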