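#' Plot a fitted cline
#'
#' Observed per-population frequencies with the fitted cline curve.
#'
#' @param object A `cline_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cline_fit <- function(object, ...) {
  aug <- augment(object)
  grid <- tibble::tibble(
    distance_km = seq(min(aug$distance_km), max(aug$distance_km),
                      length.out = 200))
  p <- object$params
  grid$.fitted <- cline_value(grid$distance_km, centre = p$centre,
                              width = p$width, pmin = p$pmin,
                              pmax = p$pmax,
                              deltaL = p$deltaL, tauL = p$tauL,
                              deltaR = p$deltaR, tauR = p$tauR,
                              model = object$model)
  ggplot2::ggplot(aug, ggplot2::aes(.data$distance_km, .data$observed)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$.fitted),
                       colour = "steelblue") +
    ggplot2::labs(x = "Distance from northern reference (km)",
                  y = "Focal-allele frequency",
                  title = paste("Cline model", object$model)) +
    ggplot2::ylim(0, 1)
}

#' Plot an isolation-by-distance fit
#'
#' Linearised F_ST against log distance with the fitted regression line.
#'
#' @param object An `ibd_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ibd_fit <- function(object, ...) {
  lab <- if (object$n_s_defined) {
    sprintf("slope = %.4g, N[S] == %.3g", object$slope, object$n_s)
  } else "N[S]~undefined"
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(log(.data$distance_km), .data$fst_lin)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "steelblue") +
    ggplot2::labs(x = "ln distance (km)",
                  y = expression(F[ST] / (1 - F[ST])),
                  subtitle = lab)
}

#' Centre-width map of clinal loci
#'
#' Scatter of fitted cline centre against width for classified loci,
#' clinal loci highlighted — the package's analogue of the usual
#' two-dimensional cline-parameter density view.
#'
#' @param calls Classified tibble from [classify_clinal()].
#' @param clinal_only Show only clinal loci (default FALSE).
#' @return A ggplot.
#' @export
plot_cline_params <- function(calls, clinal_only = FALSE) {
  dat <- dplyr::filter(calls, .data$converged, !is.na(.data$centre))
  if (clinal_only) dat <- dplyr::filter(dat, .data$is_clinal)
  ggplot2::ggplot(dat, ggplot2::aes(.data$centre, .data$width,
                                    colour = .data$is_clinal)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Cline centre (km)", y = "Cline width (km)",
                  colour = "Clinal")
}
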