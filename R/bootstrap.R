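#' Parametric bootstrap confidence intervals for a cline fit
#'
#' Resamples data from the fitted cline (binomial draws of allele counts,
#' or Gaussian noise at the profiled scale for environmental fits), refits
#' the same model to each replicate, and returns percentile intervals for
#' the free parameters.
#'
#' @param fit A converged `cline_fit`.
#' @param n_boot Number of bootstrap replicates (default 200).
#' @param level Interval coverage (default 0.95).
#' @param seed Integer; the resampling stream is seeded locally so repeat
#'   calls are identical.
#' @param options A [cline_options()] list used for the refits.
#' @return Tibble with `term`, `estimate`, `conf.low`, `conf.high` and the
#'   number of converged replicates in attribute `"n_converged"`.
#' @export
bootstrap_cline <- function(fit, n_boot = 200, level = 0.95, seed = 1,
                            options = cline_options()) {
  if (!inherits(fit, "cline_fit") || fit$model == "null") {
    stop("bootstrap_cline needs a fitted cline model", call. = FALSE)
  }
  if (!isTRUE(fit$converged)) {
    stop("refusing to bootstrap a non-converged fit", call. = FALSE)
  }
  free <- model_free(fit$model)
  gaussian <- fit$likelihood == "gaussian"
  x <- fit$data$x
  sigma_hat <- if (gaussian) {
    max(sqrt(mean((fit$data$y - fit$fitted)^2)), options$sigma_floor)
  }
  draws <- withr::with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      refit <- if (gaussian) {
        y_b <- fit$fitted + rnorm(length(x), 0, sigma_hat)
        fit_cline(x, y = pmin(pmax(y_b, 0), 1), model = fit$model,
                  options = options)
      } else {
        k_b <- rbinom(length(x), fit$data$n, fit$fitted)
        fit_cline(x, k = k_b, n = fit$data$n, model = fit$model,
                  options = options)
      }
      if (!is.null(refit) && isTRUE(refit$converged)) {
        unlist(refit$params[free])
      }
    })
  })
  draws <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  if (is.null(draws) || nrow(draws) < 10) {
    stop("too few converged bootstrap replicates", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  out <- tibble::tibble(
    term = free,
    estimate = unlist(fit$params[free]),
    conf.low = apply(draws, 2, quantile, alpha),
    conf.high = apply(draws, 2, quantile, 1 - alpha)
  )
  attr(out, "n_converged") <- nrow(draws)
  out
}
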