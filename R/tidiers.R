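#' Tidy a cline fit
#'
#' @param x A `cline_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.cline_fit <- function(x, ...) {
  keep <- if (x$model == "null") "p0" else {
    c(model_free(x$model),
      if (x$model %in% c("I", "III")) c("pmin", "pmax"))
  }
  pars <- unlist(x$params[keep])
  tibble::tibble(term = names(pars), estimate = unname(pars),
                 fixed = !names(pars) %in%
                   if (x$model == "null") "p0" else model_free(x$model))
}

#' @rdname tidy.cline_fit
#' @return `glance()`: one-row tibble with `model`, `loglik`, `k_par`,
#'   `aicc`, `rse`, `converged`.
#' @export
glance.cline_fit <- function(x, ...) {
  tibble::tibble(model = x$model, loglik = x$loglik, k_par = x$k_par,
                 aicc = x$aicc, rse = x$rse, converged = x$converged)
}

#' @rdname tidy.cline_fit
#' @return `augment()`: per-population tibble with observed and fitted
#'   frequencies and residuals.
#' @export
augment.cline_fit <- function(x, ...) {
  obs <- if (x$likelihood == "gaussian") x$data$y else x$data$k / x$data$n
  tibble::tibble(distance_km = x$data$x, observed = obs,
                 .fitted = x$fitted, .resid = obs - x$fitted)
}

#' Tidy a cline model comparison
#'
#' @param x A `cline_comparison` object.
#' @param ... Unused.
#' @return One row per compared model: AICc, Akaike weight, convergence.
#' @export
tidy.cline_comparison <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, mod) {
    tibble::tibble(model = mod, loglik = f$loglik, k_par = f$k_par,
                   aicc = f$aicc,
                   weight = unname(x$weights[mod]),
                   converged = f$converged,
                   best = identical(mod, x$best_model))
  })
}

#' @rdname tidy.cline_comparison
#' @export
glance.cline_comparison <- function(x, ...) {
  tibble::tibble(best_model = x$best_model,
                 evidence_ratio = x$evidence_ratio,
                 aicc_null = x$aicc_null)
}

#' Tidy an isolation-by-distance fit
#'
#' @param x An `ibd_fit` object.
#' @param ... Unused.
#' @return `tidy()`: the regression coefficients; `glance()`: one-row
#'   summary with slope, intercept, R^2 and neighbourhood size;
#'   `augment()`: the per-pair table with fitted values.
#' @export
tidy.ibd_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble::tibble(term = c("intercept", "log(distance_km)"),
                 estimate = unname(s[, 1]), std.error = unname(s[, 2]),
                 statistic = unname(s[, 3]), p.value = unname(s[, 4]))
}

#' @rdname tidy.ibd_fit
#' @export
glance.ibd_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n_s = x$n_s,
                 n_pairs = x$n_pairs)
}

#' @rdname tidy.ibd_fit
#' @export
augment.ibd_fit <- function(x, ...) {
  dplyr::mutate(x$pairs, .fitted = x$intercept +
                  x$slope * log(.data$distance_km),
                .resid = .data$fst_lin - .data$.fitted)
}
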