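#' Options controlling cline fitting
#'
#' @param n_starts Number of space-filling (Halton sequence) starting points
#'   per model (default 20). A moment-based data-informed start is always
#'   added.
#' @param n_polish How many of the best-scoring starts are polished with
#'   bounded L-BFGS-B (default 6).
#' @param end_fix How model I fixes the end frequencies: `"observed"` uses
#'   the observed frequencies of the two transect-end populations;
#'   `"unit"` fixes them at 0 and 1.
#' @param eps Clamp bound on predicted frequencies in the binomial
#'   likelihood.
#' @param sigma_floor Floor on the profiled Gaussian noise scale.
#' @param w_upper_mult Upper bound on width, as a multiple of the transect
#'   length (default 10). A best fit sitting on this bound is flagged
#'   non-converged: it is the signature of a linear gradient with no sharp
#'   transition.
#' @param c_margin Centre bounds extend this fraction of the transect length
#'   beyond each end (default 0.5).
#' @param factr L-BFGS-B `factr` control; the default corresponds to an
#'   objective tolerance of about 1e-8.
#' @return A list of class `cline_options`.
#' @export
cline_options <- function(n_starts = 20, n_polish = 6,
                          end_fix = c("observed", "unit"),
                          eps = 1e-6, sigma_floor = 1e-4,
                          w_upper_mult = 10, c_margin = 0.5,
                          factr = 1e7) {
  opts <- list(n_starts = n_starts, n_polish = n_polish,
               end_fix = match.arg(end_fix), eps = eps,
               sigma_floor = sigma_floor, w_upper_mult = w_upper_mult,
               c_margin = c_margin, factr = factr)
  class(opts) <- "cline_options"
  opts
}

# Free-parameter layout per model: names into the full 8-vector
# (centre, width, pmin, pmax, deltaL, tauL, deltaR, tauR).
model_free <- function(model) {
  switch(model,
    I   = c("centre", "width"),
    II  = c("centre", "width", "pmin", "pmax"),
    III = c("centre", "width", "deltaL", "tauL", "deltaR", "tauR"),
    IV  = c("centre", "width", "pmin", "pmax",
            "deltaL", "tauL", "deltaR", "tauR"),
    stop("unknown model ", model, call. = FALSE))
}

# Deterministic space-filling starts: Halton sequence (radical-inverse in
# coprime bases) scaled to the parameter box.
halton_starts <- function(n, lower, upper) {
  bases <- c(2, 3, 5, 7, 11, 13, 17, 19)
  d <- length(lower)
  h <- vapply(bases[seq_len(d)], function(b) {
    vapply(seq_len(n), function(i) {
      f <- 1; r <- 0
      while (i > 0) {
        f <- f / b
        r <- r + f * (i %% b)
        i <- i %/% b
      }
      r
    }, numeric(1))
  }, numeric(n))
  h <- matrix(h, nrow = n)
  out <- sweep(sweep(h, 2, upper - lower, `*`), 2, lower, `+`)
  # width spans orders of magnitude: place its starts log-uniformly
  wi <- match("width", names(lower))
  if (!is.na(wi)) {
    out[, wi] <- exp(log(lower[wi]) +
                       h[, wi] * (log(upper[wi]) - log(lower[wi])))
  }
  colnames(out) <- names(lower)
  out
}

# Clipped linear-gradient reference model, p(x) = clip(a + b x). A locus
# (or variable) whose best cline model cannot beat this fit carries no
# transition zone: it is excluded as a linear gradient rather than being
# allowed to masquerade as a wide cline.
fit_linear_ref <- function(x, k = NULL, n = NULL, y = NULL,
                           options = cline_options()) {
  gaussian <- !is.null(y)
  m <- length(x)
  k_par <- if (gaussian) 3 else 2
  if (m < k_par + 2) return(NULL)
  p_obs <- if (gaussian) y else k / n
  eps <- options$eps
  pred <- function(par) pmin(pmax(par[1] + par[2] * x, eps), 1 - eps)
  negll <- function(par) {
    p <- pred(par)
    if (gaussian) {
      ss <- sum((y - p)^2)
      s2 <- max(ss / m, options$sigma_floor^2)
      0.5 * m * log(2 * pi * s2) + 0.5 * ss / s2
    } else {
      -sum(k * log(p) + (n - k) * log(1 - p))
    }
  }
  ls <- stats::coef(lm(p_obs ~ x))
  L <- max(x) - min(x)
  best <- NULL
  for (start in list(c(ls[1], ls[2]), c(mean(p_obs), 0))) {
    o <- tryCatch(
      optim(start, negll, method = "L-BFGS-B",
            lower = c(-2, -4 / L), upper = c(3, 4 / L),
            control = list(factr = options$factr)),
      error = function(e) NULL)
    if (!is.null(o) && is.finite(o$value) &&
        (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) return(NULL)
  const <- if (gaussian) 0 else sum(lchoose(n, k))
  ll <- -best$value + const
  list(loglik = ll, k_par = k_par,
       aicc = if (m > k_par + 1) aicc(ll, k_par, m) else NA_real_,
       intercept = unname(best$par[1]), slope = unname(best$par[2]))
}

#' Fit one cline model to one locus (or variable)
#'
#' Bounded multistart maximum-likelihood fit of a single model. Starting
#' points come from a deterministic space-filling design over the parameter
#' box (plus one moment-based start); the best candidates are polished with
#' L-BFGS-B. Fits whose best width sits on its upper bound are retained but
#' flagged `converged = FALSE` - that is how loci with linear frequency
#' gradients (width effectively infinite, no transition zone) are excluded
#' downstream.
#'
#' @param x Transect positions (km), one per population.
#' @param k,n Allele counts and totals (binomial likelihood), or
#' @param y continuous response in \[0, 1\] (Gaussian likelihood).
#' @param model `"I"`, `"II"`, `"III"`, `"IV"` or `"null"`.
#' @param options A [cline_options()] list.
#' @return Object of class `cline_fit`: parameters, `loglik`, `k_par`,
#'   `aicc`, `rse`, `converged`, plus the data. `NULL` (with a message)
#'   when there are fewer populations than `k + 1` parameters.
#' @export
fit_cline <- function(x, k = NULL, n = NULL, y = NULL, model = "I",
                      options = cline_options()) {
  gaussian <- !is.null(y)
  likelihood <- if (gaussian) "gaussian" else "binomial"
  m <- length(x)
  k_par <- model_k(model, likelihood)
  if (m < k_par + 1) {
    message("model ", model, " skipped: ", m, " populations < ",
            k_par + 1, " (parameters + 1)")
    return(NULL)
  }
  ord <- order(x)
  x <- x[ord]
  if (gaussian) y <- y[ord] else { k <- k[ord]; n <- n[ord] }
  p_obs <- if (gaussian) y else k / n
  L <- max(x) - min(x)

  full0 <- c(centre = mean(range(x)), width = L / 4, pmin = 0, pmax = 1,
             deltaL = 0, tauL = 1, deltaR = 0, tauR = 1)
  negll_full <- function(full) {
    if (gaussian) {
      cline_negll_gauss_cpp(x, y, full[1], full[2], full[3], full[4],
                            full[5], full[6], full[7], full[8],
                            has_tails(model), options$sigma_floor)
    } else {
      cline_negll_binom_cpp(x, k, n, full[1], full[2], full[3], full[4],
                            full[5], full[6], full[7], full[8],
                            has_tails(model), options$eps)
    }
  }
  const <- if (gaussian) 0 else sum(lchoose(n, k))

  if (model == "null") {
    p0 <- if (gaussian) mean(y) else {
      min(max(sum(k) / sum(n), options$eps), 1 - options$eps)
    }
    full <- full0; full["pmin"] <- p0; full["pmax"] <- p0
    ll <- -negll_full(full) + const
    fitted <- rep(p0, m)
    rse <- fit_rse_vec(p_obs, fitted, k_par)
    out <- list(model = "null",
                params = as.list(c(full, p0 = unname(p0))),
                loglik = ll, k_par = k_par,
                aicc = if (m > k_par + 1) aicc(ll, k_par, m) else NA_real_,
                rse = rse, converged = TRUE, likelihood = likelihood,
                data = list(x = x, k = k, n = n, y = y), fitted = fitted)
    class(out) <- "cline_fit"
    return(out)
  }

  if (model %in% c("I", "III")) {
    if (options$end_fix == "observed") {
      full0["pmin"] <- p_obs[1]
      full0["pmax"] <- p_obs[m]
    } else {
      full0["pmin"] <- 0
      full0["pmax"] <- 1
    }
  }

  free <- model_free(model)
  lower <- c(centre = min(x) - options$c_margin * L, width = 1,
             pmin = 0, pmax = 0, deltaL = 0, tauL = 0,
             deltaR = 0, tauR = 0)[free]
  upper <- c(centre = max(x) + options$c_margin * L,
             width = options$w_upper_mult * L,
             pmin = 1, pmax = 1, deltaL = L, tauL = 1,
             deltaR = L, tauR = 1)[free]

  free_idx <- match(free, names(full0))
  obj <- function(par) {
    full <- full0
    full[free_idx] <- par
    negll_full(full)
  }
  grad_step <- 1e-7 * (upper - lower) + 1e-10
  obj_grad <- function(par) {
    full <- full0
    full[free_idx] <- par
    if (gaussian) {
      cline_negll_gauss_grad_cpp(x, y, full, free_idx - 1L, grad_step,
                                 has_tails(model), options$sigma_floor)
    } else {
      cline_negll_binom_grad_cpp(x, k, n, full, free_idx - 1L, grad_step,
                                 has_tails(model), options$eps)
    }
  }

  # moment-based start: centre at the steepest observed change
  steps <- abs(diff(p_obs)) / pmax(diff(x), 1e-9)
  i_star <- which.max(steps)
  data_start <- c(centre = (x[i_star] + x[i_star + 1]) / 2, width = L / 4,
                  pmin = max(min(p_obs), 0), pmax = min(max(p_obs), 1),
                  deltaL = L / 10, tauL = 0.5,
                  deltaR = L / 10, tauR = 0.5)[free]
  starts <- rbind(halton_starts(options$n_starts, lower, upper), data_start)
  scores <- apply(starts, 1, obj)
  polish <- utils::head(order(scores), options$n_polish)

  best <- NULL
  for (i in polish) {
    o <- tryCatch(
      optim(starts[i, ], obj, gr = obj_grad, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(factr = options$factr, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(o) && is.finite(o$value) &&
        (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) {
    # fall back to the best raw start so the locus is never silently lost
    best <- list(par = starts[which.min(scores), ],
                 value = min(scores), convergence = 1L)
  }

  full <- full0
  full[free] <- best$par
  ll <- -best$value + const
  w_hat <- full[["width"]]
  at_bound <- w_hat >= 0.999 * options$w_upper_mult * L
  converged <- best$convergence == 0 && is.finite(ll) && !at_bound
  fitted <- cline_pred_cpp(x, full[1], full[2], full[3], full[4],
                           full[5], full[6], full[7], full[8],
                           has_tails(model))
  out <- list(model = model, params = as.list(full), loglik = ll,
              k_par = k_par,
              aicc = if (m > k_par + 1) aicc(ll, k_par, m) else NA_real_,
              rse = fit_rse_vec(p_obs, fitted, k_par),
              converged = converged, width_at_bound = at_bound,
              likelihood = likelihood,
              data = list(x = x, k = k, n = n, y = y), fitted = fitted)
  class(out) <- "cline_fit"
  out
}

# residual standard error between observed and fitted frequencies
fit_rse_vec <- function(obs, fitted, k_par) {
  m <- length(obs)
  if (m <= k_par) return(NA_real_)
  sqrt(sum((obs - fitted)^2) / (m - k_par))
}

#' Residual standard error of a cline fit
#'
#' `sqrt(sum((observed - fitted)^2) / (n_pops - k))` with `k` the model's
#' free-parameter count; `NA` when there are not more populations than
#' parameters.
#'
#' @param fit A `cline_fit` object.
#' @return Length-1 numeric.
#' @export
fit_rse <- function(fit) {
  obs <- if (fit$likelihood == "gaussian") fit$data$y else
    fit$data$k / fit$data$n
  fit_rse_vec(obs, fit$fitted, fit$k_par)
}

#' @exportS3Method base::print
print.cline_fit <- function(x, ...) {
  cat("Cline fit, model ", x$model, " (", x$likelihood, " likelihood)\n",
      sep = "")
  if (x$model != "null") {
    cat(sprintf("  centre %.2f km, width %.2f km, pmin %.3f, pmax %.3f\n",
                x$params$centre, x$params$width,
                x$params$pmin, x$params$pmax))
  } else {
    cat(sprintf("  p0 %.3f\n", x$params$p0))
  }
  cat(sprintf("  loglik %.4f, k %d, AICc %.4f, RSE %.4f, converged: %s\n",
              x$loglik, x$k_par, x$aicc, x$rse, x$converged))
  invisible(x)
}

#' Fit and compare all cline models at one locus
#'
#' Fits the requested models plus the uniform null, selects the best model
#' by lowest AICc among converged cline fits (ties broken toward fewer
#' parameters), computes Akaike weights over the compared models, and the
#' evidence ratio of the best model against the null,
#' `exp((AICc_null - AICc_best) / 2)`. When no cline model converges the
#' locus gets `evidence_ratio = 0` and no best model.
#'
#' @inheritParams fit_cline
#' @param models Character vector of cline models to fit.
#' @return Object of class `cline_comparison`: list with `fits` (named
#'   list of `cline_fit`), `best_model`, `weights`, `evidence_ratio`.
#' @export
fit_cline_models <- function(x, k = NULL, n = NULL, y = NULL,
                             models = CLINE_MODELS,
                             options = cline_options(),
                             linear_exclusion = TRUE) {
  fits <- lapply(c(models, "null"), function(mod) {
    fit_cline(x, k = k, n = n, y = y, model = mod, options = options)
  })
  names(fits) <- c(models, "null")
  fits <- fits[!vapply(fits, is.null, logical(1))]
  linear <- if (linear_exclusion) {
    fit_linear_ref(x, k = k, n = n, y = y, options = options)
  }
  compare_cline_models(fits, linear = linear)
}

#' Compare fitted cline models against the uniform null
#'
#' @param fits Named list of `cline_fit` objects including a `"null"` fit.
#' @param linear Optional linear-gradient reference fit (from the internal
#'   clipped-linear model); when it matches or beats the best cline model
#'   on AICc the locus is excluded as a linear gradient.
#' @return See [fit_cline_models()].
#' @export
compare_cline_models <- function(fits, linear = NULL) {
  if (!"null" %in% names(fits)) {
    stop("fits must include the null model", call. = FALSE)
  }
  cline_names <- setdiff(names(fits), "null")
  ok <- vapply(fits[cline_names], function(f) {
    isTRUE(f$converged) && is.finite(f$aicc)
  }, logical(1))
  aicc_null <- fits$null$aicc
  aicc_linear <- if (!is.null(linear)) linear$aicc else NA_real_

  non_clinal <- function(reason) {
    out <- list(fits = fits, best_model = NA_character_,
                weights = c(null = 1), evidence_ratio = 0,
                aicc_null = aicc_null, aicc_linear = aicc_linear,
                linear_excluded = identical(reason, "linear"))
    class(out) <- "cline_comparison"
    out
  }
  if (!any(ok)) return(non_clinal("none_converged"))

  conv <- cline_names[ok]
  aiccs <- vapply(fits[conv], `[[`, numeric(1), "aicc")
  kpars <- vapply(fits[conv], `[[`, numeric(1), "k_par")
  tied <- aiccs <= min(aiccs) + 1e-9   # ties go to the simpler model
  best_i <- which(conv == conv[tied][which.min(kpars[tied])])
  best_model <- conv[best_i]

  # no transition zone: there is a real gradient (linear beats uniform)
  # but a plain linear gradient explains it at least as well as any cline.
  # A flat locus is best described by the null, never excluded here.
  if (is.finite(aicc_linear) && aicc_linear <= aiccs[best_i] &&
      aicc_linear < aicc_null) {
    return(non_clinal("linear"))
  }

  compared <- c(conv, "null")
  all_aicc <- c(aiccs, null = aicc_null)
  rel <- exp(-0.5 * (all_aicc - min(all_aicc)))
  weights <- rel / sum(rel)
  names(weights) <- compared
  er <- exp((aicc_null - aiccs[best_i]) / 2)

  out <- list(fits = fits, best_model = best_model, weights = weights,
              evidence_ratio = unname(er), aicc_null = aicc_null,
              aicc_linear = aicc_linear, linear_excluded = FALSE)
  class(out) <- "cline_comparison"
  out
}

#' @exportS3Method base::print
print.cline_comparison <- function(x, ...) {
  cat("Cline model comparison\n")
  if (is.na(x$best_model)) {
    cat("  no converged cline model; locus is non-clinal\n")
  } else {
    best <- x$fits[[x$best_model]]
    cat(sprintf("  best model %s: centre %.1f km, width %.1f km\n",
                x$best_model, best$params$centre, best$params$width))
    cat(sprintf("  evidence ratio vs null: %.4g\n", x$evidence_ratio))
  }
  invisible(x)
}

#' Fit clines to every locus of a counts table
#'
#' Per-locus pipeline stage: joins counts with the transect geometry,
#' re-polarises each locus so the southern-half mean frequency is at least
#' the northern-half mean (flip recorded in `polarity`; `p_north`/`p_south`
#' report end frequencies on the original focal-allele scale), fits the
#' requested models plus the null, and summarises the comparison.
#'
#' @param counts Long counts tibble (`locus_id`, `population_id`, `k`, `n`).
#' @param geometry Geometry tibble with `distance_km`.
#' @param models Cline models to fit (default all four).
#' @param options A [cline_options()] list.
#' @return Tibble, one row per locus: `locus_id`, `polarity`, `best_model`,
#'   `centre`, `width`, `pmin`, `pmax`, `deltaL`, `tauL`, `deltaR`, `tauR`,
#'   `delta_p`, `p_north`, `p_south`, `loglik`, `k_par`, per-model AICc
#'   columns, `evidence_ratio`, `rse`, `converged`.
#' @export
fit_clines <- function(counts, geometry, models = CLINE_MODELS,
                       options = cline_options()) {
  geo <- dplyr::select(geometry, "population_id", "distance_km")
  tab <- dplyr::inner_join(counts, geo, by = "population_id")
  tab <- dplyr::arrange(tab, .data$locus_id, .data$distance_km)
  if (any(tab$n == 0)) {
    stop("counts contain populations with n = 0; run filter_counts() first",
         call. = FALSE)
  }
  by_locus <- split(seq_len(nrow(tab)), tab$locus_id)
  rows <- lapply(names(by_locus), function(loc) {
    idx <- by_locus[[loc]]
    fit_clines_one(loc, tab$distance_km[idx], tab$k[idx], tab$n[idx],
                   models, options)
  })
  dplyr::bind_rows(rows)
}

fit_clines_one <- function(locus_id, x, k, n, models, options) {
  p_obs <- k / n
  south <- x > stats::median(x)
  north <- x < stats::median(x)
  if (!any(south)) south <- x >= stats::median(x)
  if (!any(north)) north <- x <= stats::median(x)
  flipped <- mean(p_obs[south]) < mean(p_obs[north])
  if (flipped) k <- n - k
  cmp <- fit_cline_models(x, k = k, n = n, models = models,
                          options = options)
  summarise_comparison(cmp, locus_id = locus_id, flipped = flipped,
                       models = models)
}

summarise_comparison <- function(cmp, locus_id, flipped, models,
                                 id_col = "locus_id") {
  best <- if (!is.na(cmp$best_model)) cmp$fits[[cmp$best_model]] else NULL
  pars <- if (!is.null(best)) best$params else
    list(centre = NA_real_, width = NA_real_, pmin = NA_real_,
         pmax = NA_real_, deltaL = NA_real_, tauL = NA_real_,
         deltaR = NA_real_, tauR = NA_real_)
  aicc_cols <- lapply(c(models, "null"), function(mod) {
    f <- cmp$fits[[mod]]
    if (is.null(f)) NA_real_ else f$aicc
  })
  names(aicc_cols) <- paste0("aicc_", c(models, "null"))
  pmin_fit <- pars$pmin; pmax_fit <- pars$pmax
  row <- tibble::tibble(
    polarity = if (flipped) "flipped" else "as-is",
    best_model = cmp$best_model,
    centre = pars$centre, width = pars$width,
    pmin = pmin_fit, pmax = pmax_fit,
    deltaL = if (!is.null(best) && has_tails(best$model))
      pars$deltaL else NA_real_,
    tauL = if (!is.null(best) && has_tails(best$model))
      pars$tauL else NA_real_,
    deltaR = if (!is.null(best) && has_tails(best$model))
      pars$deltaR else NA_real_,
    tauR = if (!is.null(best) && has_tails(best$model))
      pars$tauR else NA_real_,
    delta_p = abs(pmax_fit - pmin_fit),
    p_north = if (flipped) 1 - pmin_fit else pmin_fit,
    p_south = if (flipped) 1 - pmax_fit else pmax_fit,
    loglik = if (!is.null(best)) best$loglik else NA_real_,
    k_par = if (!is.null(best)) best$k_par else NA_integer_,
    evidence_ratio = cmp$evidence_ratio,
    rse = if (!is.null(best)) best$rse else NA_real_,
    converged = !is.null(best),
    linear_excluded = isTRUE(cmp$linear_excluded),
    aicc_linear = cmp$aicc_linear %||% NA_real_
  )
  row <- dplyr::bind_cols(tibble::tibble(!!id_col := locus_id), row,
                          tibble::as_tibble(aicc_cols))
  row
}

#' Fit clines to normalised environmental variables
#'
#' Applies the cline machinery to each (non-constant) variable of an
#' environmental table under the Gaussian likelihood, after the same
#' south-vs-north polarisation used for alleles.
#'
#' @param env Long environmental tibble from [read_env_table()].
#' @param geometry Geometry tibble.
#' @inheritParams fit_clines
#' @return Tibble, one row per non-constant variable, same columns as
#'   [fit_clines()] but keyed by `variable_id` (no `p_north`/`p_south`).
#' @export
fit_env_clines <- function(env, geometry, models = CLINE_MODELS,
                           options = cline_options()) {
  skipped <- unique(env$variable_id[env$constant])
  if (length(skipped) > 0) {
    message("skipped constant variable(s): ",
            paste(skipped, collapse = ", "))
  }
  env <- dplyr::filter(env, !.data$constant)
  geo <- dplyr::select(geometry, "population_id", "distance_km")
  tab <- dplyr::inner_join(env, geo, by = "population_id")
  tab <- dplyr::arrange(tab, .data$variable_id, .data$distance_km)
  rows <- lapply(split(seq_len(nrow(tab)), tab$variable_id), function(idx) {
    x <- tab$distance_km[idx]
    y <- tab$value_norm[idx]
    south <- x > stats::median(x); north <- x < stats::median(x)
    flipped <- mean(y[south]) < mean(y[north])
    if (flipped) y <- 1 - y
    cmp <- fit_cline_models(x, y = y, models = models, options = options)
    summarise_comparison(cmp, locus_id = tab$variable_id[idx[1]],
                         flipped = flipped, models = models,
                         id_col = "variable_id")
  })
  out <- dplyr::bind_rows(rows)
  dplyr::select(out, -dplyr::any_of(c("p_north", "p_south")))
}
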