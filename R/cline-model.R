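#' Cline model identifiers
#'
#' Four Szymura-Barton-style models plus a uniform null:
#' * `"I"`   - sigmoid, centre `c` and width `w` free, end frequencies fixed;
#' * `"II"`  - sigmoid, `c`, `w`, `pmin`, `pmax` free;
#' * `"III"` - model I plus exponential tails (`deltaL`, `tauL`, `deltaR`,
#'   `tauR`);
#' * `"IV"`  - model II plus tails;
#' * `"null"` - a single uniform frequency `p0`.
#' @name cline-models
NULL

CLINE_MODELS <- c("I", "II", "III", "IV")

# free parameters per model under the binomial likelihood;
# Gaussian adds one for the profiled noise scale.
model_k <- function(model, likelihood = c("binomial", "gaussian")) {
  likelihood <- match.arg(likelihood)
  base <- c(null = 1, I = 2, II = 4, III = 6, IV = 8)[[model]]
  if (likelihood == "gaussian") base + 1 else base
}

has_tails <- function(model) model %in% c("III", "IV")

#' Evaluate a geographic cline
#'
#' Predicted focal-allele frequency at transect position `x` (km). The
#' sigmoid core is `pmin + (pmax - pmin) / (1 + exp(-4 (x - c) / w))`, so
#' the maximum slope at the centre is `(pmax - pmin) / w`. Stepped models
#' (III, IV) switch to exponential tails beyond `c - deltaL` and
#' `c + deltaR`, continuous with the core at the junctions, with tail
#' steepness a fraction `tauL`/`tauR` of the junction slope. The null model
#' returns the uniform frequency `pmin` everywhere.
#'
#' @param x Numeric positions along the transect, km.
#' @param centre,width Cline centre and width, km (`width > 0`).
#' @param pmin,pmax End frequencies (for `model = "null"`, `pmin` is the
#'   uniform frequency `p0`).
#' @param deltaL,tauL,deltaR,tauR Tail parameters (stepped models only).
#' @param model One of `"I"`, `"II"`, `"III"`, `"IV"`, `"null"`.
#' @return Numeric vector of predicted frequencies.
#' @export
#' @examples
#' cline_value(650, centre = 650, width = 300)          # 0.5
#' cline_value(725, centre = 650, width = 300)          # 1/(1 + exp(-1))
cline_value <- function(x, centre, width, pmin = 0, pmax = 1,
                        deltaL = 0, tauL = 1, deltaR = 0, tauR = 1,
                        model = "I") {
  if (model == "null") return(rep(pmin, length(x)))
  if (width <= 0) stop("cline width must be > 0", call. = FALSE)
  cline_pred_cpp(as.numeric(x), centre, width, pmin, pmax,
                 deltaL, tauL, deltaR, tauR, has_tails(model))
}

#' Cline log-likelihood
#'
#' Binomial form (allele counts): sum over populations of
#' `log C(n, k) + k log P + (n - k) log(1 - P)`, with predictions clamped
#' to `[eps, 1 - eps]`. Gaussian form (continuous responses such as
#' normalised bioclimatic values): normal likelihood with the noise scale
#' profiled out by its MLE, floored at `sigma_floor`.
#'
#' @param x Transect positions, km.
#' @param k,n Focal-allele and total sampled copies per population
#'   (binomial form).
#' @param y Continuous response per population (Gaussian form).
#' @inheritParams cline_value
#' @param eps Clamp bound for predicted frequencies (default 1e-6).
#' @param sigma_floor Lower bound on the profiled Gaussian sigma
#'   (default 1e-4).
#' @return Log-likelihood (natural log), a length-1 numeric.
#' @export
cline_loglik <- function(x, k = NULL, n = NULL, y = NULL,
                         centre = 0, width = 1, pmin = 0, pmax = 1,
                         deltaL = 0, tauL = 1, deltaR = 0, tauR = 1,
                         model = "I", eps = 1e-6, sigma_floor = 1e-4) {
  if (model == "null") {
    # constant frequency: reuse the core with degenerate ends
    pmax <- pmin
    width <- 1
  }
  if (!is.null(y)) {
    return(-cline_negll_gauss_cpp(as.numeric(x), as.numeric(y),
                                  centre, width, pmin, pmax,
                                  deltaL, tauL, deltaR, tauR,
                                  has_tails(model), sigma_floor))
  }
  if (any(k > n)) stop("k cannot exceed n", call. = FALSE)
  -cline_negll_binom_cpp(as.numeric(x), as.numeric(k), as.numeric(n),
                         centre, width, pmin, pmax,
                         deltaL, tauL, deltaR, tauR,
                         has_tails(model), eps) +
    sum(lchoose(n, k))
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1)/(n - k - 1)` with `n` the number of
#' populations (the response units are population frequencies).
#'
#' @param loglik Log-likelihood.
#' @param k Number of free parameters (>= 1).
#' @param n Number of populations; must exceed `k + 1`.
#' @return AICc value.
#' @export
#' @examples
#' aicc(-10, 2, 12)  # 25.3333...
aicc <- function(loglik, k, n) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (n <= k + 1) {
    stop("AICc undefined: need n > k + 1 populations", call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}
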