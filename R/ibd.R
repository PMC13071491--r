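#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Vectorised over
#' any argument.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
#' @examples
#' geodesic_km(69.06, 22.55, 68.06, 22.55)  # ~one degree of meridian arc
geodesic_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("invalid coordinates", call. = FALSE)
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371008.8) / 1000
}

#' Isolation-by-distance regression and neighbourhood size
#'
#' Ordinary least squares of linearised genetic distance,
#' F_ST / (1 - F_ST), on the natural log of geographic distance (km),
#' following Rousset's one-dimensional IBD expectation. The inverse of the
#' slope estimates the neighbourhood size N_S, used downstream as a proxy
#' for the dispersal variance in s = N_S / w^2. N_S is undefined (NA, with
#' a flag) when the slope is not positive.
#'
#' @param fst Pairwise F_ST table from [pairwise_fst()] (or any tibble with
#'   `pop_i`, `pop_j`, `theta`).
#' @param geometry Geometry tibble with coordinates.
#' @param subset Optional character vector of population ids; only pairs
#'   within the subset are used (e.g. northern-only runs).
#' @return An object of class `ibd_fit`: a list with elements `slope`,
#'   `intercept`, `r_squared`, `n_s`, `n_pairs`, `pairs` (the per-pair
#'   tibble) and the underlying `lm` fit. `tidy()`/`glance()` methods apply.
#' @export
ibd_regression <- function(fst, geometry, subset = NULL) {
  geo <- geometry
  if (!is.null(subset)) {
    geo <- dplyr::filter(geo, .data$population_id %in% subset)
  }
  pairs <- fst |>
    dplyr::filter(.data$pop_i %in% geo$population_id,
                  .data$pop_j %in% geo$population_id) |>
    dplyr::left_join(dplyr::select(geo, "population_id",
                                   lat_i = "latitude", lon_i = "longitude"),
                     by = c(pop_i = "population_id")) |>
    dplyr::left_join(dplyr::select(geo, "population_id",
                                   lat_j = "latitude", lon_j = "longitude"),
                     by = c(pop_j = "population_id")) |>
    dplyr::mutate(
      distance_km = geodesic_km(.data$lat_i, .data$lon_i,
                                .data$lat_j, .data$lon_j),
      fst_lin = .data$theta / (1 - .data$theta)
    )
  zero_d <- pairs$distance_km <= 0
  if (any(zero_d)) {
    warning(sum(zero_d), " pair(s) at zero distance dropped", call. = FALSE)
  }
  pairs <- dplyr::filter(pairs, .data$distance_km > 0, !is.na(.data$fst_lin))
  if (nrow(pairs) < 3) {
    stop("need at least 3 population pairs with defined F_ST and distance",
         call. = FALSE)
  }
  fit <- lm(fst_lin ~ log(distance_km), data = pairs)
  slope <- unname(coef(fit)[2])
  tss <- sum((pairs$fst_lin - mean(pairs$fst_lin))^2)
  out <- list(
    slope = slope,
    intercept = unname(coef(fit)[1]),
    r_squared = if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else
      NA_real_,
    n_s = if (slope > 0) 1 / slope else NA_real_,
    n_s_defined = slope > 0,
    n_pairs = nrow(pairs),
    pairs = dplyr::select(pairs, "pop_i", "pop_j", "theta",
                          "distance_km", "fst_lin"),
    lm = fit
  )
  class(out) <- "ibd_fit"
  out
}

#' @exportS3Method base::print
print.ibd_fit <- function(x, ...) {
  cat("Isolation-by-distance fit (", x$n_pairs, " pairs)\n", sep = "")
  cat(sprintf("  slope     %.6g per ln(km)\n", x$slope))
  cat(sprintf("  intercept %.6g\n", x$intercept))
  cat(sprintf("  R^2       %.3f\n", x$r_squared))
  if (x$n_s_defined) {
    cat(sprintf("  N_S       %.4g\n", x$n_s))
  } else {
    cat("  N_S       undefined (non-positive slope)\n")
  }
  invisible(x)
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries, with significance from
#' simultaneous row/column permutations of the second matrix. The p-value
#' is two-sided on |rho|: p = (1 + #\{|rho_perm| >= |rho_obs|\}) /
#' (1 + n_perm).
#'
#' @param m1,m2 Symmetric matrices over the same populations.
#' @param n_perm Number of permutations (>= 99; default 9999).
#' @param seed Optional integer; when supplied the permutation stream is
#'   seeded locally so repeat calls are bit-identical and the caller's RNG
#'   state is untouched.
#' @return Tibble with `rho`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(m1, m2, n_perm = 9999, seed = NULL) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!isSymmetric(unname(m1)) || !isSymmetric(unname(m2))) {
    stop("mantel_test requires symmetric matrices", call. = FALSE)
  }
  if (!all(dim(m1) == dim(m2))) {
    stop("matrices must have identical dimensions", call. = FALSE)
  }
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  rho <- cor(v1, m2[lt])
  run <- function() {
    n <- nrow(m2)
    count <- 0L
    for (i in seq_len(n_perm)) {
      p <- sample.int(n)
      if (abs(cor(v1, m2[p, p][lt])) >= abs(rho)) count <- count + 1L
    }
    count
  }
  count <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble::tibble(rho = rho, p_value = (1 + count) / (1 + n_perm),
                 n_perm = n_perm)
}
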