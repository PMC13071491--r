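#' Weir-Cockerham variance components for one locus
#'
#' Moments-based F_ST estimator computed on allele counts, i.e. the
#' haploid-sampling form of the Weir-Cockerham ANOVA: each sampled allele
#' copy is a Bernoulli draw, so the among-individual component `b` is zero
#' by construction and theta = a / (a + c). Negative estimates are retained,
#' never truncated. A locus monomorphic across all populations has zero
#' total variance and theta is recorded as `NA`.
#'
#' @param k Integer vector, focal-allele copies per population.
#' @param n Integer vector, sampled allele copies per population (each >= 2).
#' @return One-row tibble with `a`, `b`, `c`, `theta`.
#' @export
#' @examples
#' wc_fst_locus(c(0, 20), c(20, 20))  # fixed difference: theta = 1
wc_fst_locus <- function(k, n) {
  stopifnot(length(k) == length(n), length(k) >= 2)
  if (any(n < 2)) {
    stop("wc_fst_locus requires n >= 2 allele copies in every population",
         call. = FALSE)
  }
  comp <- wc_components(matrix(k, nrow = 1), matrix(n, nrow = 1))
  tibble::tibble(a = comp$a, b = 0, c = comp$c,
                 theta = ifelse(comp$a + comp$c > 0,
                                comp$a / (comp$a + comp$c), NA_real_))
}

# Vectorised over loci (rows of k_mat / n_mat); columns are populations.
# One-way ANOVA on allele indicators:
#   MSA = sum n_i (p_i - pbar)^2 / (r - 1)
#   MSW = sum n_i p_i (1 - p_i) / (N - r)
#   n_c = (N - sum n_i^2 / N) / (r - 1)
#   a = (MSA - MSW) / n_c,  c = MSW
wc_components <- function(k_mat, n_mat) {
  r <- ncol(k_mat)
  N <- rowSums(n_mat)
  p <- k_mat / n_mat
  pbar <- rowSums(k_mat) / N
  msa <- rowSums(n_mat * (p - pbar)^2) / (r - 1)
  msw <- rowSums(n_mat * p * (1 - p)) / (N - r)
  n_c <- (N - rowSums(n_mat^2) / N) / (r - 1)
  list(a = (msa - msw) / n_c, c = msw)
}

#' Pairwise multilocus F_ST matrix
#'
#' Weir-Cockerham theta for every pair of populations, combining loci as a
#' ratio of summed variance components (ratio of averages). Loci where
#' either population of a pair has fewer than 2 sampled copies are skipped
#' for that pair; pairs with no informative locus get `NA` with a warning.
#'
#' @param counts Long counts tibble (see [read_vcf_counts()]).
#' @param geometry Geometry tibble; defines the population set and order.
#' @return Tibble `pop_i`, `pop_j`, `theta`, `n_loci_used` for all unordered
#'   pairs, with the symmetric matrix in attribute `"matrix"`.
#' @export
pairwise_fst <- function(counts, geometry) {
  pops <- geometry$population_id
  if (length(pops) < 2) stop("need >= 2 populations", call. = FALSE)
  wide_k <- counts |>
    dplyr::select("locus_id", "population_id", "k") |>
    tidyr::pivot_wider(names_from = "population_id", values_from = "k")
  wide_n <- counts |>
    dplyr::select("locus_id", "population_id", "n") |>
    tidyr::pivot_wider(names_from = "population_id", values_from = "n")
  k_mat <- as.matrix(wide_k[, pops, drop = FALSE])
  n_mat <- as.matrix(wide_n[, pops, drop = FALSE])

  pairs <- utils::combn(seq_along(pops), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    use <- n_mat[, i1] >= 2 & n_mat[, i2] >= 2
    kk <- k_mat[use, c(i1, i2), drop = FALSE]
    nn <- n_mat[use, c(i1, i2), drop = FALSE]
    comp <- wc_components(kk, nn)
    denom <- sum(comp$a + comp$c)
    informative <- sum(comp$a + comp$c > 0)
    theta <- if (nrow(kk) == 0 || denom == 0) NA_real_ else
      sum(comp$a) / denom
    tibble::tibble(pop_i = pops[i1], pop_j = pops[i2],
                   theta = theta, n_loci_used = informative)
  })
  if (anyNA(res$theta)) {
    warning(sum(is.na(res$theta)),
            " population pair(s) had no informative locus", call. = FALSE)
  }
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  m[cbind(match(res$pop_i, pops), match(res$pop_j, pops))] <- res$theta
  m[cbind(match(res$pop_j, pops), match(res$pop_i, pops))] <- res$theta
  attr(res, "matrix") <- m
  res
}

#' Extract the symmetric F_ST matrix from a pairwise table
#'
#' @param fst Result of [pairwise_fst()].
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
fst_matrix <- function(fst) {
  m <- attr(fst, "matrix")
  if (is.null(m)) {
    pops <- sort(unique(c(fst$pop_i, fst$pop_j)))
    m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
    m[cbind(match(fst$pop_i, pops), match(fst$pop_j, pops))] <- fst$theta
    m[cbind(match(fst$pop_j, pops), match(fst$pop_i, pops))] <- fst$theta
  }
  m
}
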