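# Shared fixture builders. Everything is generated in code; no stored data.

# evenly spaced meridian transect without jitter, exact distances
test_geometry <- function(n_pops = 12, length_km = 1400, n_diploid = 15) {
  km_per_deg <- pi * 6371.0088 / 180
  d <- seq(0, length_km, length.out = n_pops)
  as_geometry(tibble::tibble(
    population_id = sprintf("P%02d", seq_len(n_pops)),
    latitude = 69.06 - d / km_per_deg,
    longitude = 22.55,
    n_diploid = n_diploid
  ))
}

# minimal VCF writer for io tests: gt is a loci x samples character matrix
write_test_vcf <- function(path, gt, chrom = NULL, pos = NULL,
                           alt = NULL) {
  n_loci <- nrow(gt)
  if (is.null(chrom)) chrom <- rep("chr1", n_loci)
  if (is.null(pos)) pos <- seq_len(n_loci) * 100L
  if (is.null(alt)) alt <- rep("T", n_loci)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  body <- paste(chrom, pos, paste0(chrom, ":", pos), "A", alt, ".",
                "PASS", ".", "GT", apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  path
}

# independent model-I grid-search oracle: plain-R sigmoid + binomial
# log-likelihood maximised over a (centre, width) grid
grid_oracle_model1 <- function(x, k, n, pmin, pmax,
                               c_range, w_range, n_grid = 101) {
  cs <- seq(c_range[1], c_range[2], length.out = n_grid)
  ws <- seq(w_range[1], w_range[2], length.out = n_grid)
  best <- list(loglik = -Inf)
  const <- sum(lchoose(n, k))
  for (w in ws) {
    # vectorise over centres: matrix (n_grid x n_pops)
    p <- pmin + (pmax - pmin) /
      (1 + exp(-4 * outer(-cs, x, `+`) / w))
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    ll <- const + drop(log(p) %*% k + log(1 - p) %*% (n - k))
    i <- which.max(ll)
    if (ll[i] > best$loglik) {
      best <- list(loglik = ll[i], centre = cs[i], width = w)
    }
  }
  best
}

# Weir-Cockerham oracle via base aov on per-copy allele indicators,
# an independent route to the same variance components
wc_aov_oracle <- function(k, n) {
  y <- unlist(mapply(function(ki, ni) rep(c(1, 0), c(ki, ni - ki)),
                     k, n, SIMPLIFY = FALSE))
  pop <- factor(rep(seq_along(k), n))
  ms <- summary(stats::aov(y ~ pop))[[1]][["Mean Sq"]]
  msa <- ms[1]; msw <- ms[2]
  N <- sum(n); r <- length(n)
  n_c <- (N - sum(n^2) / N) / (r - 1)
  a <- (msa - msw) / n_c
  a / (a + msw)
}

# exact hypergeometric upper-tail enumeration (independent of phyper)
hyper_tail_oracle <- function(obs, K, N, n_draw) {
  j <- seq(max(obs, max(0, n_draw - (N - K))), min(K, n_draw))
  if (length(j) == 0) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n_draw - j) - lchoose(N, n_draw)))
}
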