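#' Configuration for the synthetic transect generator
#'
#' Defaults emulate a boreal-conifer contact-zone resequencing design:
#' 12 populations along a ~1,400 km latitudinal transect running south from
#' 69.06 N, 22.55 E, 15 diploids per population, a contact zone centred
#' around 650 km with clinal loci making up 1% of the simulated SNPs.
#'
#' @param n_pops Number of populations (default 12).
#' @param transect_length_km Transect length (default 1400).
#' @param n_diploid Diploids per population (scalar or vector, default 15).
#' @param n_loci Named counts per locus class
#'   (`clinal`, `linear`, `flat`, `ibd_neutral`).
#' @param clinal_centre,clinal_width,clinal_pmin,clinal_pmax Ranges
#'   (length-2) from which true clinal parameters are drawn uniformly;
#'   defaults put centres in the 500-800 km contact region with widths
#'   well under a third of the transect and end-frequency differences
#'   of at least 0.7.
#' @param clinal_model Generating model for clinal loci (default `"I"`).
#' @param neutral_rho_km Correlation length of the neutral spatial process
#'   (default 300 km).
#' @param neutral_fst Target mean pairwise F_ST of neutral loci
#'   (default 0.01).
#' @param env_n_clinal,env_n_linear Of the 19 bioclimatic variables, how
#'   many follow clines co-centred with the allele clines and how many are
#'   linear gradients; the remainder are flat noise.
#' @param env_noise_sd Noise sd on normalised environmental values
#'   (default 0.02).
#' @param jitter_km Sd of seeded jitter on interior population spacing.
#' @param reference `c(lat, lon)` of the transect origin.
#' @param seed Integer seed; mandatory, every draw is derived from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_pops = 12, transect_length_km = 1400,
                       n_diploid = 15,
                       n_loci = c(clinal = 20, linear = 40, flat = 1440,
                                  ibd_neutral = 500),
                       clinal_centre = c(500, 800),
                       clinal_width = c(150, 450),
                       clinal_pmin = c(0, 0.15),
                       clinal_pmax = c(0.85, 1),
                       clinal_model = "I",
                       neutral_rho_km = 300, neutral_fst = 0.01,
                       env_n_clinal = 12, env_n_linear = 5,
                       env_noise_sd = 0.02,
                       jitter_km = 10,
                       reference = c(69.06, 22.55),
                       seed) {
  if (missing(seed)) stop("sim_config requires a seed", call. = FALSE)
  need <- c("clinal", "linear", "flat", "ibd_neutral")
  if (!all(need %in% names(n_loci))) {
    stop("n_loci must name counts for: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cfg <- list(n_pops = n_pops, transect_length_km = transect_length_km,
              n_diploid = rep_len(n_diploid, n_pops),
              n_loci = n_loci[need],
              clinal_centre = clinal_centre, clinal_width = clinal_width,
              clinal_pmin = clinal_pmin, clinal_pmax = clinal_pmax,
              clinal_model = clinal_model,
              neutral_rho_km = neutral_rho_km, neutral_fst = neutral_fst,
              env_n_clinal = env_n_clinal, env_n_linear = env_n_linear,
              env_noise_sd = env_noise_sd,
              jitter_km = jitter_km, reference = reference,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# km of meridian arc per degree of latitude on the reference sphere
KM_PER_DEG <- pi * 6371.0088 / 180

#' Simulate transect geometry
#'
#' Populations are spaced evenly (plus seeded jitter on interior sites)
#' along a southward meridian from the reference point; distances are then
#' recomputed with [geodesic_km()] so they are exactly consistent with the
#' IBD machinery.
#'
#' @param config A [sim_config()] list.
#' @return Geometry tibble as from [read_geometry()].
#' @export
simulate_transect <- function(config) {
  withr::with_seed(config$seed, {
    d <- seq(0, config$transect_length_km, length.out = config$n_pops)
    if (config$n_pops > 2) {
      mid <- 2:(config$n_pops - 1)
      d[mid] <- d[mid] + rnorm(length(mid), 0, config$jitter_km)
      d <- sort(d)
    }
    geo <- tibble::tibble(
      population_id = sprintf("P%02d", seq_len(config$n_pops)),
      latitude = config$reference[1] - d / KM_PER_DEG,
      longitude = config$reference[2],
      n_diploid = config$n_diploid
    )
    as_geometry(geo, reference = config$reference)
  })
}

#' Simulate per-population allele counts for one locus
#'
#' Classes: `clinal` draws counts binomially around a true cline;
#' `linear` around a linear gradient clipped to \[0.02, 0.98\]; `flat`
#' around a constant frequency; `ibd_neutral` around a logit-scale Gaussian
#' process with covariance `sigma^2 exp(-d / rho)`, scaled so a pair's
#' expected differentiation matches the target F_ST.
#'
#' @param class One of `"clinal"`, `"linear"`, `"flat"`, `"ibd_neutral"`.
#' @param params Named list of class-specific parameters: clinal needs
#'   `centre`, `width`, `pmin`, `pmax` (optional `model`); linear `p0`,
#'   `slope`; flat `p`; ibd_neutral `p0`, `rho_km`, `target_fst`.
#' @param geometry Geometry tibble.
#' @param seed Optional integer for a locally seeded draw.
#' @return Tibble `population_id`, `p_true`, `k`, `n`.
#' @export
simulate_locus_counts <- function(class, params, geometry, seed = NULL) {
  draw <- function() {
    p <- locus_freqs(class, params, geometry)
    n <- 2 * geometry$n_diploid
    tibble::tibble(population_id = geometry$population_id, p_true = p,
                   k = rbinom(length(p), n, p), n = n)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# true per-population frequencies for one locus
locus_freqs <- function(class, params, geometry) {
  x <- geometry$distance_km
  switch(class,
    clinal = cline_value(x, centre = params$centre, width = params$width,
                         pmin = params$pmin, pmax = params$pmax,
                         model = params$model %||% "I"),
    linear = {
      p <- params$p0 + params$slope * x
      if (any(p < 0 | p > 1)) {
        p <- pmin(pmax(p, 0.02), 0.98)
      }
      if (any(p < 0 | p > 1)) stop("linear frequencies outside [0, 1]",
                                   call. = FALSE)
      p
    },
    flat = rep(params$p, length(x)),
    ibd_neutral = neutral_freqs(params$p0, params$rho_km,
                                params$target_fst, geometry),
    stop("unknown locus class '", class, "'", call. = FALSE)
  )
}

# Logit-scale Gaussian process over populations. For a pair at correlation
# r, theta is approximately p0 (1 - p0) sigma^2 (1 - r); sigma^2 is chosen
# so the mean pairwise theta matches target_fst.
neutral_freqs <- function(p0, rho_km, target_fst, geometry) {
  d <- as.matrix(stats::dist(geometry$distance_km))
  r <- exp(-d / rho_km)
  mean_decay <- mean(1 - r[lower.tri(r)])
  sigma2 <- target_fst / (p0 * (1 - p0) * mean_decay)
  cov <- sigma2 * r
  z <- qlogis(p0) + drop(crossprod(chol(cov + diag(1e-10, nrow(cov))),
                                   rnorm(nrow(cov))))
  plogis(z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full transect dataset
#'
#' Generates geometry, a truth table with one row per locus, diploid
#' genotypes in Hardy-Weinberg proportions within populations (written as a
#' VCF), a population map, and a 19-variable environmental table in which a
#' configurable subset of variables follows clines co-centred with the
#' clinal loci. Fully deterministic under the config seed: per-population
#' counts derived from the VCF genotypes equal the counts returned here.
#'
#' @param config A [sim_config()] list.
#' @param dir Output directory (created if needed). `NULL` skips writing
#'   files and returns only the in-memory tables.
#' @return List with `geometry`, `counts` (long tibble), `truth`,
#'   `pop_map`, `env` (wide), `freqs` (per-population true frequencies,
#'   long in `truth`), and — when `dir` is given — `paths` to
#'   `genotypes.vcf`, `geometry.tsv`, `popmap.tsv`, `env.tsv`,
#'   `truth.tsv`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  geometry <- simulate_transect(config)
  withr::with_seed(config$seed + 1L, {
    n_cl <- config$n_loci[["clinal"]]
    n_li <- config$n_loci[["linear"]]
    n_fl <- config$n_loci[["flat"]]
    n_ne <- config$n_loci[["ibd_neutral"]]
    n_tot <- n_cl + n_li + n_fl + n_ne

    truth <- tibble::tibble(
      class = rep(c("clinal", "linear", "flat", "ibd_neutral"),
                  times = c(n_cl, n_li, n_fl, n_ne)),
      centre = NA_real_, width = NA_real_,
      pmin = NA_real_, pmax = NA_real_, model = NA_character_
    )
    cl <- truth$class == "clinal"
    truth$centre[cl] <- runif(n_cl, config$clinal_centre[1],
                              config$clinal_centre[2])
    truth$width[cl] <- runif(n_cl, config$clinal_width[1],
                             config$clinal_width[2])
    truth$pmin[cl] <- runif(n_cl, config$clinal_pmin[1],
                            config$clinal_pmin[2])
    truth$pmax[cl] <- runif(n_cl, config$clinal_pmax[1],
                            config$clinal_pmax[2])
    truth$model[cl] <- config$clinal_model

    x <- geometry$distance_km
    L <- config$transect_length_km
    P <- matrix(NA_real_, n_tot, config$n_pops)
    for (i in which(cl)) {
      P[i, ] <- locus_freqs("clinal", list(
        centre = truth$centre[i], width = truth$width[i],
        pmin = truth$pmin[i], pmax = truth$pmax[i],
        model = truth$model[i]), geometry)
    }
    for (i in which(truth$class == "linear")) {
      p0 <- runif(1, 0.02, 0.2)
      p1 <- runif(1, 0.8, 0.98)
      P[i, ] <- locus_freqs("linear",
                            list(p0 = p0, slope = (p1 - p0) / L), geometry)
    }
    for (i in which(truth$class == "flat")) {
      P[i, ] <- locus_freqs("flat", list(p = runif(1, 0.05, 0.95)),
                            geometry)
    }
    for (i in which(truth$class == "ibd_neutral")) {
      P[i, ] <- locus_freqs("ibd_neutral", list(
        p0 = runif(1, 0.1, 0.9), rho_km = config$neutral_rho_km,
        target_fst = config$neutral_fst), geometry)
    }

    # diploid genotype dosages in Hardy-Weinberg proportions
    n_dip <- geometry$n_diploid
    sample_pop <- rep(geometry$population_id, times = n_dip)
    sample_id <- paste0(sample_pop, "_",
                        unlist(lapply(n_dip, seq_len)))
    pop_col <- match(sample_pop, geometry$population_id)
    dose <- matrix(rbinom(n_tot * length(sample_id), 2,
                          P[, pop_col, drop = FALSE]),
                   nrow = n_tot)

    # locus coordinates: ten synthetic chromosomes, shuffled classes
    ord <- sample.int(n_tot)
    chrom <- sprintf("chr%02d", ((seq_len(n_tot) - 1) %% 10) + 1)
    pos <- 1000L * (((seq_len(n_tot) - 1) %/% 10) + 1L)
    locus_id <- paste0(chrom, ":", pos)
    truth <- truth[ord, ]
    P <- P[ord, , drop = FALSE]
    dose <- dose[ord, , drop = FALSE]
    truth <- dplyr::bind_cols(
      tibble::tibble(locus_id = locus_id, chrom = chrom, pos = pos), truth)
    freq_cols <- as.data.frame(P)
    names(freq_cols) <- paste0("p_", geometry$population_id)
    truth <- dplyr::bind_cols(truth, tibble::as_tibble(freq_cols))

    k_mat <- t(rowsum(t(dose), group = sample_pop))
    k_mat <- k_mat[, geometry$population_id, drop = FALSE]
    counts <- tibble::tibble(
      locus_id = rep(locus_id, times = config$n_pops),
      chrom = rep(chrom, times = config$n_pops),
      pos = rep(pos, times = config$n_pops),
      population_id = rep(geometry$population_id, each = n_tot),
      k = as.vector(k_mat),
      n = rep(2 * n_dip, each = n_tot)
    )
    counts <- dplyr::arrange(counts, .data$chrom, .data$pos,
                             .data$population_id)

    pop_map <- tibble::tibble(sample_id = sample_id,
                              population_id = sample_pop)
    env <- simulate_env(config, geometry, truth)

    out <- list(geometry = geometry, counts = counts, truth = truth,
                pop_map = pop_map, env = env)
    if (!is.null(dir)) {
      out$paths <- write_sim_files(out, dose, sample_id, chrom, pos,
                                   locus_id, dir, config)
    }
    out
  })
}

# 19 bioclim-style variables; a subset clinal (co-centred with the allele
# clines), a subset linear, the rest flat noise. Raw values get arbitrary
# per-variable offset/scale so normalisation is exercised.
simulate_env <- function(config, geometry, truth) {
  x <- geometry$distance_km
  L <- config$transect_length_km
  n_var <- 19
  kinds <- rep(c("clinal", "linear", "flat"),
               times = c(config$env_n_clinal, config$env_n_linear,
                         n_var - config$env_n_clinal - config$env_n_linear))
  vals <- vapply(seq_len(n_var), function(j) {
    signal <- switch(kinds[j],
      clinal = cline_value(x,
        centre = runif(1, config$clinal_centre[1], config$clinal_centre[2]),
        width = runif(1, config$clinal_width[1], config$clinal_width[2])),
      linear = x / L,
      flat = rep(0.5, length(x)))
    y <- signal + rnorm(length(x), 0, config$env_noise_sd)
    offset <- runif(1, -20, 20)
    scale <- runif(1, 1, 30)
    offset + scale * y
  }, numeric(length(x)))
  env <- tibble::as_tibble(as.data.frame(vals))
  names(env) <- sprintf("bio%02d", seq_len(n_var))
  dplyr::bind_cols(
    tibble::tibble(population_id = geometry$population_id), env)
}

write_sim_files <- function(sim, dose, sample_id, chrom, pos, locus_id,
                            dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    geometry = file.path(dir, "geometry.tsv"),
    popmap = file.path(dir, "popmap.tsv"),
    env = file.path(dir, "env.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  gt <- matrix(c("0/0", "0/1", "1/1")[dose + 1], nrow = nrow(dose))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=clinescan synthetic transect generator",
    paste0("##reference_point=", config$reference[1], "N,",
           config$reference[2], "E"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", sample_id), collapse = "\t")
  )
  body <- paste(chrom, pos, locus_id, "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), paths$vcf)
  readr::write_tsv(dplyr::select(sim$geometry, "population_id", "latitude",
                                 "longitude", "n_diploid"),
                   paths$geometry, progress = FALSE)
  readr::write_tsv(sim$pop_map, paths$popmap, progress = FALSE)
  readr::write_tsv(sim$env, paths$env, progress = FALSE)
  readr::write_tsv(sim$truth, paths$truth, progress = FALSE)
  paths
}
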