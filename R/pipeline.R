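#' Run the whole contact-zone analysis pipeline
#'
#' Executes the stages in order — allele counts, pairwise F_ST, IBD and
#' neighbourhood size (with a Mantel test), per-SNP cline fits, clinal
#' classification, candidate enrichment, environmental clines, selection
#' coefficients — writing one flat TSV per stage plus a key-value run
#' manifest, so any stage can be inspected or rerun in isolation. Reruns
#' with an identical config are bit-identical.
#'
#' @param vcf Path to the genotype VCF.
#' @param pop_map Path to the sample-to-population TSV.
#' @param geometry Path to the population geometry TSV.
#' @param env Optional path to the environmental table; when `NULL` the
#'   environmental stage is skipped with a notice.
#' @param candidates Optional named list of candidate-SNP id vectors (or
#'   paths to one-column TSVs); when `NULL` the enrichment stage is
#'   skipped.
#' @param out_dir Output directory.
#' @param seed Integer seed for the stochastic stages (Mantel
#'   permutations).
#' @param reference Transect origin `c(lat, lon)`.
#' @param models Cline models to fit.
#' @param options A [cline_options()] list.
#' @param n_perm Mantel permutations (default 9999).
#' @param percentile Clinal classification percentile (default 0.99).
#' @param bin_width Enrichment delta-p bin width (default 0.05).
#' @param max_missing Per-locus missingness threshold (default 0.5).
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(vcf, pop_map, geometry, env = NULL,
                         candidates = NULL, out_dir, seed,
                         reference = c(69.06, 22.55),
                         models = CLINE_MODELS,
                         options = cline_options(),
                         n_perm = 9999, percentile = 0.99,
                         bin_width = 0.05, max_missing = 0.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  map <- stage("counts", read_population_map(pop_map))
  geo <- stage("counts", read_geometry(geometry, reference = reference))
  counts <- stage("counts", {
    cc <- read_vcf_counts(vcf, map)
    filter_counts(cc, geo, max_missing = max_missing)
  })
  write_counts(counts, file.path(out_dir, "counts.tsv"))

  fst <- stage("fst", pairwise_fst(counts, geo))
  readr::write_tsv(fst, file.path(out_dir, "fst.tsv"), progress = FALSE)

  ibd <- stage("ibd", ibd_regression(fst, geo))
  dmat <- stage("ibd", {
    outer(seq_len(nrow(geo)), seq_len(nrow(geo)), function(i, j) {
      geodesic_km(geo$latitude[i], geo$longitude[i],
                  geo$latitude[j], geo$longitude[j])
    })
  })
  mant <- stage("ibd", mantel_test(dmat, fst_matrix(fst),
                                   n_perm = n_perm, seed = seed))
  ibd_tbl <- tibble::tibble(slope = ibd$slope, intercept = ibd$intercept,
                            r_squared = ibd$r_squared,
                            mantel_rho = mant$rho, mantel_p = mant$p_value,
                            n_s = ibd$n_s, n_pairs = ibd$n_pairs)
  readr::write_tsv(ibd_tbl, file.path(out_dir, "ibd.tsv"),
                   progress = FALSE)

  clines <- stage("clines", fit_clines(counts, geo, models = models,
                                       options = options))
  readr::write_tsv(clines, file.path(out_dir, "clines.tsv"),
                   progress = FALSE)

  calls <- stage("classify", classify_clinal(clines,
                                             percentile = percentile))
  readr::write_tsv(calls, file.path(out_dir, "clinal_calls.tsv"),
                   progress = FALSE)

  enrich <- NULL
  if (!is.null(candidates)) {
    candidates <- lapply(candidates, function(v) {
      if (length(v) == 1 && is.character(v) && file.exists(v)) {
        readr::read_tsv(v, col_types = "c", progress = FALSE)[[1]]
      } else v
    })
    enrich <- stage("enrich", enrichment_test(candidates, calls,
                                              bin_width = bin_width))
    readr::write_tsv(enrich, file.path(out_dir, "enrichment.tsv"),
                     progress = FALSE)
  } else {
    message("no candidate sets supplied: enrichment stage skipped")
  }

  env_clines <- NULL
  if (!is.null(env)) {
    env_tbl <- stage("envclines", read_env_table(env, geo))
    env_clines <- stage("envclines",
                        fit_env_clines(env_tbl, geo, models = models,
                                       options = options))
    readr::write_tsv(env_clines, file.path(out_dir, "env_clines.tsv"),
                     progress = FALSE)
  } else {
    message("no environmental table supplied: env stage skipped")
  }

  selection <- stage("selection", selection_estimates(calls, ibd))
  readr::write_tsv(selection, file.path(out_dir, "selection.tsv"),
                   progress = FALSE)

  manifest <- c(
    package = "clinescan",
    version = as.character(utils::packageVersion("clinescan")),
    seed = seed, n_perm = n_perm, percentile = percentile,
    bin_width = bin_width, max_missing = max_missing,
    models = paste(models, collapse = ","),
    end_fix = options$end_fix, n_starts = options$n_starts,
    reference_lat = reference[1], reference_lon = reference[2],
    n_populations = nrow(geo),
    n_loci = dplyr::n_distinct(counts$locus_id),
    n_pairs = nrow(fst), n_clinal = sum(calls$is_clinal),
    n_env_clines = if (is.null(env_clines)) 0 else nrow(env_clines),
    n_selection = nrow(selection)
  )
  writeLines(paste0(names(manifest), "=", manifest),
             file.path(out_dir, "manifest.txt"))

  invisible(list(geometry = geo, counts = counts, fst = fst, ibd = ibd,
                 mantel = mant, clines = clines, calls = calls,
                 enrichment = enrich, env_clines = env_clines,
                 selection = selection, manifest = manifest,
                 out_dir = out_dir))
}
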