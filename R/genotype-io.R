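#' Read a sample-to-population map
#'
#' The map is a tab-separated file with a header and two columns,
#' `sample_id` and `population_id`. Every sample must appear exactly once.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with columns `sample_id` and `population_id`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\tpopulation_id", "s1\tA", "s2\tA", "s3\tB"), tf)
#' read_population_map(tf)
read_population_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(map) == 0) {
    stop("population map '", path, "' contains no samples", call. = FALSE)
  }
  if (!all(c("sample_id", "population_id") %in% names(map))) {
    names(map)[1:2] <- c("sample_id", "population_id")
  }
  map <- dplyr::select(map, "sample_id", "population_id")
  dup <- map$sample_id[duplicated(map$sample_id)]
  if (length(dup) > 0) {
    stop("duplicated sample_id in population map: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  n_pop <- dplyr::n_distinct(map$population_id)
  if (n_pop < 2) {
    stop("population map must contain at least 2 populations", call. = FALSE)
  }
  message("read ", nrow(map), " samples in ", n_pop, " populations")
  map
}

#' Read transect geometry (populations, coordinates, sample sizes)
#'
#' Expects a tab-separated file with columns `population_id`, `latitude`,
#' `longitude` and `n_diploid`. Distances (km) are great-circle distances
#' from the reference point, which serves as origin of the transect axis
#' used as predictor in cline fits.
#'
#' @param path Path to a tab-separated geometry file.
#' @param reference Numeric `c(lat, lon)` of the transect origin. Default is
#'   the northernmost site of the Scandinavian design, 69.06 N, 22.55 E.
#' @return A tibble `population_id`, `latitude`, `longitude`, `n_diploid`,
#'   `distance_km`, ordered by increasing distance, with the reference point
#'   stored in attribute `"reference"`.
#' @export
read_geometry <- function(path, reference = c(69.06, 22.55)) {
  geo <- readr::read_tsv(path, col_types = readr::cols(
    population_id = "c", .default = "d"), progress = FALSE)
  as_geometry(geo, reference = reference)
}

#' Validate a geometry data frame and compute transect distances
#'
#' @param geo Data frame with `population_id`, `latitude`, `longitude`,
#'   `n_diploid`.
#' @inheritParams read_geometry
#' @return See [read_geometry()].
#' @export
as_geometry <- function(geo, reference = c(69.06, 22.55)) {
  need <- c("population_id", "latitude", "longitude", "n_diploid")
  miss <- setdiff(need, names(geo))
  if (length(miss) > 0) {
    stop("geometry is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(abs(geo$latitude) > 90) || any(abs(geo$longitude) > 180)) {
    stop("geometry contains invalid coordinates", call. = FALSE)
  }
  if (any(geo$n_diploid < 1)) {
    stop("n_diploid must be >= 1 for every population", call. = FALSE)
  }
  geo <- tibble::as_tibble(geo)
  geo$distance_km <- geodesic_km(reference[1], reference[2],
                                 geo$latitude, geo$longitude)
  geo <- dplyr::arrange(geo, .data$distance_km)
  attr(geo, "reference") <- c(lat = reference[1], lon = reference[2])
  geo
}

#' Read a VCF into per-population allele counts
#'
#' Only biallelic SNP records are used; multiallelic records are skipped and
#' counted. Missing genotypes shrink the per-population number of sampled
#' allele copies `n`; nothing is imputed. The ALT allele is the focal allele.
#'
#' @param path Path to a VCF (v4.x, plain or gzipped) with diploid GT fields.
#' @param pop_map Tibble from [read_population_map()].
#' @return A long tibble with columns `locus_id` (`chrom:pos`), `chrom`,
#'   `pos`, `population_id`, `k` (focal-allele copies) and `n` (sampled
#'   allele copies). The number of skipped non-biallelic records is stored
#'   in attribute `"n_skipped"`.
#' @export
read_vcf_counts <- function(path, pop_map) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  fix <- tibble::as_tibble(fix)
  if (nrow(fix) == 0) stop("no usable records in VCF '", path, "'",
                           call. = FALSE)
  biallelic <- !is.na(fix$ALT) & !grepl(",", fix$ALT, fixed = TRUE)
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0) {
    message("skipped ", n_skipped, " non-biallelic record(s)")
  }
  if (!any(biallelic)) stop("zero usable biallelic records", call. = FALSE)

  gt <- vcfR::extract.gt(vcf, element = "GT")[biallelic, , drop = FALSE]
  samples <- colnames(gt)
  unknown <- setdiff(samples, pop_map$sample_id)
  if (length(unknown) > 0) {
    stop("VCF sample(s) absent from population map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pops <- pop_map$population_id[match(samples, pop_map$sample_id)]
  chrom <- fix$CHROM[biallelic]
  pos <- as.integer(fix$POS[biallelic])

  # allele dosage per genotype string; NA when either allele is missing
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  dose[ok] <- (a1 == "1")[ok] + (a2 == "1")[ok]

  pop_levels <- unique(pop_map$population_id)
  k_mat <- vapply(pop_levels, function(p) {
    cols <- which(pops == p)
    rowSums(dose[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(gt)))
  n_mat <- vapply(pop_levels, function(p) {
    cols <- which(pops == p)
    2 * rowSums(!is.na(dose[, cols, drop = FALSE]))
  }, numeric(nrow(gt)))
  k_mat <- matrix(k_mat, nrow = nrow(gt),
                  dimnames = list(NULL, pop_levels))
  n_mat <- matrix(n_mat, nrow = nrow(gt),
                  dimnames = list(NULL, pop_levels))

  counts <- tibble::tibble(
    locus_id = rep(paste0(chrom, ":", pos), times = length(pop_levels)),
    chrom = rep(chrom, times = length(pop_levels)),
    pos = rep(pos, times = length(pop_levels)),
    population_id = rep(pop_levels, each = nrow(gt)),
    k = as.vector(k_mat),
    n = as.vector(n_mat)
  )
  counts <- dplyr::arrange(counts, .data$chrom, .data$pos,
                           .data$population_id)
  attr(counts, "n_skipped") <- n_skipped
  counts
}

#' Filter loci by missingness
#'
#' Drops loci with more than `max_missing` of their possible allele copies
#' missing overall, and loci where any population has zero sampled copies
#' (the cline likelihood is undefined there).
#'
#' @param counts Long counts tibble from [read_vcf_counts()].
#' @param geometry Geometry tibble; supplies the per-population diploid
#'   totals defining the possible copy number.
#' @param max_missing Maximum tolerated overall missing fraction (default
#'   0.5, i.e., loci with more than 50% missing allele copies are excluded).
#' @return Filtered counts tibble; numbers of dropped loci are messaged.
#' @export
filter_counts <- function(counts, geometry, max_missing = 0.5) {
  total_possible <- 2 * sum(geometry$n_diploid)
  per_locus <- counts |>
    dplyr::summarise(n_tot = sum(.data$n), n_zero = sum(.data$n == 0),
                     .by = "locus_id")
  bad_miss <- per_locus$locus_id[
    1 - per_locus$n_tot / total_possible > max_missing]
  bad_zero <- setdiff(per_locus$locus_id[per_locus$n_zero > 0], bad_miss)
  if (length(bad_miss) > 0) {
    message("dropped ", length(bad_miss), " locus(i) with > ",
            round(100 * max_missing), "% missing allele copies")
  }
  if (length(bad_zero) > 0) {
    message("dropped ", length(bad_zero),
            " locus(i) with an unsampled population")
  }
  dplyr::filter(counts,
                !(.data$locus_id %in% c(bad_miss, bad_zero)))
}

#' Write / read the per-population counts table
#'
#' The on-disk form is wide: `locus_id`, `chrom`, `pos`, then a `k_<pop>` /
#' `n_<pop>` column pair per population. Re-reading reproduces the long
#' tibble exactly.
#'
#' @param counts Long counts tibble.
#' @param path Output TSV path.
#' @return `write_counts()` returns `path` invisibly; `read_counts()`
#'   returns the long counts tibble.
#' @export
write_counts <- function(counts, path) {
  wide <- counts |>
    tidyr::pivot_wider(names_from = "population_id",
                       values_from = c("k", "n"), names_sep = "_")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    locus_id = "c", chrom = "c", pos = "i", .default = "d"),
    progress = FALSE)
  long <- wide |>
    tidyr::pivot_longer(-c("locus_id", "chrom", "pos"),
                        names_to = c(".value", "population_id"),
                        names_pattern = "^([kn])_(.+)$")
  dplyr::select(long, "locus_id", "chrom", "pos", "population_id", "k", "n")
}

#' Read and normalise a per-population environmental table
#'
#' Expects a populations-by-variables table (first column `population_id`,
#' one column per bioclimatic variable). Each variable is min-max normalised
#' to \[0, 1\] across populations; constant variables are flagged and left
#' unnormalised (they cannot carry a cline).
#'
#' @param path Path to a tab-separated table.
#' @param geometry Geometry tibble; every population in the table must be
#'   present in the geometry.
#' @return Long tibble `population_id`, `variable_id`, `value`,
#'   `value_norm`, `constant`.
#' @export
read_env_table <- function(path, geometry) {
  env <- readr::read_tsv(path, col_types = readr::cols(
    population_id = "c", .default = "d"), progress = FALSE)
  normalise_env(env, geometry)
}

#' @rdname read_env_table
#' @param env Wide data frame as described for `read_env_table()`.
#' @export
normalise_env <- function(env, geometry) {
  missing_pops <- setdiff(env$population_id, geometry$population_id)
  if (length(missing_pops) > 0) {
    stop("environmental table has population(s) absent from geometry: ",
         paste(missing_pops, collapse = ", "), call. = FALSE)
  }
  env |>
    tidyr::pivot_longer(-"population_id", names_to = "variable_id",
                        values_to = "value") |>
    dplyr::mutate(
      rng = max(.data$value) - min(.data$value),
      constant = .data$rng == 0,
      value_norm = dplyr::if_else(
        .data$constant, NA_real_,
        (.data$value - min(.data$value)) / .data$rng),
      .by = "variable_id"
    ) |>
    dplyr::select("population_id", "variable_id", "value",
                  "value_norm", "constant")
}
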