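test_that("population map reading validates structure and counts populations", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpopulation_id",
               "s1\tA", "s2\tA", "s3\tB", "s4\tB"), tf)
  expect_message(map <- read_population_map(tf), "4 samples in 2 populations")
  expect_s3_class(map, "tbl_df")
  expect_equal(nrow(map), 4)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpopulation_id", "s1\tA", "s1\tB", "s2\tB"), dup)
  expect_error(read_population_map(dup), "s1")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tpopulation_id", empty)
  expect_error(read_population_map(empty), "no samples")
})

test_that("a resequencing-design-sized map reports 12 populations", {
  sizes <- c(35, 20, 15, 12, 10, 10, 10, 10, 10, 8, 7, 7)  # sums to 154
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpopulation_id",
               paste0("t", seq_len(sum(sizes)), "\t",
                      rep(sprintf("P%02d", 1:12), sizes))), tf)
  expect_message(map <- read_population_map(tf),
                 "154 samples in 12 populations")
  expect_equal(dplyr::n_distinct(map$population_id), 12)
})

make_map <- function(samples, pops) {
  tibble::tibble(sample_id = samples, population_id = pops)
}

test_that("VCF allele counting follows the missing-data and biallelic rules", {
  gt <- rbind(c("0/0", "0/1", "1/1"),
              c("./.", "0/1", "1/1"),
              c("0/0", "0/0", "0/1"))
  colnames(gt) <- c("a1", "a2", "b1")
  vcf <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"), gt,
                        alt = c("T", "T", "T,G"))
  map <- make_map(c("a1", "a2", "b1"), c("A", "A", "B"))

  expect_message(counts <- read_vcf_counts(vcf, map), "1 non-biallelic")
  expect_equal(attr(counts, "n_skipped"), 1)
  expect_equal(dplyr::n_distinct(counts$locus_id), 2)

  rec1 <- dplyr::filter(counts, pos == 100)
  expect_equal(rec1$k[rec1$population_id == "A"], 1)
  expect_equal(rec1$n[rec1$population_id == "A"], 4)
  expect_equal(rec1$k[rec1$population_id == "B"], 2)
  expect_equal(rec1$n[rec1$population_id == "B"], 2)

  # missing genotype shrinks n, never imputed
  rec2 <- dplyr::filter(counts, pos == 200)
  expect_equal(rec2$n[rec2$population_id == "A"], 2)
  expect_equal(rec2$k[rec2$population_id == "A"], 1)
})

test_that("counts are invariant to sample order in the population map", {
  gt <- rbind(c("0/1", "1/1", "0/0", "0/1"),
              c("0/0", "0/1", "1/1", "1/1"))
  colnames(gt) <- c("s1", "s2", "s3", "s4")
  vcf <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"), gt)
  map <- make_map(paste0("s", 1:4), c("A", "B", "A", "B"))
  c1 <- read_vcf_counts(vcf, map)
  c2 <- read_vcf_counts(vcf, map[c(3, 1, 4, 2), ])
  expect_equal(c1$k, c2$k)
  expect_equal(c1$n, c2$n)
  expect_equal(c1$population_id, c2$population_id)
})

test_that("unmapped samples and unusable VCFs are errors", {
  gt <- rbind(c("0/1", "1/1"))
  colnames(gt) <- c("s1", "sX")
  vcf <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"), gt)
  expect_error(read_vcf_counts(vcf, make_map("s1", "A")), "sX")

  gt2 <- rbind(c("0/1", "1/1"))
  colnames(gt2) <- c("s1", "s2")
  vcf2 <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"), gt2,
                         alt = "T,G")
  expect_error(
    suppressMessages(read_vcf_counts(vcf2, make_map(c("s1", "s2"),
                                                    c("A", "B")))),
    "zero usable")
})

test_that("counts TSV round-trips exactly", {
  sim <- simulate_dataset(sim_config(
    n_loci = c(clinal = 2, linear = 2, flat = 10, ibd_neutral = 5),
    seed = 11))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_counts(sim$counts, tf)
  back <- read_counts(tf)
  expect_equal(dplyr::arrange(back, chrom, pos, population_id),
               dplyr::arrange(sim$counts, chrom, pos, population_id),
               ignore_attr = TRUE)
})

test_that("missingness filter drops sparse loci and unsampled populations", {
  geo <- test_geometry(n_pops = 4, n_diploid = 10)
  base <- tidyr::expand_grid(locus_id = c("L1", "L2", "L3"),
                             population_id = geo$population_id)
  base$chrom <- "chr1"
  base$pos <- match(base$locus_id, c("L1", "L2", "L3"))
  base$k <- 2
  base$n <- 20
  # L2: >50% of the 80 possible copies missing; L3: one unsampled population
  base$n[base$locus_id == "L2"] <- c(20, 8, 6, 4)
  base$n[base$locus_id == "L3"] <- c(20, 20, 20, 0)
  base$k[base$locus_id == "L3" & base$n == 0] <- 0
  expect_message(kept <- filter_counts(base, geo), "missing allele copies")
  expect_setequal(unique(kept$locus_id), "L1")
})

test_that("environmental normalisation is min-max with constants flagged", {
  geo <- test_geometry(n_pops = 3)
  env <- tibble::tibble(population_id = geo$population_id,
                        bio01 = c(2, 4, 6), bio02 = c(5, 5, 5))
  out <- normalise_env(env, geo)
  b1 <- dplyr::filter(out, variable_id == "bio01")
  expect_equal(b1$value_norm, c(0, 0.5, 1))
  b2 <- dplyr::filter(out, variable_id == "bio02")
  expect_true(all(b2$constant))
  expect_true(all(is.na(b2$value_norm)))

  bad <- env
  bad$population_id[1] <- "nope"
  expect_error(normalise_env(bad, geo), "nope")
})

test_that("a 19-variable table yields 19 normalised series in [0, 1]", {
  sim <- simulate_dataset(sim_config(
    n_loci = c(clinal = 1, linear = 1, flat = 1, ibd_neutral = 1),
    seed = 5))
  out <- normalise_env(sim$env, sim$geometry)
  expect_equal(dplyr::n_distinct(out$variable_id), 19)
  ok <- dplyr::filter(out, !constant)
  expect_true(all(ok$value_norm >= 0 & ok$value_norm <= 1))
})
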