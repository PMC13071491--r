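# near-noiseless model-I data: large n with rounded expected counts
noiseless_locus <- function(geo, centre = 650, width = 300,
                            pmin = 0.1, pmax = 0.9, n_copies = 2000) {
  x <- geo$distance_km
  p <- cline_value(x, centre, width, pmin, pmax)
  list(x = x, k = round(n_copies * p), n = rep(n_copies, length(x)))
}

test_that("model-I fits agree with a dense grid-search oracle when noiseless", {
  geo <- test_geometry()
  d <- noiseless_locus(geo)
  fit <- fit_cline(d$x, k = d$k, n = d$n, model = "I")
  L <- max(d$x) - min(d$x)
  oracle <- grid_oracle_model1(d$x, d$k, d$n,
                               pmin = d$k[1] / d$n[1],
                               pmax = d$k[12] / d$n[12],
                               c_range = c(min(d$x) - 0.5 * L,
                                           max(d$x) + 0.5 * L),
                               w_range = c(1, 10 * L), n_grid = 101)
  expect_true(fit$converged)
  expect_gte(fit$loglik, oracle$loglik - 1e-3)
  expect_lt(abs(fit$params$centre - 650), 5)
  expect_lt(abs(fit$params$width - 300) / 300, 0.05)
})

test_that("the optimizer never falls below the grid oracle on random data", {
  geo <- test_geometry()
  withr::with_seed(21, {
    for (i in 1:5) {
      centre <- runif(1, 300, 1100); width <- runif(1, 100, 500)
      p <- cline_value(geo$distance_km, centre, width,
                       runif(1, 0, 0.2), runif(1, 0.8, 1))
      n <- rep(30, 12); k <- rbinom(12, n, p)
      fit <- fit_cline(geo$distance_km, k = k, n = n, model = "I")
      L <- 1400
      oracle <- grid_oracle_model1(geo$distance_km, k, n,
                                   pmin = k[1] / n[1], pmax = k[12] / n[12],
                                   c_range = c(-0.5 * L, 1.5 * L),
                                   w_range = c(1, 10 * L))
      expect_gte(fit$loglik, oracle$loglik - 1e-3)
    }
  })
})

test_that("strictly linear gradients are excluded from the cline class", {
  geo <- test_geometry()
  x <- geo$distance_km
  p <- 0.05 + 0.9 * x / max(x)
  n <- rep(30, 12); k <- round(n * p)
  cmp <- fit_cline_models(x, k = k, n = n)
  expect_true(cmp$linear_excluded)
  expect_true(is.na(cmp$best_model))
  expect_equal(cmp$evidence_ratio, 0)

  # and through the per-locus pipeline the locus is non-converged
  counts <- tibble::tibble(locus_id = "LIN", chrom = "c", pos = 1L,
                           population_id = geo$population_id, k = k, n = n)
  row <- fit_clines(counts, geo)
  expect_false(row$converged)
  expect_true(row$linear_excluded)
})

test_that("binomial sampling still recovers cline parameters", {
  # model II (free ends) is the package's estimator for parameter studies:
  # model I inherits end-population sampling noise into its width
  geo <- test_geometry()
  ests <- withr::with_seed(31, t(vapply(1:20, function(i) {
    p <- cline_value(geo$distance_km, 650, 300, 0.1, 0.9)
    n <- rep(30, 12); k <- rbinom(12, n, p)
    f <- fit_cline(geo$distance_km, k = k, n = n, model = "II")
    c(f$params$centre, f$params$width)
  }, numeric(2))))
  expect_lte(median(abs(ests[, 1] - 650)), 50)
  expect_lte(median(abs(ests[, 2] - 300) / 300), 0.25)
})

test_that("fits with more parameters than populations are skipped", {
  geo <- test_geometry(n_pops = 5)
  d <- noiseless_locus(geo)
  expect_message(fit <- fit_cline(d$x, k = d$k, n = d$n, model = "IV"),
                 "skipped")
  expect_null(fit)
})

fake_fit <- function(model, aicc, k_par, converged = TRUE) {
  structure(list(model = model, aicc = aicc, k_par = k_par,
                 converged = converged), class = "cline_fit")
}

test_that("model comparison follows the AICc and evidence-ratio rules", {
  # a ten-unit AICc gap gives an evidence ratio of exp(5)
  cmp <- compare_cline_models(list(
    I = fake_fit("I", 10, 2), null = fake_fit("null", 20, 1)))
  expect_equal(cmp$best_model, "I")
  expect_equal(cmp$evidence_ratio, exp(5), tolerance = 1e-12)
  expect_equal(sum(cmp$weights), 1, tolerance = 1e-12)

  # exact tie: the simpler model wins
  cmp2 <- compare_cline_models(list(
    I = fake_fit("I", 10, 2), II = fake_fit("II", 10, 4),
    null = fake_fit("null", 12, 1)))
  expect_equal(cmp2$best_model, "I")

  # null best overall: evidence ratio below 1
  cmp3 <- compare_cline_models(list(
    I = fake_fit("I", 15, 2), null = fake_fit("null", 10, 1)))
  expect_lt(cmp3$evidence_ratio, 1)

  # nothing converged: non-clinal by convention
  cmp4 <- compare_cline_models(list(
    I = fake_fit("I", 15, 2, converged = FALSE),
    null = fake_fit("null", 10, 1)))
  expect_true(is.na(cmp4$best_model))
  expect_equal(cmp4$evidence_ratio, 0)

  expect_error(compare_cline_models(list(I = fake_fit("I", 1, 2))), "null")
})

test_that("Akaike weights sum to one on real comparisons", {
  geo <- test_geometry()
  d <- withr::with_seed(41, {
    p <- cline_value(geo$distance_km, 650, 300, 0.1, 0.9)
    n <- rep(30, 12)
    list(k = rbinom(12, n, p), n = n)
  })
  cmp <- fit_cline_models(geo$distance_km, k = d$k, n = d$n)
  expect_equal(sum(cmp$weights), 1, tolerance = 1e-12)
  expect_s3_class(cmp, "cline_comparison")
})

test_that("residual standard error matches its definition", {
  x <- seq(0, 1400, length.out = 12)
  p <- cline_value(x, 650, 300, 0.1, 0.9)
  mk_fit <- function(obs) {
    structure(list(model = "I", likelihood = "binomial", k_par = 2,
                   data = list(x = x, k = obs * 1000, n = rep(1000, 12)),
                   fitted = p), class = "cline_fit")
  }
  expect_equal(fit_rse(mk_fit(p)), 0)
  expect_equal(fit_rse(mk_fit(p + 0.1)), 0.1 * sqrt(12 / 10),
               tolerance = 1e-12)
  obs <- withr::with_seed(2, p + rnorm(12, 0, 0.05))
  expect_equal(fit_rse(mk_fit(obs)),
               sqrt(sum((obs - p)^2) / (12 - 2)), tolerance = 1e-12)
})

test_that("the parametric bootstrap brackets the estimates deterministically", {
  geo <- test_geometry()
  d <- withr::with_seed(71, {
    p <- cline_value(geo$distance_km, 650, 300, 0.1, 0.9)
    n <- rep(30, 12)
    list(k = rbinom(12, n, p), n = n)
  })
  fit <- fit_cline(geo$distance_km, k = d$k, n = d$n, model = "II")
  ci <- bootstrap_cline(fit, n_boot = 60, seed = 5)
  expect_setequal(ci$term, c("centre", "width", "pmin", "pmax"))
  expect_true(all(ci$conf.low <= ci$estimate + 1e-9 &
                    ci$estimate <= ci$conf.high + 1e-9))
  # centre interval should comfortably cover the truth here
  expect_true(ci$conf.low[ci$term == "centre"] < 650 &&
                650 < ci$conf.high[ci$term == "centre"])
  expect_identical(ci, bootstrap_cline(fit, n_boot = 60, seed = 5))

  bad <- fit; bad$converged <- FALSE
  expect_error(bootstrap_cline(bad), "non-converged")
})

test_that("per-locus fitting re-polarises and reports on the original scale", {
  geo <- test_geometry()
  x <- geo$distance_km
  # a falling cline: frequency high in the north
  p <- cline_value(x, 650, 300, 0.1, 0.9)
  n <- rep(2000, 12)
  counts <- tibble::tibble(
    locus_id = "L1", chrom = "c", pos = 1L,
    population_id = geo$population_id,
    k = round(n * (1 - p)), n = n)
  res <- fit_clines(counts, geo, models = c("I", "II"))
  expect_equal(res$polarity, "flipped")
  # fitted ends are reported for the original (falling) allele
  expect_gt(res$p_north, res$p_south)
  expect_lt(abs(res$centre - 650), 20)
})
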