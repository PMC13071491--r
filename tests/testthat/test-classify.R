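fake_calls <- function(er, converged = TRUE, delta_p = 0.5) {
  tibble::tibble(locus_id = sprintf("L%04d", seq_along(er)),
                 evidence_ratio = er,
                 converged = rep_len(converged, length(er)),
                 delta_p = rep_len(delta_p, length(er)),
                 width = 200, best_model = "I")
}

test_that("the 99th-percentile rule picks exactly the extreme loci", {
  er <- withr::with_seed(1, c(runif(990, 0, 5), rep(1e6, 10)))
  calls <- classify_clinal(fake_calls(er))
  expect_setequal(calls$locus_id[calls$is_clinal],
                  sprintf("L%04d", 991:1000))

  # permuting loci does not change the clinal set
  shuf <- withr::with_seed(2, fake_calls(er)[sample(1000), ])
  calls2 <- classify_clinal(shuf)
  expect_setequal(calls2$locus_id[calls2$is_clinal],
                  calls$locus_id[calls$is_clinal])
})

test_that("strict exceedance means identical ratios yield no clinal calls", {
  calls <- classify_clinal(fake_calls(rep(3.3, 500)))
  expect_false(any(calls$is_clinal))
})

test_that("non-converged loci are never clinal and small sets warn", {
  er <- c(runif(200, 0, 2), 1e8)
  conv <- c(rep(TRUE, 200), FALSE)
  calls <- classify_clinal(fake_calls(er, converged = conv))
  expect_false(calls$is_clinal[201])

  expect_warning(classify_clinal(fake_calls(runif(50))), "unreliable")
  expect_warning(out <- classify_clinal(fake_calls(1, converged = FALSE)),
                 "no converged")
  expect_false(any(out$is_clinal))
})

test_that("the matched background follows the delta-p bin rules", {
  dp <- c(0.42, 0.43, 0.61, 0.07, 0.44, 0.12, 0.41)
  calls <- fake_calls(runif(7), delta_p = dp)
  # one candidate at 0.42: the background is its [0.40, 0.45) bin
  bg <- matched_background(calls$locus_id[1], calls)
  expect_setequal(bg, calls$locus_id[c(1, 2, 5, 7)])
  # a second candidate in the same bin adds nothing twice
  bg2 <- matched_background(calls$locus_id[c(1, 2)], calls)
  expect_setequal(bg2, bg)
  # degenerate bin width: everything is background
  bg3 <- matched_background(calls$locus_id[1], calls, bin_width = 1)
  expect_setequal(bg3, calls$locus_id)
  # unknown candidates are dropped with a warning
  expect_warning(matched_background(c("nope", calls$locus_id[1]), calls),
                 "absent")
})

test_that("enrichment p-values equal exact tail enumeration", {
  # N = 50 background, K = 10 clinal, n = 5 candidates, 4 of them clinal
  calls <- fake_calls(runif(50), delta_p = 0.42)
  calls$is_clinal <- c(rep(TRUE, 10), rep(FALSE, 40))
  calls$threshold_used <- 1
  cand <- calls$locus_id[c(1:4, 11)]
  res <- enrichment_test(list(scan = cand), calls)
  expect_equal(res$n_background, 50)
  expect_equal(res$n_background_clinal, 10)
  expect_equal(res$n_candidates_clinal, 4)
  expect_equal(res$p_value, hyper_tail_oracle(4, 10, 50, 5),
               tolerance = 1e-12)

  # zero clinal candidates: the whole tail, p = 1
  res0 <- enrichment_test(list(s = calls$locus_id[11:15]), calls)
  expect_equal(res0$p_value, 1)

  # candidates = background: observed equals K deterministically
  resK <- enrichment_test(list(s = calls$locus_id), calls)
  expect_equal(resK$p_value, 1)

  expect_error(enrichment_test(list(s = "missing"), calls), "no fitted")
})

test_that("enrichment matches enumeration across random configurations", {
  withr::with_seed(13, {
    for (i in 1:25) {
      N <- sample(10:60, 1)
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      calls <- fake_calls(runif(N), delta_p = 0.3)
      calls$is_clinal <- seq_len(N) <= K
      cand <- sample(calls$locus_id, n)
      obs <- sum(calls$is_clinal[match(cand, calls$locus_id)])
      res <- enrichment_test(list(x = cand), calls, bin_width = 1)
      expect_equal(res$p_value, hyper_tail_oracle(obs, K, N, n),
                   tolerance = 1e-12)
    }
  })
})

test_that("Bonferroni adjustment is capped multiplication across sets", {
  calls <- fake_calls(runif(60), delta_p = 0.3)
  calls$is_clinal <- seq_len(60) <= 12
  sets <- list(a = calls$locus_id[c(1:3, 20:22)],
               b = calls$locus_id[30:45],
               c = calls$locus_id[c(4:9, 50)])
  res <- enrichment_test(sets, calls, bin_width = 1)
  expect_equal(res$p_adjusted, pmin(1, 3 * res$p_value))
  expect_true(all(res$p_adjusted >= res$p_value))
})

test_that("selection coefficients follow s = N_S / w^2", {
  expect_equal(selection_coefficient(200, 100), 0.02)
  # doubling the width quarters the selection strength
  expect_equal(selection_coefficient(200, 200),
               selection_coefficient(200, 100) / 4)
  # monotone: decreasing in width, increasing in N_S
  w <- seq(50, 1000, by = 50)
  expect_true(all(diff(selection_coefficient(200, w)) < 0))
  expect_gt(selection_coefficient(300, 100), selection_coefficient(200, 100))
  # weak-cline regime lands in a plausibly weak band
  expect_equal(selection_coefficient(100, 1000), 1e-4)
  expect_warning(out <- selection_coefficient(NA, c(100, 200)), "undefined")
  expect_true(all(is.na(out)))
})

test_that("selection estimates propagate an undefined neighbourhood size", {
  calls <- fake_calls(c(10, 2000, 3000), delta_p = 0.6)
  calls$is_clinal <- c(FALSE, TRUE, TRUE)
  good <- list(n_s = 200, n_s_defined = TRUE)
  est <- selection_estimates(calls, good)
  expect_equal(nrow(est), 2)
  expect_equal(est$s, 200 / est$width^2)

  bad <- list(n_s = NA_real_, n_s_defined = FALSE)
  expect_warning(est2 <- selection_estimates(calls, bad), "undefined")
  expect_true(all(is.na(est2$s)))
  expect_equal(unique(est2$status), "n_s_undefined")
})
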