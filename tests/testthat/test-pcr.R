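LENS <- c(156, 195, 198)   # stage-1/2/3 scar amplicon lengths

test_that("with no length penalty pcr_observe is an unbiased multinomial sampler", {
  m <- c(0.5, 0.3, 0.2)
  flat <- bias_model(e_max = 0.9, k_len = 0, cycles = 25)
  pooled <- numeric(3)
  n_draws <- 1000; depth <- 300
  for (i in seq_len(n_draws))
    pooled <- pooled + pcr_observe(m, LENS, flat, read_depth = depth, seed = i)
  gof <- stats::chisq.test(pooled, p = m)
  expect_gt(gof$p.value, 0.01)
})

test_that("the calibrated bias preset overrepresents the 156-bp amplicon 2.72-2.84-fold", {
  bias <- bias_preset()
  w <- (1 + pmin(pmax(bias$e_max - bias$k_len * c(156, 196.5), 0), 1))^bias$cycles
  fold <- w[1] / w[2]
  expect_gte(fold, 2.72)
  expect_lte(fold, 2.84)
  # per-cycle efficiency ratio is the 25th root, ~1.042
  expect_equal((fold)^(1 / 25), 1.042, tolerance = 1e-3)
  # equimolar input: observed counts show the same fold
  cts <- pcr_observe(rep(1 / 3, 3), c(156, 196.5, 196.5), bias,
                     read_depth = 2e5, seed = 1)
  expect_equal(cts[1] / mean(cts[2:3]), fold, tolerance = 0.05)
})

test_that("overrepresentation grows with cycle count and with the length penalty", {
  fold_of <- function(k_len, cycles) {
    w <- (1 + pmin(pmax(0.9 - k_len * LENS, 0), 1))^cycles
    w[1] / w[3]
  }
  folds_c <- vapply(c(10, 20, 30), function(C) fold_of(1.6e-3, C), 0)
  expect_true(all(diff(folds_c) > 0))
  folds_k <- vapply(c(5e-4, 1.6e-3, 3e-3), function(k) fold_of(k, 25), 0)
  expect_true(all(diff(folds_k) > 0))
})

test_that("bias_correct exactly inverts the pcr_observe expectation", {
  bias <- bias_preset()
  m <- c(0.05, 0.05, 0.90)
  w <- m * (1 + pmin(pmax(bias$e_max - bias$k_len * LENS, 0), 1))^bias$cycles
  expected_counts <- 1e6 * w / sum(w)
  est <- bias_correct(expected_counts, LENS, bias, B = 10)
  expect_equal(est$estimate, m, tolerance = 1e-12)
  # with no penalty the estimates equal the raw count fractions
  flat <- bias_model(k_len = 0)
  cts <- c(120, 340, 540)
  est2 <- bias_correct(cts, LENS, flat, B = 10)
  expect_equal(est2$estimate, cts / sum(cts))
  expect_error(bias_correct(c(0, 0, 0), LENS, bias), "zero total")
})

test_that("round-trip recovery lands inside the bootstrap CI at nominal rate", {
  bias <- bias_preset()
  m <- c(0.2, 0.3, 0.5)
  hits <- 0L; total <- 0L
  for (r in seq_len(40)) {
    cts <- pcr_observe(m, LENS, bias, read_depth = 5000, seed = 100 + r)
    est <- bias_correct(cts, LENS, bias, B = 400, seed = 200 + r)
    hits <- hits + sum(m >= est$lower & m <= est$upper)
    total <- total + length(m)
  }
  coverage <- hits / total
  # nominal 95%; allow 3 binomial SE below (~0.90 at 120 checks)
  expect_gte(coverage, 0.95 - 3 * sqrt(0.95 * 0.05 / total))
})

test_that("raw counts understate the late stage; correction restores it", {
  # post-synchronization mixture with residual early-stage molecules: the
  # short stage-1 amplicon is inflated, so the raw stage-3 share is an
  # underestimate, in the direction the correction undoes
  bias <- bias_preset()
  m <- c(0.08, 0.08, 0.84)
  cts <- pcr_observe(m, LENS, bias, read_depth = 1e5, seed = 9)
  raw3 <- cts[3] / sum(cts)
  est <- estimate_stage_fractions(cts, LENS, bias, B = 200, seed = 10)
  expect_lt(raw3, est$estimate[3])
  expect_true(m[3] >= est$lower[3] && m[3] <= est$upper[3])
  # a single nonzero count maps to 100% of its stage
  one <- estimate_stage_fractions(c(0, 0, 777), LENS, bias, B = 10)
  expect_equal(one$estimate, c(0, 0, 1))
})
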