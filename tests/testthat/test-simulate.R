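fluor <- load_preset("gpcv2-fluor")$design

test_that("with zero leak and no ligand the population is frozen", {
  par <- kinetic_params(excision_hazard = 0.2, leak_hazard = 0)
  tr <- simulate_population(fluor, par,
                            schedule = ligand_schedule(NULL, horizon_h = 100),
                            n = 200, seed = 1, times = c(0, 50, 100))
  expect_equal(unname(tr$occupancy[, "stage1"]), rep(1, 3))
})

test_that("an ABA-first schedule causes no transitions in the first window", {
  # the first cassette is GIB-gated, so leading with ABA does nothing but
  # does not disrupt the subsequent GIB/ABA/GIB cascade
  w <- data.frame(ligand = c("ABA", "GIB", "ABA", "GIB"),
                  start_h = c(0, 60, 120, 180),
                  end_h = c(48, 108, 168, 228))
  par <- kinetic_params(excision_hazard = 0.2, leak_hazard = 0)
  tr <- simulate_population(fluor, par, schedule = ligand_schedule(w),
                            n = 500, seed = 2, times = c(48, 108, 168, 228))
  expect_equal(unname(tr$occupancy[1, "stage1"]), 1)
  expect_gt(tr$occupancy[4, "stage4"], 0.99)
})

test_that("stage indices are non-decreasing along every simulated path", {
  tr <- simulate_population(fluor, t1_params(), schedule = t1_schedule(),
                            n = 300, seed = 3)
  pop <- tr$population
  for (tt in list(c(0, 24), c(24, 60), c(60, 168))) {
    s1 <- stage_at(pop, tt[1]); s2 <- stage_at(pop, tt[2])
    ok <- is.na(s2) | (!is.na(s1) & s2 >= s1)
    expect_true(all(ok | is.na(s1)))
  }
  # entry-time matrix itself must be monotone by construction
  expect_true(all(apply(pop$entry, 1, function(r) !is.unsorted(r[is.finite(r)]))))
})

test_that("occupancy fractions sum to one at every sample time", {
  tr <- simulate_population(fluor, t1_params(), schedule = t1_schedule(),
                            n = 500, seed = 4)
  expect_equal(unname(rowSums(tr$occupancy)), rep(1, length(tr$times)),
               tolerance = 1e-12)
})

test_that("Monte-Carlo occupancy matches the Markov oracle within 3 SE at n = 10,000", {
  n <- 10000
  times <- c(48, 108, 168)
  tr <- simulate_population(fluor, t1_params(), schedule = t1_schedule(),
                            n = n, seed = 5, times = times)
  eo <- expected_occupancy(fluor, t1_params(), schedule = t1_schedule(),
                           times = times)
  se <- sqrt(pmax(eo * (1 - eo), 1e-12) / n)
  expect_true(all(abs(tr$occupancy - eo) <= 3 * se + 1e-9))
})

test_that("simulations are reproducible and per-cell substreams are n-invariant", {
  a <- simulate_population(fluor, t1_params(), schedule = t1_schedule(),
                           n = 50, seed = 9)
  b <- simulate_population(fluor, t1_params(), schedule = t1_schedule(),
                           n = 50, seed = 9)
  expect_identical(a$population$entry, b$population$entry)
  big <- simulate_population(fluor, t1_params(), schedule = t1_schedule(),
                             n = 80, seed = 9)
  expect_identical(big$population$entry[1:50, ], a$population$entry)
  c2 <- simulate_population(fluor, t1_params(), schedule = t1_schedule(),
                            n = 50, seed = 10)
  expect_false(identical(a$population$entry, c2$population$entry))
})

test_that("ligand orthogonality: ABA does not drive the GIB-gated cassette", {
  # stage-1 transitions under a pure-ABA window should be statistically
  # indistinguishable from the ligand-free leak
  par <- kinetic_params(excision_hazard = 0.2, leak_hazard = 2e-3)
  n <- 3000
  aba <- simulate_population(fluor, par,
    schedule = ligand_schedule(data.frame(ligand = "ABA", start_h = 0, end_h = 48)),
    n = n, seed = 11, times = 48)
  none <- simulate_population(fluor, par,
    schedule = ligand_schedule(NULL, horizon_h = 48),
    n = n, seed = 12, times = 48)
  moved_aba <- round((1 - aba$occupancy[1, "stage1"]) * n)
  moved_none <- round((1 - none$occupancy[1, "stage1"]) * n)
  p <- stats::prop.test(c(moved_aba, moved_none), c(n, n))$p.value
  expect_gt(p, 0.01)
})

test_that("a saturating excision hazard gives a deterministic cascade", {
  par <- kinetic_params(excision_hazard = 50, leak_hazard = 0)
  tr <- simulate_population(fluor, par, schedule = t1_schedule(),
                            n = 400, seed = 13, times = c(48, 108, 168))
  expect_equal(unname(tr$occupancy[1, "stage2"]), 1)
  expect_equal(unname(tr$occupancy[2, "stage3"]), 1)
  expect_equal(unname(tr$occupancy[3, "stage4"]), 1)
})

test_that("memory is retained for 8 ligand-free days at the calibrated leak", {
  tr <- simulate_population(fluor, kinetic_preset(),
                            schedule = ligand_schedule(NULL, horizon_h = 192),
                            n = 2000, seed = 14, times = 192, init_stage = 2)
  frac <- tr$occupancy[1, "stage2"]
  expect_gt(frac, 0.8)
  # and close to the closed form exp(-q * 192)
  expect_equal(unname(frac), exp(-5e-4 * 192), tolerance = 0.03)
})
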