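crispr <- load_preset("gpcv2-crispr")

crispr_trajectory <- function(n = 300, seed = 1) {
  sch <- build_schedule(crispr$design, stage_hours = 96)
  simulate_population(crispr$design, crispr$params, schedule = sch,
                      n = n, seed = seed,
                      times = seq(0, sch$horizon_h, by = 24))
}

test_that("zero editing hazard produces zero indel frequencies", {
  tr <- crispr_trajectory(100)
  ep <- editing_params(c(APC = 0, MLH1 = 0), sgRNA_halflife = 12)
  er <- simulate_editing(tr, ep, seed = 1)
  expect_true(all(er$frequencies$indel_fraction == 0))
})

test_that("unknown loci are excluded with a warning", {
  tr <- crispr_trajectory(50)
  expect_warning(
    er <- simulate_editing(tr, editing_params(c(APC = 0.02, NOPE = 0.02)), seed = 1),
    "NOPE")
  expect_identical(er$loci, "APC")
  expect_error(
    suppressWarnings(simulate_editing(tr, editing_params(c(NOPE = 0.02)))),
    "no locus")
})

test_that("indel frequencies are monotone and keep rising after excision (lag)", {
  tr <- crispr_trajectory(400)
  ep <- editing_params(c(APC = 0.02, MLH1 = 0.02, SMAD4 = 0.02, TP53 = 0.02),
                       sgRNA_halflife = 12)
  er <- simulate_editing(tr, ep, seed = 2)
  for (lc in er$loci) {
    f <- er$frequencies[er$frequencies$locus == lc, ]
    f <- f[order(f$time_h), ]
    expect_true(all(diff(f$indel_fraction) >= 0), label = lc)
  }
  # lag: APC's cassette is excised during the first window, yet APC editing
  # still climbs between the end of window 1 and the end of the run
  apc <- er$frequencies[er$frequencies$locus == "APC", ]
  apc <- apc[order(apc$time_h), ]
  f96 <- apc$indel_fraction[apc$time_h == 96]
  f_end <- apc$indel_fraction[nrow(apc)]
  expect_gt(f_end, f96)
})

test_that("Monte-Carlo editing matches the closed-form integral within 3 SE", {
  n_cells <- 2500   # x2 alleles = 5,000 Bernoulli draws per time point
  tr <- crispr_trajectory(n_cells, seed = 5)
  h <- 0.015
  ep <- editing_params(c(MLH1 = h), sgRNA_halflife = 12)
  er <- simulate_editing(tr, ep, seed = 3)
  pop <- tr$population
  d <- log(2) / 12
  k <- 2  # MLH1 cassette
  for (tt in c(96, 216, 312)) {
    # quadrature oracle: integrate the sgRNA abundance per cell numerically,
    # splitting at the (known) discontinuities
    p_cell <- vapply(seq_len(nrow(pop$entry)), function(i) {
      s0 <- pop$entry[i, k]; s1 <- min(pop$entry[i, k + 1], pop$deleted_at[i])
      g <- function(u) ifelse(u < s0, 0, ifelse(u < s1, 1, exp(-d * (u - s1))))
      cuts <- sort(unique(pmin(pmax(c(0, s0, s1, tt), 0), tt)))
      G <- sum(vapply(seq_len(length(cuts) - 1), function(j)
        if (cuts[j + 1] > cuts[j])
          stats::integrate(g, cuts[j], cuts[j + 1], rel.tol = 1e-8)$value
        else 0, 0))
      1 - exp(-h * G)
    }, 0)
    expected <- mean(p_cell)
    se <- sqrt(mean(p_cell * (1 - p_cell)) / (2 * n_cells))
    got <- er$frequencies$indel_fraction[er$frequencies$locus == "MLH1" &
                                         er$frequencies$time_h == tt]
    expect_lt(abs(got - expected), 3 * se + 1e-9)
  }
})
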