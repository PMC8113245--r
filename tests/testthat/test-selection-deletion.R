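attp <- load_preset("attp-gpcv2-crispr")

test_that("selection with survival_without = 1 leaves the population unchanged", {
  pop <- make_population(attp$design, stages = c(1, 2, 3, 3))
  out <- apply_selection(pop, marker_stage = 3, survival_with = 1,
                         survival_without = 1, seed = 1)
  expect_identical(out$alive, pop$alive)
})

test_that("hard selection keeps exactly the marker-stage cells (single copy)", {
  stages <- c(1, 2, 3, 3, 2, 1, 3)
  pop <- make_population(attp$design, stages = stages)
  out <- apply_selection(pop, 3, 1, 0, seed = 1)
  expect_identical(out$alive, stages == 3)
})

test_that("multi-copy selection matches brute-force enumeration on a 20-cell toy", {
  # 20 cells, copies 1 or 2 each; a cell survives iff ANY copy is at stage 3
  set.seed(99)
  copies <- rep(c(1L, 2L), 10)
  stages <- sample(1:4, sum(copies), replace = TRUE)
  pop <- make_population(attp$design, stages = stages, copies_per_cell = copies)
  out <- apply_selection(pop, 3, 1, 0, seed = 1)
  # enumeration oracle: walk the copy list per cell
  idx <- split(seq_along(stages), rep(seq_along(copies), copies))
  oracle <- vapply(idx, function(i) any(stages[i] == 3), TRUE)
  expect_identical(out$alive, unname(oracle))
})

test_that("partial survival probabilities act per cell", {
  stages <- rep(c(1, 3), each = 500)
  pop <- make_population(attp$design, stages = stages)
  out <- apply_selection(pop, 3, survival_with = 1, survival_without = 0.2, seed = 7)
  expect_true(all(out$alive[stages == 3]))
  frac_off <- mean(out$alive[stages == 1])
  expect_lt(abs(frac_off - 0.2), 3 * sqrt(0.2 * 0.8 / 500))
})

test_that("self-deletion follows the closed form 1 - exp(-h T) under GIB", {
  sch <- ligand_schedule(data.frame(ligand = "GIB", start_h = 0, end_h = 48))
  n <- 4000
  pop <- make_population(attp$design, stages = rep(3L, n), params = attp$params)
  out <- self_delete(pop, attp$params, pk_preset("ga4"), sch, seed = 3)
  frac <- mean(is.finite(out$deleted_at))
  p_true <- 1 - exp(-attp$params$self_deletion_hazard * 48)
  expect_equal(p_true, 0.78, tolerance = 1e-12)  # calibration identity
  expect_lt(abs(frac - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
  # zero hazard deletes nothing
  par0 <- kinetic_params(self_deletion_hazard = 0)
  out0 <- self_delete(pop, par0, pk_preset("ga4"), sch, seed = 3)
  expect_false(any(is.finite(out0$deleted_at)))
})

test_that("self-deletion requires an att wrapper", {
  pop <- make_population(load_preset("gpcv2-fluor")$design, stages = c(3, 3))
  sch <- ligand_schedule(data.frame(ligand = "GIB", start_h = 0, end_h = 48))
  expect_error(self_delete(pop, kinetic_preset(), pk_preset("ga4"), sch),
               class = "gpcsim_no_att_wrapper")
})

test_that("the qPCR ratio tracks the non-deleted copy fraction", {
  pop <- make_population(attp$design, stages = rep(3L, 100))
  expect_equal(qpcr_excision_ratio(pop)$ratio, 1)
  pop$deleted_at[] <- 0
  expect_equal(qpcr_excision_ratio(pop)$ratio, 0)
  pop$deleted_at <- c(rep(0, 78), rep(Inf, 22))
  expect_equal(qpcr_excision_ratio(pop)$ratio, 0.22)
})

test_that("in the joint simulation GIB at the PhiC31 stage deletes the circuit", {
  sch <- build_schedule(c("GIB", "ABA", "GIB"), stage_hours = 48)
  tr <- simulate_population(attp$design, attp$params, schedule = sch,
                            n = 1500, seed = 21)
  final <- tr$occupancy[nrow(tr$occupancy), ]
  p_del <- 1 - exp(-attp$params$self_deletion_hazard * 48)
  # most cells that reached stage 3 self-delete during the final GIB window
  expect_gt(final[["deleted"]], 0.6)
  expect_equal(final[["stage4"]], 0)  # wrapped circuits never "advance" past PhiC31
})
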