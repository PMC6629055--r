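test_that("population sampling is uniform over the box and reproducible", {
  n <- 1000
  pop <- samplePopulation(n, seed = 3)
  for (nm in c("rho", "alpha1", "alpha2", "P0", "K")) {
    b <- slot(ParameterBox(), nm)
    x <- vapply(pop, function(p) slot(p, nm), numeric(1))
    mid <- mean(b); se <- diff(b) / sqrt(12) / sqrt(n)
    expect_lt(abs(mean(x) - mid), 3 * se)
    expect_gte(min(x), b[1])
    expect_lte(max(x), b[2])
  }
  expect_true(all(vapply(pop, function(p) p@kappa, numeric(1)) == 1))

  pop2 <- samplePopulation(n, seed = 3)
  expect_identical(lapply(pop2, coef), lapply(pop, coef))

  # collapsed box: identical patients; inverted bounds: rejected
  same <- samplePopulation(5, ParameterBox(rho = c(1e-3, 1e-3),
                                           alpha1 = c(0.3, 0.3),
                                           alpha2 = c(0.2, 0.2),
                                           P0 = c(50, 50), K = c(500, 500)))
  expect_length(unique(lapply(same, coef)), 1L)
  expect_error(ParameterBox(rho = c(2e-3, 1e-3)), "low <= high")
})

test_that("a self-comparison trial is null", {
  sch <- standardSchedule(10)
  tr <- runTrial(60, armA = sch, armB = sch, seed = 2,
                 labels = c("std", "std-copy"))
  expect_equal(tr@hr, 1, tolerance = 1e-6)
  expect_equal(tr@logrankP, 1, tolerance = 1e-6)
  expect_equal(tr@medianDifference, 0)
  expect_equal(nrow(tr@outcomes), 120L)
})

test_that("trials are paired: same patients in both arms", {
  tr <- runTrial(25, armA = standardSchedule(12),
                 armB = combinedSchedule(), seed = 9)
  o <- tr@outcomes
  expect_equal(sort(unique(o$patient)), 1:25)
  expect_equal(table(o$arm)[[1]], 25L)
})

test_that("the 5+12 arm dominates the standard arm in a small trial", {
  tr <- runTrial(150, seed = 5)
  expect_lt(tr@hr, 1)
  expect_lt(tr@logrankP, 0.05)
  expect_gt(tr@medianDifference, 0)
})

test_that("twin benefit vanishes for treatment-insensitive patients and identical schedules", {
  insensitive <- PatientParams(P0 = 40, rho = 1.5e-3, alpha1 = 1e-9,
                               alpha2 = 1e-9)
  expect_equal(twinBenefit(insensitive, 8), 0, tolerance = 1e-4)
  # 17 standard cycles coincide with the degenerate 5+12 layout
  pat <- patientFromTable(cohortTable, 6)
  ben <- twinBenefit(pat, 17,
                     combined = combinedSchedule(maintenancePeriod = 28))
  expect_equal(ben, 0, tolerance = 1e-8)
})

test_that("maximum volume reduction follows its contracts", {
  pat <- patientFromTable(cohortTable, 6)
  # no treatment on a growing tumor: never below V(0)
  expect_equal(maxVolumeReduction(pat, DoseSchedule()), 0)
  # drug-insensitive patient: no reduction regardless of schedule
  numb <- PatientParams(P0 = 40, rho = 1e-3, alpha1 = 1e-12,
                        alpha2 = 1e-12)
  expect_lt(maxVolumeReduction(numb, standardSchedule(10)), 1e-6)
  # more cycles at fixed spacing: reduction non-decreasing
  red <- vapply(c(1, 3, 6, 12, 20), function(nc)
    maxVolumeReduction(pat, standardSchedule(nc)), numeric(1))
  expect_true(all(diff(red) >= -1e-8))
  expect_gt(red[5], red[1])
})

test_that("power sweep is reproducible and returns the grid layout", {
  g1 <- powerSweep(c(6, 10), trialsPerSize = 2, seed = 31)
  g2 <- powerSweep(c(6, 10), trialsPerSize = 2, seed = 31)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 4L)
  expect_named(g1, c("n_per_arm", "trial_index", "p_value"))
  expect_true(all(g1$p_value >= 0 & g1$p_value <= 1))
  sf <- significantFraction(g1)
  expect_equal(sf$n_per_arm, c(6L, 10L))
})
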