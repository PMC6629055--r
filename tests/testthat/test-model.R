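test_that("right-hand side matches the model equations at hand-checked states", {
  # at carrying capacity with no drug every term vanishes
  d <- tumorDerivatives(c(P = patient6@K, D = 0, C = 0), patient6)
  expect_equal(unname(d), c(0, 0, 0))

  # pure logistic term for patient 6 at the initial volume
  d <- tumorDerivatives(c(P = 46, D = 0, C = 0), patient6)
  expect_equal(d[["P"]], 1.01e-3 * 46 * (1 - 46 / 523.6), tolerance = 1e-12)
  expect_equal(d[["D"]], 0)

  # no proliferative cells: drug terms vanish, D decays, C clears
  pat <- PatientParams(P0 = 10, rho = 2e-3, alpha1 = 0.5, alpha2 = 0.2,
                       K = 500)
  d <- tumorDerivatives(c(P = 0, D = 10, C = 0.6), pat, defaultPK)
  expect_equal(d[["P"]], 0)
  expect_equal(d[["D"]], -2e-3 * 10 * (1 - 10 / 500), tolerance = 1e-12)
  expect_equal(d[["C"]], -8.3184 * 0.6, tolerance = 1e-12)

  expect_error(tumorDerivatives(c(P = NaN, D = 0, C = 0), pat),
               "finite")
})

test_that("dose impulses increment C only and are additive", {
  s <- c(P = 30, D = 2, C = 0)
  s1 <- applyDose(s, 0.6)
  expect_equal(s1[["C"]], 0.6)
  expect_equal(s1[["P"]], 30)
  expect_equal(s1[["D"]], 2)
  expect_equal(applyDose(s1, 0)[["C"]], 0.6)        # zero dose is identity
  expect_equal(applyDose(applyDose(s, 0.6), 0.6)[["C"]], 1.2)
  expect_error(applyDose(s, -0.1), "non-negative")
})

test_that("inter-dose decay follows the exponential closed form", {
  expect_equal(drugConcentration(0.6, 8.3184, 0), 0.6)
  # half-life is forced by the exponential form
  expect_equal(drugConcentration(0.6, 8.3184, log(2) / 8.3184), 0.3)
  expect_equal(drugConcentration(0.6, 8.3184, 1), 0.6 * exp(-8.3184))
  expect_error(drugConcentration(0.6, 8.3184, -1), "dt")
})

test_that("logistic closed form has its fixed point and initial value", {
  expect_equal(logisticVolume(523.6, 1e-3, 523.6, 1234), 523.6)
  expect_equal(logisticVolume(46, 1.01e-3, 523.6, 0), 46)
  expect_equal(logisticVolume(46, 1.01e-3, 523.6, 365), 63.99951,
               tolerance = 1e-6)
  expect_warning(logisticVolume(600, 1e-3, 523.6, 10), "decaying")
})

test_that("drug-free simulation matches the logistic closed form", {
  tms <- seq(0, 25 * 365, length.out = 40)
  tr <- simulateTumor(patient6, times = tms)
  expect_equal(tr@P, refLogistic(46, 1.01e-3, 523.6, tms),
               tolerance = 1e-6)
  expect_equal(tr@D, rep(0, length(tms)))  # drug-free: no damage created
  expect_equal(tr@C, rep(0, length(tms)))
})

test_that("zero-amplitude impulses reproduce the untreated trajectory", {
  tms <- seq(0, 365, by = 5)
  sch <- standardSchedule(3)
  tr0 <- simulateTumor(patient6, schedule = DoseSchedule(), times = tms)
  trz <- simulateTumor(patient6, PKParams(C0 = 0), sch, times = tms)
  expect_equal(trz@P, tr0@P, tolerance = 1e-10)
})

test_that("adaptive integration agrees with a fine fixed-step reference", {
  # one impulse at t = 0, 30-day window, Euler h = 1e-4 d
  pat <- PatientParams(P0 = 46, rho = 1.01e-3, alpha1 = 0.32, alpha2 = 0.1)
  ref <- eulerReference(pat, defaultPK, doseTimes = 0, doseAmount = 0.6,
                        tEnd = 30)
  tr <- simulateTumor(pat, defaultPK, DoseSchedule(0, 0.6),
                      times = c(0, 15, 30))
  expect_equal(tr@P[3], ref[["P"]], tolerance = 1e-3)
  expect_equal(tr@D[3], ref[["D"]], tolerance = 1e-3)
})

test_that("C is piecewise exponential between doses", {
  sch <- standardSchedule(2)
  probe <- c(4.25, 4.5, 4.9, 28.3, 32.25, 32.75)  # interior checkpoints
  tr <- simulateTumor(patient6, defaultPK, sch,
                      times = sort(unique(c(seq(0, 60, 0.25), probe))))
  dts <- doseTimes(sch)
  for (tp in probe) {
    prev <- max(dts[dts <= tp])
    # reported state at a dose time is pre-impulse: add the dose
    cAfter <- tr@C[match(prev, tr@times)] + defaultPK@C0
    expect_equal(tr@C[match(tp, tr@times)],
                 drugConcentration(cAfter, defaultPK@lam, tp - prev),
                 tolerance = 1e-6)
  }
})

test_that("simultaneous doses are summed into one impulse", {
  tms <- seq(0, 30, by = 1)
  trDup <- simulateTumor(patient6, defaultPK,
                         DoseSchedule(c(0, 0, 5), c(0.6, 0.6, 0.6)),
                         times = tms)
  trOne <- simulateTumor(patient6, defaultPK,
                         DoseSchedule(c(0, 5), c(1.2, 0.6)), times = tms)
  expect_equal(trDup@P, trOne@P, tolerance = 1e-9)
  expect_equal(trDup@C, trOne@C, tolerance = 1e-9)
})

test_that("trajectories stay non-negative and below carrying capacity", {
  set.seed(17)
  box <- ParameterBox()
  pats <- samplePopulation(8, box)
  schedules <- list(DoseSchedule(), standardSchedule(6),
                    combinedSchedule(), longCycleSchedule(4, 83))
  for (pat in pats) {
    for (sch in schedules) {
      tr <- simulateTumor(pat, defaultPK, sch,
                          times = seq(0, 3000, by = 5))
      tol <- 1e-9 * pat@K
      expect_gte(min(tr@P), -tol)
      expect_gte(min(tr@D), -tol)
      expect_gte(min(tr@C), -tol)
      expect_lte(max(totalVolume(tr)), pat@K + 1e-6 * pat@K)
    }
  }
})

test_that("untreated time-to-threshold matches the inverted logistic", {
  # t* = (1/rho) log[ th (K - P0) / (P0 (K - th)) ]
  for (id in c(6, 105, 213)) {
    pat <- patientFromTable(cohortTable, id)
    cf <- coef(pat)
    tStar <- log(280 * (cf[["K"]] - cf[["P0"]]) /
                 (cf[["P0"]] * (cf[["K"]] - 280))) / cf[["rho"]]
    out <- timeToThreshold(pat, schedule = DoseSchedule(),
                           horizonYears = 200)
    expect_true(out$event)
    expect_equal(out$time * 365, tStar, tolerance = 1e-4)
  }
})

test_that("threshold handling covers the degenerate contracts", {
  pat <- PatientParams(P0 = 300, rho = 1e-3, alpha1 = 0.3, alpha2 = 0.1)
  out <- timeToThreshold(pat, schedule = DoseSchedule(), threshold = 280)
  expect_true(out$event)
  expect_equal(out$time, 0)

  expect_error(timeToThreshold(pat, threshold = 600), "carrying capacity")

  # highly effective drug on a slow tumor: censored at the horizon
  slow <- PatientParams(P0 = 30, rho = 6e-4, alpha1 = 2.5, alpha2 = 1.2)
  out <- timeToThreshold(slow, defaultPK, standardSchedule(18),
                         horizonYears = 25)
  expect_false(out$event)
  expect_equal(out$time, 25)
})

test_that("survival is monotone in the per-dose concentration", {
  sch <- standardSchedule(8)
  c0s <- c(0, 0.2, 0.4, 0.6, 0.9)
  tt <- vapply(c0s, function(c0)
    timeToThreshold(patient6, PKParams(C0 = c0), sch,
                    horizonYears = 200)$time, numeric(1))
  expect_true(all(diff(tt) >= -1e-9))
})

test_that("trajectory container accessors and CSV round-trip work", {
  tr <- simulateTumor(patient6, schedule = standardSchedule(2),
                      times = seq(0, 100, by = 10))
  expect_s4_class(tr, "Trajectory")
  expect_equal(totalVolume(tr), tr@P + tr@D)
  expect_equal(length(tr), 11L)
  f <- tempfile(fileext = ".csv")
  writeTrajectory(tr, f)
  back <- read.csv(f)
  expect_named(back, c("t_days", "P_cm3", "D_cm3", "C_ug_per_cm3", "V_cm3"))
  expect_equal(back$V_cm3, totalVolume(tr))
})
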