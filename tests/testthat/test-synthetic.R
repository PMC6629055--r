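test_that("noise-free generation lies exactly on the model curve", {
  des <- observationDesign(noiseCV = 0)
  sch <- standardSchedule(11, start = des$nPre * des$spacing)
  obs <- generatePatientSeries(patient6, defaultPK, sch, des)
  tr <- simulateTumor(patient6, defaultPK, sch,
                      times = sort(unique(c(0, obs$t))))
  expect_equal(obs$volume, totalVolume(tr)[match(obs$t, tr@times)])
})

test_that("generated series show the four-stage response pattern", {
  des <- observationDesign(nPre = 3, nDuring = 4, nPost = 14,
                           spacing = 90, noiseCV = 0)
  sch <- standardSchedule(11, start = 270)
  obs <- generatePatientSeries(patient6, defaultPK, sch, des)
  pre <- obs$volume[obs$t <= 270]
  expect_true(all(diff(pre) > 0))                 # pre-treatment growth
  nadir <- min(obs$volume)
  expect_lt(nadir, pre[length(pre)])              # response below baseline
  tail <- obs$volume[obs$t > obs$t[which.min(obs$volume)]]
  expect_gt(tail[length(tail)], nadir)            # regrowth after nadir
})

test_that("generation is seed-deterministic and noise has the right CV", {
  des <- observationDesign(noiseCV = 0.18)
  sch <- standardSchedule(5, start = 270)
  o1 <- generatePatientSeries(patient6, defaultPK, sch, des, seed = 8)
  o2 <- generatePatientSeries(patient6, defaultPK, sch, des, seed = 8)
  expect_identical(o1, o2)
  expect_true(all(o1$volume > 0))

  # empirical CV of observed/true over many draws
  set.seed(12)
  sdlog <- sqrt(log(1 + 0.18^2))
  mult <- exp(rnorm(1e4, -sdlog^2 / 2, sdlog))
  expect_equal(sd(mult) / mean(mult), 0.18, tolerance = 0.02)
})

test_that("ellipsoidal volume follows the halved-product formula", {
  expect_equal(ellipsoidVolume(2, 2, 2), 4)
  expect_equal(ellipsoidVolume(8, 8, 8), 256)
  expect_equal(ellipsoidVolume(1, 2, 3), ellipsoidVolume(3, 1, 2))
  expect_error(ellipsoidVolume(0, 1, 1), "> 0")
})

test_that("cohort factory pairs truths with series and validates n", {
  coh <- sampleCohort(4, seed = 6)
  expect_length(coh, 4L)
  for (p in coh) {
    expect_s4_class(p$params, "PatientParams")
    expect_s4_class(p$schedule, "DoseSchedule")
    expect_equal(length(p$schedule), 5L * p$cycles)
    expect_gte(nrow(p$series), 4L)
  }
  expect_error(sampleCohort(0), "n must be")

  # injected cohort parameters give a synthetic replica of the study
  pats <- lapply(cohortTable$id, patientFromTable, table = cohortTable)
  rep11 <- sampleCohort(n = 11, patients = pats,
                        cycles = cohortTable$n_cycles, seed = 1)
  expect_length(rep11, 11L)
  expect_equal(vapply(rep11, function(p) coef(p$params)[["P0"]],
                      numeric(1)), cohortTable$P0)
})

test_that("end-to-end recovery on a noiseless cohort member returns the truth", {
  des <- observationDesign(nPre = 3, nDuring = 5, nPost = 12,
                           spacing = 90, noiseCV = 0)
  # K is fixed (not fitted), so the generating cohort shares it
  boxK <- ParameterBox(K = c(523.6, 523.6))
  coh <- sampleCohort(2, box = boxK, design = des, seed = 14)
  p <- coh[[1]]
  fit <- fitPatient(p$series, p$schedule, nStarts = 6, seed = 14)
  expect_equal(coef(fit)[1:4], coef(p$params)[1:4], tolerance = 0.01)
})
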