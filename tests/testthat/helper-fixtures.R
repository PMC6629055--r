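# Shared fixtures: the fitted reference cohort, canonical PK constants,
# and a brute-force fixed-step integrator used as an independent oracle.

cohortTable <- patientTable()

patient6 <- patientFromTable(cohortTable, 6)    # P0 46.0, rho 1.01e-3
patient10 <- patientFromTable(cohortTable, 10)  # P0 45.4, rho 7.06e-4

defaultPK <- PKParams()  # lam 8.3184 /day, C0 0.6 ug/cm^3

# Closed-form logistic, independent of the package's implementation.
refLogistic <- function(P0, rho, K, t) {
  e <- exp(rho * t)
  K * P0 * e / (K + P0 * (e - 1))
}

# Fixed-step explicit Euler integration of the model with impulses,
# written independently of the solver path it cross-checks.
eulerReference <- function(pat, pk, doseTimes, doseAmount, tEnd, h = 1e-4) {
  cf <- coef(pat)
  P <- cf[["P0"]]; D <- 0; C <- 0
  t <- 0
  doseTimes <- sort(doseTimes)
  nextDose <- 1L
  nSteps <- ceiling(tEnd / h)
  for (i in seq_len(nSteps)) {
    while (nextDose <= length(doseTimes) && doseTimes[nextDose] <= t + 1e-12) {
      C <- C + doseAmount
      nextDose <- nextDose + 1L
    }
    crowd <- 1 - (P + D) / cf[["K"]]
    dP <- cf[["rho"]] * P * crowd - (cf[["alpha1"]] + cf[["alpha2"]]) * P * C
    dD <- -(cf[["rho"]] / cf[["kappa"]]) * D * crowd + cf[["alpha1"]] * P * C
    dC <- -defaultPK@lam * C
    P <- P + h * dP; D <- D + h * dD; C <- C + h * dC
    t <- t + h
  }
  c(P = P, D = D, C = C)
}

# Noiseless follow-up design dense enough to identify all four free
# parameters (pre-growth, on-treatment decline, nadir, regrowth).
recoveryDesign <- function(noiseCV = 0) {
  observationDesign(nPre = 3, nDuring = 5, nPost = 12, spacing = 90,
                    noiseCV = noiseCV)
}

# Simulate a noiseless series for a cohort-table row and fit it back.
fitTableRow <- function(tab, i, nStarts = 6, seed = 99, noiseCV = 0) {
  pat <- patientFromTable(tab, tab$id[i])
  des <- recoveryDesign(noiseCV)
  sch <- standardSchedule(tab$n_cycles[i], start = des$nPre * des$spacing)
  obs <- generatePatientSeries(pat, defaultPK, sch, des, seed = seed)
  list(truth = coef(pat),
       fit = fitPatient(obs, sch, nStarts = nStarts, seed = seed))
}
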