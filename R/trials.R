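#' Sample a virtual patient population
#'
#' Draws \code{n} virtual patients with parameters sampled independently
#' and uniformly from the box; \code{kappa} is fixed at 1. Reproducible
#' given \code{seed}.
#'
#' @param n number of patients (>= 1).
#' @param box a \linkS4class{ParameterBox}.
#' @param seed optional integer seed.
#' @return A list of \linkS4class{PatientParams}.
#' @export
samplePopulation <- function(n, box = ParameterBox(), seed = NULL) {
  stopifnot(is(box, "ParameterBox"))
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(b) runif(n, b[1], b[2])
  rho <- draw(box@rho); a1 <- draw(box@alpha1); a2 <- draw(box@alpha2)
  P0 <- draw(box@P0); K <- draw(box@K)
  lapply(seq_len(n), function(i)
    PatientParams(P0 = P0[i], rho = rho[i], alpha1 = a1[i],
                  alpha2 = a2[i], K = K[i], kappa = 1))
}

# Normalize an arm specification to a generator function: a fixed
# DoseSchedule, or a function() drawing a schedule per patient from the
# current RNG stream.
.armGenerator <- function(spec) {
  if (is(spec, "DoseSchedule")) return(function() spec)
  if (is.function(spec)) return(spec)
  stop("arm specification must be a DoseSchedule or a function")
}

#' Default standard-of-care arm
#'
#' Schedule generator for the reference arm of the virtual trials: each
#' patient receives a uniformly random number of standard 28-day cycles
#' in the range spanned by the real cohort (5 to 18).
#'
#' @param minCycles,maxCycles inclusive cycle-count range.
#' @return A function drawing one \linkS4class{DoseSchedule} per call
#'   from the current RNG stream.
#' @export
randomStandardArm <- function(minCycles = 5, maxCycles = 18) {
  function() standardSchedule(sample(seq.int(minCycles, maxCycles), 1L))
}

#' Run a paired two-arm virtual trial
#'
#' Samples one virtual population and gives \emph{the same} patients
#' both arms' schedules (a paired design: any survival difference is
#' attributable to the schedule alone). Per-patient survival is the
#' time for \code{P + D} to reach \code{threshold}, censored at
#' \code{followupYears}. Arm-level statistics are the Kaplan-Meier
#' medians, the two-sample log-rank test, and the Cox hazard ratio of
#' arm B versus arm A.
#'
#' @param nPerArm patients per arm (>= 2).
#' @param box a \linkS4class{ParameterBox} to sample from.
#' @param armA,armB arm specifications: a fixed
#'   \linkS4class{DoseSchedule} or a schedule-generator function.
#'   Defaults: arm A random 5-18 standard cycles, arm B the 5+12
#'   combined scheme.
#' @param threshold lethal volume, cm^3 (default 280).
#' @param followupYears censoring horizon, years (default 25).
#' @param seed optional integer seed.
#' @param pk a \linkS4class{PKParams}.
#' @param labels arm labels, length 2.
#' @return A \linkS4class{TrialResult}. \code{medianDifference} is
#'   arm B minus arm A in years (positive when arm B survives longer),
#'   \code{NA} when either median is not reached.
#' @export
runTrial <- function(nPerArm, box = ParameterBox(),
                     armA = randomStandardArm(), armB = combinedSchedule(),
                     threshold = 280, followupYears = 25, seed = NULL,
                     pk = PKParams(),
                     labels = c("standard", "5+12")) {
  if (length(nPerArm) != 1L || is.na(nPerArm) || nPerArm < 2)
    stop("nPerArm must be >= 2")
  nPerArm <- as.integer(nPerArm)
  if (!is.null(seed)) set.seed(seed)
  patients <- samplePopulation(nPerArm, box)
  genA <- .armGenerator(armA)
  genB <- .armGenerator(armB)

  one <- function(pat, gen) {
    timeToThreshold(pat, pk, gen(), threshold = threshold,
                    horizonYears = followupYears)
  }
  outA <- lapply(patients, one, gen = genA)
  outB <- lapply(patients, one, gen = genB)
  armAout <- ArmSurvival(vapply(outA, `[[`, numeric(1), "time"),
                         vapply(outA, `[[`, logical(1), "event"),
                         label = labels[1])
  armBout <- ArmSurvival(vapply(outB, `[[`, numeric(1), "time"),
                         vapply(outB, `[[`, logical(1), "event"),
                         label = labels[2])

  lr <- logrankTest(armAout, armBout)
  hr <- tryCatch(coxHR(armAout, armBout),
                 error = function(e) list(hr = NA_real_,
                                          ci = c(NA_real_, NA_real_)))
  medA <- kmMedian(armAout)
  medB <- kmMedian(armBout)
  outcomes <- data.frame(
    patient = rep(seq_len(nPerArm), 2L),
    arm = rep(labels, each = nPerArm),
    time_years = c(armAout@time, armBout@time),
    event = c(armAout@event, armBout@event))
  new("TrialResult", medianA = medA, medianB = medB,
      medianDifference = medB - medA,
      logrankStat = lr$statistic, logrankP = lr$p,
      hr = hr$hr, hrCI = hr$ci, outcomes = outcomes, labels = labels)
}

#' Power sweep over trial sizes
#'
#' For each trial size, runs independent virtual trials (fresh
#' populations, sub-seeds spawned from the master seed so trials are
#' reproducible and order-independent) and records the log-rank
#' p-value of each.
#'
#' @param sizes patients-per-arm values (the reference sweep is 20 to
#'   110 in steps of 10).
#' @param trialsPerSize independent trials per size (default 20).
#' @param followupYears follow-up horizon with censoring (default 10).
#' @param box a \linkS4class{ParameterBox}.
#' @param seed master integer seed.
#' @param ... further arguments passed to \code{\link{runTrial}}.
#' @return A data.frame with columns \code{n_per_arm},
#'   \code{trial_index}, \code{p_value}.
#' @seealso \code{\link{significantFraction}}
#' @export
powerSweep <- function(sizes, trialsPerSize = 20, followupYears = 10,
                       box = ParameterBox(), seed = NULL, ...) {
  if (!length(sizes)) stop("sizes must be non-empty")
  if (trialsPerSize < 1) stop("trialsPerSize must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max,
                         length(sizes) * trialsPerSize)
  grid <- expand.grid(trial_index = seq_len(trialsPerSize),
                      n_per_arm = as.integer(sizes))
  grid$p_value <- vapply(seq_len(nrow(grid)), function(i) {
    tr <- runTrial(grid$n_per_arm[i], box = box,
                   followupYears = followupYears, seed = subSeeds[i], ...)
    tr@logrankP
  }, numeric(1))
  grid[, c("n_per_arm", "trial_index", "p_value")]
}

#' Fraction of significant trials per size
#'
#' @param grid a data.frame from \code{\link{powerSweep}}.
#' @param alpha significance level (default 0.05).
#' @return A data.frame with \code{n_per_arm} and \code{fraction}
#'   (proportion of trials with p < alpha).
#' @export
significantFraction <- function(grid, alpha = 0.05) {
  agg <- aggregate(p_value ~ n_per_arm, data = grid,
                   FUN = function(p) mean(p < alpha))
  names(agg)[2] <- "fraction"
  agg
}

#' Survival benefit of the 5+12 scheme for one in-silico twin
#'
#' Time-to-threshold under the combined induction-plus-maintenance
#' scheme minus time-to-threshold under the patient's actual number of
#' standard 28-day cycles, both with treatment starting at t = 0 and a
#' long horizon in place of the usual censoring (the benefit of a
#' well-controlled tumor can span decades).
#'
#' @param params the twin's \linkS4class{PatientParams}.
#' @param realNCycles number of standard cycles the real patient
#'   received (>= 1).
#' @param threshold lethal volume, cm^3.
#' @param pk a \linkS4class{PKParams}.
#' @param horizonYears horizon bounding both survival times (default
#'   200 years).
#' @param combined the comparison schedule (default the 5+12 scheme).
#' @return Benefit in years (combined minus standard).
#' @export
twinBenefit <- function(params, realNCycles, threshold = 280,
                        pk = PKParams(), horizonYears = 200,
                        combined = combinedSchedule()) {
  if (realNCycles < 1) stop("realNCycles must be >= 1")
  std <- timeToThreshold(params, pk, standardSchedule(realNCycles),
                         threshold = threshold,
                         horizonYears = horizonYears)
  cmb <- timeToThreshold(params, pk, combined, threshold = threshold,
                         horizonYears = horizonYears)
  if (!std$event || !cmb$event)
    warning("threshold not reached within the horizon; ",
            "benefit is censored")
  cmb$time - std$time
}

#' Maximum relative volume reduction under a schedule
#'
#' \code{100 * (1 - min_t V(t) / V(0))} over the simulation horizon,
#' where \code{V = P + D}. A schedule that never shrinks the tumor
#' scores 0.
#'
#' @param params a \linkS4class{PatientParams}.
#' @param schedule a \linkS4class{DoseSchedule}.
#' @param pk a \linkS4class{PKParams}.
#' @param horizonDays simulation horizon; defaults to the last dose
#'   plus five years (the volume nadir can trail the end of treatment
#'   by many months), or one year for an empty schedule.
#' @return Percent reduction (>= 0 up to 100).
#' @export
maxVolumeReduction <- function(params, schedule, pk = PKParams(),
                               horizonDays = NULL) {
  stopifnot(is(schedule, "DoseSchedule"))
  if (is.null(horizonDays)) {
    horizonDays <- if (length(schedule@doseTimes))
      max(schedule@doseTimes) + 5 * 365 else 365
  }
  tr <- simulateTumor(params, pk, schedule,
                      times = seq(0, horizonDays, by = 1))
  V <- totalVolume(tr)
  max(0, 100 * (1 - min(V) / V[1]))
}

#' @importFrom stats aggregate
NULL
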