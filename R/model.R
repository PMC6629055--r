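#' Model right-hand side
#'
#' Time derivatives of the two-compartment tumor model with exponential
#' drug clearance. The proliferative volume \code{P} grows logistically
#' towards the carrying capacity \code{K} shared with the damaged
#' compartment \code{D}; drug exposure moves volume from \code{P} to
#' \code{D} at rate \code{alpha1*P*C} and removes it directly at rate
#' \code{alpha2*P*C}; damaged cells die by mitotic catastrophe at rate
#' \code{(rho/kappa) * (1 - (P+D)/K)}; the drug is cleared at rate
#' \code{lam}.
#'
#' @param state named numeric vector with components \code{P}, \code{D}
#'   (cm^3) and \code{C} (ug/cm^3).
#' @param params a \linkS4class{PatientParams}.
#' @param pk a \linkS4class{PKParams} supplying the elimination rate.
#' @return Named numeric vector \code{c(P =, D =, C =)} of derivatives
#'   per day.
#' @export
tumorDerivatives <- function(state, params, pk = PKParams()) {
  stopifnot(is(params, "PatientParams"), is(pk, "PKParams"))
  P <- state[["P"]]; D <- state[["D"]]; C <- state[["C"]]
  if (any(!is.finite(c(P, D, C))))
    stop("invalid state: P, D, C must all be finite")
  crowd <- 1 - (P + D) / params@K
  c(P = params@rho * P * crowd - (params@alpha1 + params@alpha2) * P * C,
    D = -(params@rho / params@kappa) * D * crowd + params@alpha1 * P * C,
    C = -pk@lam * C)
}

#' Apply a dose impulse to a model state
#'
#' Drug administration is instantaneous on the model's time scales:
#' the tissue concentration jumps by \code{amount} while the tumor
#' compartments are unchanged.
#'
#' @param state named numeric vector with components \code{P}, \code{D},
#'   \code{C}.
#' @param amount concentration increment, ug/cm^3 (>= 0).
#' @return The state with \code{C} incremented.
#' @export
applyDose <- function(state, amount) {
  if (length(amount) != 1L || is.na(amount) || amount < 0)
    stop("dose amount must be a single non-negative number")
  state[["C"]] <- state[["C"]] + amount
  state
}

#' Inter-dose drug decay (closed form)
#'
#' Between impulses the tissue concentration decays exponentially,
#' \code{C(t) = C0 * exp(-lam * dt)}.
#'
#' @param C0 concentration at the start of the interval, ug/cm^3.
#' @param lam elimination rate, day^-1.
#' @param dt elapsed time, days (>= 0); vectorized.
#' @return Concentration after \code{dt} days.
#' @export
drugConcentration <- function(C0, lam, dt) {
  if (any(is.na(dt)) || any(dt < 0)) stop("dt must be >= 0")
  C0 * exp(-lam * dt)
}

#' Drug-free logistic growth (closed form)
#'
#' Without treatment the proliferative volume follows the logistic law
#' \code{K * P0 * exp(rho*t) / (K + P0 * (exp(rho*t) - 1))}, used as an
#' exact oracle for the integrator.
#'
#' @param P0 initial volume, cm^3 (0 < P0; values above \code{K} are
#'   admissible mathematically and produce the decaying branch, with a
#'   warning).
#' @param rho growth rate, day^-1.
#' @param K carrying capacity, cm^3.
#' @param t time, days; vectorized.
#' @return Volume at time \code{t}, cm^3.
#' @export
logisticVolume <- function(P0, rho, K, t) {
  if (P0 <= 0) stop("P0 must be > 0")
  if (P0 > K) warning("P0 > K: volume is on the decaying branch")
  e <- exp(rho * t)
  K * P0 * e / (K + P0 * (e - 1))
}

# Resolve per-dose amounts, merge simultaneous doses, drop doses beyond
# the simulation window; returns NULL for an effectively empty schedule.
.doseEvents <- function(schedule, pk, tMax) {
  tms <- schedule@doseTimes
  amt <- schedule@doseAmounts
  if (!length(amt)) amt <- rep(pk@C0, length(tms))
  keep <- tms <= tMax
  tms <- tms[keep]; amt <- amt[keep]
  if (!length(tms) || all(amt == 0)) return(NULL)
  if (anyDuplicated(tms)) {            # simultaneous doses sum into one impulse
    amt <- as.numeric(tapply(amt, tms, sum))
    tms <- sort(unique(tms))
  }
  data.frame(var = "C", time = tms, value = amt, method = "add")
}

# Single integration pass over [0, tMax]. When `threshold` is finite the
# run uses lsodar with a root on P + D - threshold and stops there.
.integrate <- function(params, pk, schedule, times, threshold = NA_real_,
                       rtol = 1e-8, atol = 1e-10) {
  tMax <- max(times)
  evt <- .doseEvents(schedule, pk, tMax)
  fullTimes <- if (is.null(evt)) times else
    sort(unique(c(times, evt$time)))
  y0 <- c(P = params@P0, D = 0, C = 0)
  parms <- c(params@rho, params@K, params@alpha1, params@alpha2,
             params@kappa, pk@lam,
             if (is.na(threshold)) params@K * 2 else threshold)
  args <- list(y = y0, times = fullTimes, func = "tmz_derivs",
               parms = parms, dllname = "lgoTMZ", initfunc = "tmz_init",
               rtol = rtol, atol = atol, maxsteps = 10000)
  if (!is.null(evt)) args$events <- list(data = evt)
  if (!is.na(threshold)) {
    args$method <- "lsodar"
    args$rootfunc <- "tmz_root"
    args$nroot <- 1L
  } else {
    args$method <- "lsoda"
  }
  out <- suppressWarnings(do.call(deSolve::ode, args))
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop(sprintf("integration failed (istate = %d) at t = %g",
                 diagn[1], out[nrow(out), 1]))
  out
}

#' Simulate the impulsive treatment model
#'
#' Integrates the model from \code{(P0, D = 0, C = 0)} with dose
#' impulses applied at the schedule's times (the integrator stops at
#' each dose, increments \code{C}, and restarts, preserving error
#' control). Simultaneous doses are summed; doses beyond the last output
#' time are ignored.
#'
#' @param params a \linkS4class{PatientParams}.
#' @param pk a \linkS4class{PKParams}.
#' @param schedule a \linkS4class{DoseSchedule}; empty means no
#'   treatment, in which case \code{P} follows the logistic closed form.
#' @param times output times, days, sorted increasing from 0.
#' @param rtol,atol integrator tolerances.
#' @return A \linkS4class{Trajectory}.
#' @examples
#' pat <- PatientParams(46, 1.01e-3, 0.32, 0.1)
#' tr <- simulateTumor(pat, schedule = standardSchedule(11),
#'                     times = seq(0, 3650, by = 10))
#' head(totalVolume(tr))
#' @export
simulateTumor <- function(params, pk = PKParams(),
                          schedule = DoseSchedule(),
                          times = seq(0, 365, by = 1),
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(is(params, "PatientParams"), is(pk, "PKParams"),
            is(schedule, "DoseSchedule"))
  times <- as.numeric(times)
  if (length(times) < 2L || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing with at least two points")
  if (times[1] < 0) stop("times must start at or after 0")
  if (times[1] > 0) times <- c(0, times)
  out <- .integrate(params, pk, schedule, times, rtol = rtol, atol = atol)
  keep <- match(times, out[, 1])
  if (anyNA(keep))  # output times the solver snapped onto nearby event times
    keep[is.na(keep)] <- vapply(times[is.na(keep)], function(tt)
      which.min(abs(out[, 1] - tt)), integer(1))
  # Class= must be named: a slot named "C" would otherwise partially
  # match new()'s Class argument
  new(Class = "Trajectory", times = times, P = unname(out[keep, "P"]),
      D = unname(out[keep, "D"]), C = unname(out[keep, "C"]))
}

#' Time for the tumor to reach a lethal volume threshold
#'
#' Integrates the model under the given schedule and locates the first
#' time the total volume \code{P + D} reaches \code{threshold} by root
#' detection on the integrated trajectory. Virtual patients are assumed
#' to die at 280 cm^3 (a sphere of 8 cm diameter); those whose tumors
#' stay below the threshold through the follow-up horizon are censored.
#'
#' @param params a \linkS4class{PatientParams}.
#' @param pk a \linkS4class{PKParams}.
#' @param schedule a \linkS4class{DoseSchedule}.
#' @param threshold lethal volume, cm^3; must be below \code{K} (the
#'   logistic dynamics can never reach \code{K} from below).
#' @param horizonYears follow-up horizon, years (1 year = 365 days).
#' @return A list with elements \code{time} (years) and \code{event}
#'   (\code{TRUE} if the threshold was reached, \code{FALSE} if censored
#'   at the horizon).
#' @export
timeToThreshold <- function(params, pk = PKParams(),
                            schedule = DoseSchedule(), threshold = 280,
                            horizonYears = 25) {
  stopifnot(is(params, "PatientParams"), is(pk, "PKParams"),
            is(schedule, "DoseSchedule"))
  if (horizonYears <= 0) stop("horizonYears must be > 0")
  if (threshold >= params@K)
    stop("threshold must be below the carrying capacity K")
  if (params@P0 >= threshold)
    return(list(time = 0, event = TRUE))
  horizonDays <- horizonYears * 365
  out <- .integrate(params, pk, schedule, c(0, horizonDays),
                    threshold = threshold)
  troot <- attr(out, "troot")
  if (is.null(troot) || !length(troot))
    list(time = horizonYears, event = FALSE)
  else
    list(time = troot[1] / 365, event = TRUE)
}

#' Trajectory accessors
#'
#' @param x a \linkS4class{Trajectory}.
#' @return \code{totalVolume} returns the observable tumor volume
#'   \code{P + D} (cm^3) at the output times.
#' @name Trajectory-accessors
NULL

#' @rdname Trajectory-accessors
#' @export
setMethod("totalVolume", "Trajectory", function(x) x@P + x@D)

#' @export
setMethod("length", "Trajectory", function(x) length(x@times))

setMethod("show", "Trajectory", function(object) {
  V <- object@P + object@D
  cat(sprintf(paste0("Trajectory: %d points over %g days; ",
                     "V(0) = %.2f cm^3, min V = %.2f, final V = %.2f\n"),
              length(object@times), max(object@times), V[1], min(V),
              V[length(V)]))
})

#' @export
#' @method as.data.frame Trajectory
as.data.frame.Trajectory <- function(x, ...) {
  data.frame(t_days = x@times, P_cm3 = x@P, D_cm3 = x@D,
             C_ug_per_cm3 = x@C, V_cm3 = x@P + x@D)
}

#' Write a trajectory to CSV
#'
#' Columns: \code{t_days, P_cm3, D_cm3, C_ug_per_cm3, V_cm3}.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param file output path.
#' @return The path, invisibly.
#' @export
writeTrajectory <- function(traj, file) {
  stopifnot(is(traj, "Trajectory"))
  write.csv(as.data.frame(traj), file, row.names = FALSE)
  invisible(file)
}
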