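#' @useDynLib lgoTMZ
#' @import methods
#' @importFrom stats coef median optim pchisq quantile rnorm runif sd setNames
#' @importFrom utils read.delim write.csv
NULL

#' Patient-specific biological parameters
#'
#' Parameters of the two-compartment tumor model for one patient:
#' logistic growth of the proliferative volume \code{P}, drug-induced
#' transfer into the lethally damaged compartment \code{D} (rate
#' \code{alpha1}), direct drug kill (rate \code{alpha2}), shared carrying
#' capacity \code{K}, and the mean number of divisions \code{kappa} a
#' damaged cell attempts before dying by mitotic catastrophe.
#'
#' @slot P0 initial proliferative tumor volume, cm^3.
#' @slot rho proliferation rate, day^-1.
#' @slot alpha1 damage (delayed-death) rate, cm^3/(ug day).
#' @slot alpha2 direct-kill rate, cm^3/(ug day).
#' @slot K carrying capacity, cm^3.
#' @slot kappa mean divisions before mitotic-catastrophe death
#'   (dimensionless, >= 1).
#' @name PatientParams-class
#' @aliases PatientParams-class
#' @exportClass PatientParams
setClass("PatientParams",
  representation(P0 = "numeric", rho = "numeric", alpha1 = "numeric",
                 alpha2 = "numeric", K = "numeric", kappa = "numeric"),
  prototype(K = 523.6, kappa = 1))

setValidity("PatientParams", function(object) {
  v <- c(P0 = object@P0, rho = object@rho, alpha1 = object@alpha1,
         alpha2 = object@alpha2, K = object@K, kappa = object@kappa)
  if (any(lengths(list(object@P0, object@rho, object@alpha1, object@alpha2,
                       object@K, object@kappa)) != 1L))
    return("all parameter slots must have length 1")
  if (any(!is.finite(v))) return("all parameters must be finite")
  if (object@P0 <= 0 || object@rho <= 0 || object@K <= 0)
    return("P0, rho and K must be strictly positive")
  if (object@alpha1 < 0 || object@alpha2 < 0)
    return("alpha1 and alpha2 must be non-negative")
  if (object@P0 >= object@K) return("P0 must be smaller than K")
  if (object@kappa < 1) return("kappa must be >= 1")
  TRUE
})

#' Drug pharmacokinetic constants
#'
#' Exponential tissue clearance of temozolomide. \code{lam} is the
#' first-order elimination rate (default 8.3184 day^-1, i.e. a half-life
#' of about two hours), and \code{C0} the effective concentration
#' delivered to tumor tissue by one oral dose (default 0.6 ug/cm^3, the
#' peak tissue concentration for a 150 mg/m^2 dose).
#'
#' @slot lam elimination rate, day^-1.
#' @slot C0 effective per-dose concentration, ug/cm^3.
#' @name PKParams-class
#' @aliases PKParams-class
#' @exportClass PKParams
setClass("PKParams",
  representation(lam = "numeric", C0 = "numeric"),
  prototype(lam = 8.3184, C0 = 0.6))

setValidity("PKParams", function(object) {
  if (length(object@lam) != 1L || length(object@C0) != 1L)
    return("lam and C0 must have length 1")
  if (!is.finite(object@lam) || object@lam <= 0) return("lam must be > 0")
  if (!is.finite(object@C0) || object@C0 < 0) return("C0 must be >= 0")
  TRUE
})

#' Impulsive dosing schedule
#'
#' An ordered sequence of dose administration times (days) with the
#' amount delivered by each impulse. An empty \code{doseAmounts} slot
#' means "use the per-dose concentration \code{C0} of the pharmacokinetic
#' parameters" at simulation time.
#'
#' @slot doseTimes administration times in days, sorted non-decreasing.
#' @slot doseAmounts per-dose concentration increments, ug/cm^3; either
#'   empty (defaults to \code{C0}) or one value per dose.
#' @name DoseSchedule-class
#' @aliases DoseSchedule-class
#' @exportClass DoseSchedule
setClass("DoseSchedule",
  representation(doseTimes = "numeric", doseAmounts = "numeric"),
  prototype(doseTimes = numeric(0), doseAmounts = numeric(0)))

setValidity("DoseSchedule", function(object) {
  tms <- object@doseTimes
  amt <- object@doseAmounts
  if (length(tms) && any(!is.finite(tms))) return("dose times must be finite")
  if (length(tms) && any(tms < 0)) return("dose times must be >= 0")
  if (is.unsorted(tms)) return("dose times must be sorted non-decreasing")
  if (length(amt) && length(amt) != length(tms))
    return("doseAmounts must be empty or match doseTimes in length")
  if (length(amt) && any(!is.finite(amt) | amt < 0))
    return("dose amounts must be finite and >= 0")
  TRUE
})

#' Simulated model trajectory
#'
#' Aligned time series of the model state: proliferative volume \code{P},
#' damaged volume \code{D}, tissue drug concentration \code{C}. The
#' observable tumor volume is \code{P + D} (both compartments occupy
#' tissue visible on T2/FLAIR imaging).
#'
#' @slot times output times, days, strictly increasing.
#' @slot P proliferative volume series, cm^3.
#' @slot D damaged volume series, cm^3.
#' @slot C drug concentration series, ug/cm^3.
#' @name Trajectory-class
#' @aliases Trajectory-class
#' @exportClass Trajectory
setClass("Trajectory",
  representation(times = "numeric", P = "numeric", D = "numeric",
                 C = "numeric"))

setValidity("Trajectory", function(object) {
  n <- length(object@times)
  if (length(object@P) != n || length(object@D) != n || length(object@C) != n)
    return("P, D, C series must match times in length")
  if (n > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  TRUE
})

#' Arm-level survival outcomes
#'
#' Time-to-event records for one treatment arm of a (virtual) trial:
#' event time in years and an event indicator (\code{TRUE} = lethal
#' volume threshold reached, \code{FALSE} = censored at follow-up).
#'
#' @slot time event or censoring times, years.
#' @slot event logical event indicators.
#' @slot label arm label.
#' @name ArmSurvival-class
#' @aliases ArmSurvival-class
#' @exportClass ArmSurvival
setClass("ArmSurvival",
  representation(time = "numeric", event = "logical", label = "character"),
  prototype(label = "arm"))

setValidity("ArmSurvival", function(object) {
  if (length(object@time) == 0L) return("arm must contain at least one subject")
  if (length(object@event) != length(object@time))
    return("time and event must have equal length")
  if (any(!is.finite(object@time) | object@time < 0))
    return("times must be finite and >= 0")
  if (any(is.na(object@event))) return("event indicators must not be NA")
  TRUE
})

#' Result of a patient-level parameter fit
#'
#' @slot params fitted \linkS4class{PatientParams}.
#' @slot sse residual sum of squares of the fit, cm^6.
#' @slot relErrorPct mean absolute relative deviation between observed
#'   and fitted volumes, percent.
#' @slot nStarts number of optimizer starts used.
#' @slot converged whether the best start reported convergence.
#' @name FitResult-class
#' @aliases FitResult-class
#' @exportClass FitResult
setClass("FitResult",
  representation(params = "PatientParams", sse = "numeric",
                 relErrorPct = "numeric", nStarts = "integer",
                 converged = "logical"))

setValidity("FitResult", function(object) {
  if (object@sse < 0) return("sse must be >= 0")
  if (object@relErrorPct < 0) return("relErrorPct must be >= 0")
  TRUE
})

#' Arm-level result of a two-arm virtual trial
#'
#' @slot medianA,medianB Kaplan-Meier median survival per arm, years;
#'   \code{NA} when the curve never drops to 0.5 ("not reached").
#' @slot medianDifference difference medianA - medianB, years.
#' @slot logrankStat,logrankP two-sample log-rank chi-square (1 df) and
#'   its two-sided p-value.
#' @slot hr hazard ratio of arm B relative to arm A (Cox model, Efron
#'   ties); values below 1 favor arm B.
#' @slot hrCI Wald 95\% confidence interval for the hazard ratio.
#' @slot outcomes per-subject data.frame: patient, arm, time (years),
#'   event.
#' @slot labels arm labels, length 2.
#' @name TrialResult-class
#' @aliases TrialResult-class
#' @exportClass TrialResult
setClass("TrialResult",
  representation(medianA = "numeric", medianB = "numeric",
                 medianDifference = "numeric", logrankStat = "numeric",
                 logrankP = "numeric", hr = "numeric", hrCI = "numeric",
                 outcomes = "data.frame", labels = "character"))

setValidity("TrialResult", function(object) {
  if (!is.na(object@logrankP) &&
      (object@logrankP < 0 || object@logrankP > 1))
    return("logrankP must lie in [0, 1]")
  if (!is.na(object@hr) && object@hr <= 0) return("hr must be > 0")
  if (length(object@hrCI) == 2L && all(!is.na(object@hrCI)) &&
      !is.na(object@hr) &&
      (object@hr < object@hrCI[1] || object@hr > object@hrCI[2]))
    return("hr must lie inside hrCI")
  TRUE
})

#' Uniform sampling box for virtual patients
#'
#' Per-parameter (low, high) bounds from which virtual-patient
#' parameters are drawn independently and uniformly. Defaults are the
#' representative region spanned by the fitted cohort: rho in
#' [0.5e-3, 2.5e-3] day^-1, alpha1 in [0.01, 1.0], alpha2 in
#' [0.1, 0.75] cm^3/(ug day), P0 in [20, 200] cm^3, K in [300, 550]
#' cm^3; kappa is fixed at 1.
#'
#' @slot rho,alpha1,alpha2,P0,K numeric length-2 (low, high) bounds.
#' @name ParameterBox-class
#' @aliases ParameterBox-class
#' @exportClass ParameterBox
setClass("ParameterBox",
  representation(rho = "numeric", alpha1 = "numeric", alpha2 = "numeric",
                 P0 = "numeric", K = "numeric"),
  prototype(rho = c(0.5e-3, 2.5e-3), alpha1 = c(0.01, 1.0),
            alpha2 = c(0.1, 0.75), P0 = c(20, 200), K = c(300, 550)))

setValidity("ParameterBox", function(object) {
  for (nm in c("rho", "alpha1", "alpha2", "P0", "K")) {
    b <- slot(object, nm)
    if (length(b) != 2L || any(!is.finite(b)))
      return(sprintf("%s bounds must be two finite numbers", nm))
    if (b[1] > b[2])
      return(sprintf("%s bounds must satisfy low <= high", nm))
    if (b[1] < 0) return(sprintf("%s bounds must be non-negative", nm))
  }
  TRUE
})
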