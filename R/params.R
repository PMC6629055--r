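#' Construct patient-specific model parameters
#'
#' @param P0 initial proliferative volume, cm^3.
#' @param rho growth rate, day^-1.
#' @param alpha1 damage (delayed-death) rate, cm^3/(ug day).
#' @param alpha2 direct-kill rate, cm^3/(ug day).
#' @param K carrying capacity, cm^3; default 523.6 (a 5 cm-radius
#'   sphere, roughly 2/5 of brain volume).
#' @param kappa mean divisions before mitotic-catastrophe death;
#'   default 1.
#' @return A \linkS4class{PatientParams} object.
#' @examples
#' PatientParams(P0 = 46, rho = 1.01e-3, alpha1 = 0.32, alpha2 = 0.1)
#' @export
PatientParams <- function(P0, rho, alpha1, alpha2, K = 523.6, kappa = 1) {
  new("PatientParams", P0 = as.numeric(P0), rho = as.numeric(rho),
      alpha1 = as.numeric(alpha1), alpha2 = as.numeric(alpha2),
      K = as.numeric(K), kappa = as.numeric(kappa))
}

#' Construct drug pharmacokinetic constants
#'
#' @param lam elimination rate, day^-1 (default 8.3184).
#' @param C0 effective per-dose tissue concentration, ug/cm^3
#'   (default 0.6).
#' @return A \linkS4class{PKParams} object.
#' @export
PKParams <- function(lam = 8.3184, C0 = 0.6) {
  new("PKParams", lam = as.numeric(lam), C0 = as.numeric(C0))
}

#' @describeIn PatientParams-class named parameter vector.
#' @param object a \code{PatientParams}.
#' @export
setMethod("coef", "PatientParams", function(object, ...) {
  c(P0 = object@P0, rho = object@rho, alpha1 = object@alpha1,
    alpha2 = object@alpha2, K = object@K, kappa = object@kappa)
})

#' @describeIn FitResult-class fitted parameter vector.
#' @param object a \code{FitResult}.
#' @export
setMethod("coef", "FitResult", function(object, ...) coef(object@params))

setMethod("show", "PatientParams", function(object) {
  cat("PatientParams:",
      sprintf("P0 = %g cm^3, rho = %g /day, alpha1 = %g, alpha2 = %g,",
              object@P0, object@rho, object@alpha1, object@alpha2),
      sprintf("K = %g cm^3, kappa = %g", object@K, object@kappa), "\n")
})

setMethod("show", "PKParams", function(object) {
  cat(sprintf("PKParams: lam = %g /day (t1/2 = %.3g h), C0 = %g ug/cm^3\n",
              object@lam, 24 * log(2) / object@lam, object@C0))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%d starts, %sconverged):\n", object@nStarts,
              if (object@converged) "" else "NOT "))
  print(signif(coef(object@params), 4))
  cat(sprintf("  SSE = %.6g cm^6, mean relative error = %.3g%%\n",
              object@sse, object@relErrorPct))
})

#' Construct a uniform virtual-patient sampling box
#'
#' @param rho,alpha1,alpha2,P0,K numeric length-2 (low, high) bounds;
#'   defaults are the cohort's representative parameter region.
#' @return A \linkS4class{ParameterBox}.
#' @export
ParameterBox <- function(rho = c(0.5e-3, 2.5e-3), alpha1 = c(0.01, 1.0),
                         alpha2 = c(0.1, 0.75), P0 = c(20, 200),
                         K = c(300, 550)) {
  new("ParameterBox", rho = as.numeric(rho), alpha1 = as.numeric(alpha1),
      alpha2 = as.numeric(alpha2), P0 = as.numeric(P0), K = as.numeric(K))
}

setMethod("show", "ParameterBox", function(object) {
  cat("ParameterBox (uniform sampling bounds):\n")
  for (nm in c("rho", "alpha1", "alpha2", "P0", "K")) {
    b <- slot(object, nm)
    cat(sprintf("  %-7s [%g, %g]\n", nm, b[1], b[2]))
  }
})

#' Construct arm-level survival outcomes
#'
#' @param time event or censoring times, years.
#' @param event logical event indicators (\code{TRUE} = death/threshold
#'   reached, \code{FALSE} = censored).
#' @param label arm label.
#' @return An \linkS4class{ArmSurvival}.
#' @export
ArmSurvival <- function(time, event, label = "arm") {
  new("ArmSurvival", time = as.numeric(time), event = as.logical(event),
      label = as.character(label)[1])
}

#' @describeIn ArmSurvival event/censoring times in years.
#' @param x an \code{ArmSurvival}.
#' @export
setMethod("survivalTimes", "ArmSurvival", function(x) x@time)

#' @describeIn ArmSurvival logical event indicators.
#' @export
setMethod("eventIndicator", "ArmSurvival", function(x) x@event)

setMethod("show", "ArmSurvival", function(object) {
  cat(sprintf("ArmSurvival '%s': %d subjects, %d events, %d censored\n",
              object@label, length(object@time), sum(object@event),
              sum(!object@event)))
})

#' @export
#' @method as.data.frame ArmSurvival
as.data.frame.ArmSurvival <- function(x, ...) {
  data.frame(time = x@time, event = x@event, label = x@label)
}

setMethod("show", "TrialResult", function(object) {
  fmtMed <- function(m) if (is.na(m)) "not reached" else sprintf("%.2f y", m)
  cat("Two-arm virtual trial\n")
  cat(sprintf("  arm A (%s): median %s\n", object@labels[1],
              fmtMed(object@medianA)))
  cat(sprintf("  arm B (%s): median %s\n", object@labels[2],
              fmtMed(object@medianB)))
  if (!is.na(object@medianDifference))
    cat(sprintf("  median difference (B - A): %.2f y\n",
                object@medianDifference))
  cat(sprintf("  log-rank: chi^2 = %.3g, p = %.3g\n", object@logrankStat,
              object@logrankP))
  cat(sprintf("  HR (B vs A) = %.3f (95%% CI %.3f-%.3f)\n", object@hr,
              object@hrCI[1], object@hrCI[2]))
})
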