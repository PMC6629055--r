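#' @importFrom survival Surv survfit survdiff coxph
NULL

.armsToFrame <- function(armA, armB) {
  stopifnot(is(armA, "ArmSurvival"), is(armB, "ArmSurvival"))
  data.frame(
    time = c(armA@time, armB@time),
    event = c(armA@event, armB@event),
    arm = factor(rep(c("A", "B"), c(length(armA@time), length(armB@time))),
                 levels = c("A", "B")))
}

#' Kaplan-Meier estimate for one arm
#'
#' Product-limit estimate of the survival function with right censoring.
#' The median is the first time the estimate drops to 0.5 or below;
#' when the curve stays above 0.5 through follow-up the median is
#' \code{NA} ("not reached"), never the horizon.
#'
#' @param arm an \linkS4class{ArmSurvival}.
#' @return A list with \code{time} and \code{surv} (the step function's
#'   knots and values), \code{median} (years or \code{NA}), \code{fn}
#'   (the survival step function), and the underlying
#'   \code{\link[survival]{survfit}} object as \code{fit}.
#' @export
kmEstimate <- function(arm) {
  stopifnot(is(arm, "ArmSurvival"))
  fit <- survival::survfit(survival::Surv(arm@time, arm@event) ~ 1)
  # first time the curve drops to 0.5 or below (not survfit's midpoint
  # convention for an exact-0.5 plateau)
  med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1]]
         else NA_real_
  list(time = fit$time, surv = fit$surv,
       median = as.numeric(med),
       fn = stats::stepfun(fit$time, c(1, fit$surv), right = FALSE),
       fit = fit)
}

#' @rdname kmEstimate
#' @return \code{kmMedian} returns just the median (years, or \code{NA}
#'   when not reached).
#' @export
kmMedian <- function(arm) kmEstimate(arm)$median

#' Two-sample log-rank test
#'
#' Standard two-sample log-rank chi-square test (1 degree of freedom)
#' comparing the survival distributions of two arms.
#'
#' @param armA,armB \linkS4class{ArmSurvival} objects.
#' @return A list with \code{statistic} (chi-square) and \code{p}
#'   (two-sided p-value).
#' @export
logrankTest <- function(armA, armB) {
  d <- .armsToFrame(armA, armB)
  if (!any(d$event))
    stop("log-rank test undefined: no events in either arm")
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = d)
  stat <- unname(sd$chisq)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Hazard ratio between two arms
#'
#' Cox proportional-hazards fit on the single binary arm covariate
#' (Efron tie handling); the hazard ratio is for arm B relative to
#' arm A, with a Wald 95\% confidence interval. HR < 1 favors arm B.
#'
#' @param armA,armB \linkS4class{ArmSurvival} objects, each with at
#'   least one event.
#' @return A list with \code{hr} and \code{ci} (length-2 lower/upper).
#' @export
coxHR <- function(armA, armB) {
  if (!any(armA@event) || !any(armB@event))
    stop("each arm needs at least one event to estimate a hazard ratio")
  d <- .armsToFrame(armA, armB)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ arm, data = d,
                    ties = "efron"),
    warning = function(w) stop("Cox fit did not converge: ",
                               conditionMessage(w)))
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se))
    stop("Cox fit did not converge (non-finite estimate)")
  list(hr = exp(beta),
       ci = exp(beta + c(-1, 1) * qnorm(0.975) * se))
}

#' @importFrom stats qnorm stepfun
NULL
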