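#' Validate a longitudinal volume series
#'
#' @param t observation times, days since the first scan (the first
#'   observation defines the model's t0); strictly increasing, >= 0.
#' @param volume observed tumor volumes, cm^3, strictly positive.
#' @return A data.frame with columns \code{t} and \code{volume}.
#' @export
volumeSeries <- function(t, volume) {
  t <- as.numeric(t); volume <- as.numeric(volume)
  if (length(t) != length(volume)) stop("t and volume lengths differ")
  if (!length(t)) stop("series must be non-empty")
  if (any(!is.finite(t)) || any(t < 0)) stop("times must be finite and >= 0")
  if (is.unsorted(t, strictly = TRUE)) stop("times must be strictly increasing")
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volumes must be finite and > 0")
  data.frame(t = t, volume = volume)
}

#' Mean absolute relative fit error
#'
#' The per-series fit-quality metric: the mean of
#' \code{|V_obs - V_fit| / V_obs}, expressed in percent.
#'
#' @param observed observed volumes, cm^3 (> 0).
#' @param fitted model volumes at the same times.
#' @return Percent error (scalar).
#' @examples
#' relativeError(c(100, 200), c(90, 220))  # 10
#' @export
relativeError <- function(observed, fitted) {
  if (length(observed) != length(fitted)) stop("lengths differ")
  if (any(observed <= 0)) stop("observed volumes must be > 0")
  100 * mean(abs(observed - fitted) / observed)
}

#' Default bounds for the free patient parameters
#'
#' The cohort's fitted parameter ranges widened by about 50\%:
#' P0 in [1, 300] cm^3, rho in [1e-4, 5e-3] day^-1, alpha1 in [0, 3],
#' alpha2 in [0, 1.5] cm^3/(ug day). K and kappa are held fixed.
#'
#' @return Named list of length-2 (low, high) bounds.
#' @export
defaultFitBounds <- function() {
  list(P0 = c(1, 300), rho = c(1e-4, 5e-3), alpha1 = c(0, 3),
       alpha2 = c(0, 1.5))
}

# Model total volume at the observation times for a candidate parameter set.
.modelVolumes <- function(free, observations, schedule, K, kappa, pk) {
  pat <- PatientParams(P0 = free[["P0"]], rho = free[["rho"]],
                       alpha1 = free[["alpha1"]], alpha2 = free[["alpha2"]],
                       K = K, kappa = kappa)
  tms <- observations$t
  simTimes <- sort(unique(c(0, tms)))
  if (length(simTimes) == 1L)   # all observations at t0: V(0) = P0
    return(rep(pat@P0, length(tms)))
  tr <- simulateTumor(pat, pk, schedule, times = simTimes)
  totalVolume(tr)[match(tms, tr@times)]
}

#' Least-squares objective for patient fitting
#'
#' Simulates the model from \code{(P0, D = 0, C = 0)} under the known
#' dosing history and returns the sum of squared residuals between the
#' observed and model total volumes at the observation times.
#' Simulation failures return a large finite penalty so the optimizer
#' can continue.
#'
#' @param free named numeric vector with \code{P0}, \code{rho},
#'   \code{alpha1}, \code{alpha2}.
#' @param observations a data.frame from \code{\link{volumeSeries}}.
#' @param schedule the patient's \linkS4class{DoseSchedule}.
#' @param K,kappa fixed model constants.
#' @param pk fixed \linkS4class{PKParams}.
#' @param relative if \code{TRUE}, residuals are divided by the observed
#'   volumes (off by default; the reference objective is unweighted SSE
#'   on absolute volumes).
#' @return Scalar objective value, cm^6.
#' @export
volumeObjective <- function(free, observations, schedule,
                            K = 523.6, kappa = 1, pk = PKParams(),
                            relative = FALSE) {
  observations <- volumeSeries(observations$t, observations$volume)
  vf <- tryCatch(
    .modelVolumes(free, observations, schedule, K, kappa, pk),
    error = function(e) NULL)
  if (is.null(vf) || any(!is.finite(vf))) {
    warning("simulation failed for a candidate parameter set; penalized")
    return(1e12)
  }
  r <- observations$volume - vf
  if (relative) r <- r / observations$volume
  sum(r^2)
}

#' Fit patient-specific parameters to a volume series
#'
#' Multi-start bounded least-squares estimation of the four free
#' parameters (P0, rho, alpha1, alpha2) from a longitudinal tumor-volume
#' series under a known dosing history. Starts are a seeded Latin
#' hypercube over the bounds; each start runs a bounded quasi-Newton
#' (L-BFGS-B) search on the unit-box-scaled parameters, and the best
#' start is polished once more. Deterministic given \code{seed}.
#'
#' @param observations a data.frame from \code{\link{volumeSeries}};
#'   at least 4 observations (one per free parameter).
#' @param schedule the dosing history, a \linkS4class{DoseSchedule}.
#' @param bounds named list of (low, high) bounds for the free
#'   parameters; collapsed bounds (low == high) pin a parameter.
#' @param nStarts number of optimizer starts (default 20).
#' @param seed integer seed for the start design.
#' @param K,kappa fixed model constants (defaults 523.6 cm^3 and 1).
#' @param pk fixed \linkS4class{PKParams}.
#' @param relative use relative residuals in the objective.
#' @return A \linkS4class{FitResult}.
#' @export
fitPatient <- function(observations, schedule, bounds = defaultFitBounds(),
                       nStarts = 20, seed = NULL, K = 523.6, kappa = 1,
                       pk = PKParams(), relative = FALSE) {
  observations <- volumeSeries(observations$t, observations$volume)
  if (nrow(observations) < 4L)
    stop("at least 4 observations are required to fit 4 free parameters")
  parNames <- c("P0", "rho", "alpha1", "alpha2")
  if (!all(parNames %in% names(bounds)))
    stop("bounds must name P0, rho, alpha1, alpha2")
  lo <- vapply(bounds[parNames], `[`, numeric(1), 1L)
  hi <- vapply(bounds[parNames], `[`, numeric(1), 2L)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(hi < lo))
    stop("bounds must be finite with low <= high")

  free <- hi > lo                       # collapsed bounds pin the parameter
  toPar <- function(u) {
    p <- lo
    p[free] <- lo[free] + u * (hi[free] - lo[free])
    names(p) <- parNames
    p
  }
  obj <- function(u) volumeObjective(toPar(u), observations, schedule,
                                     K = K, kappa = kappa, pk = pk,
                                     relative = relative)

  if (!any(free)) {                     # zero-dimensional search
    p <- setNames(lo, parNames)
    sse <- obj(numeric(0))
    vf <- .modelVolumes(p, observations, schedule, K, kappa, pk)
    return(new("FitResult",
               params = PatientParams(p[["P0"]], p[["rho"]], p[["alpha1"]],
                                      p[["alpha2"]], K = K, kappa = kappa),
               sse = sse,
               relErrorPct = relativeError(observations$volume, vf),
               nStarts = 0L, converged = TRUE))
  }

  nFree <- sum(free)
  if (!is.null(seed)) set.seed(seed)
  starts <- lhs::randomLHS(max(1L, as.integer(nStarts)), nFree)

  nPenalized <- 0L
  quietObj <- function(u)                 # count penalties, don't spam
    withCallingHandlers(obj(u), warning = function(w) {
      nPenalized <<- nPenalized + 1L
      invokeRestart("muffleWarning")
    })
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(
      optim(starts[i, ], quietObj, method = "L-BFGS-B",
            lower = rep(0, nFree), upper = rep(1, nFree),
            control = list(factr = 1e4, maxit = 500,
                           ndeps = rep(1e-6, nFree))),
      error = function(e) list(value = Inf, convergence = 1L,
                               message = conditionMessage(e)))
  })
  values <- vapply(runs, `[[`, numeric(1), "value")
  if (all(!is.finite(values))) {
    msgs <- vapply(runs, function(r)
      if (!is.null(r$message)) r$message else "non-finite objective",
      character(1))
    stop("all optimizer starts failed:\n",
         paste(sprintf("  start %d: %s", seq_along(msgs), msgs),
               collapse = "\n"))
  }
  best <- runs[[which.min(values)]]
  preConverged <- identical(best$convergence, 0L)
  polish <- tryCatch(
    optim(best$par, quietObj, method = "L-BFGS-B", lower = rep(0, nFree),
          upper = rep(1, nFree),
          control = list(factr = 1e3, maxit = 1000,
                         ndeps = rep(1e-7, nFree))),
    error = function(e) best)
  if (polish$value <= best$value) best <- polish

  p <- toPar(best$par)
  vf <- .modelVolumes(p, observations, schedule, K, kappa, pk)
  new("FitResult",
      params = PatientParams(p[["P0"]], p[["rho"]], p[["alpha1"]],
                             p[["alpha2"]], K = K, kappa = kappa),
      sse = best$value,
      relErrorPct = relativeError(observations$volume, vf),
      nStarts = as.integer(nrow(starts)),
      converged = identical(best$convergence, 0L) || preConverged)
}
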