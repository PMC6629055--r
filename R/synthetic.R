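#' Observation design for synthetic follow-up series
#'
#' Describes the cadence of volumetric follow-up emulated by the
#' synthetic-cohort generator: scans before, during and after
#' treatment, their spacing, and the multiplicative measurement noise.
#' The default noise CV of 0.18 matches the 18\% mean discrepancy of
#' ellipsoidal volume measurement against segmentation; the default
#' cadence is a scan roughly every three months.
#'
#' @param nPre scans before treatment start.
#' @param nDuring scans during the treatment course.
#' @param nPost scans after the last dose.
#' @param spacing days between scans (> 0).
#' @param noiseCV fractional measurement noise (0 <= noiseCV < 1).
#' @return A validated list with class \code{"observationDesign"}.
#' @export
observationDesign <- function(nPre = 3, nDuring = 4, nPost = 10,
                              spacing = 90, noiseCV = 0.18) {
  if (any(c(nPre, nDuring, nPost) < 0)) stop("scan counts must be >= 0")
  if (nPre + nDuring + nPost < 4) stop("at least 4 scans are required")
  if (spacing <= 0) stop("spacing must be > 0")
  if (noiseCV < 0 || noiseCV >= 1) stop("noiseCV must lie in [0, 1)")
  structure(list(nPre = as.integer(nPre), nDuring = as.integer(nDuring),
                 nPost = as.integer(nPost), spacing = spacing,
                 noiseCV = noiseCV),
            class = "observationDesign")
}

# Scan times for a design around a schedule: pre-treatment scans at the
# design spacing from t = 0, scans spread over the treatment course,
# then post-treatment scans at the spacing again.
.scanTimes <- function(design, schedule) {
  d <- design
  if (!length(schedule@doseTimes)) {
    tms <- d$spacing * (seq_len(d$nPre + d$nDuring + d$nPost) - 1)
    return(tms)
  }
  first <- min(schedule@doseTimes)
  last <- max(schedule@doseTimes)
  pre <- if (d$nPre) seq(0, by = d$spacing, length.out = d$nPre) else
    numeric(0)
  pre <- pre[pre < first]
  during <- if (d$nDuring)
    seq(first + 1, last + 1, length.out = d$nDuring) else numeric(0)
  post <- if (d$nPost)
    last + 1 + d$spacing * seq_len(d$nPost) else numeric(0)
  sort(unique(c(pre, during, post)))
}

#' Generate one synthetic longitudinal volume series
#'
#' Simulates the model for a patient under a dosing history, samples
#' the total volume \code{P + D} at the design's scan times, and
#' applies multiplicative lognormal measurement noise with coefficient
#' of variation \code{noiseCV} (mean multiplier 1, volumes guaranteed
#' positive). With \code{noiseCV = 0} the observations lie exactly on
#' the model curve.
#'
#' @param params ground-truth \linkS4class{PatientParams}.
#' @param pk a \linkS4class{PKParams}.
#' @param schedule the dosing history.
#' @param design an \code{\link{observationDesign}}.
#' @param seed optional integer seed.
#' @return A data.frame from \code{\link{volumeSeries}} (columns
#'   \code{t}, \code{volume}).
#' @export
generatePatientSeries <- function(params, pk = PKParams(),
                                  schedule = DoseSchedule(),
                                  design = observationDesign(),
                                  seed = NULL) {
  stopifnot(inherits(design, "observationDesign"))
  if (!is.null(seed)) set.seed(seed)
  tms <- .scanTimes(design, schedule)
  tr <- simulateTumor(params, pk, schedule,
                      times = sort(unique(c(0, tms))))
  V <- totalVolume(tr)[match(tms, tr@times)]
  cv <- design$noiseCV
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    V <- V * exp(rnorm(length(V), mean = -sdlog^2 / 2, sd = sdlog))
  }
  volumeSeries(tms, V)
}

#' Ellipsoidal tumor volume from three orthogonal diameters
#'
#' The standard manual volumetric approximation used on T2/FLAIR MRI:
#' \code{V = (D1 * D2 * D3) / 2} from the three largest diameters along
#' the axial, coronal and sagittal planes.
#'
#' @param d1,d2,d3 diameters, cm (> 0); vectorized.
#' @return Volume, cm^3.
#' @examples
#' ellipsoidVolume(2, 2, 2)  # 4
#' @export
ellipsoidVolume <- function(d1, d2, d3) {
  if (any(c(d1, d2, d3) <= 0)) stop("diameters must be > 0")
  d1 * d2 * d3 / 2
}

#' Generate a synthetic cohort with known ground truth
#'
#' Pairs sampled (or supplied) ground-truth parameters with generated
#' volume series for parameter-recovery testing. Each patient receives
#' a random number of standard cycles in the cohort's 4-20 range,
#' starting after the pre-treatment scans.
#'
#' @param n cohort size (>= 1); ignored when \code{patients} is given.
#' @param box a \linkS4class{ParameterBox} to sample truths from.
#' @param design an \code{\link{observationDesign}}.
#' @param seed optional integer seed.
#' @param patients optional list of \linkS4class{PatientParams} to use
#'   as ground truth instead of sampling (e.g. the fitted cohort's
#'   values, giving a synthetic replica cohort).
#' @param cycles optional integer vector of cycle counts per patient;
#'   default drawn uniformly from 4-20.
#' @param pk a \linkS4class{PKParams}.
#' @return A list, one element per patient:
#'   \code{list(params, cycles, schedule, series)}.
#' @export
sampleCohort <- function(n, box = ParameterBox(),
                         design = observationDesign(), seed = NULL,
                         patients = NULL, cycles = NULL,
                         pk = PKParams()) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(patients)) {
    if (length(n) != 1L || is.na(n) || n < 1) stop("n must be >= 1")
    patients <- samplePopulation(n, box)
  }
  n <- length(patients)
  if (is.null(cycles)) cycles <- sample(4:20, n, replace = TRUE)
  if (length(cycles) != n) stop("cycles must match the cohort size")
  treatStart <- design$nPre * design$spacing
  lapply(seq_len(n), function(i) {
    sch <- standardSchedule(cycles[i], start = treatStart)
    list(params = patients[[i]], cycles = cycles[i], schedule = sch,
         series = generatePatientSeries(patients[[i]], pk, sch, design))
  })
}
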