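#' Dosing schedules
#'
#' Constructors for the TMZ dosing schedules studied with the model.
#' All schedules are sequences of once-daily oral doses described as
#' concentration impulses. The clinical standard is a 28-day cycle with
#' five daily doses followed by a 23-day rest; "days 1 to 5" of a cycle
#' are encoded as offsets 0-4 from the cycle start, so \code{t = 0} is
#' the first administration.
#'
#' @param doseTimes administration times, days.
#' @param doseAmounts per-dose amounts, ug/cm^3; empty means "use
#'   \code{C0} from the \linkS4class{PKParams}".
#' @return A \linkS4class{DoseSchedule}.
#' @seealso \code{\link{standardSchedule}}, \code{\link{combinedSchedule}}
#' @export
DoseSchedule <- function(doseTimes = numeric(0), doseAmounts = numeric(0)) {
  new("DoseSchedule", doseTimes = as.numeric(doseTimes),
      doseAmounts = as.numeric(doseAmounts))
}

#' @rdname DoseSchedule
#' @param x a \code{DoseSchedule}.
#' @export
setMethod("doseTimes", "DoseSchedule", function(x) x@doseTimes)

#' @rdname DoseSchedule
#' @export
setMethod("doseAmounts", "DoseSchedule", function(x) x@doseAmounts)

#' @export
setMethod("length", "DoseSchedule", function(x) length(x@doseTimes))

setMethod("show", "DoseSchedule", function(object) {
  n <- length(object@doseTimes)
  if (n == 0L) {
    cat("DoseSchedule: empty (no treatment)\n")
  } else {
    cat(sprintf("DoseSchedule: %d doses, days %g-%g%s\n", n,
                min(object@doseTimes), max(object@doseTimes),
                if (length(object@doseAmounts)) "" else
                  " (amounts default to C0)"))
  }
})

# 5 daily doses at the start of each cycle of the given period
.fiveDayBlocks <- function(starts) {
  sort(rep(starts, each = 5L) + 0:4)
}

#' Standard 28-day TMZ schedule
#'
#' Cycles of \code{cycleLength} days with five daily doses at the start
#' of each cycle (offsets 0-4) and a rest for the remainder.
#'
#' @param nCycles number of cycles (>= 1).
#' @param cycleLength cycle period, days (default 28: 5 dosing days +
#'   23 rest days).
#' @param start day of the first dose.
#' @return A \linkS4class{DoseSchedule} with \code{5 * nCycles} doses.
#' @examples
#' doseTimes(standardSchedule(1))   # 0 1 2 3 4
#' @export
standardSchedule <- function(nCycles, cycleLength = 28, start = 0) {
  if (length(nCycles) != 1L || is.na(nCycles) || nCycles < 1)
    stop("nCycles must be >= 1")
  nCycles <- as.integer(nCycles)
  DoseSchedule(.fiveDayBlocks(start + cycleLength * (0:(nCycles - 1L))))
}

#' Long-cycle TMZ schedule
#'
#' Five daily doses followed by a rest period lengthened beyond the
#' standard 23 days; the cycle period is \code{5 + restDays}.
#'
#' @param nCycles number of cycles (>= 1).
#' @param restDays rest period after the 5 dosing days; must be >= 23
#'   (the long-cycle family only lengthens the rest).
#' @param start day of the first dose.
#' @return A \linkS4class{DoseSchedule}.
#' @export
longCycleSchedule <- function(nCycles, restDays, start = 0) {
  if (length(restDays) != 1L || is.na(restDays) || restDays < 23)
    stop("restDays must be >= 23")
  standardSchedule(nCycles, cycleLength = 5 + restDays, start = start)
}

#' Rest periods of the long-cycle sweep
#'
#' The 12 rest-period lengths studied for the long-cycle family: the
#' standard 23 days lengthened in 15-day steps up to about six months.
#'
#' @return Integer vector \code{23 + 15 * (0:11)}.
#' @export
longCycleRestSweep <- function() 23 + 15 * (0:11)

#' Distributed-dose TMZ schedules
#'
#' Redistributions of the five doses within the 28-day cycle:
#' \code{"alternate_days"} gives the doses 1-day-on/1-day-off over the
#' first 10 days (offsets 0, 2, 4, 6, 8); \code{"evenly_spaced"} gives
#' one dose every 4 days (offsets 0, 4, 8, 12, 16 by default; shift
#' with \code{firstDose}).
#'
#' @param nCycles number of cycles (>= 1).
#' @param variant \code{"alternate_days"} or \code{"evenly_spaced"}.
#' @param cycleLength cycle period, days.
#' @param firstDose offset of the first dose within each cycle.
#' @return A \linkS4class{DoseSchedule} with \code{5 * nCycles} doses.
#' @export
distributedSchedule <- function(nCycles,
                                variant = c("alternate_days",
                                            "evenly_spaced"),
                                cycleLength = 28, firstDose = 0) {
  if (length(nCycles) != 1L || is.na(nCycles) || nCycles < 1)
    stop("nCycles must be >= 1")
  variant <- match.arg(variant)
  offsets <- switch(variant,
    alternate_days = seq(0, 8, by = 2),
    evenly_spaced  = seq(0, 16, by = 4))
  offsets <- offsets + firstDose
  if (max(offsets) >= cycleLength)
    stop("doses do not fit within the cycle")
  starts <- cycleLength * (0:(as.integer(nCycles) - 1L))
  DoseSchedule(sort(rep(starts, each = 5L) + offsets))
}

#' Induction-plus-maintenance ("5+12") TMZ schedule
#'
#' The combined regimen: \code{inductionCycles} standard cycles given
#' monthly, followed by \code{maintenanceCycles} cycles whose starts are
#' \code{maintenancePeriod} days apart, the first maintenance start one
#' \code{maintenancePeriod} after the last induction start. Each cycle
#' is 5 daily doses. With the defaults (5 induction cycles at 28 days,
#' 12 maintenance cycles at 84 days) this is the 5+12 scheme: 17 cycles,
#' 85 doses, last dose on day 1124.
#'
#' @param month induction cycle period, days (default 28).
#' @param maintenancePeriod maintenance start-to-start spacing, days
#'   (default 84, i.e. three 28-day months); must be >= \code{month}.
#' @param inductionCycles,maintenanceCycles cycle counts (defaults 5
#'   and 12).
#' @return A \linkS4class{DoseSchedule}.
#' @examples
#' length(combinedSchedule())  # 85 doses
#' @export
combinedSchedule <- function(month = 28, maintenancePeriod = 84,
                             inductionCycles = 5, maintenanceCycles = 12) {
  if (maintenancePeriod < month)
    stop("maintenancePeriod must be >= month")
  indStarts <- month * (0:(inductionCycles - 1L))
  lastInd <- indStarts[length(indStarts)]
  mntStarts <- lastInd + maintenancePeriod * seq_len(maintenanceCycles)
  DoseSchedule(.fiveDayBlocks(c(indStarts, mntStarts)))
}
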