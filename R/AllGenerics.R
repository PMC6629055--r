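#' @rdname DoseSchedule
#' @export
setGeneric("doseTimes", function(x) standardGeneric("doseTimes"))

#' @rdname DoseSchedule
#' @export
setGeneric("doseAmounts", function(x) standardGeneric("doseAmounts"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("totalVolume", function(x) standardGeneric("totalVolume"))

#' @rdname ArmSurvival
#' @export
setGeneric("survivalTimes", function(x) standardGeneric("survivalTimes"))

#' @rdname ArmSurvival
#' @export
setGeneric("eventIndicator", function(x) standardGeneric("eventIndicator"))
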