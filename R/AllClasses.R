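#' @import methods
NULL

#' Interaction condition labels
#'
#' The four human-robot tactile interaction conditions, in the fixed order
#' used for one-hot encoding: low-intensity touch (LI), high-intensity touch
#' (HI), no-touch/verbal-only (NT) and no-robot control (NR).
#'
#' @format Character vector of length 4.
#' @export
CONDITIONS <- c("LI", "HI", "NT", "NR")

## NR is the no-robot control and serves as the reference level in
## treatment-coded model matrices.
conditionFactor <- function(x) {
  bad <- setdiff(unique(as.character(x)), CONDITIONS)
  if (length(bad) > 0L) {
    stop(errorCondition(
      sprintf("unknown condition label(s): %s", paste(bad, collapse = ", ")),
      class = c("invalidCondition", "tactileRiskError", "error")
    ))
  }
  factor(as.character(x), levels = c("NR", "LI", "HI", "NT"))
}

#' SignalSeries: a uniformly sampled physiological channel
#'
#' Holds one continuously sampled channel of an Empatica-E4-style recording:
#' electrodermal activity (EDA, microsiemens, 4 Hz), blood volume pulse
#' (BVP, arbitrary units, 64 Hz) or skin temperature (TEMP, degrees Celsius,
#' 4 Hz).
#'
#' @slot values numeric vector of samples.
#' @slot startTime numeric scalar, seconds since epoch.
#' @slot rateHz numeric scalar, sampling rate in Hz (> 0).
#' @slot channel one of `"EDA"`, `"BVP"`, `"TEMP"`.
#'
#' @export
setClass("SignalSeries",
  representation(
    values = "numeric",
    startTime = "numeric",
    rateHz = "numeric",
    channel = "character"
  )
)

setValidity("SignalSeries", function(object) {
  msgs <- character(0)
  if (length(object@values) == 0L) msgs <- c(msgs, "values must be non-empty")
  if (!is.finite(object@rateHz) || object@rateHz <= 0) {
    msgs <- c(msgs, "rateHz must be a positive finite number")
  }
  if (!object@channel %in% c("EDA", "BVP", "TEMP")) {
    msgs <- c(msgs, "channel must be one of EDA, BVP, TEMP")
  }
  if (object@channel == "EDA" && any(object@values < 0)) {
    msgs <- c(msgs, "EDA values must be non-negative (microsiemens)")
  }
  if (object@channel == "TEMP" &&
      (any(object@values < 20) || any(object@values > 45))) {
    msgs <- c(msgs, "TEMP values must lie within [20, 45] degrees Celsius")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SignalSeries
#'
#' @param values numeric samples.
#' @param rateHz sampling rate in Hz.
#' @param channel `"EDA"`, `"BVP"` or `"TEMP"`.
#' @param startTime session start, seconds since epoch.
#' @return A [SignalSeries-class] object.
#' @export
SignalSeries <- function(values, rateHz, channel, startTime = 0) {
  new("SignalSeries", values = as.numeric(values), startTime = as.numeric(startTime),
      rateHz = as.numeric(rateHz), channel = as.character(channel))
}

#' IbiSeries: interbeat-interval events
#'
#' Event-coded interbeat intervals: for each detected beat-to-beat interval,
#' the time of the event from session start and the interval duration, both in
#' seconds. Durations outside (0.25, 3) s are physiologically implausible and
#' rejected by validity (ingestion drops them before construction).
#'
#' @slot eventTimes numeric, seconds from session start, strictly increasing.
#' @slot durations numeric, interval durations in seconds.
#'
#' @export
setClass("IbiSeries",
  representation(eventTimes = "numeric", durations = "numeric")
)

setValidity("IbiSeries", function(object) {
  msgs <- character(0)
  if (length(object@eventTimes) != length(object@durations)) {
    msgs <- c(msgs, "eventTimes and durations must have equal length")
  }
  if (length(object@eventTimes) > 1L && any(diff(object@eventTimes) <= 0)) {
    msgs <- c(msgs, "eventTimes must be strictly increasing")
  }
  if (length(object@durations) &&
      (any(object@durations <= 0.25) || any(object@durations >= 3.0))) {
    msgs <- c(msgs, "durations must lie in (0.25, 3) s")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an IbiSeries
#'
#' @param eventTimes event times in seconds from session start.
#' @param durations interbeat intervals in seconds.
#' @return An [IbiSeries-class] object.
#' @export
IbiSeries <- function(eventTimes, durations) {
  new("IbiSeries", eventTimes = as.numeric(eventTimes),
      durations = as.numeric(durations))
}

#' PhysioRecord: one session of one subject under one condition
#'
#' The atomic unit of the dataset: the four raw signals recorded during one
#' session, the interaction condition, the subject identifier and the BART
#' score (mean number of pumps per unexploded balloon) obtained in that
#' session.
#'
#' @slot subjectId character subject identifier.
#' @slot condition one of `"LI"`, `"HI"`, `"NT"`, `"NR"`.
#' @slot eda,bvp,temp [SignalSeries-class] objects for the EDA, BVP and TEMP
#'   channels.
#' @slot ibi an [IbiSeries-class].
#' @slot bartScore non-negative numeric.
#'
#' @export
setClass("PhysioRecord",
  representation(
    subjectId = "character",
    condition = "character",
    eda = "SignalSeries",
    bvp = "SignalSeries",
    temp = "SignalSeries",
    ibi = "IbiSeries",
    bartScore = "numeric"
  )
)

setValidity("PhysioRecord", function(object) {
  msgs <- character(0)
  if (!object@condition %in% CONDITIONS) {
    msgs <- c(msgs, sprintf("condition must be one of %s",
                            paste(CONDITIONS, collapse = ", ")))
  }
  if (!is.finite(object@bartScore) || object@bartScore < 0) {
    msgs <- c(msgs, "bartScore must be a non-negative finite number")
  }
  if (object@eda@channel != "EDA") msgs <- c(msgs, "eda slot must hold an EDA channel")
  if (object@bvp@channel != "BVP") msgs <- c(msgs, "bvp slot must hold a BVP channel")
  if (object@temp@channel != "TEMP") msgs <- c(msgs, "temp slot must hold a TEMP channel")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PhysioRecord
#'
#' @param subjectId subject identifier.
#' @param condition one of `"LI"`, `"HI"`, `"NT"`, `"NR"`.
#' @param eda,bvp,temp [SignalSeries-class] objects.
#' @param ibi an [IbiSeries-class].
#' @param bartScore non-negative BART score.
#' @return A [PhysioRecord-class] object.
#' @export
PhysioRecord <- function(subjectId, condition, eda, bvp, temp, ibi, bartScore) {
  new("PhysioRecord", subjectId = as.character(subjectId),
      condition = as.character(condition), eda = eda, bvp = bvp, temp = temp,
      ibi = ibi, bartScore = as.numeric(bartScore))
}

## ---- generics and accessors -------------------------------------------------

#' @rdname SignalSeries-class
#' @param object,x an object.
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))
#' @rdname SignalSeries-class
#' @export
setMethod("signalValues", "SignalSeries", function(x) x@values)

#' @rdname SignalSeries-class
#' @export
setGeneric("rateHz", function(x) standardGeneric("rateHz"))
#' @rdname SignalSeries-class
#' @export
setMethod("rateHz", "SignalSeries", function(x) x@rateHz)

#' @rdname SignalSeries-class
#' @export
setGeneric("channel", function(x) standardGeneric("channel"))
#' @rdname SignalSeries-class
#' @export
setMethod("channel", "SignalSeries", function(x) x@channel)

#' @rdname IbiSeries-class
#' @param x an object.
#' @export
setGeneric("eventTimes", function(x) standardGeneric("eventTimes"))
#' @rdname IbiSeries-class
#' @export
setMethod("eventTimes", "IbiSeries", function(x) x@eventTimes)

#' @rdname IbiSeries-class
#' @export
setGeneric("durations", function(x) standardGeneric("durations"))
#' @rdname IbiSeries-class
#' @export
setMethod("durations", "IbiSeries", function(x) x@durations)

#' @rdname PhysioRecord-class
#' @param x an object.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname PhysioRecord-class
#' @export
setMethod("subjectId", "PhysioRecord", function(x) x@subjectId)

#' @rdname PhysioRecord-class
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))
#' @rdname PhysioRecord-class
#' @export
setMethod("condition", "PhysioRecord", function(x) x@condition)

#' @rdname PhysioRecord-class
#' @export
setGeneric("bartScore", function(x) standardGeneric("bartScore"))
#' @rdname PhysioRecord-class
#' @export
setMethod("bartScore", "PhysioRecord", function(x) x@bartScore)

#' @rdname PhysioRecord-class
#' @export
setGeneric("eda", function(x) standardGeneric("eda"))
#' @rdname PhysioRecord-class
#' @export
setMethod("eda", "PhysioRecord", function(x) x@eda)

#' @rdname PhysioRecord-class
#' @export
setGeneric("bvp", function(x) standardGeneric("bvp"))
#' @rdname PhysioRecord-class
#' @export
setMethod("bvp", "PhysioRecord", function(x) x@bvp)

#' @rdname PhysioRecord-class
#' @export
setGeneric("temp", function(x) standardGeneric("temp"))
#' @rdname PhysioRecord-class
#' @export
setMethod("temp", "PhysioRecord", function(x) x@temp)

#' @rdname PhysioRecord-class
#' @export
setGeneric("ibi", function(x) standardGeneric("ibi"))
#' @rdname PhysioRecord-class
#' @export
setMethod("ibi", "PhysioRecord", function(x) x@ibi)

setMethod("show", "SignalSeries", function(object) {
  cat(sprintf("SignalSeries [%s] %d samples @ %g Hz (%.1f s)\n",
              object@channel, length(object@values), object@rateHz,
              length(object@values) / object@rateHz))
  invisible(object)
})

setMethod("show", "IbiSeries", function(object) {
  n <- length(object@durations)
  cat(sprintf("IbiSeries: %d intervals, mean RR %.3f s\n",
              n, if (n) mean(object@durations) else NA_real_))
  invisible(object)
})

setMethod("show", "PhysioRecord", function(object) {
  cat(sprintf(
    "PhysioRecord subject=%s condition=%s BART=%.2f\n  EDA %d @ %g Hz | BVP %d @ %g Hz | TEMP %d @ %g Hz | IBI %d beats\n",
    object@subjectId, object@condition, object@bartScore,
    length(object@eda@values), object@eda@rateHz,
    length(object@bvp@values), object@bvp@rateHz,
    length(object@temp@values), object@temp@rateHz,
    length(object@ibi@durations)))
  invisible(object)
})

## classed error helper used across modules
tactileError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tactileRiskError", "error")))
}
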