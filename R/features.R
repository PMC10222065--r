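#' Names of the 11 physiological features
#'
#' Time-domain heart-rate-variability features from the interbeat intervals
#' (mHR, mRRi, IBISDNN, IBIRMSSD), skin-conductance features from EDA
#' (mAmp, Slope, event), blood-volume-pulse summaries (mBVP, miBVP, maBVP)
#' and the mean temperature rate of change (TCR).
#'
#' @format Character vector of length 11.
#' @export
FEATURE_NAMES <- c("mHR", "mRRi", "IBISDNN", "IBIRMSSD",
                   "mAmp", "Slope", "event",
                   "mBVP", "miBVP", "maBVP", "TCR")

#' Heart-rate-variability features from interbeat intervals
#'
#' * `mRRi`: mean interbeat interval (s).
#' * `mHR`: 60 / mRRi (beats per minute). Defined from the mean interval, not
#'   as the mean of instantaneous rates, so `mHR * mRRi == 60` exactly.
#' * `IBISDNN`: population (denominator n) standard deviation of the
#'   intervals (s).
#' * `IBIRMSSD`: root mean square of successive interval differences (s).
#'
#' @param ibi an [IbiSeries-class] with at least 2 intervals.
#' @return Named numeric vector `c(mHR, mRRi, IBISDNN, IBIRMSSD)`.
#' @export
ibiFeatures <- function(ibi) {
  d <- durations(ibi)
  if (length(d) < 2L) {
    tactileError("need at least 2 interbeat intervals", "insufficientData")
  }
  mRRi <- mean(d)
  c(mHR = 60 / mRRi,
    mRRi = mRRi,
    IBISDNN = sqrt(mean((d - mRRi)^2)),
    IBIRMSSD = sqrt(mean(diff(d)^2)))
}

## Minimal qualifying end per start: smallest j in (i, i + maxLag] with
## values[j] - values[i] > thresh. maxLag enforces a strict span < window s.
scrCandidateWindows <- function(values, rate, thresh, windowS) {
  n <- length(values)
  maxLag <- ceiling(windowS * rate) - 1L
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(n - 1L)) {
    hi <- min(n, i + maxLag)
    seg <- values[(i + 1L):hi] - values[i]
    j <- which(seg > thresh)
    if (length(j)) {
      starts <- c(starts, i)
      ends <- c(ends, i + j[1L])
    }
  }
  list(starts = starts, ends = ends)
}

#' Electrodermal-activity features
#'
#' * `mAmp`: mean skin conductance (microsiemens).
#' * `Slope`: mean absolute first difference of the conductance per sample
#'   step.
#' * `event`: number of disjoint skin-conductance-response episodes. An
#'   episode starts where some window spanning strictly less than `windowS`
#'   seconds gains more than `thresh` microsiemens net, and extends to the
#'   local peak of that rise, so all qualifying windows within one monotone
#'   rise count once; the next episode must start after the previous peak.
#'   The alternative monotone-rise reading of the definition would reject
#'   windows containing any decrease; the net-gain reading implemented here
#'   is the weaker (more inclusive) one.
#'
#' @param edaSeries a [SignalSeries-class] with channel `"EDA"` and at least
#'   2 samples.
#' @param thresh rise threshold in microsiemens (default 0.05).
#' @param windowS maximum episode span in seconds, exclusive (default 5).
#' @return Named numeric vector `c(mAmp, Slope, event)`.
#' @export
edaFeatures <- function(edaSeries, thresh = 0.05, windowS = 5) {
  if (channel(edaSeries) != "EDA") {
    tactileError("edaFeatures requires an EDA channel", "channelMismatch")
  }
  v <- signalValues(edaSeries)
  if (length(v) < 2L) {
    tactileError("need at least 2 EDA samples", "insufficientData")
  }
  cand <- scrCandidateWindows(v, rateHz(edaSeries), thresh, windowS)
  ## greedy earliest-end scheduling over qualifying windows; each counted
  ## episode is extended to its local peak so one monotone rise counts once
  count <- 0L
  pos <- 1L
  n <- length(v)
  if (length(cand$starts)) {
    ord <- order(cand$ends)
    for (k in ord) {
      if (cand$starts[k] >= pos) {
        count <- count + 1L
        e <- cand$ends[k]
        while (e < n && v[e + 1L] > v[e]) e <- e + 1L
        pos <- e + 1L
      }
    }
  }
  c(mAmp = mean(v), Slope = mean(abs(diff(v))), event = as.numeric(count))
}

#' Blood-volume-pulse features
#'
#' Mean absolute value, minimum and maximum of the BVP waveform.
#'
#' @param bvpSeries a [SignalSeries-class] with channel `"BVP"`.
#' @return Named numeric vector `c(mBVP, miBVP, maBVP)`.
#' @export
bvpFeatures <- function(bvpSeries) {
  if (channel(bvpSeries) != "BVP") {
    tactileError("bvpFeatures requires a BVP channel", "channelMismatch")
  }
  v <- signalValues(bvpSeries)
  c(mBVP = mean(abs(v)), miBVP = min(v), maBVP = max(v))
}

#' Temperature rate of change (TCR)
#'
#' Mean first difference of the temperature divided by the sample period,
#' in degrees Celsius per second. For a uniformly sampled series this equals
#' the endpoint slope (last - first) / duration; the mean-of-differences form
#' is kept for robustness.
#'
#' @param tempSeries a [SignalSeries-class] with channel `"TEMP"` and at
#'   least 2 samples.
#' @return Numeric scalar, degrees Celsius per second.
#' @export
tempFeature <- function(tempSeries) {
  if (channel(tempSeries) != "TEMP") {
    tactileError("tempFeature requires a TEMP channel", "channelMismatch")
  }
  v <- signalValues(tempSeries)
  if (length(v) < 2L) {
    tactileError("need at least 2 TEMP samples", "insufficientData")
  }
  mean(diff(v)) * rateHz(tempSeries)
}

#' Extract the 11-feature vector from one record
#'
#' @param record a [PhysioRecord-class].
#' @return Named numeric vector of length 11 in [FEATURE_NAMES] order.
#' @export
extractFeatures <- function(record) {
  out <- c(ibiFeatures(ibi(record)),
           edaFeatures(eda(record)),
           bvpFeatures(bvp(record)),
           TCR = tempFeature(temp(record)))
  out[FEATURE_NAMES]
}

#' Feature table for a list of records
#'
#' @param records list of [PhysioRecord-class] objects.
#' @return A data.frame with `subject_id`, `condition`, the 11 features and
#'   `bart_score`, one row per record.
#' @export
featureTable <- function(records) {
  feats <- t(vapply(records, extractFeatures, numeric(length(FEATURE_NAMES))))
  data.frame(
    subject_id = vapply(records, subjectId, character(1)),
    condition = vapply(records, condition, character(1)),
    feats,
    bart_score = vapply(records, bartScore, numeric(1)),
    stringsAsFactors = FALSE
  )
}
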