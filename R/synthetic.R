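## Synthetic dataset generator.
##
## A single latent per-session "arousal" variable drives all four channels:
## higher arousal raises heart rate, lowers beat-to-beat variability, raises
## tonic skin conductance, increases the rate and amplitude of
## skin-conductance responses, modulates pulse amplitude, and tilts the skin
## temperature. The BART score is then produced either by a planted linear
## map over the extracted features (plus condition contrasts, a per-subject
## random intercept and Gaussian noise) or by a planted nonlinear map (a
## saturating arousal-by-condition interaction plus a strong
## temperature-drift term and a skin-conductance-response amplitude term).

#' Parameters of the synthetic-data generator
#'
#' Defaults emulate the study design: `nSubjects` subjects each observed once
#' under each of the four conditions, with session lengths chosen so the
#' modal channel lengths are 72 samples of EDA/TEMP (18 s at 4 Hz), 1200
#' samples of BVP (18.75 s at 64 Hz) and about 16 interbeat intervals.
#'
#' Two per-subject intercepts are drawn independently: `arousalSubjectSd`
#' scales the subject effect on the latent arousal (arousal units), and
#' `subjectSd` scales the random intercept added to the BART score (pumps) —
#' the quantity a mixed-effects fit estimates as its random-intercept
#' standard deviation.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param recordsPerCondition sessions per subject and condition (default 1).
#' @param conditionEffects named latent-arousal shift per condition.
#' @param conditionScoreEffects named BART-score contrast per condition
#'   (pumps), entering the score map directly.
#' @param arousalSubjectSd sd of the per-subject arousal intercept.
#' @param subjectSd sd of the per-subject BART-score random intercept.
#' @param arousalJitterSd sd of the per-record arousal jitter.
#' @param beta named numeric: planted linear coefficients over (a subset of)
#'   the 11 features; applied to features extracted from the realised
#'   signals, so the linear map is exactly identified at zero noise.
#' @param intercept planted score intercept (pumps).
#' @param noiseSd residual sd of the BART score (pumps).
#' @param nonlinear logical; use the planted nonlinear score map instead.
#' @param nonlinearParams list defining the planted nonlinear score map
#'   \deqn{y = b_0 + w_s\,\tanh(slope/s_0)\,g_s[cond] +
#'              a\,\tanh(arousal - a_0)\,g_a[cond] + w_m\,\bar{A} + u_i +
#'              \epsilon,}
#'   with elements `wSlope` (\eqn{w_s}), `s0` (drift saturation scale,
#'   degC/s), `slopeGain` (\eqn{g_s}, per-condition multiplier of the
#'   temperature-drift term), `amp` (\eqn{a}), `a0` (arousal centring),
#'   `condGain` (\eqn{g_a}), and `wTrend`/`trendScale`,
#'   `wEdaDrift`/`edaDriftScale` weighting the signed within-session
#'   heart-rate trend and EDA tonic drift (each divided by its scale).
#'   The saturating transforms and condition interactions make the map
#'   genuinely nonlinear in the extracted features, and the two signed
#'   trend terms live in temporal structure that the 11 summary features
#'   discard entirely (their summaries are direction-blind), emulating the
#'   premise that end-to-end models can access information that manual
#'   feature extraction loses.
#' @param sessionLengthS EDA/TEMP/IBI session length in seconds.
#' @param bvpLengthS BVP session length in seconds.
#' @param seed integer; fully determines the generated dataset.
#' @return A validated list of class `GenParams`.
#' @export
genParams <- function(nSubjects = 38,
                      recordsPerCondition = 1,
                      conditionEffects = c(LI = 0.8, HI = 1.5, NT = 0.4, NR = 0),
                      conditionScoreEffects = c(LI = 4, HI = 7, NT = 2, NR = 0),
                      arousalSubjectSd = 0.3,
                      subjectSd = 3,
                      arousalJitterSd = 0.2,
                      beta = c(IBISDNN = 40, IBIRMSSD = -25, Slope = 50,
                               mAmp = 2, TCR = 300),
                      intercept = 30,
                      noiseSd = 1,
                      nonlinear = FALSE,
                      nonlinearParams = list(wSlope = 5, s0 = 0.008,
                                             slopeGain = c(LI = 1.2, HI = 2,
                                                           NT = 0.8, NR = 0.4),
                                             amp = 5, a0 = 0.8,
                                             condGain = c(LI = 1.5, HI = 2.5,
                                                          NT = 1, NR = 0.3),
                                             wTrend = -5, trendScale = 0.08,
                                             wEdaDrift = 8,
                                             edaDriftScale = 0.025),
                      sessionLengthS = 18,
                      bvpLengthS = 18.75,
                      seed = 1) {
  p <- list(nSubjects = as.integer(nSubjects),
            recordsPerCondition = as.integer(recordsPerCondition),
            conditionEffects = conditionEffects,
            conditionScoreEffects = conditionScoreEffects,
            arousalSubjectSd = arousalSubjectSd,
            subjectSd = subjectSd,
            arousalJitterSd = arousalJitterSd,
            beta = beta, intercept = intercept, noiseSd = noiseSd,
            nonlinear = isTRUE(nonlinear), nonlinearParams = nonlinearParams,
            sessionLengthS = sessionLengthS, bvpLengthS = bvpLengthS,
            seed = as.integer(seed))
  class(p) <- "GenParams"
  validateGenParams(p)
  p
}

validateGenParams <- function(p) {
  ok <- p$nSubjects >= 1L && p$recordsPerCondition >= 1L &&
    p$subjectSd >= 0 && p$noiseSd >= 0 && p$arousalSubjectSd >= 0 &&
    p$arousalJitterSd >= 0 && p$sessionLengthS > 0 && p$bvpLengthS > 0 &&
    all(CONDITIONS %in% names(p$conditionEffects)) &&
    all(CONDITIONS %in% names(p$conditionScoreEffects)) &&
    all(names(p$beta) %in% FEATURE_NAMES)
  if (!ok) tactileError("invalid generator parameters", "invalidGenParams")
  invisible(p)
}

## evaluate expr under a local deterministic seed, restoring the RNG state
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## per-subject arousal intercepts, a deterministic function of the seed
subjectArousalIntercepts <- function(params) {
  withLocalSeed(params$seed, stats::rnorm(params$nSubjects, 0, params$arousalSubjectSd))
}

## per-subject score intercepts (independent stream)
subjectScoreIntercepts <- function(params) {
  withLocalSeed(params$seed + 500009L,
                stats::rnorm(params$nSubjects, 0, params$subjectSd))
}

recordSeed <- function(params, subjectIndex, condition, rep = 1L) {
  ci <- match(condition, CONDITIONS)
  (params$seed + 104729L * subjectIndex + 977L * ci + 31L * rep) %% .Machine$integer.max
}

#' Latent arousal for one session
#'
#' `arousal = conditionEffects[condition] + u_i + N(0, arousalJitterSd)`,
#' where the per-subject intercept `u_i ~ N(0, arousalSubjectSd^2)` and the
#' jitter are deterministic functions of `params$seed`, the subject index,
#' the condition and the repetition — the same call always returns the same
#' value.
#'
#' @param params a `GenParams` list from [genParams()].
#' @param subjectIndex integer in `1:nSubjects`.
#' @param condition one of `"LI"`, `"HI"`, `"NT"`, `"NR"`.
#' @param rep repetition index (for `recordsPerCondition > 1`).
#' @return Numeric scalar.
#' @export
simulateArousal <- function(params, subjectIndex, condition, rep = 1L) {
  if (!condition %in% CONDITIONS) {
    tactileError(sprintf("unknown condition: %s", condition), "invalidCondition")
  }
  u <- subjectArousalIntercepts(params)[subjectIndex]
  jitter <- withLocalSeed(recordSeed(params, subjectIndex, condition, rep) + 1L,
                          stats::rnorm(1, 0, params$arousalJitterSd))
  unname(params$conditionEffects[condition] + u + jitter)
}

#' Simulate an interbeat-interval series
#'
#' Interval durations are drawn around a mean of `60 / (60 + kHr * arousal)`
#' seconds with standard deviation `rrSd * exp(-kVar * arousal)` — so mean
#' heart rate rises and RMSSD/SDNN fall monotonically (in expectation) with
#' arousal — plus a linear within-session trend: the interval drifts by
#' `trend` seconds from the start to the end of the session (heart-rate
#' acceleration when negative). The trend changes neither the expected mean
#' interval nor the direction-blind dispersion summaries; only its sign-
#' aware temporal structure carries it. Cumulative event times fill
#' `lengthS`. Draws come from the current RNG state.
#'
#' @param arousal latent arousal.
#' @param lengthS session length in seconds.
#' @param kHr heart-rate gain, beats/min per arousal unit.
#' @param rrSd baseline interval sd in seconds at zero arousal.
#' @param kVar variability decay rate per arousal unit.
#' @param trend total interval change across the session, seconds; drawn
#'   `N(0, trendSd^2)` when `NULL`.
#' @param trendSd sd of the random trend draw.
#' @return A list: `series` (an [IbiSeries-class]) and `trend` (the
#'   realised total interval change, seconds).
#' @export
simulateIbi <- function(arousal, lengthS, kHr = 8, rrSd = 0.05, kVar = 0.5,
                        trend = NULL, trendSd = 0.08) {
  meanRR <- 60 / (60 + kHr * arousal)
  sdRR <- rrSd * exp(-kVar * arousal)
  if (is.null(trend)) trend <- stats::rnorm(1, 0, trendSd)
  n <- ceiling(lengthS / meanRR) + 10L
  frac <- if (n > 1L) (seq_len(n) - 1) / (n - 1) - 0.5 else 0
  d <- pmin(pmax(stats::rnorm(n, meanRR, sdRR) + trend * frac, 0.3), 2.9)
  t <- cumsum(d)
  keep <- t <= lengthS
  if (!any(keep)) keep[1L] <- TRUE
  list(series = IbiSeries(eventTimes = t[keep], durations = d[keep]),
       trend = trend)
}

## one SCR bump: linear rise over riseS, exponential decay with time scale tau
scrBump <- function(tGrid, onset, amp, riseS = 1.5, tau = 2) {
  dt <- tGrid - onset
  out <- numeric(length(tGrid))
  rising <- dt >= 0 & dt < riseS
  falling <- dt >= riseS
  out[rising] <- amp * dt[rising] / riseS
  out[falling] <- amp * exp(-(dt[falling] - riseS) / tau)
  out
}

#' Simulate an electrodermal-activity series (4 Hz)
#'
#' Tonic level `tonicBase * (1 + tonicGain * arousal)` plus an independent
#' tonic nuisance, plus Poisson-rate skin-conductance-response bumps
#' (linear rise over 1.5 s, exponential decay) whose rate and amplitude both
#' increase with arousal, plus Gaussian noise far below the 0.05 microsiemens
#' event threshold.
#'
#' @param arousal latent arousal.
#' @param lengthS session length in seconds.
#' @param nEvents optional exact number of bumps (overrides the Poisson draw).
#' @param onsets optional exact bump onset times in seconds (default: drawn
#'   uniformly over the session).
#' @param amp optional exact bump amplitude in microsiemens.
#' @param rate0,rateA Poisson mean event count at zero arousal and its gain.
#' @param amp0,ampA base bump amplitude at zero arousal and its gain
#'   (microsiemens).
#' @param ampHetero scale of the exponential amplitude heterogeneity across
#'   bumps within a session (microsiemens).
#' @param tonicBase,tonicGain,tonicSd tonic level parameters (microsiemens).
#' @param tonicDrift signed linear tonic drift in microsiemens per second;
#'   drawn `N(0, tonicDriftSd^2)` when `NULL`. Mean-type summaries see at
#'   most its magnitude, never its sign.
#' @param tonicDriftSd sd of the random drift draw.
#' @param noiseSd measurement noise sd (microsiemens).
#' @return A list: `series` (a [SignalSeries-class], channel `"EDA"`),
#'   `nEvents`, `ampMean`/`ampMax` (planted mean/maximum bump amplitude)
#'   and `tonicDrift` (microsiemens per second).
#' @export
simulateEda <- function(arousal, lengthS, nEvents = NULL, onsets = NULL,
                        amp = NULL,
                        rate0 = 1, rateA = 1.5, amp0 = 0.12, ampA = 0.08,
                        ampHetero = 0.12, tonicBase = 1, tonicGain = 0.3,
                        tonicSd = 0.5, tonicDrift = NULL, tonicDriftSd = 0.025,
                        noiseSd = 0.003) {
  rate <- 4
  n <- round(lengthS * rate)
  tGrid <- (seq_len(n) - 1L) / rate
  tonic <- max(0.6, tonicBase * (1 + tonicGain * arousal) + stats::rnorm(1, 0, tonicSd))
  if (is.null(tonicDrift)) tonicDrift <- stats::rnorm(1, 0, tonicDriftSd)
  if (is.null(nEvents)) {
    nEvents <- stats::rpois(1, max(0, rate0 + rateA * arousal))
  }
  v <- tonic + tonicDrift * (tGrid - lengthS / 2)
  amps <- numeric(0)
  if (nEvents > 0) {
    if (is.null(onsets)) onsets <- sort(stats::runif(nEvents, 0, max(0.1, lengthS - 4)))
    amps <- if (is.null(amp)) {
      pmax(0.08, amp0 + ampA * arousal + stats::rexp(nEvents, 1 / ampHetero))
    } else rep(amp, nEvents)
    for (k in seq_len(nEvents)) v <- v + scrBump(tGrid, onsets[k], amps[k])
  }
  if (noiseSd > 0) v <- v + stats::rnorm(n, 0, noiseSd)
  list(series = SignalSeries(pmax(v, 0), rateHz = rate, channel = "EDA"),
       nEvents = nEvents,
       ampMean = if (length(amps)) mean(amps) else 0,
       ampMax = if (length(amps)) max(amps) else 0,
       tonicDrift = tonicDrift)
}

#' Simulate a blood-volume-pulse series (64 Hz)
#'
#' A zero-mean pulse train at the arousal-implied heart rate with amplitude
#' `ampScale * (1 + kAmp * arousal)`, an optional second harmonic, and
#' Gaussian noise.
#'
#' @param arousal latent arousal.
#' @param lengthS session length in seconds.
#' @param ampScale base amplitude (arbitrary units).
#' @param kAmp amplitude gain per arousal unit.
#' @param harmonic relative amplitude of the second harmonic.
#' @param noiseSd measurement noise sd.
#' @param kHr heart-rate gain (matches [simulateIbi()]).
#' @return A [SignalSeries-class] with channel `"BVP"`.
#' @export
simulateBvp <- function(arousal, lengthS, ampScale = 1, kAmp = 0.3,
                        harmonic = 0.2, noiseSd = 0.02, kHr = 8) {
  rate <- 64
  n <- round(lengthS * rate)
  tGrid <- (seq_len(n) - 1L) / rate
  f <- (60 + kHr * arousal) / 60
  A <- ampScale * (1 + kAmp * arousal)
  phase <- stats::runif(1, 0, 2 * pi)
  v <- A * sin(2 * pi * f * tGrid + phase) +
    A * harmonic * sin(4 * pi * f * tGrid + 2 * phase)
  if (noiseSd > 0) v <- v + stats::rnorm(n, 0, noiseSd)
  SignalSeries(v, rateHz = rate, channel = "BVP")
}

#' Simulate a skin-temperature series (4 Hz)
#'
#' A linear drift whose slope is `kSlope * arousal` plus an independent
#' drift component (visible only in this channel), around a base level,
#' with Gaussian noise; values are clamped to the [20, 45] degC validity
#' window.
#'
#' @param arousal latent arousal.
#' @param lengthS session length in seconds.
#' @param base base temperature, degrees Celsius.
#' @param kSlope drift gain, degC/s per arousal unit.
#' @param driftSd sd of the independent drift component, degC/s.
#' @param baseSd sd of the session-level base temperature.
#' @param noiseSd measurement noise sd, degC.
#' @return A list: `series` (a [SignalSeries-class], channel `"TEMP"`),
#'   `slope` (the realised drift, degC/s).
#' @export
simulateTemp <- function(arousal, lengthS, base = 33, kSlope = 0.01,
                         driftSd = 0.005, baseSd = 0.3, noiseSd = 0.002) {
  rate <- 4
  n <- round(lengthS * rate)
  tGrid <- (seq_len(n) - 1L) / rate
  slope <- kSlope * arousal + stats::rnorm(1, 0, driftSd)
  b0 <- base + stats::rnorm(1, 0, baseSd)
  v <- b0 + slope * tGrid
  if (noiseSd > 0) v <- v + stats::rnorm(n, 0, noiseSd)
  list(series = SignalSeries(pmin(pmax(v, 20), 45), rateHz = rate, channel = "TEMP"),
       slope = slope)
}

#' Generate a synthetic dataset with known ground truth
#'
#' Produces `nSubjects * 4 * recordsPerCondition` records (condition order
#' randomised within subject) whose signals are driven by the latent arousal
#' of [simulateArousal()], and whose BART scores follow the planted linear
#' map over the extracted features (default) or the planted nonlinear map
#' (`nonlinear = TRUE`). Fully deterministic given `params$seed`.
#'
#' @param params a `GenParams` list from [genParams()].
#' @return A list with elements `records` (list of [PhysioRecord-class]) and
#'   `truth` (data.frame with per-record latent arousal, subject intercepts,
#'   planted temperature drift and SCR amplitude, and the noiseless score),
#'   plus the `params` used.
#' @export
generateDataset <- function(params) {
  validateGenParams(params)
  uScore <- subjectScoreIntercepts(params)
  records <- vector("list", 0L)
  truthRows <- list()
  for (i in seq_len(params$nSubjects)) {
    sid <- sprintf("S%02d", i)
    conds <- withLocalSeed(params$seed + 33331L * i, sample(CONDITIONS))
    for (cond in conds) {
      for (rep in seq_len(params$recordsPerCondition)) {
        a <- simulateArousal(params, i, cond, rep)
        rs <- recordSeed(params, i, cond, rep)
        sig <- withLocalSeed(rs + 2L, {
          edaSim <- simulateEda(a, params$sessionLengthS)
          bvpSim <- simulateBvp(a, params$bvpLengthS)
          tempSim <- simulateTemp(a, params$sessionLengthS)
          ibiSim <- simulateIbi(a, params$sessionLengthS)
          eps <- stats::rnorm(1, 0, params$noiseSd)
          list(eda = edaSim, bvp = bvpSim, temp = tempSim, ibi = ibiSim, eps = eps)
        })
        rec <- PhysioRecord(subjectId = sid, condition = cond,
                            eda = sig$eda$series, bvp = sig$bvp,
                            temp = sig$temp$series, ibi = sig$ibi$series,
                            bartScore = 0)
        feats <- extractFeatures(rec)
        noiseless <- if (params$nonlinear) {
          np <- params$nonlinearParams
          params$intercept +
            np$wSlope * tanh(sig$temp$slope / np$s0) * np$slopeGain[[cond]] +
            np$amp * tanh(a - np$a0) * np$condGain[[cond]] +
            np$wTrend * (sig$ibi$trend / np$trendScale) +
            np$wEdaDrift * (sig$eda$tonicDrift / np$edaDriftScale) +
            uScore[i]
        } else {
          params$intercept +
            sum(params$beta * feats[names(params$beta)]) +
            params$conditionScoreEffects[[cond]] +
            uScore[i]
        }
        y <- max(0, noiseless + sig$eps)
        rec@bartScore <- y
        records[[length(records) + 1L]] <- rec
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          subject_id = sid, condition = cond, rep = rep,
          arousal = a, u_score = uScore[i],
          temp_slope = sig$temp$slope, scr_amp = sig$eda$ampMean,
          scr_amp_max = sig$eda$ampMax, rr_trend = sig$ibi$trend,
          eda_drift = sig$eda$tonicDrift,
          noiseless_score = unname(noiseless), bart_score = y,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(records = records, truth = do.call(rbind, truthRows), params = params)
}
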