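## Session directories follow the Empatica E4 export dialect:
##   EDA.csv / BVP.csv / TEMP.csv : line 1 = start timestamp (s since epoch),
##     line 2 = sampling rate (Hz), then one sample per line.
##   IBI.csv : line 1 = start timestamp, then "offset_seconds,duration_seconds".
## Labels (subject, condition, BART score) live in a sidecar meta.csv because
## E4 exports carry none.

readContinuousChannel <- function(file, chan) {
  if (!file.exists(file)) {
    tactileError(sprintf("missing channel file: %s", file), "missingChannel")
  }
  x <- scan(file, what = numeric(), sep = ",", quiet = TRUE)
  if (length(x) < 3L) {
    tactileError(sprintf("channel file too short: %s", file), "malformedHeader")
  }
  start <- x[1L]
  rate <- x[2L]
  if (!is.finite(rate) || rate <= 0) {
    tactileError(sprintf("non-positive sampling rate in %s", file), "malformedHeader")
  }
  SignalSeries(values = x[-(1:2)], rateHz = rate, channel = chan, startTime = start)
}

readIbiChannel <- function(file, dropImplausible = TRUE) {
  if (!file.exists(file)) {
    tactileError(sprintf("missing channel file: %s", file), "missingChannel")
  }
  lines <- readLines(file)
  if (length(lines) < 1L) {
    tactileError(sprintf("empty IBI file: %s", file), "malformedHeader")
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) return(IbiSeries(numeric(0), numeric(0)))
  parts <- do.call(rbind, strsplit(body, ","))
  offs <- as.numeric(parts[, 1L])
  durs <- as.numeric(parts[, 2L])
  if (anyNA(offs) || anyNA(durs)) {
    tactileError(sprintf("non-numeric rows in %s", file), "malformedIbi")
  }
  if (length(offs) > 1L && any(diff(offs) <= 0)) {
    tactileError(sprintf("non-monotone IBI offsets in %s", file), "malformedIbi")
  }
  keep <- durs > 0.25 & durs < 3.0
  if (dropImplausible && any(!keep)) {
    message(sprintf("%s: dropped %d IBI interval(s) outside (0.25, 3) s",
                    file, sum(!keep)))
    offs <- offs[keep]
    durs <- durs[keep]
  }
  IbiSeries(eventTimes = offs, durations = durs)
}

#' Read one Empatica-E4-style session directory
#'
#' Expects `EDA.csv`, `BVP.csv`, `TEMP.csv`, `IBI.csv` in the E4 export layout
#' plus a `meta.csv` with columns `subject_id`, `condition`, `bart_score`.
#' Sampling rates are taken from the file headers, never assumed.
#' Interbeat intervals outside the (0.25, 3) s plausibility gate are dropped
#' with a message rather than failing the load.
#'
#' @param path session directory.
#' @return A [PhysioRecord-class].
#' @seealso [writeSession()], [loadDataset()]
#' @export
readSession <- function(path) {
  meta_file <- file.path(path, "meta.csv")
  if (!file.exists(meta_file)) {
    tactileError(sprintf("missing meta.csv in %s", path), "missingChannel")
  }
  meta <- utils::read.csv(meta_file, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "condition", "bart_score") %in% names(meta)))
  PhysioRecord(
    subjectId = meta$subject_id[1L],
    condition = meta$condition[1L],
    eda = readContinuousChannel(file.path(path, "EDA.csv"), "EDA"),
    bvp = readContinuousChannel(file.path(path, "BVP.csv"), "BVP"),
    temp = readContinuousChannel(file.path(path, "TEMP.csv"), "TEMP"),
    ibi = readIbiChannel(file.path(path, "IBI.csv")),
    bartScore = meta$bart_score[1L]
  )
}

writeContinuousChannel <- function(sig, file) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  writeLines(format(c(sig@startTime, sig@rateHz), digits = 17, trim = TRUE,
                    scientific = FALSE), con)
  writeLines(format(sig@values, digits = 17, trim = TRUE, scientific = FALSE), con)
  invisible(NULL)
}

#' Write one session directory in the E4 export dialect
#'
#' The inverse of [readSession()]: values are written at full double precision
#' so the write-read round trip is the identity on [PhysioRecord-class].
#'
#' @param record a valid [PhysioRecord-class].
#' @param path directory to create/populate.
#' @return The session directory, invisibly.
#' @export
writeSession <- function(record, path) {
  if (!is(record, "PhysioRecord")) {
    tactileError("record must be a PhysioRecord", "invalidRecord")
  }
  validObject(record)
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    tactileError(sprintf("cannot create session directory %s", path), "ioError")
  }
  writeContinuousChannel(record@eda, file.path(path, "EDA.csv"))
  writeContinuousChannel(record@bvp, file.path(path, "BVP.csv"))
  writeContinuousChannel(record@temp, file.path(path, "TEMP.csv"))
  con <- file(file.path(path, "IBI.csv"), open = "wt")
  writeLines("0", con)
  if (length(record@ibi@eventTimes)) {
    writeLines(paste(
      format(record@ibi@eventTimes, digits = 17, trim = TRUE, scientific = FALSE),
      format(record@ibi@durations, digits = 17, trim = TRUE, scientific = FALSE),
      sep = ","), con)
  }
  close(con)
  utils::write.csv(
    data.frame(subject_id = record@subjectId, condition = record@condition,
               bart_score = record@bartScore),
    file.path(path, "meta.csv"), row.names = FALSE)
  invisible(path)
}

#' Write a dataset of records as session directories plus a manifest
#'
#' @param records list of [PhysioRecord-class] objects.
#' @param dir root directory; one sub-directory per session is created.
#' @return Path to the manifest CSV, invisibly.
#' @export
writeDataset <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    sess <- sprintf("%s_%s", r@subjectId, r@condition)
    writeSession(r, file.path(dir, sess))
    data.frame(subject_id = r@subjectId, condition = r@condition,
               path = sess, bart_score = r@bartScore)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}

#' Load a dataset from a manifest
#'
#' The manifest is a CSV with one row per session: `subject_id`, `condition`,
#' `path` (relative to the manifest's directory) and `bart_score`. Duplicate
#' (subject, condition) pairs are rejected.
#'
#' @param manifest path to the manifest CSV.
#' @return List of [PhysioRecord-class] objects.
#' @export
loadDataset <- function(manifest) {
  mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (nrow(mf) == 0L) {
    warning("empty manifest: no sessions to load")
    return(list())
  }
  key <- paste(mf$subject_id, mf$condition, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- mf[duplicated(key), , drop = FALSE]
    tactileError(sprintf("duplicate (subject, condition) session: (%s, %s)",
                         dup$subject_id[1L], dup$condition[1L]),
                 "duplicateSession")
  }
  root <- dirname(manifest)
  lapply(seq_len(nrow(mf)), function(i) readSession(file.path(root, mf$path[i])))
}
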