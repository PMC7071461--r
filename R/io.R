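#' Write a recording as an ASCII/CSV matrix
#'
#' One column per channel with a header row of channel labels; one row
#' per sample. Values are written in full double precision.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAsciiEEG <- function(rec, path) {
  df <- as.data.frame(t(eegData(rec)))
  colnames(df) <- channelLabels(rec)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read an ASCII/CSV EEG matrix
#'
#' Accepts samples-in-rows (default, matching \code{writeAsciiEEG}) or
#' channels-in-rows orientation. The sampling rate is not stored in the
#' format and must be supplied.
#'
#' @param path input file.
#' @param fs sampling rate in Hz.
#' @param channelLabels channel names; defaults to the file header when
#'   present. Must match the channel count.
#' @param orientation "samples_rows" or "channels_rows".
#' @param subjectId,classLabel optional metadata.
#' @return an \linkS4class{EEGRecording}.
#' @export
readAsciiEEG <- function(path, fs, channelLabels = NULL,
                         orientation = c("samples_rows", "channels_rows"),
                         subjectId = NA_character_,
                         classLabel = NA_character_) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty or unparsable file: ", path)
  hasHeader <- orientation == "samples_rows"
  dt <- data.table::fread(path, header = hasHeader, data.table = FALSE,
                          fill = FALSE)
  if (nrow(dt) == 0L || ncol(dt) == 0L) stop("empty or unparsable file: ", path)
  if (!all(vapply(dt, is.numeric, logical(1))))
    stop("non-numeric values in EEG matrix: ", path)
  M <- as.matrix(dt)
  X <- if (orientation == "samples_rows") t(M) else M
  if (is.null(channelLabels)) {
    channelLabels <- if (hasHeader) colnames(dt)
                     else paste0("ch", seq_len(nrow(X)))
  }
  if (length(channelLabels) != nrow(X))
    stop("channel label count (", length(channelLabels),
         ") does not match channel count (", nrow(X), ")")
  EEGRecording(X, fs = fs, channelLabels = channelLabels,
               subjectId = subjectId, classLabel = classLabel)
}

# ---- EDF (European Data Format, 16-bit) ----

padField <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

numField <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = width - 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  padField(s, width)
}

#' Write a recording as an EDF file
#'
#' Minimal single-rate EDF writer: one 1-second data record per second
#' of signal, 16-bit samples, per-channel physical scaling from the
#' data range. The recording length must be an integer number of
#' seconds.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(rec, path) {
  X <- eegData(rec)
  fs <- samplingRate(rec)
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer fs")
  fs <- as.integer(round(fs))
  nRec <- ncol(X) / fs
  if (abs(nRec - round(nRec)) > 1e-9)
    stop("EDF writer requires an integer number of seconds")
  nRec <- as.integer(round(nRec))
  ns <- nrow(X)
  physMin <- apply(X, 1, min)
  physMax <- apply(X, 1, max)
  flat <- physMax - physMin < 1e-12
  physMin[flat] <- physMin[flat] - 1
  physMax[flat] <- physMax[flat] + 1
  digMin <- -32768; digMax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(c(
    padField("0", 8),
    padField(subjectId(rec), 80),
    padField("eegmoments synthetic", 80),
    padField("01.01.00", 8), padField("00.00.00", 8),
    padField(256 + 256 * ns, 8),
    padField("", 44),
    padField(nRec, 8), padField(1, 8), padField(ns, 4),
    vapply(channelLabels(rec), padField, "", width = 16),
    rep(padField("", 80), ns),            # transducer
    rep(padField("uV", 8), ns),           # physical dimension
    vapply(physMin, numField, "", width = 8),
    vapply(physMax, numField, "", width = 8),
    rep(padField(digMin, 8), ns),
    rep(padField(digMax, 8), ns),
    rep(padField("", 80), ns),            # prefiltering
    rep(padField(fs, 8), ns),
    rep(padField("", 32), ns)),
    collapse = "")
  writeChar(hdr, con, eos = NULL)
  # re-read the header fields actually written (numField may round),
  # so scaling uses exactly the stored physical range
  physMinW <- as.numeric(vapply(physMin, numField, "", width = 8))
  physMaxW <- as.numeric(vapply(physMax, numField, "", width = 8))
  scale <- (physMaxW - physMinW) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    idx <- (r - 1L) * fs + seq_len(fs)
    block <- matrix(0L, nrow = fs, ncol = ns)
    for (ch in seq_len(ns)) {
      d <- round((X[ch, idx] - physMinW[ch]) / scale[ch]) + digMin
      block[, ch] <- as.integer(pmin(pmax(d, digMin), digMax))
    }
    writeBin(as.integer(as.vector(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Supports the plain 16-bit EDF layout written by \code{\link{writeEDF}}
#' and other single-rate continuous EDF recordings. All selected
#' channels must share one sampling rate.
#'
#' @param path input file.
#' @param channels optional character vector of channel labels to keep,
#'   in the requested order (default: all, file order).
#' @param subjectId,classLabel optional metadata overrides; subjectId
#'   defaults to the EDF patient field.
#' @return an \linkS4class{EEGRecording}.
#' @export
readEDF <- function(path, channels = NULL, subjectId = NULL,
                    classLabel = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  version <- rd(8)
  patient <- rd(80); rd(80); rd(8); rd(8)
  headerBytes <- as.integer(rd(8)); rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fields <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fields(16)
  fields(80); fields(8)
  physMin <- as.numeric(fields(8))
  physMax <- as.numeric(fields(8))
  digMin <- as.numeric(fields(8))
  digMax <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  sel <- seq_len(ns)
  if (!is.null(channels)) {
    sel <- match(channels, labels)
    if (anyNA(sel)) stop("channel(s) not in EDF: ",
                         paste(channels[is.na(sel)], collapse = ", "))
  }
  if (length(unique(spr[sel])) != 1L)
    stop("selected channels have mixed sampling rates; unsupported")
  fs <- spr[sel[1]] / recDur
  raw <- readBin(con, integer(), n = nRec * sum(spr), size = 2,
                 endian = "little")
  offsets <- c(0, cumsum(spr))
  X <- matrix(0, nrow = length(sel), ncol = nRec * spr[sel[1]])
  for (j in seq_along(sel)) {
    ch <- sel[j]
    sc <- (physMax[ch] - physMin[ch]) / (digMax[ch] - digMin[ch])
    for (r in seq_len(nRec)) {
      src <- (r - 1L) * sum(spr) + offsets[ch] + seq_len(spr[ch])
      dst <- (r - 1L) * spr[ch] + seq_len(spr[ch])
      X[j, dst] <- (raw[src] - digMin[ch]) * sc + physMin[ch]
    }
  }
  EEGRecording(X, fs = fs, channelLabels = labels[sel],
               subjectId = if (is.null(subjectId)) patient else subjectId,
               classLabel = classLabel)
}

# ---- cohort manifest ----

#' Write a cohort to disk with a JSON manifest
#'
#' Writes each recording in the requested format and a manifest listing
#' subject id, class, relative file path, sampling rate and format.
#'
#' @param cohort named list of \linkS4class{EEGRecording}s.
#' @param dir output directory (created if missing).
#' @param format "csv" or "edf".
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    fn <- paste0(subjectId(rec), ".", format)
    fp <- file.path(dir, fn)
    if (format == "csv") writeAsciiEEG(rec, fp) else writeEDF(rec, fp)
    entries[[i]] <- list(subject_id = subjectId(rec),
                         class_label = classLabel(rec),
                         file = fn, fs = samplingRate(rec),
                         format = format)
  }
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}

#' Read a cohort manifest and load its recordings
#'
#' @param manifestPath path to a manifest written by
#'   \code{\link{writeCohort}}.
#' @return named list of \linkS4class{EEGRecording}s.
#' @export
readCohort <- function(manifestPath) {
  entries <- jsonlite::read_json(manifestPath)
  base <- dirname(manifestPath)
  out <- list()
  for (e in entries) {
    fp <- file.path(base, e$file)
    if (!file.exists(fp))
      stop("manifest references a missing file for subject ",
           e$subject_id, ": ", fp)
    rec <- if (identical(e$format, "edf"))
      readEDF(fp, subjectId = e$subject_id, classLabel = e$class_label)
    else
      readAsciiEEG(fp, fs = e$fs, subjectId = e$subject_id,
                   classLabel = e$class_label)
    out[[e$subject_id]] <- rec
  }
  out
}
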