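#' Bandpass + notch filter specification
#'
#' Defaults follow offline resting-EEG practice for this pipeline:
#' 3rd-order Butterworth bandpass 1-70 Hz plus a 50 Hz IIR notch
#' (Q = 30), both applied forward-backward (zero phase), so the
#' effective magnitude response is squared.
#'
#' @param bpLow,bpHigh bandpass edges in Hz.
#' @param order Butterworth order (per pass).
#' @param notchFreq notch centre frequency in Hz (NA disables it).
#' @param notchQ notch quality factor (centre / -3 dB width).
#' @return list of class \code{FilterSpec}.
#' @export
filterSpec <- function(bpLow = 1, bpHigh = 70, order = 3,
                       notchFreq = 50, notchQ = 30) {
  if (!(bpLow > 0 && bpLow < bpHigh)) stop("need 0 < bpLow < bpHigh")
  if (order < 1) stop("order must be >= 1")
  structure(list(bpLow = bpLow, bpHigh = bpHigh, order = as.integer(order),
                 notchFreq = notchFreq, notchQ = notchQ),
            class = "FilterSpec")
}

# RBJ biquad notch coefficients; returned as list(b, a).
notchCoefficients <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Zero-phase Butterworth bandpass plus 50 Hz notch
#'
#' Applies the bandpass and (when enabled) the notch with
#' forward-backward filtering to every channel. Shape, sampling rate
#' and metadata are preserved.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param spec a \code{\link{filterSpec}}.
#' @return the filtered \linkS4class{EEGRecording}.
#' @export
bandpassNotch <- function(rec, spec = filterSpec()) {
  fs <- samplingRate(rec)
  if (spec$bpHigh >= fs / 2)
    stop("bpHigh must be below the Nyquist frequency fs/2")
  bf <- signal::butter(spec$order,
                       c(spec$bpLow, spec$bpHigh) / (fs / 2),
                       type = "pass")
  nc <- if (!is.na(spec$notchFreq) && spec$notchFreq < fs / 2)
          notchCoefficients(spec$notchFreq, fs, spec$notchQ) else NULL
  X <- eegData(rec)
  for (ch in seq_len(nrow(X))) {
    y <- signal::filtfilt(bf, X[ch, ])
    if (!is.null(nc)) y <- signal::filtfilt(nc$b, nc$a, y)
    X[ch, ] <- y
  }
  initialize(rec, data = X)
}

#' Downsample a recording by an integer factor
#'
#' Anti-alias filters and decimates each channel
#' (\code{signal::decimate}); the sampling rate of the returned
#' recording is \code{targetFs}. \code{targetFs} equal to the current
#' rate is the identity.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param targetFs target sampling rate; \code{fs / targetFs} must be a
#'   positive integer.
#' @return the downsampled \linkS4class{EEGRecording}.
#' @export
downsampleRecording <- function(rec, targetFs) {
  fs <- samplingRate(rec)
  if (targetFs == fs) return(rec)
  q <- fs / targetFs
  if (abs(q - round(q)) > 1e-9 || q < 1)
    stop("fs must be an integer multiple of targetFs")
  q <- as.integer(round(q))
  X <- eegData(rec)
  Y <- t(apply(X, 1L, function(x) signal::decimate(x, q, ftype = "iir")))
  initialize(rec, data = Y, fs = targetFs, segStarts = 1L)
}

#' Canonicalize artifact annotations
#'
#' Sorts and merges overlapping or touching half-open
#' \code{[start, end)} second intervals.
#'
#' @param intervals two-column matrix or data.frame of
#'   (start_s, end_s); may have zero rows.
#' @return matrix with columns start, end, non-overlapping and sorted.
#' @export
#' @examples
#' mergeIntervals(rbind(c(10, 20), c(15, 25)))
mergeIntervals <- function(intervals) {
  m <- matrix(as.numeric(unlist(intervals)), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  if (nrow(m) == 0L) return(m)
  if (any(m[, 1] >= m[, 2])) stop("intervals must have start < end")
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    j <- nrow(out)
    if (m[i, 1] <= out[j, 2]) out[j, 2] <- max(out[j, 2], m[i, 2])
    else out <- rbind(out, m[i, ])
  }
  out
}

#' Remove annotated artifact spans from a recording
#'
#' Deletes the samples whose time falls in any annotated
#' \code{[start, end)} span and concatenates the remaining clean
#' segments. Segment boundaries are recorded in the result's
#' \code{segStarts} so that \code{\link{epochRecording}} never cuts an
#' epoch across a splice.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param intervals artifact spans in seconds (two-column matrix /
#'   data.frame, possibly empty), relative to the recording start.
#' @return the masked \linkS4class{EEGRecording}.
#' @export
applyArtifactMask <- function(rec, intervals) {
  m <- mergeIntervals(intervals)
  n <- ncol(eegData(rec))
  dur <- n / samplingRate(rec)
  if (nrow(m) == 0L) return(rec)
  if (any(m[, 1] < 0) || any(m[, 2] > dur + 1e-9))
    stop("annotation interval outside the recording duration")
  tIdx <- (seq_len(n) - 1) / samplingRate(rec)
  drop <- rep(FALSE, n)
  for (i in seq_len(nrow(m)))
    drop <- drop | (tIdx >= m[i, 1] & tIdx < m[i, 2])
  keep <- which(!drop)
  if (length(keep) == 0L) stop("annotation removes the entire recording")
  # segment starts: kept samples whose predecessor was dropped/absent
  isStart <- c(TRUE, diff(keep) > 1L)
  initialize(rec, data = eegData(rec)[, keep, drop = FALSE],
             segStarts = as.integer(which(isStart)))
}

#' Cut a recording into nonoverlapping fixed-length epochs
#'
#' Epochs are contiguous half-open windows of
#' \code{epochLenS * fs} samples, earliest first, taken within each
#' clean segment independently (so no epoch straddles an artifact cut);
#' trailing partial windows are discarded. At most \code{maxEpochs} are
#' returned.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param epochLenS epoch length in seconds (default 5).
#' @param maxEpochs cap on the number of epochs (default 120;
#'   \code{Inf} keeps all).
#' @return an \linkS4class{EpochSet}; zero epochs (with a warning) when
#'   no segment holds a full window.
#' @export
epochRecording <- function(rec, epochLenS = 5, maxEpochs = 120) {
  fs <- samplingRate(rec)
  L <- round(epochLenS * fs)
  X <- eegData(rec)
  n <- ncol(X)
  segStarts <- rec@segStarts
  segEnds <- c(segStarts[-1] - 1L, n)
  starts <- integer(0)
  for (s in seq_along(segStarts)) {
    segLen <- segEnds[s] - segStarts[s] + 1L
    k <- segLen %/% L
    if (k > 0) starts <- c(starts, segStarts[s] + (0:(k - 1L)) * L)
  }
  if (length(starts) > maxEpochs) starts <- starts[seq_len(maxEpochs)]
  if (length(starts) == 0L)
    warning("recording shorter than one epoch; returning an empty EpochSet")
  arr <- array(0, dim = c(length(starts), nrow(X), L))
  for (e in seq_along(starts))
    arr[e, , ] <- X[, starts[e] + 0:(L - 1L), drop = FALSE]
  new("EpochSet", epochs = arr, fs = fs, epochLenS = epochLenS,
      channelLabels = channelLabels(rec), subjectId = subjectId(rec),
      classLabel = classLabel(rec))
}

#' Standard preprocessing chain for one recording
#'
#' Downsample (when requested), bandpass + notch filter, mask annotated
#' artifacts, and cut epochs — in that order, so the filters are
#' designed at the final sampling rate.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param targetFs final sampling rate (default: keep).
#' @param fspec a \code{\link{filterSpec}}.
#' @param artifacts artifact intervals in seconds (possibly empty).
#' @param epochLenS,maxEpochs passed to \code{\link{epochRecording}}.
#' @return an \linkS4class{EpochSet}.
#' @export
preprocessRecording <- function(rec, targetFs = samplingRate(rec),
                                fspec = filterSpec(),
                                artifacts = matrix(numeric(0), ncol = 2),
                                epochLenS = 5, maxEpochs = 120) {
  rec <- downsampleRecording(rec, targetFs)
  rec <- bandpassNotch(rec, fspec)
  rec <- applyArtifactMask(rec, artifacts)
  epochRecording(rec, epochLenS = epochLenS, maxEpochs = maxEpochs)
}
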