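#' Conventional EEG rhythm bands
#'
#' Half-open bands \code{[low, high)} Hz: delta (1-4), theta (4-8),
#' alpha (8-13), beta (13-32), and the whole band (1-32). Shared edges
#' therefore belong to the upper band exactly once, and the four rhythm
#' bands partition the whole band on an integer frequency grid.
#'
#' @return data.frame with columns name, low, high.
#' @export
#' @examples
#' rhythmBands()
rhythmBands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "whole"),
    low  = c(1, 4, 8, 13, 1),
    high = c(4, 8, 13, 32, 32),
    stringsAsFactors = FALSE
  )
}

#' Welch estimator configuration
#'
#' Defaults give 9 averaged segments per 1280-sample epoch: 256-sample
#' Hamming-tapered segments with 50\% overlap, \code{nfft} equal to the
#' segment length, so one-sided spectra have \code{nfft/2 + 1} bins at
#' 1 Hz spacing when \code{fs = 256}.
#'
#' @param windowLen segment length M in samples.
#' @param overlapFrac fractional overlap in [0, 1); hop is
#'   \code{M * (1 - overlapFrac)}.
#' @param windowKind taper, "hamming" (periodic) or "rect".
#' @param nfft DFT length (>= windowLen; segments are zero-padded).
#' @param fs sampling rate, Hz.
#' @return list of class \code{WelchConfig}; includes the taper vector
#'   and its mean-square normalisation U.
#' @export
welchConfig <- function(windowLen = 256, overlapFrac = 0.5,
                        windowKind = c("hamming", "rect"),
                        nfft = windowLen, fs = 256) {
  windowKind <- match.arg(windowKind)
  if (overlapFrac < 0 || overlapFrac >= 1)
    stop("overlapFrac must lie in [0, 1)")
  if (nfft < windowLen) stop("nfft must be >= windowLen")
  M <- as.integer(windowLen)
  w <- switch(windowKind,
    hamming = 0.54 - 0.46 * cos(2 * pi * (0:(M - 1)) / M),  # periodic
    rect = rep(1, M))
  U <- mean(w^2)
  structure(
    list(windowLen = M, overlapFrac = overlapFrac,
         windowKind = windowKind, nfft = as.integer(nfft), fs = fs,
         window = w, U = U,
         hop = as.integer(round(M * (1 - overlapFrac)))),
    class = "WelchConfig")
}

# Core Welch machinery shared by the scalar and matrix paths.
# X: channels x N matrix. Returns channels x (nfft/2 + 1) one-sided
# density matrix (units^2/Hz) averaged over L segments.
welchCore <- function(X, cfg) {
  M <- cfg$windowLen; h <- cfg$hop; nfft <- cfg$nfft
  N <- ncol(X); C <- nrow(X)
  if (N < M) stop("signal shorter than one Welch window")
  starts <- seq.int(1L, N - M + 1L, by = h)
  L <- length(starts)
  idx <- outer(0:(M - 1L), starts, `+`)       # M x L sample indices
  nb <- nfft %/% 2L + 1L
  out <- matrix(0, nrow = C, ncol = nb)
  seg <- matrix(0, nrow = nfft, ncol = L)
  for (ch in seq_len(C)) {
    seg[seq_len(M), ] <- X[ch, idx] * cfg$window
    Z <- stats::mvfft(seg)[seq_len(nb), , drop = FALSE]
    P <- (Mod(Z)^2) / (cfg$fs * M * cfg$U)
    # one-sided: double everything except DC and (for even nfft) Nyquist
    dbl <- rep(2, nb); dbl[1L] <- 1
    if (nfft %% 2L == 0L) dbl[nb] <- 1
    out[ch, ] <- dbl * rowMeans(P)
  }
  out
}

welchFreqs <- function(cfg) {
  (0:(cfg$nfft %/% 2L)) * cfg$fs / cfg$nfft
}

#' Modified periodogram of a single tapered segment
#'
#' One-sided power spectral density of one segment: the squared DFT
#' magnitude of the tapered segment, scaled by 1/(fs * M * U) with
#' U the mean squared taper, so that integrating the density over
#' frequency approximates the tapered segment's variance.
#'
#' @param segment numeric vector of length \code{cfg$windowLen}.
#' @param cfg a \code{\link{welchConfig}}.
#' @return list with components \code{freqs} and \code{power}.
#' @export
modifiedPeriodogram <- function(segment, cfg) {
  if (length(segment) != cfg$windowLen)
    stop("segment length must equal cfg$windowLen")
  P <- welchCore(matrix(segment, nrow = 1), cfg)
  list(freqs = welchFreqs(cfg), power = drop(P))
}

#' Welch power spectral density of one epoch channel
#'
#' Arithmetic mean of the modified periodograms of the
#' \code{L = floor((N - M)/h) + 1} overlapping tapered segments.
#'
#' @param x numeric vector, one channel of one epoch (length >= window).
#' @param cfg a \code{\link{welchConfig}}.
#' @return list with components \code{freqs} and \code{power}.
#' @export
#' @examples
#' cfg <- welchConfig(fs = 256)
#' s <- welchPsd(sin(2 * pi * 10 * (0:1279) / 256), cfg)
#' s$freqs[which.max(s$power)]  # 10 Hz
welchPsd <- function(x, cfg) {
  if (length(x) < cfg$windowLen)
    stop("epoch shorter than one Welch window")
  P <- welchCore(matrix(x, nrow = 1), cfg)
  list(freqs = welchFreqs(cfg), power = drop(P))
}

#' Number of Welch segments for a given epoch length
#' @param n epoch length in samples.
#' @param cfg a \code{\link{welchConfig}}.
#' @return integer segment count L.
#' @export
nWelchSegments <- function(n, cfg) {
  as.integer((n - cfg$windowLen) %/% cfg$hop + 1L)
}

#' Welch PSD map of a multichannel epoch
#'
#' Row c of the map is the Welch PSD of channel c; all rows share one
#' frequency axis.
#'
#' @param epoch channels x samples numeric matrix.
#' @param cfg a \code{\link{welchConfig}}.
#' @param channelLabels optional channel names (row names of
#'   \code{epoch} are used when present).
#' @return a \linkS4class{PSDMap}.
#' @export
psdMap <- function(epoch, cfg, channelLabels = NULL) {
  epoch <- as.matrix(epoch)
  if (is.null(channelLabels)) {
    channelLabels <- rownames(epoch)
    if (is.null(channelLabels))
      channelLabels <- paste0("ch", seq_len(nrow(epoch)))
  }
  P <- welchCore(epoch, cfg)
  new("PSDMap", power = P, freqs = welchFreqs(cfg),
      channelLabels = channelLabels)
}

#' Slice a PSD map to one frequency band
#'
#' Retains the frequency bins with \code{low <= f < high} (half-open
#' convention, so adjacent bands never share a bin).
#'
#' @param map a \linkS4class{PSDMap}.
#' @param band band name from \code{\link{rhythmBands}} or a numeric
#'   \code{c(low, high)} pair in Hz.
#' @return a \linkS4class{PSDMap} restricted to the band's columns.
#' @export
bandSlice <- function(map, band) {
  if (is.character(band)) {
    tab <- rhythmBands()
    row <- tab[tab$name == band, ]
    if (nrow(row) != 1L) stop("unknown band name: ", band)
    lo <- row$low; hi <- row$high
  } else {
    lo <- band[1]; hi <- band[2]
  }
  if (lo >= hi) stop("band must have low < high")
  if (lo > max(map@freqs) || hi <= min(map@freqs))
    stop("band lies outside the frequency axis")
  keep <- map@freqs >= lo & map@freqs < hi
  if (!any(keep)) stop("band contains no frequency bins")
  new("PSDMap", power = map@power[, keep, drop = FALSE],
      freqs = map@freqs[keep], channelLabels = map@channelLabels)
}

#' Four statistical moments of a vector of PSD values
#'
#' Population (1/N) moments: mean m, standard deviation d,
#' Fisher-Pearson skewness v, and non-excess Pearson kurtosis k
#' (a Gaussian sample tends to k = 3). Degenerate rule: when d = 0
#' the standardized moments are undefined and v and k are set to 0,
#' so constant bands propagate finite features.
#'
#' @param x numeric vector with at least one value.
#' @return named numeric vector \code{c(m, d, v, k)}.
#' @export
#' @examples
#' bandMoments(c(0, 0, 0, 4))
bandMoments <- function(x) {
  if (length(x) < 1L) stop("empty input")
  m <- mean(x)
  cen <- x - m
  d <- sqrt(mean(cen^2))
  if (d == 0) {
    v <- 0; k <- 0
  } else {
    v <- mean(cen^3) / d^3
    k <- mean(cen^4) / d^4
  }
  c(m = m, d = d, v = v, k = k)
}
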