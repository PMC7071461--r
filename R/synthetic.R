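#' Spectral profile of one class in a synthetic cohort
#'
#' Describes the class-conditional spectral content of the simulator:
#' relative linear power per rhythm band, a 1/f^alpha background, an
#' optional 50 Hz mains component, and the lognormal SD of the
#' per-subject multiplicative band-power jitter.
#'
#' @param classLabel "CNT" or "PNES".
#' @param bandPower named nonnegative numeric vector with entries
#'   delta, theta, alpha, beta: relative linear power of each band-limited
#'   noise component (unitless; at least one must be positive).
#' @param backgroundExponent alpha of the 1/f^alpha background (>= 0).
#' @param backgroundPower relative linear power of the background
#'   component (unitless, >= 0).
#' @param lineNoiseAmp amplitude of an added 50 Hz sinusoid (signal
#'   units; 0 disables it).
#' @param subjectSd lognormal SD (on the log scale) of the per-subject
#'   multiplicative power jitter, drawn independently per component.
#' @return A list of class \code{ClassSpectralProfile}.
#' @export
#' @examples
#' classProfile("CNT")
classProfile <- function(classLabel = c("CNT", "PNES"),
                         bandPower = c(delta = 2.0, theta = 1.0,
                                       alpha = 1.5, beta = 0.8),
                         backgroundExponent = 1.0,
                         backgroundPower = 1.0,
                         lineNoiseAmp = 0,
                         subjectSd = 0.1) {
  classLabel <- match.arg(classLabel)
  need <- c("delta", "theta", "alpha", "beta")
  if (!all(need %in% names(bandPower)))
    stop("bandPower must name delta, theta, alpha and beta")
  bandPower <- bandPower[need]
  if (any(bandPower < 0) || all(bandPower == 0))
    stop("band powers must be >= 0 with at least one > 0")
  if (subjectSd < 0) stop("subjectSd must be >= 0")
  if (backgroundPower < 0) stop("backgroundPower must be >= 0")
  structure(
    list(classLabel = classLabel, bandPower = bandPower,
         backgroundExponent = backgroundExponent,
         backgroundPower = backgroundPower,
         lineNoiseAmp = lineNoiseAmp, subjectSd = subjectSd),
    class = "ClassSpectralProfile")
}

#' Cohort geometry and seed for the synthetic generator
#'
#' Defaults emulate the acquisition this package targets: 19-channel
#' 10/20 montage, 256 Hz (post-downsampling), 120 nonoverlapping 5-s
#' epochs per subject, 10 subjects per class.
#'
#' @param nPerClass subjects per class.
#' @param nChannels channel count (10/20 labels are used for up to 19).
#' @param fs sampling rate, Hz.
#' @param epochLenS epoch length, seconds; \code{epochLenS * fs} must be
#'   an integer.
#' @param nEpochsPerSubject epochs generated per subject.
#' @param seed master seed; all subject substreams derive from it.
#' @return A list of class \code{CohortSpec}.
#' @export
cohortSpec <- function(nPerClass = 10, nChannels = 19, fs = 256,
                       epochLenS = 5, nEpochsPerSubject = 120, seed = 1) {
  if (nPerClass < 1 || nChannels < 1)
    stop("nPerClass and nChannels must be >= 1")
  L <- epochLenS * fs
  if (abs(L - round(L)) > 1e-9)
    stop("epochLenS * fs must be an integer number of samples")
  structure(
    list(nPerClass = as.integer(nPerClass),
         nChannels = as.integer(nChannels), fs = fs,
         epochLenS = epochLenS,
         nEpochsPerSubject = as.integer(nEpochsPerSubject),
         seed = as.integer(seed)),
    class = "CohortSpec")
}

# Stable per-subject substream derivation from the master seed.
# Keeps derived seeds inside the 32-bit signed range.
subjectSeed <- function(masterSeed, index) {
  as.integer((as.numeric(masterSeed) + 104729 * as.numeric(index)) %%
               2147483647)
}

#' Band-limited unit-variance Gaussian noise
#'
#' Draws white Gaussian noise and restricts its spectrum to
#' \code{[low, high)} Hz by Fourier masking, then rescales so the
#' expected variance is 1. Consumes R's global random number stream;
#' seed with \code{set.seed} for determinism.
#'
#' @param low,high band edges in Hz; must satisfy
#'   \code{0 < low < high <= fs/2}.
#' @param nSamples number of samples (0 returns an empty vector).
#' @param fs sampling rate, Hz.
#' @return Numeric vector of length \code{nSamples} with zero mean and
#'   unit expected variance, power concentrated in the band.
#' @export
#' @examples
#' set.seed(1)
#' x <- synthesizeBandNoise(8, 13, 2560, 256)
synthesizeBandNoise <- function(low, high, nSamples, fs) {
  if (!(low > 0 && low < high && high <= fs / 2))
    stop("band must satisfy 0 < low < high <= fs/2")
  n <- as.integer(nSamples)
  if (n == 0L) return(numeric(0))
  z <- rnorm(n)
  if (n == 1L) return(z)  # no spectral structure possible
  f <- (seq_len(n) - 1) * fs / n
  fmir <- pmin(f, fs - f)           # |frequency| of each DFT bin
  keep <- fmir >= low & fmir < high
  p <- mean(keep)
  if (p == 0) stop("band contains no DFT bins at this length/fs")
  Z <- fft(z)
  Z[!keep] <- 0
  Re(fft(Z, inverse = TRUE)) / n / sqrt(p)
}

# 1/f^alpha background noise over [fmin, fs/2], unit expected variance.
synthesizeBackgroundNoise <- function(exponent, nSamples, fs, fmin = 1) {
  n <- as.integer(nSamples)
  if (n == 0L) return(numeric(0))
  z <- rnorm(n)
  if (n == 1L) return(z)
  f <- (seq_len(n) - 1) * fs / n
  fmir <- pmin(f, fs - f)
  shape <- ifelse(fmir >= fmin, fmir^(-exponent / 2), 0)
  ms <- mean(shape^2)
  Z <- fft(z) * shape
  Re(fft(Z, inverse = TRUE)) / n / sqrt(ms)
}

#' Generate one synthetic subject
#'
#' Channels are independent sums of four band-limited Gaussian noises
#' (delta/theta/alpha/beta) and a 1/f^alpha background, each scaled by
#' its profile power times a per-subject lognormal jitter factor (one
#' factor per component per subject, shared across channels), plus an
#' optional 50 Hz sinusoid with random phase per channel.
#'
#' @param profile a \code{\link{classProfile}}.
#' @param spec a \code{\link{cohortSpec}}.
#' @param subjectId subject identifier string.
#' @param seed integer seed for this subject's substream.
#' @return An \linkS4class{EEGRecording} with
#'   \code{nChannels x (nEpochsPerSubject * epochLenS * fs)} samples.
#' @export
generateSubject <- function(profile, spec, subjectId, seed) {
  stopifnot(inherits(profile, "ClassSpectralProfile"),
            inherits(spec, "CohortSpec"))
  set.seed(as.integer(seed))
  n <- as.integer(round(spec$nEpochsPerSubject * spec$epochLenS * spec$fs))
  bands <- rhythmBands()
  bands <- bands[bands$name != "whole", ]
  # one lognormal jitter per component (4 bands + background), shared
  # across channels: this is what makes epochs within a subject correlated
  jit <- exp(rnorm(5, mean = 0, sd = profile$subjectSd))
  names(jit) <- c(bands$name, "background")
  X <- matrix(0, nrow = spec$nChannels, ncol = n)
  tt <- (seq_len(n) - 1) / spec$fs
  for (ch in seq_len(spec$nChannels)) {
    sig <- numeric(n)
    for (b in seq_len(nrow(bands))) {
      pw <- profile$bandPower[[bands$name[b]]] * jit[[bands$name[b]]]
      if (pw > 0)
        sig <- sig + sqrt(pw) *
          synthesizeBandNoise(bands$low[b], bands$high[b], n, spec$fs)
    }
    if (profile$backgroundPower > 0)
      sig <- sig + sqrt(profile$backgroundPower * jit[["background"]]) *
        synthesizeBackgroundNoise(profile$backgroundExponent, n, spec$fs)
    if (profile$lineNoiseAmp > 0)
      sig <- sig + profile$lineNoiseAmp * sin(2 * pi * 50 * tt +
                                              runif(1, 0, 2 * pi))
    X[ch, ] <- sig
  }
  labels <- if (spec$nChannels <= 19L) montage1020()[seq_len(spec$nChannels)]
            else paste0("ch", seq_len(spec$nChannels))
  EEGRecording(X, fs = spec$fs, channelLabels = labels,
               subjectId = subjectId, classLabel = profile$classLabel)
}

#' Generate a labelled two-class cohort
#'
#' Subject substreams are derived from \code{spec$seed} by a fixed
#' arithmetic rule, so any subject can be regenerated independently and
#' the whole cohort is a pure function of (profiles, spec).
#'
#' @param cntProfile,pnesProfile \code{\link{classProfile}}s with
#'   distinct class labels.
#' @param spec a \code{\link{cohortSpec}}.
#' @return Named list of \linkS4class{EEGRecording}s
#'   (\code{CNT01..., PNES01...}), \code{2 * nPerClass} in total.
#' @export
generateCohort <- function(cntProfile, pnesProfile, spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  if (identical(cntProfile$classLabel, pnesProfile$classLabel))
    stop("profiles must carry distinct class labels")
  profiles <- list(cntProfile, pnesProfile)
  out <- list()
  idx <- 0L
  for (pr in profiles) {
    for (i in seq_len(spec$nPerClass)) {
      idx <- idx + 1L
      sid <- sprintf("%s%02d", pr$classLabel, i)
      out[[sid]] <- generateSubject(pr, spec, sid,
                                    seed = subjectSeed(spec$seed, idx))
    }
  }
  out
}

#' Convenience constructor for matched CNT/PNES profile pairs
#'
#' Returns a CNT profile with the package's default eyes-closed resting
#' spectrum and a PNES profile identical except that alpha-band power is
#' multiplied by \code{alphaRatio}. \code{alphaRatio = 1} yields the
#' identical-profile null cohort used for chance-level calibration.
#' No claim about PNES physiology is implied; the effect direction and
#' size are free simulation parameters.
#'
#' @param alphaRatio multiplicative alpha-power effect in the PNES class.
#' @param subjectSd per-subject lognormal jitter SD for both classes.
#' @param lineNoiseAmp 50 Hz amplitude for both classes.
#' @return list with elements \code{cnt} and \code{pnes}.
#' @export
makeCohortProfiles <- function(alphaRatio = 2, subjectSd = 0.1,
                               lineNoiseAmp = 0) {
  base <- c(delta = 2.0, theta = 1.0, alpha = 1.5, beta = 0.8)
  eff <- base
  eff[["alpha"]] <- eff[["alpha"]] * alphaRatio
  list(cnt = classProfile("CNT", bandPower = base, subjectSd = subjectSd,
                          lineNoiseAmp = lineNoiseAmp),
       pnes = classProfile("PNES", bandPower = eff, subjectSd = subjectSd,
                           lineNoiseAmp = lineNoiseAmp))
}
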