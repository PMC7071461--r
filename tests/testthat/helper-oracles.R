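# Independent oracles and small fixtures shared by the test files.

# Brute-force Welch estimate: explicit segment loop + direct DFT by
# complex-exponential matrix multiplication (no call to fft or to the
# package's welch code path).
bruteWelch <- function(x, M = 256, overlapFrac = 0.5, fs = 256) {
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(M - 1)) / M)  # periodic Hamming
  U <- mean(w^2)
  h <- as.integer(round(M * (1 - overlapFrac)))
  starts <- seq.int(1L, length(x) - M + 1L, by = h)
  k <- 0:(M %/% 2)
  E <- exp(-2i * pi * outer(k, 0:(M - 1)) / M)
  dbl <- rep(2, length(k)); dbl[1] <- 1
  if (M %% 2 == 0) dbl[length(k)] <- 1
  acc <- numeric(length(k))
  for (s in starts) {
    seg <- x[s + 0:(M - 1)] * w
    acc <- acc + dbl * Mod(as.vector(E %*% seg))^2 / (fs * M * U)
  }
  acc / length(starts)
}

# Direct-formula moment oracle (population moments, non-excess kurtosis).
bruteMoments <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  d <- sqrt(m2)
  if (d == 0) c(m = m, d = 0, v = 0, k = 0)
  else c(m = m, d = d, v = m3 / d^3, k = m4 / d^4)
}

# Rank-statistic AUC oracle: Mann-Whitney U / (n+ * n-), midranks for ties.
rankAuc <- function(scores, truth) {
  pos <- truth == "PNES"
  r <- rank(scores)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

# Small synthetic feature table: nPerClass subjects per class with
# nEpochs epochs of nChannels channels, optionally with an alpha-power
# class effect. Used where a full-scale cohort is unnecessary.
smallFeatureTable <- function(nPerClass = 3, nChannels = 4, nEpochs = 10,
                              alphaRatio = 3, subjectSd = 0.05, seed = 11) {
  sp <- cohortSpec(nPerClass = nPerClass, nChannels = nChannels,
                   nEpochsPerSubject = nEpochs, seed = seed)
  pr <- makeCohortProfiles(alphaRatio = alphaRatio, subjectSd = subjectSd)
  co <- generateCohort(pr$cnt, pr$pnes, sp)
  sets <- lapply(co, function(r)
    preprocessRecording(r, maxEpochs = nEpochs))
  buildFeatureTable(sets, welchConfig(fs = sp$fs))
}

# Two well-separated Gaussian clouds as a feature table (no signal
# processing involved): distance 10 SD along every feature.
toyFeatureTable <- function(nPerClass = 4, nEpochs = 8, nFeat = 6,
                            sep = 10, seed = 3) {
  set.seed(seed)
  rows <- list(); meta <- list()
  for (cl in c("CNT", "PNES")) {
    for (s in seq_len(nPerClass)) {
      mu <- if (cl == "PNES") sep else 0
      X <- matrix(rnorm(nEpochs * nFeat, mean = mu), nrow = nFeat)
      rows[[paste0(cl, s)]] <- X
      meta[[paste0(cl, s)]] <- data.frame(
        subject_id = sprintf("%s%02d", cl, s), class_label = cl,
        epoch_index = seq_len(nEpochs))
    }
  }
  A <- do.call(cbind, rows)
  cd <- do.call(rbind, meta)
  rownames(A) <- sprintf("ch%d.alpha.m", seq_len(nFeat))
  colnames(A) <- paste(cd$subject_id, cd$epoch_index, sep = ".")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = A),
    rowData = S4Vectors::DataFrame(channel = sprintf("ch%d", seq_len(nFeat)),
                                   band = "alpha", moment = "m"),
    colData = S4Vectors::DataFrame(cd, row.names = colnames(A)))
  new("EEGFeatureTable", se)
}
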