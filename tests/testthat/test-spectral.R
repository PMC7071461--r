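test_that("welch_psd matches the brute-force segment-loop DFT oracle", {
  set.seed(42)
  cfg <- welchConfig(fs = 256)
  for (i in 1:20) {
    n <- sample(c(1280, 1280, 1500, 256, 300), 1)
    x <- rnorm(n) * runif(1, 0.5, 5)
    got <- welchPsd(x, cfg)$power
    want <- bruteWelch(x, M = 256, overlapFrac = 0.5, fs = 256)
    expect_lt(max(abs(got - want)) / max(want), 1e-10)
  }
  # overlap geometry: floor((1280 - 256)/128) + 1 = 9 segments
  expect_equal(nWelchSegments(1280, cfg), 9L)
})

test_that("the modified periodogram behaves as a one-sided density", {
  cfg <- welchConfig(fs = 256)
  # zero in, zero out
  expect_equal(modifiedPeriodogram(numeric(256), cfg)$power,
               numeric(129))
  # a 32 Hz unit tone peaks exactly at the 32 Hz bin
  tone <- sin(2 * pi * 32 * (0:255) / 256)
  s <- modifiedPeriodogram(tone, cfg)
  expect_equal(s$freqs[which.max(s$power)], 32)
  expect_error(modifiedPeriodogram(numeric(100), cfg), "length")
  # white-noise density integrates to the variance (Parseval):
  # average many segments to beat Monte-Carlo noise
  set.seed(7)
  sigma <- 1.7
  acc <- numeric(129); reps <- 400
  for (r in seq_len(reps))
    acc <- acc + modifiedPeriodogram(rnorm(256, sd = sigma), cfg)$power
  integral <- sum(acc / reps) * (256 / 256)  # df = fs/nfft = 1 Hz
  expect_equal(integral, sigma^2, tolerance = 0.05)
})

test_that("welch equals the periodogram when segments repeat without overlap", {
  set.seed(12)
  seg <- rnorm(256)
  cfg0 <- welchConfig(overlapFrac = 0, fs = 256)
  w <- welchPsd(rep(seg, 5), cfg0)$power
  p <- modifiedPeriodogram(seg, cfg0)$power
  expect_equal(w, p, tolerance = 1e-12)
})

test_that("psd maps have one row per channel and respect channel order", {
  set.seed(13)
  cfg <- welchConfig(fs = 256)
  ep <- matrix(rnorm(19 * 1280), nrow = 19,
               dimnames = list(montage1020(), NULL))
  map <- psdMap(ep, cfg)
  expect_equal(dim(psdPower(map)), c(19, 129))
  one <- psdMap(ep[3, , drop = FALSE], cfg)
  expect_equal(psdPower(one)[1, ], welchPsd(ep[3, ], cfg)$power)
  perm <- sample(19)
  permuted <- psdMap(ep[perm, ], cfg)
  expect_equal(psdPower(permuted), psdPower(map)[perm, ])
  expect_identical(channelLabels(permuted), montage1020()[perm])
})

test_that("band slicing uses half-open bins and partitions the whole band", {
  set.seed(14)
  map <- psdMap(matrix(rnorm(2 * 1280), 2), welchConfig(fs = 256))
  alpha <- bandSlice(map, "alpha")
  expect_equal(psdFreqs(alpha), 8:12)  # [8, 13) on the 1 Hz grid
  whole <- bandSlice(map, "whole")
  expect_equal(psdFreqs(whole), 1:31)
  bands <- rhythmBands()
  sub <- bands[bands$name != "whole", ]
  binSets <- lapply(seq_len(nrow(sub)), function(i)
    psdFreqs(bandSlice(map, sub$name[i])))
  expect_equal(sort(unlist(binSets)), 1:31)          # union = whole
  expect_equal(anyDuplicated(unlist(binSets)), 0L)   # disjoint
  expect_error(bandSlice(map, c(200, 300)), "outside")
})

test_that("band moments match the direct-formula oracle incl. degenerate rule", {
  expect_equal(bandMoments(c(2, 2, 2, 2)), c(m = 2, d = 0, v = 0, k = 0))
  expect_equal(bandMoments(c(1, 2, 3))[["v"]], 0)
  expect_equal(bandMoments(c(0, 0, 0, 4)), bruteMoments(c(0, 0, 0, 4)))
  expect_error(bandMoments(numeric(0)), "empty")
  set.seed(15)
  for (i in 1:25) {
    x <- rexp(sample(3:40, 1))
    expect_equal(bandMoments(x), bruteMoments(x), tolerance = 1e-12)
  }
  # cross-check the standardized moments against e1071's estimators
  x <- rexp(31)
  expect_equal(bandMoments(x)[["v"]], e1071::skewness(x, type = 1))
  expect_equal(bandMoments(x)[["k"]], e1071::kurtosis(x, type = 1) + 3)
})

test_that("epoch features follow the fixed channel-major layout", {
  set.seed(16)
  cfg <- welchConfig(fs = 256)
  ep <- matrix(rnorm(19 * 1280), 19, dimnames = list(montage1020(), NULL))
  f <- epochFeatures(ep, cfg)
  expect_length(f, 380)
  one <- epochFeatures(ep[5, , drop = FALSE], cfg)
  expect_length(one, 20)
  # per-channel independence: each channel owns its 20-column block
  expect_equal(unname(f[81:100]), unname(one))  # channel 5 block
  # duplicated channel duplicates its block exactly
  dup <- epochFeatures(ep[c(5, 5), ], cfg,
                       channelLabels = c("a", "b"))
  expect_equal(unname(dup[1:20]), unname(dup[21:40]))
  # layout round-trips: name -> (channel, band, moment) -> index
  lay <- featureLayout(montage1020())
  expect_identical(names(f), lay$name)
  i <- 137
  expect_equal(which(lay$channel == lay$channel[i] &
                     lay$band == lay$band[i] &
                     lay$moment == lay$moment[i]), i)
})

test_that("features obey PSD scale equivariance", {
  set.seed(17)
  cfg <- welchConfig(fs = 256)
  ep <- matrix(rnorm(2 * 1280), 2)
  f1 <- epochFeatures(ep, cfg)
  f3 <- epochFeatures(3 * ep, cfg)
  lay <- featureLayout(c("ch1", "ch2"))
  quad <- lay$moment %in% c("m", "d")
  expect_equal(f3[quad], 9 * f1[quad], tolerance = 1e-12)
  expect_equal(f3[!quad], f1[!quad], tolerance = 1e-10)
})

test_that("feature tables stack subjects with metadata and round-trip CSV", {
  ft <- smallFeatureTable(nPerClass = 2, nChannels = 3, nEpochs = 4)
  expect_s4_class(ft, "EEGFeatureTable")
  expect_equal(dim(ft), c(3 * 5 * 4, 2 * 2 * 4))
  cd <- SummarizedExperiment::colData(ft)
  expect_equal(as.vector(table(cd$class_label)), c(8, 8))
  expect_equal(cd$epoch_index[1:4], 1:4)
  # empty input gives an empty table with schema
  empty <- buildFeatureTable(list())
  expect_equal(dim(empty), c(0, 0))
  # CSV round trip preserves values and metadata
  tmp <- tempfile(fileext = ".csv")
  writeFeatureTable(ft, tmp)
  back <- readFeatureTable(tmp)
  expect_equal(SummarizedExperiment::assay(back),
               SummarizedExperiment::assay(ft), tolerance = 1e-12)
  expect_equal(as.data.frame(SummarizedExperiment::colData(back)),
               as.data.frame(SummarizedExperiment::colData(ft)))
})
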