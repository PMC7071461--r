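test_that("band-limited noise concentrates its power in the requested band", {
  set.seed(101)
  cfg <- welchConfig(fs = 256)
  for (band in list(c(8, 13), c(1, 4), c(13, 32))) {
    x <- synthesizeBandNoise(band[1], band[2], 25600, 256)
    s <- welchPsd(x, cfg)
    frac <- sum(s$power[s$freqs >= band[1] & s$freqs < band[2]]) /
      sum(s$power)
    expect_gte(frac, 0.8)
    expect_lt(abs(mean(x)), 0.05)
    expect_equal(var(x), 1, tolerance = 0.15)
  }
})

test_that("band noise handles edge cases: empty input, bad band, determinism", {
  expect_identical(synthesizeBandNoise(8, 13, 0, 256), numeric(0))
  expect_error(synthesizeBandNoise(8, 200, 1000, 256), "band")
  expect_error(synthesizeBandNoise(0, 13, 1000, 256), "band")
  set.seed(5); a <- synthesizeBandNoise(4, 8, 2048, 256)
  set.seed(5); b <- synthesizeBandNoise(4, 8, 2048, 256)
  expect_identical(a, b)
})

test_that("generateSubject produces the specified geometry and labels", {
  sp <- cohortSpec()  # defaults: 19 ch, 256 Hz, 120 x 5 s epochs
  expect_equal(sp$nEpochsPerSubject * sp$epochLenS * sp$fs, 153600)
  sp2 <- cohortSpec(nPerClass = 1, nChannels = 3, nEpochsPerSubject = 4)
  rec <- generateSubject(classProfile("CNT"), sp2, "CNT01", 9)
  expect_s4_class(rec, "EEGRecording")
  expect_equal(dim(eegData(rec)), c(3, 4 * 5 * 256))
  expect_identical(channelLabels(rec), montage1020()[1:3])
  expect_identical(classLabel(rec), "CNT")
})

test_that("line noise adds 50 Hz power relative to a clean profile", {
  sp <- cohortSpec(nPerClass = 1, nChannels = 1, nEpochsPerSubject = 4)
  clean <- classProfile("CNT", lineNoiseAmp = 0, subjectSd = 0)
  mains <- classProfile("CNT", lineNoiseAmp = 2, subjectSd = 0)
  cfg <- welchConfig(fs = 256)
  p50 <- function(rec) {
    s <- welchPsd(eegData(rec)[1, ], cfg)
    s$power[s$freqs == 50]
  }
  expect_gt(p50(generateSubject(mains, sp, "a", 3)),
            5 * p50(generateSubject(clean, sp, "a", 3)))
})

test_that("with no jitter, same-class subjects share band-power expectations", {
  sp <- cohortSpec(nPerClass = 1, nChannels = 2, nEpochsPerSubject = 20)
  prof <- classProfile("CNT", subjectSd = 0, lineNoiseAmp = 0)
  cfg <- welchConfig(fs = 256)
  bandMean <- function(rec) {
    s <- welchPsd(eegData(rec)[1, ], cfg)
    mean(s$power[s$freqs >= 8 & s$freqs < 13])
  }
  a <- bandMean(generateSubject(prof, sp, "s1", 21))
  b <- bandMean(generateSubject(prof, sp, "s2", 22))
  expect_equal(a, b, tolerance = 0.2)  # Monte-Carlo error only
})

test_that("cohorts are deterministic functions of (profiles, spec, seed)", {
  sp <- cohortSpec(nPerClass = 2, nChannels = 2, nEpochsPerSubject = 2,
                   seed = 77)
  pr <- makeCohortProfiles()
  a <- generateCohort(pr$cnt, pr$pnes, sp)
  b <- generateCohort(pr$cnt, pr$pnes, sp)
  expect_equal(length(a), 4)
  expect_identical(names(a), c("CNT01", "CNT02", "PNES01", "PNES02"))
  expect_identical(lapply(a, eegData), lapply(b, eegData))
  expect_error(generateCohort(pr$cnt, pr$cnt, sp), "distinct")
  one <- generateCohort(pr$cnt, pr$pnes,
                        cohortSpec(nPerClass = 1, nChannels = 1,
                                   nEpochsPerSubject = 1))
  expect_equal(length(one), 2)
})

test_that("a single-band power effect moves that band's mean-PSD feature", {
  # PNES differs from CNT only by doubled alpha power; the alpha-band
  # mean moment must shift upward (one-sided test over epochs).
  sp <- cohortSpec(nPerClass = 1, nChannels = 2, nEpochsPerSubject = 120,
                   seed = 31)
  pr <- makeCohortProfiles(alphaRatio = 2, subjectSd = 0)
  co <- generateCohort(pr$cnt, pr$pnes, sp)
  sets <- lapply(co, function(r) preprocessRecording(r, maxEpochs = 120))
  ft <- buildFeatureTable(sets, welchConfig(fs = 256))
  rd <- SummarizedExperiment::rowData(ft)
  cd <- SummarizedExperiment::colData(ft)
  alphaM <- SummarizedExperiment::assay(ft)[
    rd$band == "alpha" & rd$moment == "m" & rd$channel == "Fp1", ]
  tt <- t.test(alphaM[cd$class_label == "PNES"],
               alphaM[cd$class_label == "CNT"], alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("profile validation rejects degenerate inputs", {
  expect_error(classProfile("CNT", bandPower = c(delta = 0, theta = 0,
                                                 alpha = 0, beta = 0)))
  expect_error(classProfile("CNT", subjectSd = -1))
  expect_error(cohortSpec(nPerClass = 0))
  expect_error(cohortSpec(epochLenS = 1/3, fs = 256))
})
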