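#' Default end-to-end pipeline configuration
#'
#' One nested list holding every stage's parameters, with the package's
#' documented defaults: 19-channel 256 Hz cohorts of 10 subjects per
#' class with 120 five-second epochs; 1-70 Hz order-3 Butterworth
#' bandpass plus 50 Hz notch (Q = 30); 256-sample Hamming Welch
#' segments with 50\% overlap; the five rhythm bands; RBF-SVM
#' (gamma = 0.01, C = 1), LDA and Gaussian naive Bayes under
#' subject-level random-split (7 training subjects per class) and
#' leave-one-subject-out validation. Fully serializable: a run is
#' reproducible from the config alone.
#'
#' @param seed master seed recorded in the config.
#' @return nested list of class \code{PipelineConfig}.
#' @export
defaultPipelineConfig <- function(seed = 1) {
  structure(list(
    cohort = list(n_per_class = 10, n_channels = 19, fs = 256,
                  epoch_len_s = 5, n_epochs = 120, seed = seed,
                  format = "edf",
                  profiles = list(
                    alpha_ratio = 2, subject_sd = 0.1,
                    line_noise_amp = 0)),
    filter = list(bp_low = 1, bp_high = 70, order = 3,
                  notch_freq = 50, notch_q = 30),
    welch = list(window_len = 256, overlap_frac = 0.5,
                 window_kind = "hamming", nfft = 256),
    classifiers = list(
      svm = list(kernel = "radial", degree = 3, gamma = 0.01,
                 coef0 = 0, cost = 1, epsilon = 0.1),
      lda = list(), nb = list()),
    evaluation = list(schemes = c("random_split", "loo"),
                      train_per_class = 7, n_random_splits = 1,
                      scale = TRUE, seed = seed)
  ), class = "PipelineConfig")
}

#' Read / write a pipeline configuration (YAML or JSON)
#'
#' @param path file ending in .yaml/.yml or .json.
#' @return \code{readPipelineConfig} returns a \code{PipelineConfig};
#'   \code{writePipelineConfig} returns \code{path} invisibly.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  base <- unclass(defaultPipelineConfig())
  merged <- utils::modifyList(base, cfg)
  structure(merged, class = "PipelineConfig")
}

#' @rdname readPipelineConfig
#' @param config a \code{PipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
  cfg <- unclass(config)
  if (grepl("\\.json$", path))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  else yaml::write_yaml(cfg, path)
  invisible(path)
}

configProfiles <- function(config) {
  p <- config$cohort$profiles
  makeCohortProfiles(alphaRatio = p$alpha_ratio,
                     subjectSd = p$subject_sd,
                     lineNoiseAmp = p$line_noise_amp)
}

configCohortSpec <- function(config) {
  co <- config$cohort
  cohortSpec(nPerClass = co$n_per_class, nChannels = co$n_channels,
             fs = co$fs, epochLenS = co$epoch_len_s,
             nEpochsPerSubject = co$n_epochs, seed = co$seed)
}

configFilterSpec <- function(config) {
  f <- config$filter
  filterSpec(bpLow = f$bp_low, bpHigh = f$bp_high, order = f$order,
             notchFreq = f$notch_freq, notchQ = f$notch_q)
}

configWelch <- function(config, fs) {
  w <- config$welch
  welchConfig(windowLen = w$window_len, overlapFrac = w$overlap_frac,
              windowKind = w$window_kind, nfft = w$nfft, fs = fs)
}

#' Simulate a cohort and write it to disk
#'
#' Generates the configured synthetic cohort and writes recordings plus
#' a JSON manifest to \code{outDir}.
#'
#' @param config a \code{PipelineConfig}.
#' @param outDir output directory.
#' @param verbose print stage-by-stage shapes.
#' @return the manifest path, invisibly.
#' @export
cmdSimulate <- function(config = defaultPipelineConfig(), outDir,
                        verbose = TRUE) {
  if (config$cohort$n_per_class < 1) stop("n_per_class must be >= 1")
  profiles <- configProfiles(config)
  spec <- configCohortSpec(config)
  cohort <- generateCohort(profiles$cnt, profiles$pnes, spec)
  if (verbose)
    message(sprintf("simulate: %d recordings (%d per class), %d ch x %d samples @ %g Hz, seed %d",
                    length(cohort), spec$nPerClass, spec$nChannels,
                    spec$nEpochsPerSubject * spec$epochLenS * spec$fs,
                    spec$fs, spec$seed))
  writeCohort(cohort, outDir, format = config$cohort$format)
}

#' Extract the feature table for a cohort on disk
#'
#' Reads every manifest entry, preprocesses it (filter, optional
#' artifact sidecar \code{<subject>.artifacts.json} holding a list of
#' [start_s, end_s] pairs, epoching), extracts Welch band-moment
#' features, and writes one feature CSV.
#'
#' @param manifestPath cohort manifest from \code{\link{cmdSimulate}} /
#'   \code{\link{writeCohort}}.
#' @param config a \code{PipelineConfig}.
#' @param outPath output CSV path.
#' @param verbose print per-subject feature counts.
#' @return the \linkS4class{EEGFeatureTable}, invisibly.
#' @export
cmdExtract <- function(manifestPath, config = defaultPipelineConfig(),
                       outPath = file.path(dirname(manifestPath),
                                           "features.csv"),
                       verbose = TRUE) {
  cohort <- readCohort(manifestPath)
  fspec <- configFilterSpec(config)
  sets <- list()
  for (sid in names(cohort)) {
    rec <- cohort[[sid]]
    side <- file.path(dirname(manifestPath),
                      paste0(sid, ".artifacts.json"))
    arts <- if (file.exists(side)) {
      a <- jsonlite::read_json(side, simplifyVector = TRUE)
      matrix(unlist(a), ncol = 2, byrow = !is.matrix(a))
    } else matrix(numeric(0), ncol = 2)
    es <- preprocessRecording(rec, targetFs = config$cohort$fs,
                              fspec = fspec,
                              artifacts = arts,
                              epochLenS = config$cohort$epoch_len_s,
                              maxEpochs = config$cohort$n_epochs)
    sets[[sid]] <- es
    if (verbose) {
      d <- dim(es@epochs)
      message(sprintf("extract: %s -> %d epochs x %d ch x %d samples (%d features)",
                      sid, d[1], d[2], d[3], d[1] * d[2] * 20L))
    }
  }
  cfg <- configWelch(config, fs = config$cohort$fs)
  ft <- buildFeatureTable(sets, cfg)
  writeFeatureTable(ft, outPath)
  if (verbose)
    message(sprintf("extract: feature table %d epochs x %d features -> %s",
                    ncol(ft), nrow(ft), outPath))
  invisible(ft)
}

#' Evaluate classifiers on a feature table file
#'
#' Loads the feature CSV, runs the configured classifier x scheme grid,
#' writes JSON/CSV reports plus per-split ROC CSVs, and prints a
#' per-class precision / recall / F1 block and mean +/- SD summary per
#' classifier and scheme.
#'
#' @param featurePath feature CSV from \code{\link{cmdExtract}}.
#' @param config a \code{PipelineConfig}.
#' @param outDir report output directory.
#' @param verbose print the console summary.
#' @return the \linkS4class{EvalReport}, invisibly.
#' @export
cmdEvaluate <- function(featurePath, config = defaultPipelineConfig(),
                        outDir = dirname(featurePath), verbose = TRUE) {
  ft <- readFeatureTable(featurePath)
  cls <- unique(SummarizedExperiment::colData(ft)$class_label)
  if (length(cls) < 2L)
    stop("feature table must contain both classes; found: ",
         paste(cls, collapse = ", "))
  ev <- config$evaluation
  svm <- config$classifiers$svm
  specs <- list(classifierSpec("SVM", gamma = svm$gamma, cost = svm$cost,
                               coef0 = svm$coef0, degree = svm$degree),
                classifierSpec("LDA"), classifierSpec("NB"))
  report <- evaluateCohort(ft, classifiers = specs,
                           schemes = ev$schemes, seed = ev$seed,
                           nRandomSplits = ev$n_random_splits,
                           trainPerClass = ev$train_per_class,
                           scale = ev$scale)
  writeEvalReport(report, outDir)
  if (verbose) show(report)
  invisible(report)
}

#' Run the full pipeline in memory
#'
#' simulate -> preprocess + extract -> evaluate, without touching disk.
#'
#' @param config a \code{PipelineConfig}.
#' @param verbose print progress.
#' @return list with elements \code{features}
#'   (\linkS4class{EEGFeatureTable}) and \code{report}
#'   (\linkS4class{EvalReport}).
#' @export
runPipeline <- function(config = defaultPipelineConfig(), verbose = FALSE) {
  profiles <- configProfiles(config)
  spec <- configCohortSpec(config)
  cohort <- generateCohort(profiles$cnt, profiles$pnes, spec)
  fspec <- configFilterSpec(config)
  sets <- lapply(cohort, function(rec)
    preprocessRecording(rec, fspec = fspec,
                        epochLenS = spec$epochLenS,
                        maxEpochs = spec$nEpochsPerSubject))
  cfg <- configWelch(config, fs = spec$fs)
  ft <- buildFeatureTable(sets, cfg)
  if (verbose)
    message(sprintf("pipeline: feature table %d epochs x %d features",
                    ncol(ft), nrow(ft)))
  ev <- config$evaluation
  report <- evaluateCohort(ft, schemes = ev$schemes, seed = ev$seed,
                           nRandomSplits = ev$n_random_splits,
                           trainPerClass = ev$train_per_class,
                           scale = ev$scale)
  list(features = ft, report = report)
}
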