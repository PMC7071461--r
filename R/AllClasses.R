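#' @import methods
#' @importFrom stats fft mvfft rnorm runif sd var approx predict setNames
#' @importFrom utils head tail
NULL

#' The 19-electrode 10/20 montage used throughout the package
#'
#' Standard international 10/20 scalp positions, referenced to G2
#' (between Fz and Cz) at acquisition time.
#'
#' @return Character vector of 19 channel labels.
#' @export
#' @examples
#' montage1020()
montage1020 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz")
}

#' EEGRecording: a continuous multichannel EEG signal
#'
#' Holds a channels x samples numeric matrix (microvolts by convention),
#' its sampling rate, ordered channel labels, and optional subject
#' identity and class label. `segStarts` records the start sample of
#' each clean segment after artifact masking, so that downstream
#' epoching never straddles a cut; an unmasked recording has a single
#' segment starting at sample 1.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector, one unique label per channel.
#' @slot subjectId character scalar.
#' @slot classLabel character scalar, "CNT", "PNES" or NA.
#' @slot segStarts integer vector of clean-segment start samples
#'   (1-based, strictly increasing, first element 1).
#'
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelLabels = "character",
    subjectId = "character",
    classLabel = "character",
    segStarts = "integer"
  ),
  prototype(
    fs = 256, subjectId = NA_character_, classLabel = NA_character_,
    segStarts = 1L
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (nrow(object@data) < 1L || ncol(object@data) < 1L)
    msg <- c(msg, "data must have at least one channel and one sample")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a positive scalar")
  if (length(object@channelLabels) != nrow(object@data))
    msg <- c(msg, "channelLabels length must equal the channel count")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channelLabels must be unique")
  if (length(object@segStarts) < 1L || object@segStarts[1L] != 1L ||
      is.unsorted(object@segStarts, strictly = TRUE) ||
      any(object@segStarts > ncol(object@data)))
    msg <- c(msg, "segStarts must be strictly increasing, start at 1 and lie within the data")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate (Hz).
#' @param channelLabels channel names; defaults to the first
#'   \code{nrow(data)} labels of \code{\link{montage1020}} when that many
#'   exist, otherwise "ch1", "ch2", ...
#' @param subjectId,classLabel optional metadata.
#' @param segStarts clean-segment start samples (see class docs).
#' @return An \linkS4class{EEGRecording}.
#' @export
EEGRecording <- function(data, fs, channelLabels = NULL,
                         subjectId = NA_character_,
                         classLabel = NA_character_,
                         segStarts = 1L) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  dimnames(data) <- NULL  # labels live in channelLabels
  if (is.null(channelLabels)) {
    channelLabels <- if (nrow(data) <= 19L) montage1020()[seq_len(nrow(data))]
                     else paste0("ch", seq_len(nrow(data)))
  }
  new("EEGRecording", data = data, fs = as.numeric(fs),
      channelLabels = as.character(channelLabels),
      subjectId = as.character(subjectId),
      classLabel = as.character(classLabel),
      segStarts = as.integer(segStarts))
}

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
  cat(sprintf("  subject: %s   class: %s   segments: %d\n",
              object@subjectId, object@classLabel, length(object@segStarts)))
  cat("  channels:", paste(head(object@channelLabels, 8), collapse = ", "),
      if (length(object@channelLabels) > 8) "..." else "", "\n")
})

#' EpochSet: a per-subject stack of fixed-length epochs
#'
#' Nonoverlapping, contiguous epochs cut from one recording, stored as
#' an n_epochs x channels x samples array.
#'
#' @slot epochs 3-d numeric array (epoch, channel, sample).
#' @slot fs sampling rate in Hz.
#' @slot epochLenS epoch length in seconds.
#' @slot channelLabels channel names.
#' @slot subjectId,classLabel subject metadata.
#' @export
setClass("EpochSet",
  representation(
    epochs = "array", fs = "numeric", epochLenS = "numeric",
    channelLabels = "character", subjectId = "character",
    classLabel = "character"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character(0)
  d <- dim(object@epochs)
  if (length(d) != 3L) msg <- c(msg, "epochs must be a 3-d array")
  else {
    if (d[3L] != round(object@epochLenS * object@fs))
      msg <- c(msg, "epoch sample count must equal epochLenS * fs")
    if (length(object@channelLabels) != d[2L])
      msg <- c(msg, "channelLabels length must equal the channel dimension")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              d[1], d[2], d[3], object@epochLenS, object@fs))
  cat(sprintf("  subject: %s   class: %s\n", object@subjectId, object@classLabel))
})

#' PSDMap: per-epoch channels x frequency-bins Welch power map
#'
#' @slot power channels x bins nonnegative matrix (signal-units^2/Hz).
#' @slot freqs one-sided frequency axis (Hz), strictly increasing.
#' @slot channelLabels channel names, one per row.
#' @export
setClass("PSDMap",
  representation(power = "matrix", freqs = "numeric",
                 channelLabels = "character")
)

setValidity("PSDMap", function(object) {
  msg <- character(0)
  if (ncol(object@power) != length(object@freqs))
    msg <- c(msg, "power column count must match freqs length")
  if (nrow(object@power) != length(object@channelLabels))
    msg <- c(msg, "power row count must match channelLabels length")
  if (is.unsorted(object@freqs, strictly = TRUE))
    msg <- c(msg, "freqs must be strictly increasing")
  if (any(!is.finite(object@power)) || any(object@power < 0))
    msg <- c(msg, "power values must be finite and nonnegative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PSDMap", function(object) {
  cat(sprintf("PSDMap: %d channels x %d frequency bins [%g, %g] Hz\n",
              nrow(object@power), ncol(object@power),
              min(object@freqs), max(object@freqs)))
})

#' EEGFeatureTable: epochs-by-feature table as a SummarizedExperiment
#'
#' Rows are features (channel x band x moment, in fixed channel-major
#' order), columns are epochs. \code{rowData} carries the (channel,
#' band, moment) decomposition of each feature; \code{colData} carries
#' \code{subject_id}, \code{class_label} and \code{epoch_index}.
#'
#' @import SummarizedExperiment
#' @export
setClass("EEGFeatureTable", contains = "SummarizedExperiment")

setValidity("EEGFeatureTable", function(object) {
  msg <- character(0)
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject_id", "class_label", "epoch_index")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain", paste(need, collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("channel", "band", "moment") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain channel, band, moment")
  if (length(SummarizedExperiment::assayNames(object)) &&
      anyNA(SummarizedExperiment::assay(object)))
    msg <- c(msg, "feature values must not be missing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EEGFeatureTable", function(object) {
  cat(sprintf("EEGFeatureTable: %d features x %d epochs\n",
              nrow(object), ncol(object)))
  cd <- SummarizedExperiment::colData(object)
  if (nrow(cd)) {
    cat(sprintf("  subjects: %d   classes: %s\n",
                length(unique(cd$subject_id)),
                paste(names(table(cd$class_label)),
                      table(cd$class_label), sep = "=", collapse = ", ")))
  }
})

#' EvalReport: classification results per classifier x scheme x split
#'
#' @slot results one row per classifier x scheme x split, with confusion
#'   counts, metrics and AUC.
#' @slot roc per-entry ROC point lists (FPR/TPR), keyed
#'   "classifier.scheme.split".
#' @slot summary mean and SD of each metric per classifier x scheme.
#' @export
setClass("EvalReport",
  representation(results = "data.frame", roc = "list",
                 summary = "data.frame")
)

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport:", nrow(object@results), "split evaluations\n\n")
  s <- object@summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("%-4s %-12s  ACC %.2f +/- %.3f  PR %.2f +/- %.3f  RC %.2f +/- %.3f\n",
                s$classifier[i], s$scheme[i],
                s$accuracy_mean[i], s$accuracy_sd[i],
                s$precision_mean[i], s$precision_sd[i],
                s$recall_mean[i], s$recall_sd[i]))
  }
})

# ---- accessors ----

#' @rdname EEGRecording-class
#' @param object an EEGRecording or EpochSet.
#' @export
setGeneric("eegData", function(object) standardGeneric("eegData"))
#' @rdname EEGRecording-class
#' @export
setMethod("eegData", "EEGRecording", function(object) object@data)

#' @rdname EEGRecording-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@fs)
#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@fs)

#' @rdname EEGRecording-class
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname EEGRecording-class
#' @export
setMethod("channelLabels", "EEGRecording", function(object) object@channelLabels)
#' @rdname EEGRecording-class
#' @export
setMethod("channelLabels", "EpochSet", function(object) object@channelLabels)
#' @rdname EEGRecording-class
#' @export
setMethod("channelLabels", "PSDMap", function(object) object@channelLabels)

#' @rdname EEGRecording-class
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname EEGRecording-class
#' @export
setMethod("subjectId", "EEGRecording", function(object) object@subjectId)
#' @rdname EEGRecording-class
#' @export
setMethod("subjectId", "EpochSet", function(object) object@subjectId)

#' @rdname EEGRecording-class
#' @export
setGeneric("classLabel", function(object) standardGeneric("classLabel"))
#' @rdname EEGRecording-class
#' @export
setMethod("classLabel", "EEGRecording", function(object) object@classLabel)
#' @rdname EEGRecording-class
#' @export
setMethod("classLabel", "EpochSet", function(object) object@classLabel)

#' @rdname EpochSet-class
#' @param object an EpochSet.
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))
#' @rdname EpochSet-class
#' @export
setMethod("nEpochs", "EpochSet", function(object) dim(object@epochs)[1L])

#' @rdname EpochSet-class
#' @export
setGeneric("epochArray", function(object) standardGeneric("epochArray"))
#' @rdname EpochSet-class
#' @export
setMethod("epochArray", "EpochSet", function(object) object@epochs)

#' @rdname PSDMap-class
#' @param object a PSDMap or Spectrum-like object.
#' @export
setGeneric("psdPower", function(object) standardGeneric("psdPower"))
#' @rdname PSDMap-class
#' @export
setMethod("psdPower", "PSDMap", function(object) object@power)

#' @rdname PSDMap-class
#' @export
setGeneric("psdFreqs", function(object) standardGeneric("psdFreqs"))
#' @rdname PSDMap-class
#' @export
setMethod("psdFreqs", "PSDMap", function(object) object@freqs)

#' Extract the feature matrix from an EEGFeatureTable
#'
#' @param object an \linkS4class{EEGFeatureTable}.
#' @return numeric matrix, epochs x features (the transpose of the
#'   stored assay), with feature names as column names.
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "EEGFeatureTable", function(object) {
  t(SummarizedExperiment::assay(object, "features"))
})

#' @rdname EvalReport-class
#' @param object an EvalReport.
#' @export
setGeneric("evalResults", function(object) standardGeneric("evalResults"))
#' @rdname EvalReport-class
#' @export
setMethod("evalResults", "EvalReport", function(object) object@results)

#' @rdname EvalReport-class
#' @export
setGeneric("evalSummary", function(object) standardGeneric("evalSummary"))
#' @rdname EvalReport-class
#' @export
setMethod("evalSummary", "EvalReport", function(object) object@summary)

#' @rdname EvalReport-class
#' @export
setGeneric("evalRoc", function(object) standardGeneric("evalRoc"))
#' @rdname EvalReport-class
#' @export
setMethod("evalRoc", "EvalReport", function(object) object@roc)
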