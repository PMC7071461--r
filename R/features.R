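momentNames <- function() c("m", "d", "v", "k")

#' Feature column naming and index mapping
#'
#' Features are laid out channel-major: for each channel, bands in the
#' order delta, theta, alpha, beta, whole; within each band the moments
#' m, d, v, k. With 19 channels this yields 19 x 5 x 4 = 380 columns.
#'
#' @param channels character vector of channel labels.
#' @param bands band table, default \code{\link{rhythmBands}}.
#' @return data.frame with columns name, channel, band, moment (one row
#'   per feature, in storage order).
#' @export
#' @examples
#' head(featureLayout(montage1020()))
featureLayout <- function(channels, bands = rhythmBands()) {
  grid <- expand.grid(moment = momentNames(), band = bands$name,
                      channel = channels, stringsAsFactors = FALSE)
  grid <- grid[, c("channel", "band", "moment")]
  grid$name <- paste(grid$channel, grid$band, grid$moment, sep = ".")
  grid[, c("name", "channel", "band", "moment")]
}

#' Feature row of one multichannel epoch
#'
#' Computes the Welch PSD map of the epoch, slices it into the given
#' bands, and extracts the four moments per channel per band, in the
#' fixed channel-major order of \code{\link{featureLayout}}. One channel
#' contributes 5 x 4 = 20 values; the default 19-channel montage gives
#' 380.
#'
#' @param epoch channels x samples numeric matrix.
#' @param cfg a \code{\link{welchConfig}}.
#' @param bands band table, default \code{\link{rhythmBands}}.
#' @param channelLabels optional channel names.
#' @return named numeric vector of length
#'   \code{nchannels * nrow(bands) * 4}.
#' @export
epochFeatures <- function(epoch, cfg, bands = rhythmBands(),
                          channelLabels = NULL) {
  map <- psdMap(epoch, cfg, channelLabels = channelLabels)
  nC <- nrow(map@power)
  nB <- nrow(bands)
  out <- numeric(nC * nB * 4L)
  pos <- 0L
  # slice once per band, then moments per channel
  for (b in seq_len(nB)) {
    sub <- bandSlice(map, c(bands$low[b], bands$high[b]))
    for (ch in seq_len(nC)) {
      out[(ch - 1L) * nB * 4L + (b - 1L) * 4L + 1:4] <-
        bandMoments(sub@power[ch, ])
    }
    pos <- pos + 1L
  }
  names(out) <- featureLayout(map@channelLabels, bands)$name
  out
}

#' Build the epochs-by-feature table for a cohort
#'
#' Stacks the per-epoch feature rows of every subject, ordered by
#' (subject, epoch index), into an \linkS4class{EEGFeatureTable}
#' (features x epochs SummarizedExperiment).
#'
#' @param epochSets list of \linkS4class{EpochSet}s with a common
#'   channel layout.
#' @param cfg a \code{\link{welchConfig}}; its \code{fs} must match the
#'   epoch sets.
#' @param bands band table, default \code{\link{rhythmBands}}.
#' @return an \linkS4class{EEGFeatureTable}.
#' @export
buildFeatureTable <- function(epochSets, cfg = NULL, bands = rhythmBands()) {
  if (length(epochSets) == 0L) {
    lay <- featureLayout(character(0), bands)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(features = matrix(numeric(0), nrow = 0, ncol = 0)),
      rowData = S4Vectors::DataFrame(channel = character(0),
                                     band = character(0),
                                     moment = character(0)),
      colData = S4Vectors::DataFrame(subject_id = character(0),
                                     class_label = character(0),
                                     epoch_index = integer(0)))
    return(new("EEGFeatureTable", se))
  }
  labs <- channelLabels(epochSets[[1L]])
  for (es in epochSets) {
    if (!identical(channelLabels(es), labs))
      stop("all subjects must share one channel layout")
  }
  if (is.null(cfg)) cfg <- welchConfig(fs = samplingRate(epochSets[[1L]]))
  lay <- featureLayout(labs, bands)
  blocks <- vector("list", length(epochSets))
  meta <- vector("list", length(epochSets))
  for (s in seq_along(epochSets)) {
    es <- epochSets[[s]]
    ne <- nEpochs(es)
    M <- matrix(NA_real_, nrow = nrow(lay), ncol = ne)
    for (e in seq_len(ne)) {
      M[, e] <- epochFeatures(es@epochs[e, , , drop = TRUE], cfg,
                              bands = bands, channelLabels = labs)
    }
    blocks[[s]] <- M
    meta[[s]] <- data.frame(subject_id = rep(subjectId(es), ne),
                            class_label = rep(classLabel(es), ne),
                            epoch_index = seq_len(ne),
                            stringsAsFactors = FALSE)
  }
  A <- do.call(cbind, blocks)
  cd <- do.call(rbind, meta)
  rownames(A) <- lay$name
  colnames(A) <- paste(cd$subject_id, cd$epoch_index, sep = ".")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = A),
    rowData = S4Vectors::DataFrame(channel = lay$channel, band = lay$band,
                                   moment = lay$moment, row.names = lay$name),
    colData = S4Vectors::DataFrame(cd, row.names = colnames(A)))
  new("EEGFeatureTable", se)
}

#' Write / read a feature table as CSV
#'
#' The CSV holds one row per epoch: metadata columns
#' \code{subject_id, class_label, epoch_index} followed by the feature
#' columns in storage order.
#'
#' @param ft an \linkS4class{EEGFeatureTable}.
#' @param path output file.
#' @return \code{writeFeatureTable} returns \code{path} invisibly;
#'   \code{readFeatureTable} returns an \linkS4class{EEGFeatureTable}.
#' @export
writeFeatureTable <- function(ft, path) {
  X <- featureMatrix(ft)
  cd <- as.data.frame(SummarizedExperiment::colData(ft))
  out <- cbind(cd[, c("subject_id", "class_label", "epoch_index")],
               as.data.frame(X))
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  metaCols <- c("subject_id", "class_label", "epoch_index")
  if (!all(metaCols %in% colnames(dt)))
    stop("feature CSV must contain subject_id, class_label, epoch_index")
  featCols <- setdiff(colnames(dt), metaCols)
  A <- t(as.matrix(dt[, featCols, drop = FALSE]))
  parts <- strsplit(featCols, ".", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("feature column names must be channel.band.moment")
  rd <- S4Vectors::DataFrame(
    channel = vapply(parts, `[`, "", 1L),
    band = vapply(parts, `[`, "", 2L),
    moment = vapply(parts, `[`, "", 3L),
    row.names = featCols)
  cd <- S4Vectors::DataFrame(
    subject_id = as.character(dt$subject_id),
    class_label = as.character(dt$class_label),
    epoch_index = as.integer(dt$epoch_index),
    row.names = paste(dt$subject_id, dt$epoch_index, sep = "."))
  colnames(A) <- rownames(cd)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = A), rowData = rd, colData = cd)
  new("EEGFeatureTable", se)
}
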