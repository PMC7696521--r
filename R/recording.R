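#' Construct an EEG recording
#'
#' A recording holds a samples-by-channels matrix together with its sampling
#' rate and metadata.  Column names carry the channel labels.
#'
#' @param samples Numeric matrix, one column per channel, one row per sample.
#'   Column names are the channel labels.
#' @param rate Sampling frequency in Hz (> 0; 256 for the data this pipeline
#'   targets).
#' @param group_label Binary class label, `"mdd"` or `"control"`, or `NA`.
#' @param condition Recording condition, `"EC"` (eyes closed), `"EO"`
#'   (eyes open) or `NA`.
#' @param subject_id Opaque subject identifier.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate,
                          group_label = NA_character_,
                          condition = NA_character_,
                          subject_id = NA_character_) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || nrow(samples) < 1L) {
    stop("samples must be a non-empty numeric matrix", call. = FALSE)
  }
  if (is.null(colnames(samples))) {
    stop("samples must have channel labels as column names", call. = FALSE)
  }
  if (anyDuplicated(colnames(samples)) > 0) {
    stop("channel labels must be unique", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number", call. = FALSE)
  }
  if (!is.na(group_label) && !group_label %in% c("mdd", "control")) {
    stop('group_label must be "mdd", "control" or NA', call. = FALSE)
  }
  structure(
    list(samples = samples, rate = rate, group_label = group_label,
         condition = condition, subject_id = subject_id),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    ncol(x$samples), nrow(x$samples), x$rate, nrow(x$samples) / x$rate))
  cat("  channels:", paste(colnames(x$samples), collapse = ", "), "\n")
  cat(sprintf("  subject: %s  group: %s  condition: %s\n",
              x$subject_id, x$group_label, x$condition))
  invisible(x)
}

#' Channel labels of a recording
#' @param recording An [eeg_recording()].
#' @return Character vector of channel labels in storage order.
#' @export
channel_labels <- function(recording) colnames(recording$samples)

#' Min-max normalize each channel to \[0, 1\]
#'
#' Each channel is independently mapped to \[0, 1\] via
#' `(x - min) / (max - min)`, computed over the full recording (before any
#' epoching), so that every channel has the same amplitude scale.  Relative
#' band power is invariant to per-channel affine rescaling with positive
#' slope, so this step cannot change downstream asymmetry features; it exists
#' so that raw amplitudes are comparable across channels and subjects.
#'
#' @param recording An [eeg_recording()].
#' @return The recording with every channel in \[0, 1\].
#' @export
#' @examples
#' rec <- eeg_recording(matrix(c(2, 4, 6), 3, 1,
#'                             dimnames = list(NULL, "Fp1")), rate = 256)
#' minmax_normalize(rec)$samples[, 1]
minmax_normalize <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$samples
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  flat <- maxs <= mins
  if (any(flat)) {
    stop("constant channel(s), min-max normalization undefined: ",
         paste(colnames(x)[flat], collapse = ", "), call. = FALSE)
  }
  recording$samples <- sweep(sweep(x, 2L, mins, "-"), 2L, maxs - mins, "/")
  recording
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts the recording into consecutive non-overlapping epochs of `duration`
#' seconds starting at time zero.  A trailing partial segment is discarded.
#' Epochs are returned as a single array with a manifest so downstream code
#' can process them in bulk.
#'
#' @param recording An [eeg_recording()].
#' @param duration Epoch length in seconds; `duration * rate` must be a
#'   positive integer (4 s = 1024 samples at 256 Hz).
#' @return An object of class `epoch_set`: list with `samples` (array,
#'   sample x channel x epoch), `rate`, `channel_labels`, and `manifest`
#'   (data frame with `subject_id`, `group_label`, `condition`,
#'   `epoch_index`, indexed from 0).
#' @export
segment_epochs <- function(recording, duration = 4) {
  stopifnot(inherits(recording, "eeg_recording"))
  n_per <- duration * recording$rate
  if (!isTRUE(all.equal(n_per, round(n_per))) || n_per <= 0) {
    stop("duration * rate must be a positive integer", call. = FALSE)
  }
  n_per <- as.integer(round(n_per))
  n_total <- nrow(recording$samples)
  n_epochs <- n_total %/% n_per
  if (n_epochs == 0L) {
    warning("recording shorter than one epoch; returning an empty epoch set",
            call. = FALSE)
  }
  used <- recording$samples[seq_len(n_epochs * n_per), , drop = FALSE]
  # samples are channel-major; reshape to (sample, epoch, channel) first,
  # then reorder to (sample, channel, epoch)
  arr <- aperm(array(used, dim = c(n_per, n_epochs, ncol(used))),
               c(1L, 3L, 2L))
  manifest <- data.frame(
    subject_id = rep(recording$subject_id, n_epochs),
    group_label = rep(recording$group_label, n_epochs),
    condition = rep(recording$condition, n_epochs),
    epoch_index = seq_len(n_epochs) - 1L,
    stringsAsFactors = FALSE)
  structure(
    list(samples = arr, rate = recording$rate,
         channel_labels = colnames(recording$samples), manifest = manifest),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              dim(x$samples)[3L], dim(x$samples)[2L], dim(x$samples)[1L],
              x$rate))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param epochs An `epoch_set`.
#' @return Integer count of epochs.
#' @export
n_epochs <- function(epochs) dim(epochs$samples)[3L]

#' Extract one epoch as a samples-by-channels matrix
#' @param epochs An `epoch_set`.
#' @param i Epoch position (1-based).
#' @return Numeric matrix, sample x channel, with channel labels as colnames.
#' @export
epoch_matrix <- function(epochs, i) {
  m <- epochs$samples[, , i, drop = TRUE]
  m <- matrix(m, nrow = dim(epochs$samples)[1L])
  colnames(m) <- epochs$channel_labels
  m
}

#' Combine epoch sets from several recordings
#' @param sets A list of `epoch_set` objects with identical rate, epoch
#'   length and channel labels.
#' @return One `epoch_set` with epochs concatenated in order.
#' @export
bind_epoch_sets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  ref <- sets[[1L]]
  for (s in sets[-1L]) {
    if (s$rate != ref$rate ||
        !identical(s$channel_labels, ref$channel_labels) ||
        dim(s$samples)[1L] != dim(ref$samples)[1L]) {
      stop("epoch sets are not compatible", call. = FALSE)
    }
  }
  arr <- array(
    unlist(lapply(sets, function(s) s$samples), use.names = FALSE),
    dim = c(dim(ref$samples)[1L], dim(ref$samples)[2L],
            sum(vapply(sets, n_epochs, integer(1L)))))
  manifest <- do.call(rbind, lapply(sets, function(s) s$manifest))
  rownames(manifest) <- NULL
  structure(list(samples = arr, rate = ref$rate,
                 channel_labels = ref$channel_labels, manifest = manifest),
            class = "epoch_set")
}

#' Zero-phase band-pass and notch filtering
#'
#' Optional preprocessing mirroring typical EEG acquisition filters
#' (0.5-70 Hz band-pass with a 50 Hz power-line notch).  Uses 4th-order
#' Butterworth designs applied forward-backward (zero phase).  Off by
#' default in the pipeline because the target datasets arrive pre-filtered.
#'
#' @param recording An [eeg_recording()].
#' @param low,high Band edges in Hz; `0 < low < high < rate/2`.
#' @param notch Notch center frequency in Hz, or `NULL` to disable. The
#'   stop band is `notch` +- 2 Hz.
#' @return The filtered recording.
#' @export
bandpass_notch <- function(recording, low = 0.5, high = 70, notch = 50) {
  stopifnot(inherits(recording, "eeg_recording"))
  nyq <- recording$rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("band edges must satisfy 0 < low < high < rate/2", call. = FALSE)
  }
  bp <- signal::butter(4, c(low, high) / nyq, type = "pass")
  x <- recording$samples
  for (j in seq_len(ncol(x))) {
    x[, j] <- signal::filtfilt(bp, x[, j])
  }
  if (!is.null(notch)) {
    if (!(notch > 0 && notch < nyq)) {
      stop("notch frequency must lie in (0, rate/2)", call. = FALSE)
    }
    bs <- signal::butter(2, c(notch - 2, notch + 2) / nyq, type = "stop")
    for (j in seq_len(ncol(x))) {
      x[, j] <- signal::filtfilt(bs, x[, j])
    }
  }
  recording$samples <- x
  recording
}

#' Apply a caller-supplied artifact-removal hook
#'
#' Artifact removal by ICA (or any other method) is dataset- and
#' operator-specific; no automatic component-rejection rule is shipped.
#' Instead, any function mapping a recording to a cleaned recording can be
#' plugged in here.  The hook must preserve the channel count, sample count
#' and sampling rate; the default is the identity.
#'
#' @param recording An [eeg_recording()].
#' @param hook A function `recording -> recording`, or `NULL` (identity).
#' @return The (possibly cleaned) recording.
#' @export
apply_ica_hook <- function(recording, hook = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (is.null(hook)) return(recording)
  stopifnot(is.function(hook))
  out <- hook(recording)
  ok <- inherits(out, "eeg_recording") &&
    identical(dim(out$samples), dim(recording$samples)) &&
    identical(colnames(out$samples), colnames(recording$samples)) &&
    identical(out$rate, recording$rate)
  if (!ok) {
    stop("artifact hook must preserve channel count, length and rate",
         call. = FALSE)
  }
  out
}
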