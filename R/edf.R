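# EDF (European Data Format) I/O.
#
# EDF is a fixed-layout ASCII-header + 16-bit little-endian format:
# a 256-byte global header, 256 bytes of per-signal header fields
# (stored field-major: all labels, then all transducers, ...), then data
# records of int16 samples.  Physical values are reconstructed from the
# per-signal physical/digital min/max calibration.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

# Format a number into <= `width` ASCII characters and return the exact
# value that the formatted string re-parses to, so that calibration applied
# at write time matches what a reader recovers from the header.
edf_num_field <- function(x, width = 8L) {
  for (digits in seq(10L, 1L)) {
    s <- formatC(x, digits = digits, format = "g", width = 1L)
    if (nchar(s) <= width) break
  }
  list(text = edf_pad(s, width), value = as.numeric(s))
}

#' Write a recording to an EDF file
#'
#' Writes a valid EDF file with one-second data records and per-channel
#' calibration spanning each channel's observed amplitude range.  Samples
#' are quantized to 16 bits; a read-back therefore reproduces the input
#' within one quantization step of the channel range.
#'
#' @param recording An [eeg_recording()] whose sampling rate is a positive
#'   integer and whose duration is a whole number of seconds.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  rate <- recording$rate
  if (rate != round(rate)) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  x <- recording$samples
  n <- nrow(x)
  if (n %% rate != 0) {
    stop("EDF writer requires a whole number of seconds of data",
         call. = FALSE)
  }
  ns <- ncol(x)
  n_rec <- n %/% rate

  dig_min <- -32768L
  dig_max <- 32767L
  pmin_txt <- pmax_txt <- character(ns)
  digital <- matrix(0L, n, ns)
  for (j in seq_len(ns)) {
    lo <- min(x[, j]); hi <- max(x[, j])
    if (hi <= lo) hi <- lo + 1  # constant channel: arbitrary 1-unit span
    # widen until the parsed 8-character header values bracket the data
    fl <- edf_num_field(lo)
    delta <- max(abs(lo) * 1e-6, 1e-9)
    while (fl$value > lo) {
      fl <- edf_num_field(lo - delta)
      delta <- delta * 10
    }
    fh <- edf_num_field(hi)
    delta <- max(abs(hi) * 1e-6, 1e-9)
    while (fh$value < hi) {
      fh <- edf_num_field(hi + delta)
      delta <- delta * 10
    }
    pmin_txt[j] <- fl$text; pmax_txt[j] <- fh$text
    scale <- (dig_max - dig_min) / (fh$value - fl$value)
    digital[, j] <- as.integer(round((x[, j] - fl$value) * scale) + dig_min)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(edf_pad("0", 8L))
  wr(edf_pad(recording$subject_id, 80L))
  wr(edf_pad(paste0("deepasym ", recording$group_label, " ",
                    recording$condition), 80L))
  wr(edf_pad("01.01.20", 8L))
  wr(edf_pad("00.00.00", 8L))
  wr(edf_pad(256L * (ns + 1L), 8L))
  wr(edf_pad("", 44L))
  wr(edf_pad(n_rec, 8L))
  wr(edf_pad("1", 8L))
  wr(edf_pad(ns, 4L))
  for (lab in colnames(x)) wr(edf_pad(lab, 16L))
  for (j in seq_len(ns)) wr(edf_pad("", 80L))
  for (j in seq_len(ns)) wr(edf_pad("uV", 8L))
  for (j in seq_len(ns)) wr(pmin_txt[j])
  for (j in seq_len(ns)) wr(pmax_txt[j])
  for (j in seq_len(ns)) wr(edf_pad(dig_min, 8L))
  for (j in seq_len(ns)) wr(edf_pad(dig_max, 8L))
  for (j in seq_len(ns)) wr(edf_pad("", 80L))
  for (j in seq_len(ns)) wr(edf_pad(rate, 8L))
  for (j in seq_len(ns)) wr(edf_pad("", 32L))
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * rate + 1L):(r * rate)
    # records are signal-major: all samples of signal 1, then signal 2, ...
    writeBin(as.integer(digital[rows, , drop = FALSE]),
             con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  version <- rd(8L)
  patient <- rd(80L)
  recording_id <- rd(80L)
  rd(8L); rd(8L)                      # start date/time, unused
  header_bytes <- as.integer(rd(8L))
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L || is.na(n_rec) || is.na(rec_dur)) {
    stop("not a valid EDF header", call. = FALSE)
  }
  per <- function(nc) vapply(seq_len(ns), function(i) rd(nc), character(1L))
  labels <- per(16L)
  per(80L)                            # transducer
  per(8L)                             # physical dimension
  pmin <- as.numeric(per(8L))
  pmax <- as.numeric(per(8L))
  dmin <- as.numeric(per(8L))
  dmax <- as.numeric(per(8L))
  per(80L)                            # prefiltering
  nsamp <- as.integer(per(8L))
  per(32L)
  list(version = version, patient = patient, recording_id = recording_id,
       header_bytes = header_bytes, n_rec = n_rec, rec_dur = rec_dur,
       ns = ns, labels = labels, pmin = pmin, pmax = pmax,
       dmin = dmin, dmax = dmax, nsamp = nsamp)
}

# Match a 10-20 channel name against vendor-decorated EDF labels such as
# "EEG Fp1-LE": case-insensitive, preferring token-boundary matches and
# falling back to plain substring.
match_channel <- function(name, labels) {
  ln <- toupper(labels)
  nm <- toupper(name)
  hit <- which(ln == nm)
  if (length(hit)) return(hit[1L])
  rx <- paste0("(^|[^A-Z0-9])", nm, "([^A-Z0-9]|$)")
  hit <- grep(rx, ln)
  if (length(hit)) return(hit[1L])
  hit <- grep(nm, ln, fixed = TRUE)
  if (length(hit)) return(hit[1L])
  NA_integer_
}

#' Read an EDF recording, selecting and ordering montage channels
#'
#' Reads an EDF/EDF+ file, reconstructs physical sample values from the
#' per-signal calibration, and returns the channels named by `montage`, in
#' montage order, regardless of their order on disk.  Label matching is
#' case-insensitive and tolerates vendor prefixes/suffixes such as
#' `"EEG Fp1-LE"`.  Channels not in the montage (e.g. midline Fz, Cz, Pz)
#' are ignored.
#'
#' @param path Path to an EDF file.
#' @param montage Character vector of channel names to extract, in the
#'   desired order.  Defaults to [default_montage()].
#' @param group_label,condition,subject_id Metadata attached to the
#'   returned recording; `subject_id` defaults to the EDF patient field
#'   (or the file name if that is empty).
#' @return An [eeg_recording()] with `length(montage)` channels.
#' @export
read_edf <- function(path, montage = default_montage(),
                     group_label = NA_character_, condition = NA_character_,
                     subject_id = NULL) {
  if (!file.exists(path)) {
    stop("cannot read EDF file: ", path, call. = FALSE)
  }
  validate_montage(montage)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- tryCatch(read_edf_header(con),
                  error = function(e) stop("cannot parse EDF file ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  idx <- vapply(montage, match_channel, integer(1L), labels = hdr$labels)
  if (anyNA(idx)) {
    stop("montage channel(s) absent from EDF: ",
         paste(montage[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (length(unique(hdr$nsamp)) != 1L) {
    stop("EDF files with per-signal sampling rates are not supported",
         call. = FALSE)
  }
  nsamp <- hdr$nsamp[1L]
  rate <- nsamp / hdr$rec_dur
  raw <- readBin(con, integer(), n = hdr$n_rec * hdr$ns * nsamp,
                 size = 2L, endian = "little")
  if (length(raw) < hdr$n_rec * hdr$ns * nsamp) {
    stop("EDF file truncated: ", path, call. = FALSE)
  }
  # records x (signal-major blocks of nsamp)
  arr <- array(raw, dim = c(nsamp, hdr$ns, hdr$n_rec))
  out <- matrix(0, nrow = hdr$n_rec * nsamp, ncol = length(montage))
  colnames(out) <- montage
  for (k in seq_along(montage)) {
    j <- idx[k]
    gain <- (hdr$pmax[j] - hdr$pmin[j]) / (hdr$dmax[j] - hdr$dmin[j])
    out[, k] <- as.vector(arr[, j, ]) * gain +
      (hdr$pmin[j] - hdr$dmin[j] * gain)
  }
  if (is.null(subject_id)) {
    subject_id <- if (nzchar(hdr$patient)) hdr$patient else basename(path)
  }
  eeg_recording(out, rate = rate, group_label = group_label,
                condition = condition, subject_id = subject_id)
}
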