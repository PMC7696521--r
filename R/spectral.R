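# Welch spectral estimation and Simpson band-power integration.

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / n))

#' Welch power spectral density of one epoch
#'
#' Averages periodograms of Hann-tapered, mean-detrended segments with the
#' given overlap.  The window duration follows the rule
#' "two times the inverse of the lower frequency of interest": with
#' `window_rule = "band"` the band's own lower edge `f1` is used (alpha,
#' `f1 = 8` gives a 0.25 s window, 64 samples at 256 Hz), guaranteeing at
#' least two cycles of the slowest in-band component per segment; with
#' `window_rule = "total"` the lower edge of the total 0.5-30 Hz range is
#' used (a 4 s window).  Either way the window is capped at the epoch
#' duration.
#'
#' @param x Numeric vector or samples-by-channels matrix (one epoch).
#' @param rate Sampling frequency in Hz.
#' @param band An [eeg_band()] or canonical band name; sets the window
#'   duration via `window_rule`.
#' @param overlap Fractional overlap between segments in `[0, 1)`;
#'   default 0.5.
#' @param window_rule `"band"` or `"total"` (see above).
#' @return An object of class `band_spectrum`: list with `freqs` (Hz, from
#'   0 to Nyquist), `S` (PSD matrix, frequency x channel, units power/Hz),
#'   `window_sec`, `overlap`, `rate`.
#' @export
welch_psd <- function(x, rate, band = "alpha", overlap = 0.5,
                      window_rule = c("band", "total")) {
  window_rule <- match.arg(window_rule)
  band <- as_band(band)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("epoch is too short for spectral estimation",
                   call. = FALSE)
  if (!(overlap >= 0 && overlap < 1)) {
    stop("overlap must lie in [0, 1)", call. = FALSE)
  }
  f_low <- if (window_rule == "band") band$f1 else total_band()$f1
  window_sec <- min(2 / f_low, n / rate)
  nwin <- as.integer(round(window_sec * rate))
  nwin <- min(nwin, n)
  step <- max(1L, nwin - as.integer(floor(nwin * overlap)))
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- hann_window(nwin)
  nch <- ncol(x)
  nseg <- length(starts)
  # one FFT call over all (segment, channel) columns
  seg <- matrix(0, nrow = nwin, ncol = nseg * nch)
  for (s in seq_len(nseg)) {
    block <- x[starts[s]:(starts[s] + nwin - 1L), , drop = FALSE]
    block <- sweep(block, 2L, colMeans(block), "-")  # constant detrend
    seg[, ((s - 1L) * nch + 1L):(s * nch)] <- block * w
  }
  ft <- stats::mvfft(seg)
  nfreq <- nwin %/% 2L + 1L
  p <- (Mod(ft[seq_len(nfreq), , drop = FALSE])^2) / (rate * sum(w^2))
  # one-sided: double everything except DC (and Nyquist when nwin is even)
  dbl <- rep(2, nfreq)
  dbl[1L] <- 1
  if (nwin %% 2L == 0L) dbl[nfreq] <- 1
  p <- p * dbl
  S <- matrix(0, nrow = nfreq, ncol = nch)
  for (ch in seq_len(nch)) {
    cols <- (seq_len(nseg) - 1L) * nch + ch
    S[, ch] <- rowMeans(p[, cols, drop = FALSE])
  }
  colnames(S) <- colnames(x)
  structure(
    list(freqs = seq(0L, nfreq - 1L) * rate / nwin, S = S,
         window_sec = nwin / rate, overlap = overlap, rate = rate,
         window_rule = window_rule, taper = "hann", detrend = "constant"),
    class = "band_spectrum")
}

#' @export
print.band_spectrum <- function(x, ...) {
  cat(sprintf(
    "<band_spectrum> %d freqs (0-%g Hz, df = %g) x %d channels; %gs %s window, %.0f%% overlap\n",
    length(x$freqs), max(x$freqs), x$freqs[2L] - x$freqs[1L], ncol(x$S),
    x$window_sec, x$taper, 100 * x$overlap))
  invisible(x)
}

# Composite Simpson rule on a uniformly spaced grid; for an even number of
# points, Simpson over the first n-1 points plus a trapezoid on the final
# interval.
simpson_uniform <- function(y, h) {
  n <- length(y)
  if (n < 3L) {
    if (n < 2L) return(0)
    return(h * (y[1L] + y[2L]) / 2)
  }
  if (n %% 2L == 0L) {
    return(simpson_uniform(y[-n], h) + h * (y[n - 1L] + y[n]) / 2)
  }
  idx <- seq(2L, n - 1L)
  w <- ifelse(idx %% 2L == 0L, 4, 2)
  h / 3 * (y[1L] + sum(w * y[idx]) + y[n])
}

#' Integrated band power from a spectrum
#'
#' Integrates the PSD over the grid frequencies falling inside the closed
#' interval `[f1, f2]` using Simpson's rule (a parabolic approximation).
#' Bands holding fewer than three grid points fall back to the trapezoid
#' rule with a warning.
#'
#' @param spectrum A `band_spectrum` from [welch_psd()].
#' @param band An [eeg_band()] or canonical band name.
#' @return Named numeric vector of per-channel band powers
#'   (PSD units x Hz).
#' @export
band_power <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "band_spectrum"))
  band <- as_band(band)
  sel <- spectrum$freqs >= band$f1 & spectrum$freqs <= band$f2
  npts <- sum(sel)
  if (npts == 0L) {
    stop(sprintf("band %s (%g-%g Hz) contains no grid frequencies",
                 band$name, band$f1, band$f2), call. = FALSE)
  }
  h <- spectrum$freqs[2L] - spectrum$freqs[1L]
  if (npts < 3L) {
    warning(sprintf(
      "band %s holds only %d grid point(s); using trapezoid rule",
      band$name, npts), call. = FALSE)
  }
  out <- apply(spectrum$S[sel, , drop = FALSE], 2L, simpson_uniform, h = h)
  if (is.null(names(out)) && !is.null(colnames(spectrum$S))) {
    names(out) <- colnames(spectrum$S)
  }
  out
}

#' Relative band power of one epoch
#'
#' Per channel, the ratio of Simpson-integrated PSD over the requested band
#' to the integrated PSD over the total 0.5-30 Hz range, both taken from
#' one shared spectrum.  The ratio is dimensionless, lies in `[0, 1]` for
#' bands inside the total range, and is invariant to positive rescaling of
#' the channel's time series.
#'
#' @param x Numeric vector or samples-by-channels matrix (one epoch).
#' @param rate Sampling frequency in Hz.
#' @param band An [eeg_band()] or canonical band name.
#' @param overlap Welch overlap fraction; default 0.5.
#' @param window_rule Which lower frequency drives the Welch window rule:
#'   `"total"` (default; the 0.5 Hz edge of the denominator range, a 4 s
#'   window) or `"band"` (the band's own `f1`).  The default resolves both
#'   integrals on the same fine frequency grid; see the methods vignette.
#' @return Named numeric vector of per-channel relative powers with
#'   attributes `band` and `window_rule`.
#' @export
relative_power <- function(x, rate, band, overlap = 0.5,
                           window_rule = c("total", "band")) {
  window_rule <- match.arg(window_rule)
  band <- as_band(band)
  if (band$f1 < total_band()$f1 - 1e-9 || band$f2 > total_band()$f2 + 1e-9) {
    stop("band must lie within the total 0.5-30 Hz range", call. = FALSE)
  }
  spec <- welch_psd(x, rate, band = band, overlap = overlap,
                    window_rule = window_rule)
  num <- band_power(spec, band)
  den <- band_power(spec, total_band())
  bad <- !(den > 0)
  if (any(bad)) {
    nm <- names(den)[bad]
    stop("zero total power in channel(s): ",
         paste(if (is.null(nm)) which(bad) else nm, collapse = ", "),
         call. = FALSE)
  }
  structure(num / den, band = band$name, window_rule = window_rule)
}

#' Relative power of every epoch in a set, as a long table
#'
#' @param epochs An `epoch_set` from [segment_epochs()] or
#'   [bind_epoch_sets()].
#' @param bands Character vector of canonical band names (or list of
#'   [eeg_band()] objects).
#' @param overlap,window_rule Passed to [relative_power()].
#' @return Data frame with columns `subject_id`, `epoch_index`, `channel`,
#'   `band`, `rp`, plus `group_label`.
#' @export
rp_table <- function(epochs, bands = "alpha", overlap = 0.5,
                     window_rule = "total") {
  stopifnot(inherits(epochs, "epoch_set"))
  bands <- lapply(bands, as_band)
  rows <- vector("list", n_epochs(epochs) * length(bands))
  k <- 0L
  for (i in seq_len(n_epochs(epochs))) {
    m <- epoch_matrix(epochs, i)
    info <- epochs$manifest[i, ]
    for (b in bands) {
      rp <- relative_power(m, epochs$rate, b, overlap = overlap,
                           window_rule = window_rule)
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject_id = info$subject_id, group_label = info$group_label,
        epoch_index = info$epoch_index, channel = epochs$channel_labels,
        band = b$name, rp = unname(rp), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
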