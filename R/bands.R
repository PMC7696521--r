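#' Construct an EEG frequency band
#'
#' @param name Band label (e.g. `"alpha"`).
#' @param f1 Lower edge in Hz; must satisfy `0 < f1 < f2`.
#' @param f2 Upper edge in Hz.
#' @return An object of class `eeg_band`: a list with `name`, `f1`, `f2`.
#' @export
#' @examples
#' eeg_band("alpha", 8, 13)
eeg_band <- function(name, f1, f2) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(f1) || !is.finite(f2) || f1 <= 0 || f2 <= f1) {
    stop("band edges must satisfy 0 < f1 < f2", call. = FALSE)
  }
  structure(list(name = name, f1 = f1, f2 = f2), class = "eeg_band")
}

#' Canonical EEG bands
#'
#' The four classical bands used throughout: delta 0.5-4, theta 4-8,
#' alpha 8-13 and beta 13-30 Hz.  Band edges are shared between adjacent
#' bands (closed intervals).
#'
#' @param which Optional character vector selecting a subset by name.
#' @return A named list of [eeg_band()] objects.
#' @export
#' @examples
#' eeg_bands()$alpha
eeg_bands <- function(which = NULL) {
  bands <- list(
    delta = eeg_band("delta", 0.5, 4),
    theta = eeg_band("theta", 4, 8),
    alpha = eeg_band("alpha", 8, 13),
    beta  = eeg_band("beta", 13, 30)
  )
  if (is.null(which)) return(bands)
  missing <- setdiff(which, names(bands))
  if (length(missing)) {
    stop("unknown band(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bands[which]
}

#' Total band used as the relative-power denominator (0.5-30 Hz)
#' @return An [eeg_band()] spanning 0.5-30 Hz.
#' @export
total_band <- function() eeg_band("total", 0.5, 30)

#' @export
print.eeg_band <- function(x, ...) {
  cat(sprintf("<eeg_band> %s: %g-%g Hz\n", x$name, x$f1, x$f2))
  invisible(x)
}

# Resolve a band given either an eeg_band or a canonical band name.
as_band <- function(band) {
  if (inherits(band, "eeg_band")) return(band)
  if (is.character(band) && length(band) == 1L) return(eeg_bands(band)[[1L]])
  stop("band must be an eeg_band object or a canonical band name",
       call. = FALSE)
}
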