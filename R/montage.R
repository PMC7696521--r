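#' Default 16-channel 10-20 montage
#'
#' The fixed channel order used for asymmetry matrices: the eight left
#' hemisphere electrodes (odd indices in the 10-20 scheme) followed by their
#' right-hemisphere homologs.  Midline electrodes (Fz, Cz, Pz) are excluded,
#' reducing a standard 19-channel acquisition to the 16 channels that carry
#' lateralized information.
#'
#' @return Character vector of 16 channel labels in matrix order.
#' @export
#' @examples
#' default_montage()
default_montage <- function() {
  c("Fp1", "F3", "C3", "P3", "O1", "F7", "T3", "T5",
    "Fp2", "F4", "C4", "P4", "O2", "F8", "T4", "T6")
}

#' Left-hemisphere channels of the default montage
#' @return Character vector of the eight left (odd-numbered) channel labels.
#' @export
left_channels <- function() default_montage()[1:8]

#' Right-hemisphere channels of the default montage
#' @return Character vector of the eight right (even-numbered) channel labels,
#'   ordered so that `right_channels()[i]` is the homolog of
#'   `left_channels()[i]`.
#' @export
right_channels <- function() default_montage()[9:16]

#' Validate a montage (channel order)
#'
#' @param montage Character vector of unique channel labels.
#' @param n Required length, or `NULL` to accept any length.
#' @return The montage, invisibly, after validation.
#' @keywords internal
validate_montage <- function(montage, n = NULL) {
  if (!is.character(montage) || anyDuplicated(montage) > 0) {
    stop("montage must be a character vector of unique channel labels",
         call. = FALSE)
  }
  if (!is.null(n) && length(montage) != n) {
    stop(sprintf("montage must have exactly %d channels, got %d",
                 n, length(montage)), call. = FALSE)
  }
  invisible(montage)
}
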