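# Pairwise relative-power asymmetry scores and the 16x16 asymmetry matrix.

#' Pairwise asymmetry score
#'
#' The normalized difference `(rp1 - rp2) / (rp1 + rp2)` between the
#' relative powers of two channels.  Bounded in `[-1, 1]`: positive when
#' channel 1 carries relatively more power, `+1`/`-1` when one channel
#' carries all of it.  Vectorized over its arguments.
#'
#' @param rp1,rp2 Non-negative relative powers with `rp1 + rp2 > 0`.
#' @return Asymmetry score(s) in `[-1, 1]`.
#' @export
#' @examples
#' asymmetry_score(0.6, 0.2)  # 0.5
asymmetry_score <- function(rp1, rp2) {
  if (any(rp1 < 0) || any(rp2 < 0)) {
    stop("relative powers must be non-negative", call. = FALSE)
  }
  s <- rp1 + rp2
  if (any(s <= 0)) {
    stop("asymmetry score undefined when rp1 + rp2 = 0", call. = FALSE)
  }
  (rp1 - rp2) / s
}

#' Assemble the 16x16 pairwise asymmetry matrix
#'
#' Entry `[i, j]` is `asymmetry_score(rp[order[i]], rp[order[j]])`: row =
#' first channel, column = second channel, in montage order.  The matrix is
#' antisymmetric with a zero diagonal (the diagonal is set to exactly 0
#' rather than computed, which also covers channels with zero relative
#' power).
#'
#' @param rp Named numeric vector of per-channel relative powers covering
#'   every channel in `order` (e.g. one row group of [rp_table()] or the
#'   output of [relative_power()]).
#' @param order Channel order for rows/columns; default [default_montage()].
#' @param band,subject_id,epoch_index,group_label Metadata carried as
#'   attributes (taken from `rp`'s attributes when present).
#' @return A matrix of class `asym_matrix` with channel dimnames.
#' @export
asymmetry_matrix <- function(rp, order = default_montage(),
                             band = attr(rp, "band"),
                             subject_id = NA_character_,
                             epoch_index = NA_integer_,
                             group_label = NA_character_) {
  validate_montage(order)
  if (is.null(names(rp))) {
    if (length(rp) != length(order)) {
      stop("unnamed rp must have exactly one value per montage channel",
           call. = FALSE)
    }
    names(rp) <- order
  }
  missing <- setdiff(order, names(rp))
  if (length(missing)) {
    stop("relative power missing for channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- unname(rp[order])
  if (any(v < 0)) stop("relative powers must be non-negative", call. = FALSE)
  s <- outer(v, v, "+")
  if (any(s[upper.tri(s)] <= 0)) {
    stop("asymmetry undefined: a channel pair has zero total relative power",
         call. = FALSE)
  }
  d <- outer(v, v, "-")
  m <- d / s
  diag(m) <- 0
  dimnames(m) <- list(ch1 = order, ch2 = order)
  structure(m, class = c("asym_matrix", "matrix"),
            band = if (is.null(band)) NA_character_ else band,
            subject_id = subject_id, epoch_index = epoch_index,
            group_label = group_label)
}

#' @export
print.asym_matrix <- function(x, ...) {
  cat(sprintf("<asym_matrix> %dx%d, band %s, subject %s, epoch %s, group %s\n",
              nrow(x), ncol(x), attr(x, "band"), attr(x, "subject_id"),
              attr(x, "epoch_index"), attr(x, "group_label")))
  print(round(unclass(x), 3L))
  invisible(x)
}

#' Write an asymmetry matrix as CSV
#'
#' 16 rows x 16 columns with channel names as header and row names.
#'
#' @param matrix An `asym_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_asym_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "asym_matrix"))
  utils::write.csv(as.data.frame(unclass(matrix)), path, row.names = TRUE)
  invisible(path)
}
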