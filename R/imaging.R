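# Rendering asymmetry matrices as fixed-scale RGB images.

#' Fixed diverging jet-style colormap on \[-1, 1\]
#'
#' Maps asymmetry scores to RGB with a fixed lookup independent of any
#' particular matrix's range (no per-image autoscaling): -1 maps to the
#' blue endpoint, 0 to the green/yellow midrange, +1 to the red endpoint.
#' The map is piecewise linear and injective, so distinct scores yield
#' distinct colors.
#'
#' @param v Numeric vector of scores in `[-1, 1]`.
#' @return Matrix with `length(v)` rows and columns `r`, `g`, `b` in
#'   `[0, 1]`.
#' @export
#' @examples
#' asym_colormap(c(-1, 0, 1))
asym_colormap <- function(v) {
  if (any(!is.finite(v)) || any(v < -1) || any(v > 1)) {
    stop("asymmetry values must be finite and lie in [-1, 1]", call. = FALSE)
  }
  x <- (v + 1) / 2
  clamp <- function(z) pmin(pmax(z, 0), 1)
  cbind(r = clamp(1.5 - abs(4 * x - 3)),
        g = clamp(1.5 - abs(4 * x - 2)),
        b = clamp(1.5 - abs(4 * x - 1)))
}

#' Colorize an asymmetry matrix into a 16x16 RGB grid
#'
#' @param matrix An `asym_matrix` (or any numeric matrix with entries in
#'   `[-1, 1]`).
#' @return A `nrow x ncol x 3` array of RGB components in `[0, 1]`, with
#'   the matrix metadata carried as attributes.
#' @export
colorize <- function(matrix) {
  m <- unclass(matrix)
  rgb <- asym_colormap(as.vector(m))
  out <- array(rgb, dim = c(nrow(m), ncol(m), 3L))
  attr(out, "band") <- attr(matrix, "band")
  attr(out, "subject_id") <- attr(matrix, "subject_id")
  attr(out, "epoch_index") <- attr(matrix, "epoch_index")
  attr(out, "group_label") <- attr(matrix, "group_label")
  out
}

#' Upscale a color grid by nearest-neighbor block replication
#'
#' Each 16x16 cell becomes a constant `(size/16) x (size/16)` pixel block;
#' colors are preserved exactly and no interpolated colors are introduced,
#' so the original grid is recoverable from block centers.
#'
#' @param grid A 16x16x3 array from [colorize()].
#' @param size Output side length; must be an integer multiple of the grid
#'   side (64 for the CNN input).
#' @return A `size x size x 3` array of class `asym_image`, components in
#'   `[0, 1]`, metadata attributes preserved.
#' @export
upscale <- function(grid, size = 64L) {
  d <- dim(grid)
  if (length(d) != 3L || d[3L] != 3L) {
    stop("grid must be an h x w x 3 array", call. = FALSE)
  }
  if (size %% d[1L] != 0L || size %% d[2L] != 0L) {
    stop("size must be an integer multiple of the grid dimensions",
         call. = FALSE)
  }
  f <- size %/% d[1L]
  idx_r <- rep(seq_len(d[1L]), each = f)
  idx_c <- rep(seq_len(d[2L]), each = size %/% d[2L])
  out <- grid[idx_r, idx_c, , drop = FALSE]
  for (a in c("band", "subject_id", "epoch_index", "group_label")) {
    attr(out, a) <- attr(grid, a)
  }
  attr(out, "block") <- f
  class(out) <- "asym_image"
  out
}

#' Render an asymmetry matrix directly to a CNN-ready image
#'
#' Convenience composition of [colorize()] and [upscale()].
#'
#' @param matrix An `asym_matrix`.
#' @param size Output side length (default 64).
#' @return An `asym_image` (`size x size x 3`, components in `[0, 1]`).
#' @export
render_asym_image <- function(matrix, size = 64L) {
  upscale(colorize(matrix), size = size)
}

#' File name convention for asymmetry images
#' @param subject_id,epoch_index,band,group_label Image metadata.
#' @return `"<subject>_<epoch>_<band>_<label>.png"`.
#' @export
asym_png_name <- function(subject_id, epoch_index, band, group_label) {
  sprintf("%s_%s_%s_%s.png", subject_id, epoch_index, band, group_label)
}

#' Write an asymmetry image as an 8-bit RGB PNG
#'
#' @param image An `asym_image` (or 64x64x3 array in `[0, 1]`).
#' @param path Output path; use [asym_png_name()] to embed metadata in the
#'   file name.
#' @return `path`, invisibly.
#' @export
write_asym_png <- function(image, path) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L) {
    stop("image must be an h x w x 3 array", call. = FALSE)
  }
  png::writePNG(unclass(image), path)
  invisible(path)
}

#' Read a 64x64 RGB PNG asymmetry image
#'
#' @param path Path to a PNG written by [write_asym_png()].
#' @param size Expected side length (default 64).
#' @return An `asym_image` with components in `[0, 1]` (8-bit resolution).
#' @export
read_asym_png <- function(path, size = 64L) {
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop("not a readable PNG file: ", path,
                                           call. = FALSE))
  d <- dim(img)
  if (length(d) == 3L && d[3L] == 4L) img <- img[, , 1:3]  # drop alpha
  d <- dim(img)
  if (length(d) != 3L || d[1L] != size || d[2L] != size || d[3L] != 3L) {
    stop(sprintf("expected a %dx%d RGB PNG, got %s", size, size,
                 paste(dim(img), collapse = "x")), call. = FALSE)
  }
  structure(img, class = "asym_image")
}
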