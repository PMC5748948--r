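#' Construct an intensity image
#'
#' The common currency of the package: a 2-D grid of fluorescence intensities
#' on a fixed 0--255 scale. All thresholds in the quantification pipeline are
#' defined on this scale, so images from 16-bit cameras must be (and are, by
#' [load_gfp_image()]) linearly rescaled by 255/65535 before analysis --
#' never contrast-stretched, which would silently move every threshold.
#'
#' @param pixels numeric matrix of intensities, each value in \[0, 255\].
#' @param source_depth bit depth of the originating file, 8 or 16. Purely
#'   informative; `pixels` is always on the 0--255 scale.
#' @return An `intensity_image`: the matrix with class and `source_depth`
#'   attributes.
#' @examples
#' img <- intensity_image(matrix(0, 10, 10))
#' dim(img)
#' @export
intensity_image <- function(pixels, source_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (anyNA(pixels))
    stop("image contains NA pixels", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]; got range [",
         signif(min(pixels), 6), ", ", signif(max(pixels), 6), "]",
         call. = FALSE)
  if (!source_depth %in% c(8L, 16L))
    stop("`source_depth` must be 8 or 16", call. = FALSE)
  structure(pixels,
            source_depth = as.integer(source_depth),
            class = c("intensity_image", "matrix", "array"))
}

#' Test for an intensity image
#' @param x object to test.
#' @return `TRUE` if `x` is an `intensity_image`.
#' @export
is_intensity_image <- function(x) inherits(x, "intensity_image")

as_pixel_matrix <- function(image) {
  # strip class/attrs for raw matrix arithmetic
  m <- unclass(image)
  attr(m, "source_depth") <- NULL
  m
}

assert_image <- function(image, arg = "image") {
  if (!is_intensity_image(image))
    stop("`", arg, "` must be an intensity_image (see intensity_image())",
         call. = FALSE)
  invisible(image)
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d px, %d-bit source, range [%.6g, %.6g]\n",
              nrow(x), ncol(x), attr(x, "source_depth"),
              min(x), max(x)))
  invisible(x)
}

#' Crop a rectangular region of interest
#'
#' Coordinates are 0-based and row-major, with the rectangle given as
#' half-open extents: `rect = c(row0, col0, height, width)` selects rows
#' `row0 .. row0 + height - 1` and columns `col0 .. col0 + width - 1`
#' (0-based). Used to restrict analysis to the yolk region of an embryo.
#'
#' @param image an [intensity_image()].
#' @param rect integer vector `c(row0, col0, height, width)`; must lie fully
#'   inside the image.
#' @return The cropped `intensity_image`.
#' @examples
#' img <- intensity_image(matrix(7, 100, 100))
#' dim(crop_roi(img, c(10, 20, 10, 10)))
#' @export
crop_roi <- function(image, rect) {
  assert_image(image)
  if (length(rect) != 4L || anyNA(rect) || any(rect != floor(rect)))
    stop("`rect` must be four integers c(row0, col0, height, width)",
         call. = FALSE)
  rect <- as.integer(rect)
  r0 <- rect[1L]; c0 <- rect[2L]; h <- rect[3L]; w <- rect[4L]
  if (h < 1L || w < 1L)
    stop("crop height and width must be >= 1", call. = FALSE)
  if (r0 < 0L || c0 < 0L || r0 + h > nrow(image) || c0 + w > ncol(image))
    stop(sprintf(
      "crop rect [row %d..%d, col %d..%d] falls outside the %d x %d image",
      r0, r0 + h - 1L, c0, c0 + w - 1L, nrow(image), ncol(image)),
      call. = FALSE)
  m <- as_pixel_matrix(image)[(r0 + 1L):(r0 + h), (c0 + 1L):(c0 + w), drop = FALSE]
  intensity_image(m, attr(image, "source_depth"))
}
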