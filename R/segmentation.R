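#' Segmentation configuration
#'
#' Bundles the parameters of the vegetation/soil segmentation stage: the
#' three coefficients of the linear greenness colour index, the fixed
#' binarisation threshold, and the side of the square structuring element
#' used for the morphological opening.
#'
#' The default coefficients (−0.884, 1.262, −0.311) were fitted on raw
#' 0–255 channel intensities for maize inter-row imagery and outperform the
#' classical Excess Green coefficients (−1, 2, −1) on that kind of scene;
#' the index is therefore applied to raw intensities, never to channels
#' rescaled to \[0, 1\].
#'
#' @param coeff_r,coeff_g,coeff_b Real coefficients multiplying the R, G
#'   and B channels.
#' @param threshold Greenness-index value above which (strictly) a pixel is
#'   called vegetation. Default 10.
#' @param opening_size Odd side length (pixels) of the all-ones square
#'   structuring element; 5 removes speckle noise while leaving seedling
#'   leaves intact, 1 disables the opening.
#' @return An object of class `seg_config`.
#' @export
#' @examples
#' seg_config()
seg_config <- function(coeff_r = -0.884, coeff_g = 1.262, coeff_b = -0.311,
                       threshold = 10, opening_size = 5) {
  stopifnot(is.numeric(coeff_r), is.numeric(coeff_g), is.numeric(coeff_b),
            is.numeric(threshold), length(threshold) == 1L)
  opening_size <- as.integer(opening_size)
  if (length(opening_size) != 1L || is.na(opening_size) ||
      opening_size < 1L || opening_size %% 2L == 0L) {
    stop("`opening_size` must be an odd positive integer", call. = FALSE)
  }
  structure(list(coeff_r = coeff_r, coeff_g = coeff_g, coeff_b = coeff_b,
                 threshold = threshold, opening_size = opening_size),
            class = "seg_config")
}

#' @export
print.seg_config <- function(x, ...) {
  cat(sprintf(
    "<seg_config> GI = %.3f R + %.3f G + %.3f B; threshold > %g; opening %dx%d\n",
    x$coeff_r, x$coeff_g, x$coeff_b, x$threshold,
    x$opening_size, x$opening_size))
  invisible(x)
}

.check_rgb <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop("malformed image: expected an H x W x 3 RGB array ",
         "(greyscale or RGBA input is rejected, not coerced)", call. = FALSE)
  }
  if (d[1] < 1L || d[2] < 1L) stop("malformed image: empty", call. = FALSE)
  invisible(TRUE)
}

#' Greenness colour index of an RGB image
#'
#' Computes the per-pixel linear combination
#' `GI = coeff_r * R + coeff_g * G + coeff_b * B` in real arithmetic on the
#' raw 0–255 intensities, without any clipping or rescaling. Vegetation
#' pixels (strong green component) score high; soil scores low or negative.
#'
#' @param image Numeric `H x W x 3` array of 0–255 intensities, channels
#'   ordered R, G, B.
#' @param config A [seg_config()].
#' @return Numeric `H x W` matrix of index values (may be negative).
#' @export
#' @examples
#' px <- array(c(100, 100, 100), dim = c(1, 1, 3))
#' greenness_index(px)  # 6.7
greenness_index <- function(image, config = seg_config()) {
  .check_rgb(image)
  gi <- config$coeff_r * image[, , 1] +
    config$coeff_g * image[, , 2] +
    config$coeff_b * image[, , 3]
  matrix(gi, dim(image)[1], dim(image)[2])
}

#' Binarise a greenness-index image
#'
#' Strict comparison: a pixel is vegetation iff its index exceeds the
#' threshold (`gi > threshold`); values exactly at the threshold are
#' background.
#'
#' @param gi Numeric matrix, e.g. from [greenness_index()].
#' @param threshold Scalar threshold (default 10).
#' @return Logical matrix, `TRUE` = vegetation.
#' @export
binarise <- function(gi, threshold = 10) {
  stopifnot(is.matrix(gi), is.numeric(threshold), length(threshold) == 1L)
  gi > threshold
}

#' Morphological opening of a binary mask
#'
#' Erosion followed by dilation with a square all-ones structuring element.
#' Pixels outside the image are treated as background, so foreground
#' touching the border is eroded like any other boundary. Opening removes
#' speckles and thin protrusions smaller than the structuring element; it is
#' idempotent and anti-extensive. `size = 1` is the identity.
#'
#' @param mask Logical matrix.
#' @param size Odd positive integer side of the structuring element.
#' @return Logical matrix of the same shape.
#' @export
open_mask <- function(mask, size = 5) {
  stopifnot(is.matrix(mask))
  size <- as.integer(size)
  if (length(size) != 1L || is.na(size) || size < 1L || size %% 2L == 0L) {
    stop("opening size must be an odd positive integer", call. = FALSE)
  }
  if (size == 1L) return(mask | FALSE)
  pad <- (size - 1L) %/% 2L
  h <- nrow(mask); w <- ncol(mask)
  # pad with background so the exterior does not support erosion survivors
  m <- matrix(0L, h + 2L * pad, w + 2L * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- as.integer(mask)
  kern <- EBImage::makeBrush(size, shape = "box")
  op <- EBImage::opening(m, kern)
  op[pad + seq_len(h), pad + seq_len(w), drop = FALSE] > 0.5
}

#' Segment vegetation in an RGB field image
#'
#' The full segmentation stage: greenness index, strict thresholding, then
#' morphological opening.
#'
#' @inheritParams greenness_index
#' @return Logical vegetation mask.
#' @export
#' @examples
#' img <- array(0, dim = c(8, 8, 3))
#' img[3:6, 3:6, 2] <- 180   # a green patch on black
#' sum(segment_vegetation(img, seg_config(opening_size = 1)))
segment_vegetation <- function(image, config = seg_config()) {
  gi <- greenness_index(image, config)
  open_mask(binarise(gi, config$threshold), config$opening_size)
}

#' Read an RGB image from PNG or TIFF
#'
#' Decodes to the raw 0–255 scale used throughout the package. Greyscale
#' and RGBA files are rejected rather than silently coerced.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric `H x W x 3` array of 0–255 intensities.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format '.", ext, "' (PNG and TIFF are supported)",
         call. = FALSE)
  )
  .check_rgb(img)
  img * 255
}

#' Write a binary mask as an 8-bit PNG
#'
#' Vegetation pixels are written as 255, background as 0.
#'
#' @param mask Logical matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
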