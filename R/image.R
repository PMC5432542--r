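#' RGB image container
#'
#' A thin wrapper around an `H x W x 3` array of 8-bit samples with an optional
#' ground sampling distance. All wheatdens rasters use matrix convention:
#' first index is the image row (y, increasing downwards), second the column
#' (x, increasing rightwards), both 1-based.
#'
#' @param px numeric or integer array, `H x W x 3`, values in `[0, 255]`.
#' @param resolution_mm ground sampling distance in mm/pixel, or `NA` when the
#'   image has not been rectified yet (perspective views have no single GSD).
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(px, resolution_mm = NA_real_) {
  wd_assert(is.array(px) && length(dim(px)) == 3 && dim(px)[3] == 3,
            "wheatdens_shape_error", "`px` must be an H x W x 3 array")
  wd_assert(dim(px)[1] >= 1 && dim(px)[2] >= 1,
            "wheatdens_shape_error", "image must have at least one pixel")
  rng <- range(px)
  wd_assert(rng[1] >= 0 && rng[2] <= 255,
            "wheatdens_shape_error", "channel values must lie in [0, 255]")
  structure(list(px = px, resolution_mm = as.numeric(resolution_mm)),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$px)
  cat(sprintf("<rgb_image %d x %d px, resolution %s mm/px>\n",
              d[1], d[2],
              if (is.na(x$resolution_mm)) "unknown" else format(x$resolution_mm)))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$px)

#' Read an RGB image from PNG, TIFF or JPEG
#'
#' 8-bit images are used as-is; 16-bit input is rescaled to the 8-bit range.
#' Grayscale input is rejected (the pipeline needs colour to find plants).
#'
#' @param path file path.
#' @param resolution_mm optional ground sampling distance to attach.
#' @return An [rgb_image].
#' @export
read_rgb_image <- function(path, resolution_mm = NA_real_) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  wd_assert(length(d) == 3 && d[3] >= 3, "wheatdens_shape_error",
            sprintf("'%s' is not a 3-channel image", path))
  # EBImage stores (x, y, channel) in [0, 1]; transpose to (row, col, channel)
  px <- aperm(EBImage::imageData(img)[, , 1:3, drop = FALSE], c(2, 1, 3))
  rgb_image(round(px * 255), resolution_mm = resolution_mm)
}

#' Write a binary mask as a PNG file
#'
#' @param mask a [binary_mask] or logical matrix.
#' @param path output path (PNG).
#' @export
write_mask_png <- function(mask, path) {
  m <- as_mask_matrix(mask)
  EBImage::writeImage(EBImage::Image(t(m * 1)), path, type = "png")
  invisible(path)
}

#' Read a binary mask written by [write_mask_png()]
#' @param path PNG path.
#' @return A [binary_mask].
#' @export
read_mask_png <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  m <- if (length(d) == 3) EBImage::imageData(img)[, , 1] else EBImage::imageData(img)
  binary_mask(t(m) > 0.5)
}

#' Convert sRGB samples to CIELab
#'
#' Implements the standard colorimetric chain sRGB (D65 reference white,
#' piecewise gamma decoding) -> linear RGB -> XYZ -> CIELab. The a* channel is
#' the green-magenta axis: chlorophyll-green pixels have strongly negative a*,
#' soil browns positive a*, which is what makes a* a robust single-channel
#' greenness signal under variable illumination.
#'
#' @param image an [rgb_image] or `H x W x 3` array in `[0, 255]`.
#' @return `H x W x 3` numeric array with L*, a*, b* planes.
#' @export
rgb_to_lab <- function(image) {
  px <- if (inherits(image, "rgb_image")) image$px else image
  wd_assert(is.array(px) && length(dim(px)) == 3 && dim(px)[3] == 3,
            "wheatdens_shape_error", "expected an H x W x 3 RGB array")
  d <- dim(px)
  v <- matrix(as.numeric(px), ncol = 3) / 255
  # inverse sRGB companding (indexed assignment: the vectors are large)
  lin <- v / 12.92
  big <- v > 0.04045
  lin[big] <- ((v[big] + 0.055) / 1.055)^2.4
  # sRGB primaries -> XYZ (D65)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              nrow = 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  white <- c(0.95047, 1.0, 1.08883)
  t3 <- sweep(xyz, 2, white, "/")
  eps <- (6 / 29)^3
  f <- t3 / (3 * (6 / 29)^2) + 4 / 29
  big <- t3 > eps
  f[big] <- t3[big]^(1 / 3)
  L <- 116 * f[, 2] - 16
  a <- 500 * (f[, 1] - f[, 2])
  b <- 200 * (f[, 2] - f[, 3])
  array(c(L, a, b), dim = c(d[1], d[2], 3),
        dimnames = list(NULL, NULL, c("L", "a", "b")))
}
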