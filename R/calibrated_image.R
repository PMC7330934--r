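#' Calibrated RGB image
#'
#' Container tying an 8-bit RGB pixel grid to its physical pixel size.
#' Every area in the pipeline (particle areas in \eqn{\mu m^2}, region areas
#' in \eqn{mm^2}, densities in cells/\eqn{mm^2}) derives from the single
#' isotropic calibration stored here.
#'
#' @param pixels integer array `H x W x 3` with values in `[0, 255]`.
#'   A greyscale matrix (`H x W`) is promoted to RGB by channel
#'   triplication.
#' @param microns_per_pixel positive number: physical edge length of one
#'   pixel in microns (isotropic).
#' @return An object of class `calibrated_image` with fields `pixels` and
#'   `microns_per_pixel`.
#' @examples
#' img <- calibrated_image(array(255L, c(10, 20, 3)), microns_per_pixel = 0.5)
#' physical_area_um2(img) # 10 * 20 * 0.25
#' @export
calibrated_image <- function(pixels, microns_per_pixel) {
  assert_scalar_number(microns_per_pixel, "microns_per_pixel", positive = TRUE)
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    validation_error("`pixels` must be an H x W x 3 array (or an H x W matrix)")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    validation_error("image must have at least one row and one column")
  storage.mode(pixels) <- "integer"
  rng <- range(pixels)
  if (anyNA(pixels) || rng[1] < 0L || rng[2] > 255L)
    validation_error("pixel values must lie in [0, 255] with no missing values")
  structure(list(pixels = pixels, microns_per_pixel = as.numeric(microns_per_pixel)),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px (%.4g um^2)\n",
              d[1], d[2], x$microns_per_pixel, physical_area_um2(x)))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' Physical area of a calibrated image
#'
#' @param image a [calibrated_image()].
#' @return Total physical area `H * W * microns_per_pixel^2` in
#'   \eqn{\mu m^2}.
#' @export
physical_area_um2 <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  d <- dim(image$pixels)
  d[1] * d[2] * image$microns_per_pixel^2
}
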