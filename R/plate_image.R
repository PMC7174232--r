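#' Plate image container
#'
#' One acquired or synthetic frame. Gel-imager frames (`gel16`) are
#' single-channel 16-bit transmittance images (dark buds on a bright field);
#' phone frames (`phone8`) are 8-bit RGB arrays. Pixel values are stored as
#' integers on the native scale of the mode.
#'
#' @param pixels numeric matrix (gel16, values 0..65535) or H x W x 3 array
#'   (phone8, values 0..255).
#' @param mode `"gel16"` or `"phone8"`.
#' @param dpi optional pixel pitch metadata.
#' @return Object of class `plate_image` with fields `pixels`, `mode`,
#'   `bit_depth`, `dpi`.
#' @export
plate_image <- function(pixels, mode = c("gel16", "phone8"), dpi = NULL) {
  mode <- match.arg(mode)
  if (mode == "gel16") {
    if (!is.matrix(pixels)) stopf("gel16 plates are single-channel matrices")
    if (min(pixels) < 0 || max(pixels) > 65535)
      stopf("gel16 values must lie in [0, 65535]")
    bit <- 16L
  } else {
    if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
      stopf("phone8 plates are H x W x 3 arrays")
    if (min(pixels) < 0 || max(pixels) > 255)
      stopf("phone8 values must lie in [0, 255]")
    bit <- 8L
  }
  d <- dim(pixels)
  if (d[1] < 32 || d[2] < 32) stopf("plate must be at least 32 x 32 px")
  structure(list(pixels = pixels, mode = mode, bit_depth = bit, dpi = dpi),
            class = "plate_image")
}

#' @export
print.plate_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<plate_image> %s, %d x %d px, %d-bit\n",
              x$mode, d[1], d[2], x$bit_depth))
  invisible(x)
}

#' @export
dim.plate_image <- function(x) dim(x$pixels)

# pull the pixel grid out of a plate_image or pass a bare matrix/array through
as_pixels <- function(img) {
  if (inherits(img, "plate_image")) img$pixels else img
}

#' Convert an RGB array to luma grayscale
#'
#' Rec. 601 luma weights, the standard projection used before thresholding
#' colour plates.
#'
#' @param img `plate_image` (phone8) or H x W x 3 array.
#' @return Numeric matrix on the same intensity scale as the input.
#' @export
rgb_to_gray <- function(img) {
  px <- as_pixels(img)
  if (length(dim(px)) != 3) stopf("expected an RGB array")
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}
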