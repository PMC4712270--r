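#' Read a microscopy image from TIFF
#'
#' Reads a single-image 8- or 16-bit TIFF. 16-bit input is linearly rescaled
#' to `[0, 255]` and rounded; RGB input is converted to luminance with
#' [rgb_to_gray()].
#'
#' @param path Path to a TIFF file.
#' @param um_per_pixel Calibration in µm/pixel; defaults to 1 with a warning.
#' @param meta Named list of tags (group, region, marker, ...).
#' @return A [gray_image()].
#' @export
read_image <- function(path, um_per_pixel = NULL, meta = list()) {
  if (!file.exists(path)) tj_abort("io", paste0("Cannot read image file: ", path))
  raw <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) tj_abort("io", paste0("Failed to decode TIFF '", path, "': ", conditionMessage(e))))
  if (is.list(raw)) tj_abort("format", paste0("Multi-image TIFF stacks are unsupported: ", path))
  if (length(dim(raw)) == 3) {
    if (dim(raw)[3] != 3) {
      tj_abort("format", sprintf("Unsupported channel count (%d) in %s; expected 1 or 3.",
                                 dim(raw)[3], path))
    }
    return(rgb_to_gray(raw, um_per_pixel = um_per_pixel, meta = meta))
  }
  if (length(dim(raw)) != 2) tj_abort("format", paste0("Unsupported image dimensionality in ", path))
  mx <- max(raw)
  if (mx > 255) {
    # 16-bit: linear rescale so 0 -> 0 and 65535 -> 255
    raw <- round(raw * (255 / 65535))
  }
  gray_image(raw, um_per_pixel = um_per_pixel, meta = meta)
}

#' Write an 8-bit grayscale TIFF
#'
#' @param img A [gray_image()] or [binary_mask()] (masks are written with
#'   foreground 255).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  px <- as_pixels(img)
  if (inherits(img, "binary_mask")) px <- px * 255L
  tiff::writeTIFF(px / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Convert an RGB raster to 8-bit grayscale
#'
#' Uses ITU-R BT.601 luminance weights (0.299, 0.587, 0.114), rounded to the
#' nearest integer. Single-marker immunofluorescence channels are effectively
#' monochrome, so the precise weights are immaterial in practice; the
#' conversion is fixed and documented for reproducibility.
#'
#' @param rgb A `height x width x 3` array with 8-bit channel values.
#' @inheritParams read_image
#' @return A [gray_image()].
#' @export
#' @examples
#' rgb <- array(rep(c(255, 0, 0), each = 4), c(2, 2, 3))
#' rgb_to_gray(rgb, um_per_pixel = 1)$pixels
rgb_to_gray <- function(rgb, um_per_pixel = NULL, meta = list()) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    tj_abort("format", "rgb_to_gray() expects a height x width x 3 array.")
  }
  g <- round(0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3])
  gray_image(matrix(g, dim(rgb)[1], dim(rgb)[2]),
             um_per_pixel = um_per_pixel, meta = meta)
}

#' Threshold a grayscale image to a binary mask
#'
#' Converts an 8-bit image to a 1-bit mask: pixels strictly greater than the
#' threshold become foreground. `method = "otsu"` picks the threshold that
#' maximizes between-class variance of the 256-level histogram;
#' `method = "fixed"` applies `fixed_value` directly. The threshold applied
#' is recorded in the mask's provenance and does not depend on the spatial
#' calibration.
#'
#' @param img A [gray_image()].
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value Intensity in `[0, 255]`, required for `method = "fixed"`.
#' @return A [binary_mask()].
#' @export
#' @examples
#' img <- gray_image(matrix(c(10L, 200L), 4, 4), um_per_pixel = 1)
#' threshold_image(img, "fixed", 100)$pixels
threshold_image <- function(img, method = c("otsu", "fixed"), fixed_value = NULL) {
  method <- match.arg(method)
  px <- as_pixels(img)
  if (method == "otsu") {
    if (min(px) == max(px)) {
      tj_abort("degenerate", sprintf(
        "Otsu threshold undefined: image%s is constant (value %d).",
        if (length(img$meta$image_id)) paste0(" '", img$meta$image_id, "'") else "",
        px[1]))
    }
    thr <- EBImage::otsu(EBImage::Image(px / 255), range = c(0, 1), levels = 256) * 255
  } else {
    if (is.null(fixed_value) || fixed_value < 0 || fixed_value > 255) {
      tj_abort("param", "`fixed_value` must be supplied in [0, 255] for method = 'fixed'.")
    }
    thr <- fixed_value
  }
  binary_mask(px > thr, um_per_pixel = img$um_per_pixel,
              threshold = as.numeric(thr), method = method)
}
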