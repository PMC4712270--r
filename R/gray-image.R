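#' Calibrated 8-bit grayscale image
#'
#' The substrate of every metric in the package: an integer pixel matrix in
#' `[0, 255]` (row-major, `(row, col)` indexing, origin at the top-left)
#' carrying a physical calibration in micrometres per pixel and free-form
#' metadata tags (group, region, marker, ...).
#'
#' @param pixels Numeric matrix of intensities; values must be whole numbers
#'   in `[0, 255]`.
#' @param um_per_pixel Physical calibration, micrometres per pixel (> 0).
#'   Defaults to 1 with a warning so pure-pixel workflows still run.
#' @param meta Named list of free-form tags.
#' @return An object of class `gray_image`.
#' @export
#' @examples
#' img <- gray_image(matrix(0L, 8, 8), um_per_pixel = 0.2)
#' dim(img)
gray_image <- function(pixels, um_per_pixel = NULL, meta = list()) {
  if (!is.matrix(pixels)) tj_abort("param", "`pixels` must be a matrix.")
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255) ||
      any(pixels != round(pixels))) {
    tj_abort("param", "Pixel intensities must be integers in [0, 255].")
  }
  if (nrow(pixels) < 1 || ncol(pixels) < 1) {
    tj_abort("param", "Image must have positive height and width.")
  }
  if (is.null(um_per_pixel)) {
    warning("No calibration supplied; assuming 1 µm/pixel.", call. = FALSE)
    um_per_pixel <- 1
  }
  if (!is.numeric(um_per_pixel) || length(um_per_pixel) != 1 || um_per_pixel <= 0) {
    tj_abort("param", "`um_per_pixel` must be a single positive number.")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, um_per_pixel = as.numeric(um_per_pixel), meta = meta),
    class = "gray_image"
  )
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d px, %.4g µm/px, intensities [%d, %d]\n",
    nrow(x$pixels), ncol(x$pixels), x$um_per_pixel,
    min(x$pixels), max(x$pixels)
  ))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Binary mask over an image
#'
#' A `{0, 1}` matrix with the shape and calibration of its source image.
#' Thresholding records the threshold used in the mask's provenance
#' attributes.
#'
#' @param pixels Logical or 0/1 matrix.
#' @param um_per_pixel Calibration inherited from the source image.
#' @param threshold,method Provenance: the threshold value applied and how it
#'   was chosen.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, um_per_pixel = 1, threshold = NA_real_,
                        method = NA_character_) {
  if (is.logical(pixels)) pixels <- pixels * 1L
  if (!is.matrix(pixels) || !all(pixels %in% c(0L, 1L))) {
    tj_abort("param", "Mask pixels must be a matrix of 0/1 values.")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, um_per_pixel = as.numeric(um_per_pixel),
         threshold = threshold, method = method),
    class = "binary_mask"
  )
}

#' @export
dim.binary_mask <- function(x) dim(x$pixels)

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask> %d x %d px, %d foreground px (%.1f%%), method=%s, threshold=%s\n",
    nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
    100 * mean(x$pixels), x$method, format(x$threshold)
  ))
  invisible(x)
}

# coerce helpers used internally
as_pixels <- function(img) {
  if (inherits(img, "gray_image") || inherits(img, "binary_mask")) return(img$pixels)
  if (is.matrix(img)) return(img)
  tj_abort("param", "Expected a gray_image, binary_mask or matrix.")
}

mask_logical <- function(mask) as_pixels(mask) != 0L
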