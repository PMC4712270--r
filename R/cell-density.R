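# chain-code length of an object's outer boundary (EBImage::ocontour trace);
# diagonal steps weigh sqrt(2). Degenerate 1-2 px objects get length >= 1.
contour_perimeter <- function(obj) {
  oc <- EBImage::ocontour(EBImage::Image(obj * 1))
  if (length(oc) == 0) return(1)
  xy <- oc[[1]]
  if (nrow(xy) < 2) return(1)
  d <- rbind(diff(xy), xy[1, ] - xy[nrow(xy), ])
  steps <- abs(d)
  sum(ifelse(steps[, 1] + steps[, 2] == 2, sqrt(2), 1))
}

#' Detect labeled particles in a binary mask
#'
#' Labels 8-connected components of a thresholded 1-bit image and reports,
#' per particle, its area (pixel count scaled by the calibration), a
#' boundary-following perimeter estimate (chain code of the traced outer
#' contour, diagonal steps weighted sqrt(2)), the circularity `4*pi*A/P^2`,
#' and the centroid. Circularity of a rasterized object can slightly exceed
#' 1; [filter_particles()] clamps it before filtering. The perimeter
#' estimator is stated here because circularity depends on it.
#'
#' @param mask A [binary_mask()] with calibration.
#' @param um_per_pixel Calibration override; defaults to the mask's.
#' @return Tibble with one row per particle: `label`, `area_px`, `area_um2`,
#'   `perimeter_um`, `circularity`, `centroid_row`, `centroid_col`.
#' @export
detect_particles <- function(mask, um_per_pixel = NULL) {
  px <- mask_logical(mask)
  um <- um_per_pixel %||%
    (if (inherits(mask, "binary_mask")) mask$um_per_pixel else 1)
  lab <- label_components(px, connectivity = 8)
  n <- max(lab)
  if (n == 0) {
    return(tibble::tibble(
      label = integer(0), area_px = integer(0), area_um2 = numeric(0),
      perimeter_um = numeric(0), circularity = numeric(0),
      centroid_row = numeric(0), centroid_col = numeric(0)))
  }
  purrr::map_dfr(seq_len(n), function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    r0 <- range(idx[, 1]); c0 <- range(idx[, 2])
    crop <- matrix(FALSE, r0[2] - r0[1] + 3L, c0[2] - c0[1] + 3L)
    crop[cbind(idx[, 1] - r0[1] + 2L, idx[, 2] - c0[1] + 2L)] <- TRUE
    per_px <- contour_perimeter(crop)
    area_px <- nrow(idx)
    tibble::tibble(
      label = i,
      area_px = area_px,
      area_um2 = area_px * um^2,
      perimeter_um = per_px * um,
      circularity = 4 * pi * area_px / per_px^2,
      centroid_row = mean(idx[, 1]),
      centroid_col = mean(idx[, 2])
    )
  })
}

#' Filter particles by area and circularity
#'
#' Keeps particles with area strictly greater than `min_area_um2`
#' (micrometres squared; the strict reading of "larger than") and
#' circularity inside `circ_range` (inclusive). Circularity values above 1
#' arising from rasterization are clamped to 1 before filtering, so the
#' conventional `(0, 1)` window excludes nothing by shape — it is retained,
#' and configurable, because it is part of the published procedure.
#'
#' @param particles Tibble from [detect_particles()].
#' @param min_area_um2 Area threshold (default 50).
#' @param circ_range Length-2 numeric, inclusive circularity window
#'   (default `c(0, 1)`).
#' @return The filtered particle tibble (with clamped circularity in
#'   `circularity_clamped`).
#' @export
filter_particles <- function(particles, min_area_um2 = 50, circ_range = c(0, 1)) {
  particles %>%
    dplyr::mutate(circularity_clamped = pmin(.data$circularity, 1)) %>%
    dplyr::filter(
      .data$area_um2 > min_area_um2,
      .data$circularity_clamped >= circ_range[1],
      .data$circularity_clamped <= circ_range[2]
    )
}

# ray-casting point-in-polygon; vertices as (row, col) rows, boundary counts in
point_in_polygon <- function(pr, pc, poly) {
  n <- nrow(poly)
  j <- n
  inside <- rep(FALSE, length(pr))
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    cross <- ((yi > pr) != (yj > pr)) &
      (pc < (xj - xi) * (pr - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Cell density per 1000 square micrometres
#'
#' Counts the filtered particles whose centroid lies in the region of
#' interest and reports the count per 1000 µm² of ROI area. The centroid
#' rule avoids double-counting cells across adjacent fields. With no ROI the
#' full frame is used.
#'
#' @param particles Filtered particle tibble ([filter_particles()]).
#' @param image_dim Image dimensions `c(height, width)` in pixels (needed for
#'   the full-frame area when `roi` is `NULL`).
#' @param um_per_pixel Calibration.
#' @param roi Optional polygon: a two-column matrix/data frame of `(row, col)`
#'   vertices in pixel coordinates.
#' @return One-row tibble with `n_cells`, `roi_area_um2`, `density`
#'   (cells per 1000 µm²).
#' @export
cell_density <- function(particles, image_dim, um_per_pixel, roi = NULL) {
  if (is.null(roi)) {
    area_um2 <- prod(image_dim) * um_per_pixel^2
    n <- nrow(particles)
  } else {
    roi <- as.matrix(roi)
    if (nrow(roi) < 3) tj_abort("param", "ROI polygon needs at least 3 vertices.")
    # shoelace area in px^2
    r <- roi[, 1]; c <- roi[, 2]
    area_px <- abs(sum(c * (dplyr::lead(r, default = r[1])) -
                       (dplyr::lead(c, default = c[1])) * r)) / 2
    area_um2 <- area_px * um_per_pixel^2
    if (area_um2 <= 0) tj_abort("param", "ROI polygon has zero area.")
    n <- if (nrow(particles)) {
      sum(point_in_polygon(particles$centroid_row, particles$centroid_col, roi))
    } else 0L
  }
  if (area_um2 <= 0) tj_abort("param", "Region of interest has zero area.")
  tibble::tibble(
    n_cells = as.integer(n),
    roi_area_um2 = area_um2,
    density = n / area_um2 * 1000
  )
}
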