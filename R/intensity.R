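#' Automatic foreground mask for ROI placement
#'
#' The intensity procedure places its foreground rectangles on intensely
#' immunolabeled structures and its background rectangles on unstained area.
#' Manual placement is not reproducible, so this helper derives an
#' algorithmic foreground mask: the brightest `1 - quantile` fraction of
#' pixels, with blobs smaller than `min_blob_px` removed. Background
#' eligibility is the complement of a dilated copy of the mask (attached as
#' the `"bg_exclusion"` attribute), so background rectangles keep a margin
#' from labeled structures. A user-supplied mask can be passed to
#' [place_rois()] instead, to reproduce manual workflows.
#'
#' @param img A [gray_image()].
#' @param quantile Fraction in (0, 1); pixels in the top `1 - quantile` of
#'   the intensity distribution are foreground (default 0.95).
#' @param min_blob_px Minimum blob size kept, in pixels (default 5).
#' @param bg_margin_px Dilation radius defining the background exclusion
#'   zone (default 5).
#' @return A [binary_mask()] with attribute `bg_exclusion` (logical matrix).
#' @export
auto_foreground_mask <- function(img, quantile = 0.95, min_blob_px = 5,
                                 bg_margin_px = 5) {
  if (quantile <= 0 || quantile >= 1) tj_abort("param", "`quantile` must be in (0, 1).")
  px <- as_pixels(img)
  if (min(px) == max(px)) {
    tj_abort("degenerate", "Cannot derive a foreground mask from a constant image.")
  }
  # smallest gray level whose upper tail holds at most 1 - quantile of pixels
  tail_frac <- rev(cumsum(rev(tabulate(px + 1L, 256)))) / length(px)
  g <- which(tail_frac <= (1 - quantile) + 1e-12)[1] - 1L
  if (is.na(g)) g <- 256L
  fg <- px >= g
  if (!any(fg)) {
    # a heavy tie at the top level can push the upper-tail rule past every
    # pixel; fall back to the brightest occupied level
    g <- max(px)
    fg <- px >= g
  }
  if (any(fg)) {
    lab <- label_components(fg, connectivity = 8)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0], nbins = max(lab))
      fg <- lab > 0 & sizes[pmax(lab, 1L)] >= min_blob_px
    }
  }
  out <- binary_mask(fg, um_per_pixel = img$um_per_pixel,
                     threshold = as.numeric(g), method = "quantile")
  attr(out, "bg_exclusion") <- dilate_disc(fg, bg_margin_px)
  out
}

#' Randomly place foreground and background measurement rectangles
#'
#' Implements the rectangle placement of the semiquantitative intensity
#' procedure: by default 10 foreground rectangles of 7 x 7 pixels placed
#' uniformly at random on immunolabeled structures and 5 equal rectangles on
#' unstained background. Every rectangle lies fully inside the image;
#' foreground rectangles lie fully inside the foreground mask and background
#' rectangles fully outside it (outside its dilated exclusion zone when the
#' mask carries one, as masks from [auto_foreground_mask()] do). Rectangles
#' of the same class may not overlap, so no pixel is double-counted.
#' Placement is deterministic given `seed`.
#'
#' @param img A [gray_image()].
#' @param fg_mask A [binary_mask()] of the immunolabeled foreground.
#' @param n_fg,n_bg Rectangle counts (defaults 10 and 5).
#' @param size Rectangle side in pixels (default 7).
#' @param seed RNG seed for placement.
#' @return A `tj_roi_sample`: list with tibbles `rects_fg` and `rects_bg`
#'   (top-left `row`/`col`, 1-based, and `size`), plus `size` and `seed`.
#' @export
place_rois <- function(img, fg_mask, n_fg = 10, n_bg = 5, size = 7, seed = 1) {
  px <- as_pixels(img)
  fg <- mask_logical(fg_mask)
  if (!all(dim(fg) == dim(px))) tj_abort("param", "Mask and image shapes differ.")
  excl <- attr(fg_mask, "bg_exclusion")
  if (is.null(excl)) excl <- fg
  elig_fg <- window_sums(fg, size) == size^2
  elig_bg <- window_sums(excl, size) == 0
  sample_class <- function(elig, n, class) {
    avail <- elig
    rows <- integer(0); cols <- integer(0)
    for (i in seq_len(n)) {
      cand <- which(avail)
      if (length(cand) == 0) {
        tj_abort("infeasible", sprintf(
          "Cannot place %d non-overlapping %s rectangles (%d x %d px): only %d fit.",
          n, class, size, size, i - 1L))
      }
      pick <- cand[sample.int(length(cand), 1L)]
      r <- (pick - 1L) %% nrow(avail) + 1L
      cc <- (pick - 1L) %/% nrow(avail) + 1L
      rows <- c(rows, r); cols <- c(cols, cc)
      block_r <- max(1L, r - size + 1L):min(nrow(avail), r + size - 1L)
      block_c <- max(1L, cc - size + 1L):min(ncol(avail), cc + size - 1L)
      avail[block_r, block_c] <- FALSE
    }
    tibble::tibble(row = rows, col = cols, size = as.integer(size))
  }
  withr::with_seed(seed, {
    rects_fg <- sample_class(elig_fg, n_fg, "foreground")
    rects_bg <- sample_class(elig_bg, n_bg, "background")
  })
  structure(list(rects_fg = rects_fg, rects_bg = rects_bg,
                 size = as.integer(size), seed = seed),
            class = "tj_roi_sample")
}

#' Background-subtracted mean intensity over placed rectangles
#'
#' For each rectangle the average intensity per pixel is computed; the mean
#' over background rectangles is subtracted from the mean over foreground
#' rectangles. A negative corrected value is possible on pathological input
#' and is flagged in the `negative_corrected` column.
#'
#' @param img A [gray_image()].
#' @param rois A `tj_roi_sample` from [place_rois()].
#' @return One-row tibble with `mean_fg`, `mean_bg`, `corrected`
#'   (`mean_fg - mean_bg`), `n_fg`, `n_bg`, `roi_size`, `seed`,
#'   `negative_corrected`.
#' @export
measure_intensity <- function(img, rois) {
  px <- as_pixels(img)
  k <- rois$size
  rect_mean <- function(r, c) mean(px[r:(r + k - 1L), c:(c + k - 1L)])
  check <- function(rects) {
    if (any(rects$row < 1 | rects$col < 1 |
            rects$row + k - 1L > nrow(px) | rects$col + k - 1L > ncol(px))) {
      tj_abort("param", "ROI rectangles do not fit inside the image.")
    }
  }
  check(rois$rects_fg); check(rois$rects_bg)
  mean_fg <- mean(purrr::map2_dbl(rois$rects_fg$row, rois$rects_fg$col, rect_mean))
  mean_bg <- mean(purrr::map2_dbl(rois$rects_bg$row, rois$rects_bg$col, rect_mean))
  tibble::tibble(
    mean_fg = mean_fg,
    mean_bg = mean_bg,
    corrected = mean_fg - mean_bg,
    n_fg = nrow(rois$rects_fg),
    n_bg = nrow(rois$rects_bg),
    roi_size = k,
    seed = rois$seed,
    negative_corrected = mean_fg - mean_bg < 0
  )
}

#' ROI-based corrected intensity for one image
#'
#' Convenience driver combining [auto_foreground_mask()], [place_rois()] and
#' [measure_intensity()].
#'
#' @inheritParams place_rois
#' @inheritParams auto_foreground_mask
#' @param fg_mask Optional user-supplied foreground mask; when `NULL` the
#'   quantile mask is derived automatically.
#' @return One-row tibble as from [measure_intensity()].
#' @export
corrected_intensity <- function(img, fg_mask = NULL, quantile = 0.95,
                                n_fg = 10, n_bg = 5, size = 7, seed = 1) {
  if (is.null(fg_mask)) fg_mask <- auto_foreground_mask(img, quantile = quantile)
  rois <- place_rois(img, fg_mask, n_fg = n_fg, n_bg = n_bg, size = size, seed = seed)
  measure_intensity(img, rois)
}
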