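#' Skeletonize a binary mask
#'
#' Topology-preserving thinning of the foreground to one-pixel-wide
#' centerlines (Zhang-Suen two-subiteration thinning). Already-thin input is
#' left essentially unchanged; an empty mask yields an empty skeleton.
#'
#' @param mask A [binary_mask()] (or logical/0-1 matrix).
#' @return A [binary_mask()] holding the skeleton.
#' @export
skeletonize_mask <- function(mask) {
  px <- mask_logical(mask)
  # neighbor order P2..P9: N, NE, E, SE, S, SW, W, NW (clockwise)
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- lapply(offs, function(o) shift_mat(px, o[1], o[2]))
      B <- Reduce(`+`, p)
      A <- matrix(0L, nrow(px), ncol(px))
      sq <- c(p, p[1])
      for (k in 1:8) A <- A + (!sq[[k]] & sq[[k + 1]])
      if (sub == 1) {
        cond <- !(p[[1]] & p[[3]] & p[[5]]) & !(p[[3]] & p[[5]] & p[[7]])
      } else {
        cond <- !(p[[1]] & p[[3]] & p[[7]]) & !(p[[1]] & p[[5]] & p[[7]])
      }
      del <- px & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        px[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  um <- if (inherits(mask, "binary_mask")) mask$um_per_pixel else 1
  binary_mask(px, um_per_pixel = um, method = "skeleton")
}

# 8-neighbor count of every pixel of a logical matrix
neighbor_counts <- function(px) {
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  Reduce(`+`, lapply(offs, function(o) shift_mat(px, o[1], o[2])))
}

# junction clusters: skeleton pixels with >= 3 skeleton neighbors, with
# 8-connected clusters of such pixels collapsed to one junction
junction_clusters <- function(px) {
  bp <- px & neighbor_counts(px) >= 3
  lab <- label_components(bp, connectivity = 8)
  n <- max(lab)
  pts <- which(bp, arr.ind = TRUE)
  tibble::tibble(
    row = as.integer(pts[, 1]), col = as.integer(pts[, 2]),
    junction = lab[bp]
  ) %>% dplyr::arrange(.data$junction, .data$row, .data$col)
}

#' Strand length, branch points and complexity index of a skeleton
#'
#' The core statistic of the tight-junction pattern analysis. Strand length
#' sums over adjacent skeleton-pixel pairs with weight 1 for 4-neighbors and
#' sqrt(2) for diagonal steps (diagonal pairs that merely shortcut a
#' 4-connected corner are not double-counted); `length_metric = "count"`
#' instead reports the raw skeleton pixel count, for strict ImageJ-style
#' reproduction. Branch points are skeleton pixels with at least three
#' skeleton neighbors in 8-connectivity, with adjacent branch pixels merged
#' into a single junction — raw neighbor counting over-counts at thick
#' crossings. The complexity index is the ratio of junction count to strand
#' length; it is `NA` for an empty skeleton.
#'
#' @param skel A skeletonized [binary_mask()].
#' @param length_metric `"geodesic"` (default) or `"count"`.
#' @return One-row tibble with `strand_length_px`, `n_branch_points`,
#'   `complexity_index`; the branch-pixel coordinates are attached as the
#'   `"junctions"` attribute.
#' @export
skeleton_metrics <- function(skel, length_metric = c("geodesic", "count")) {
  length_metric <- match.arg(length_metric)
  px <- mask_logical(skel)
  h <- nrow(px); w <- ncol(px)
  if (length_metric == "geodesic") {
    hh <- if (w > 1) sum(px[, 1:(w - 1)] & px[, 2:w]) else 0
    vv <- if (h > 1) sum(px[1:(h - 1), ] & px[2:h, ]) else 0
    dg <- 0
    if (h > 1 && w > 1) {
      # main diagonal pairs, skipped when either shared 4-neighbor is skeleton
      d1 <- px[1:(h - 1), 1:(w - 1)] & px[2:h, 2:w] &
        !px[1:(h - 1), 2:w] & !px[2:h, 1:(w - 1)]
      d2 <- px[1:(h - 1), 2:w] & px[2:h, 1:(w - 1)] &
        !px[1:(h - 1), 1:(w - 1)] & !px[2:h, 2:w]
      dg <- sum(d1) + sum(d2)
    }
    len <- hh + vv + sqrt(2) * dg
  } else {
    len <- sum(px)
  }
  jc <- junction_clusters(px)
  n_junctions <- if (nrow(jc)) max(jc$junction) else 0L
  out <- tibble::tibble(
    strand_length_px = len,
    n_branch_points = as.integer(n_junctions),
    complexity_index = if (len > 0) n_junctions / len else NA_real_
  )
  attr(out, "junctions") <- jc
  out
}

#' Connected-component object statistics
#'
#' Labels the mask's foreground at the requested connectivity and reports the
#' object count, summed object size, and mean object size (their ratio).
#' Sizes are in pixels; when the calibration differs from 1 µm/pixel the
#' micrometre-squared equivalents are included.
#'
#' @param mask A [binary_mask()].
#' @param connectivity 4 or 8 (default 8).
#' @return One-row tibble with `n_objects`, `total_size_px`,
#'   `mean_object_size` (`NA` when the mask is empty) and, when calibrated,
#'   `total_size_um2` / `mean_object_size_um2`.
#' @export
object_stats <- function(mask, connectivity = 8) {
  px <- mask_logical(mask)
  lab <- label_components(px, connectivity = connectivity)
  n <- max(lab)
  total <- sum(px)
  out <- tibble::tibble(
    n_objects = as.integer(n),
    total_size_px = as.integer(total),
    mean_object_size = if (n > 0) total / n else NA_real_
  )
  um <- if (inherits(mask, "binary_mask")) mask$um_per_pixel else 1
  if (um != 1) {
    out$total_size_um2 <- total * um^2
    out$mean_object_size_um2 <- out$mean_object_size * um^2
  }
  out
}

#' Gray-level histogram of an image
#'
#' The full `[0, 255]` intensity range is partitioned into `n_bins` equal
#' bins and relative frequencies are returned; this is the histogram the
#' image-entropy statistic is computed from.
#'
#' @param img A [gray_image()].
#' @param n_bins Number of bins (default 256, one per gray level).
#' @return Tibble with `bin` (1-based), `lower` (inclusive bin edge),
#'   `count`, and `p` (relative frequency; sums to 1).
#' @export
gray_histogram <- function(img, n_bins = 256) {
  if (n_bins < 2) tj_abort("param", "`n_bins` must be at least 2.")
  px <- as_pixels(img)
  width <- 256 / n_bins
  idx <- pmin(floor(px / width), n_bins - 1) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  tibble::tibble(
    bin = seq_len(n_bins),
    lower = (seq_len(n_bins) - 1) * width,
    count = counts,
    p = counts / length(px)
  )
}

#' Shannon entropy of the gray-level histogram
#'
#' `H = -sum(p * log2(p))` over occupied bins of the [gray_histogram()];
#' zero-probability bins contribute 0 (standard limit convention). With 256
#' bins H lies in `[0, 8]` bits: 0 for a constant image, 8 when all 256 gray
#' levels are equally represented. Entropy is a histogram-only statistic —
#' any spatial rearrangement of the pixels leaves it unchanged. It is
#' computed on the full grayscale image, not on a thresholded mask.
#'
#' @inheritParams gray_histogram
#' @return Entropy in bits (a single double).
#' @export
#' @examples
#' img <- gray_image(matrix(7L, 16, 16), um_per_pixel = 1)
#' image_entropy(img) # 0
image_entropy <- function(img, n_bins = 256) {
  p <- gray_histogram(img, n_bins)$p
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' All junction-pattern metrics for one image
#'
#' Convenience driver: thresholds the image, skeletonizes, and returns the
#' strand length, branch-point count, complexity index, object count, mean
#' object size and image entropy as one tidy row.
#'
#' @param img A [gray_image()].
#' @param threshold `"otsu"` (default) or `"fixed"`.
#' @param fixed_value Threshold intensity when `threshold = "fixed"`.
#' @param connectivity Connectivity for object labeling (default 8).
#' @param length_metric Passed to [skeleton_metrics()].
#' @param n_bins Passed to [image_entropy()].
#' @return One-row tibble.
#' @export
junction_metrics <- function(img, threshold = "otsu", fixed_value = NULL,
                             connectivity = 8,
                             length_metric = "geodesic", n_bins = 256) {
  mask <- threshold_image(img, threshold, fixed_value)
  skel <- skeletonize_mask(mask)
  dplyr::bind_cols(
    skeleton_metrics(skel, length_metric = length_metric),
    object_stats(mask, connectivity = connectivity)[, c("n_objects", "mean_object_size")],
    tibble::tibble(entropy_bits = image_entropy(img, n_bins = n_bins))
  )
}
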