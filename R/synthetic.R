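# Ground-truthed synthetic image generators for the three staining
# phenotypes the analysis assumes: branched junction-strand networks
# (claudin-5/occludin-like), blob-shaped transporter/glial staining fields,
# and fields of roughly elliptical cell bodies (NeuN-like). Every generator
# uses one explicitly seeded RNG scope (withr::with_seed) and is
# bit-reproducible given identical parameters and seed.

# 8 directions, clockwise from north, as (drow, dcol)
DIR8 <- matrix(c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
               ncol = 2, byrow = TRUE)

#' Simulate a branched tight-junction strand image
#'
#' Emulates the vessel-wall staining phenotype of junctional proteins: a
#' network of thin, branched strands on a darker background. Strand
#' centerlines are grown as direction-persistent random walks that fork with
#' probability `branch_prob` per step; walks stop at the image border or
#' when they come close to an already-drawn strand, so strands never cross
#' and junctions arise only at forks. A `fragmentation` fraction of
#' centerline pixels is then deleted in contiguous runs (mimicking
#' discontinuous staining), centerlines are dilated by `strand_width`,
#' intensities composed, and clipped rounded Gaussian noise added.
#'
#' Ground truth is derived from the (fragmented) centerline mask itself:
#' branch points are the 8-neighbor junction clusters of that mask (the same
#' rule [skeleton_metrics()] uses) and the true strand length uses the same
#' geodesic step weighting, so recovery through threshold + skeletonize is a
#' genuine round trip, not a shared code path.
#'
#' @param image_size Side of the square image in pixels (default 256).
#' @param n_seeds Number of primary vessel paths (default 4).
#' @param branch_prob Per-step probability that a walker forks (default 0.05).
#' @param fragmentation Fraction of centerline pixels deleted in contiguous
#'   gaps, in `[0, 1]` (default 0).
#' @param strand_width Dilation radius in pixels (default 1, i.e. strands
#'   about 3 px wide).
#' @param fg_intensity,bg_intensity Mean strand and background intensities
#'   (defaults 180 and 30).
#' @param noise_sd Additive Gaussian noise SD (default 8).
#' @param turn_prob Per-step probability of a 45-degree turn (default 0.08).
#' @param um_per_pixel Calibration (default 1).
#' @param seed RNG seed.
#' @return List with `image` (a [gray_image()]) and `truth`: `skeleton_mask`
#'   (a [binary_mask()] of centerlines), `branch_points` (tibble of branch
#'   pixels with junction ids), `n_branch_points`, `true_strand_length`,
#'   `true_fg_mean`, `true_bg_mean`.
#' @export
simulate_junction_image <- function(image_size = 256, n_seeds = 4,
                                    branch_prob = 0.05, fragmentation = 0,
                                    strand_width = 1, fg_intensity = 180,
                                    bg_intensity = 30, noise_sd = 8,
                                    turn_prob = 0.08, um_per_pixel = 1,
                                    seed = 1) {
  if (fragmentation < 0 || fragmentation > 1) {
    tj_abort("param", "`fragmentation` must be in [0, 1].")
  }
  if (fg_intensity <= bg_intensity) {
    tj_abort("param", "`fg_intensity` must exceed `bg_intensity`.")
  }
  if (noise_sd < 0) tj_abort("param", "`noise_sd` must be non-negative.")
  sz <- as.integer(image_size)
  margin <- 2L * strand_width + 2L  # keeps dilated strands separated
  reach <- 2L * margin + 2L  # grace window: fork vicinity, in steps and pixels
  paths <- withr::with_seed(seed, {
    occ <- matrix(0L, sz, sz)       # walker id that drew each pixel
    occ_step <- matrix(0L, sz, sz)  # step index along that walker's path
    paths <- list()
    queue <- lapply(seq_len(n_seeds), function(i) {
      side <- sample.int(4L, 1L)
      pos <- sample(seq(margin + 1L, sz - margin), 1L)
      switch(side,
        list(r = margin + 1L, c = pos, dir = 5L, parent = 0L),  # from top
        list(r = sz - margin, c = pos, dir = 1L, parent = 0L),  # from bottom
        list(r = pos, c = margin + 1L, dir = 3L, parent = 0L),  # from left
        list(r = pos, c = sz - margin, dir = 7L, parent = 0L)   # from right
      )
    })
    wid <- 0L
    max_walkers <- 80L
    n_spawned <- length(queue)
    while (length(queue) > 0) {
      w <- queue[[1]]; queue <- queue[-1]
      wid <- wid + 1L
      r <- w$r; cc <- w$c; dir <- w$dir
      parent <- w$parent %||% 0L
      fork_step <- w$fork_step %||% 0L
      grace <- reach  # steps during which the parent's fork vicinity is ignored
      straight <- w$straight %||% 0L  # forced straight steps after a fork
      path <- matrix(NA_integer_, 4L * sz, 2L)
      np <- 0L
      steps_since_fork <- 0L
      steps_since_turn <- reach + 1L
      repeat {
        if (r < 1L || r > sz || cc < 1L || cc > sz) break
        # stop rather than run into / alongside a foreign strand; a freshly
        # forked child ignores only the stretch of its parent around the fork
        r0 <- max(1L, r - margin):min(sz, r + margin)
        c0 <- max(1L, cc - margin):min(sz, cc + margin)
        near <- occ[r0, c0]
        nstep <- occ_step[r0, c0]
        # own pixels beyond the recent trail count as foreign too, so a
        # meandering walk can never cross or run alongside itself
        foreign <- (near != 0L & near != wid) |
          (near == wid & nstep <= np - (reach + 2L))
        if (grace > 0L && parent > 0L) {
          foreign <- foreign &
            !(near == parent & abs(nstep - fork_step) <= reach)
        }
        if (any(foreign)) break
        np <- np + 1L
        path[np, ] <- c(r, cc)
        occ[r, cc] <- wid
        occ_step[r, cc] <- np
        if (np >= nrow(path)) break
        # fork occasionally, spawning a walker heading perpendicular; forks
        # happen only on straight runs, away from the border and from foreign
        # strands, and both arms leave the fork straight, so every junction
        # stays individually resolvable after dilation and re-thinning
        steps_since_fork <- steps_since_fork + 1L
        steps_since_turn <- steps_since_turn + 1L
        near_border <- r <= 3L * margin || r >= sz - 3L * margin ||
          cc <= 3L * margin || cc >= sz - 3L * margin
        if (n_spawned < max_walkers && steps_since_fork > 8L && !near_border &&
            steps_since_turn > reach && stats::runif(1) < branch_prob) {
          rf <- max(1L, r - reach):min(sz, r + reach)
          cf <- max(1L, cc - reach):min(sz, cc + reach)
          clear <- !any(occ[rf, cf] != 0L & occ[rf, cf] != wid)
          if (clear) {
            turn <- sample(c(-2L, 2L), 1L)
            cdir <- ((dir - 1L + turn) %% 8L) + 1L
            queue[[length(queue) + 1L]] <-
              list(r = r + DIR8[cdir, 1], c = cc + DIR8[cdir, 2], dir = cdir,
                   straight = reach + 1L, parent = wid, fork_step = np)
            n_spawned <- n_spawned + 1L
            steps_since_fork <- 0L
            straight <- max(straight, reach + 1L)  # parent departs straight too
          }
        }
        if (straight > 0L) {
          straight <- straight - 1L
        } else if (steps_since_turn > 4L && stats::runif(1) < turn_prob) {
          # single 45-degree bends with a straight run between them: sharp
          # 90-degree corners thin back with spur artifacts
          dir <- ((dir - 1L + sample(c(-1L, 1L), 1L)) %% 8L) + 1L
          steps_since_turn <- 0L
        }
        r <- r + DIR8[dir, 1]; cc <- cc + DIR8[dir, 2]
        grace <- grace - 1L
      }
      # a child too short to survive dilation + re-thinning as a branch is
      # dropped from the scene entirely (its fork never becomes a junction);
      # its occupancy marks are cleared so it cannot invisibly stop others
      min_len <- if (parent > 0L) reach + 2L else 2L
      if (np >= min_len) {
        paths[[length(paths) + 1L]] <- list(
          px = path[seq_len(np), , drop = FALSE],
          wid = wid, parent = parent, fork_step = fork_step)
      } else if (np >= 1L) {
        occ[path[seq_len(np), , drop = FALSE]] <- 0L
      }
    }
    paths
  })

  # repair pass: the walk's stopping rule can leak in rare corner cases
  # (fork vicinities overlapping later traffic), so enforce the separation
  # invariant outright — truncate any strand that comes within `margin` of a
  # non-parent strand, and drop children orphaned by a truncation. This is
  # deterministic and uses no RNG.
  paths <- local({
    occ2 <- matrix(0L, sz, sz)
    step2 <- matrix(0L, sz, sz)
    kept_len <- integer(0)  # indexed by wid
    out <- list()
    for (rec in paths) {
      pxm <- rec$px
      if (rec$parent > 0L) {
        plen <- if (rec$parent <= length(kept_len)) kept_len[rec$parent] else 0L
        # parent gone, truncated before the fork, or left with a stub arm too
        # short to survive re-thinning: the fork would be unrecoverable
        if (is.na(plen) || plen < rec$fork_step + 6L) next
      }
      cut <- nrow(pxm)
      for (k in seq_len(nrow(pxm))) {
        r <- pxm[k, 1]; cc <- pxm[k, 2]
        r0 <- max(1L, r - margin):min(sz, r + margin)
        c0 <- max(1L, cc - margin):min(sz, cc + margin)
        near <- occ2[r0, c0]
        viol <- (near != 0L & near != rec$wid) |
          (near == rec$wid & step2[r0, c0] <= k - (reach + 2L))
        if (rec$parent > 0L && k <= reach) {
          viol <- viol & !(near == rec$parent &
                             abs(step2[r0, c0] - rec$fork_step) <= reach)
        }
        if (any(viol)) {
          cut <- k - 1L
          break
        }
      }
      if (cut < nrow(pxm)) pxm <- pxm[seq_len(cut), , drop = FALSE]
      min_len <- if (rec$parent > 0L) reach + 2L else 2L
      if (cut < min_len) next
      occ2[pxm] <- rec$wid
      step2[pxm] <- seq_len(cut)
      kept_len[rec$wid] <- cut
      out[[length(out) + 1L]] <- pxm
    }
    out
  })

  # fragmentation: delete contiguous runs from the ordered paths
  if (fragmentation > 0 && length(paths) > 0) {
    paths <- withr::with_seed(derive_seed(seed, "fragment", "runs"), {
      total <- sum(vapply(paths, nrow, 1L))
      target <- round(fragmentation * total)
      keep <- lapply(paths, function(p) rep(TRUE, nrow(p)))
      removed <- 0L
      guard <- 0L
      while (removed < target && guard < 10000L) {
        guard <- guard + 1L
        i <- sample.int(length(paths), 1L)
        alive <- which(keep[[i]])
        if (length(alive) == 0L) next
        start <- alive[sample.int(length(alive), 1L)]
        len <- 3L + stats::rgeom(1L, 1 / 4)
        run <- start:min(start + len - 1L, nrow(paths[[i]]))
        newly <- sum(keep[[i]][run])
        keep[[i]][run] <- FALSE
        removed <- removed + newly
      }
      purrr::map2(paths, keep, function(p, k) p[k, , drop = FALSE])
    })
  }

  center <- matrix(FALSE, sz, sz)
  for (p in paths) if (nrow(p)) center[p] <- TRUE

  # ground truth from the centerline mask, by the package's stated rules
  bp <- junction_clusters(center)
  sm <- skeleton_metrics(binary_mask(center, um_per_pixel = um_per_pixel))

  strands <- dilate_disc(center, strand_width)
  img_px <- matrix(bg_intensity, sz, sz)
  img_px[strands] <- fg_intensity
  if (noise_sd > 0) {
    noise <- withr::with_seed(derive_seed(seed, "noise", "junction"),
                              stats::rnorm(sz * sz, 0, noise_sd))
    img_px <- img_px + matrix(noise, sz, sz)
  }
  img_px <- round(pmin(pmax(img_px, 0), 255))
  img <- gray_image(img_px, um_per_pixel = um_per_pixel,
                    meta = list(phenotype = "junction", seed = seed))
  list(
    image = img,
    truth = list(
      skeleton_mask = binary_mask(center, um_per_pixel = um_per_pixel,
                                  method = "ground-truth"),
      strand_mask = binary_mask(strands, um_per_pixel = um_per_pixel,
                                method = "ground-truth"),
      branch_points = bp,
      n_branch_points = sm$n_branch_points,
      true_strand_length = sm$strand_length_px,
      true_fg_mean = fg_intensity,
      true_bg_mean = bg_intensity,
      paths = paths
    )
  )
}

# rasterize one ellipse; returns index matrix of (row, col) pixels
rasterize_ellipse <- function(cr, cc, a, b, theta, sz) {
  rad <- ceiling(a) + 1L
  rs <- max(1L, floor(cr - rad)):min(sz, ceiling(cr + rad))
  cs <- max(1L, floor(cc - rad)):min(sz, ceiling(cc + rad))
  g <- expand.grid(row = rs, col = cs)
  dy <- g$row - cr; dx <- g$col - cc
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  as.matrix(g[inside, c("row", "col")])
}

# pick the circle/ellipse scale whose rasterized pixel count best matches the
# target area (lattice-point count vs continuous area can otherwise drift)
calibrate_ellipse <- function(cr, cc, area_px, aspect, theta, sz) {
  b0 <- sqrt(area_px / (pi * aspect))
  best <- NULL; best_err <- Inf
  for (f in seq(0.9, 1.1, by = 0.005)) {
    b <- b0 * f; a <- aspect * b
    pxs <- rasterize_ellipse(cr, cc, a, b, theta, sz)
    err <- abs(nrow(pxs) - area_px)
    if (err < best_err) {
      best <- pxs; best_err <- err
    }
    if (err == 0) break
  }
  best
}

#' Simulate a field of labeled cell bodies
#'
#' Emulates neuronal-marker staining: `n_cells` non-overlapping filled
#' ellipses with areas sampled uniformly from `area_range` (µm²) and axis
#' ratios from `aspect_range`, on a uniform background, with optional
#' clipped Gaussian noise. All random draws are made in physical units
#' before placement is attempted, so the same seed renders the same physical
#' scene at any calibration. Each cell's rasterization radius is tuned so
#' the pixel count matches the sampled area closely.
#'
#' @param image_size Image side in pixels (default 256).
#' @param n_cells Number of cells to place (default 25).
#' @param area_range Cell-area bounds in µm² (default `c(60, 120)`).
#' @param aspect_range Ellipse axis-ratio bounds (default `c(1, 1.6)`).
#' @param fg_intensity,bg_intensity Cell and background intensities
#'   (defaults 200 and 40).
#' @param noise_sd Additive Gaussian noise SD (default 0).
#' @param min_gap Minimum centroid separation in pixels (default 4).
#' @param um_per_pixel Calibration (default 1).
#' @param seed RNG seed.
#' @param max_tries Candidate positions attempted per cell before a capacity
#'   error (default 60).
#' @return List with `image` (a [gray_image()]) and `truth`: `object_mask`
#'   (labeled integer matrix), `true_count`, and a `cells` tibble
#'   (label, centroid, target and realized areas).
#' @export
simulate_cell_image <- function(image_size = 256, n_cells = 25,
                                area_range = c(60, 120), aspect_range = c(1, 1.6),
                                fg_intensity = 200, bg_intensity = 40,
                                noise_sd = 0, min_gap = 4, um_per_pixel = 1,
                                seed = 1, max_tries = 60) {
  if (n_cells < 0) tj_abort("param", "`n_cells` must be non-negative.")
  if (any(area_range <= 0)) tj_abort("param", "`area_range` must be positive.")
  sz <- as.integer(image_size)
  field_um <- sz * um_per_pixel
  draws <- withr::with_seed(seed, list(
    area = stats::runif(max(n_cells, 1L), area_range[1], area_range[2]),
    aspect = stats::runif(max(n_cells, 1L), aspect_range[1], aspect_range[2]),
    theta = stats::runif(max(n_cells, 1L), 0, pi),
    # candidate centers in micrometres, a full fixed block per cell so the
    # random stream does not depend on rejection outcomes or resolution
    cand_r = matrix(stats::runif(max(n_cells, 1L) * max_tries, 0, field_um),
                    ncol = max_tries),
    cand_c = matrix(stats::runif(max(n_cells, 1L) * max_tries, 0, field_um),
                    ncol = max_tries)
  ))
  lab <- matrix(0L, sz, sz)
  cells <- list()
  if (n_cells > 0) {
    centroids <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n_cells)) {
      area_px <- draws$area[i] / um_per_pixel^2
      aspect <- draws$aspect[i]
      a_px <- aspect * sqrt(area_px / (pi * aspect))  # semi-major in px
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        cr <- draws$cand_r[i, t] / um_per_pixel
        cc <- draws$cand_c[i, t] / um_per_pixel
        if (cr < a_px + 2 || cr > sz - a_px - 1 ||
            cc < a_px + 2 || cc > sz - a_px - 1) next
        if (nrow(centroids) > 0 &&
            min((centroids[, 1] - cr)^2 + (centroids[, 2] - cc)^2) < min_gap^2) next
        pxs <- calibrate_ellipse(cr, cc, area_px, aspect, draws$theta[i], sz)
        if (is.null(pxs) || nrow(pxs) == 0) next
        # require a clear 1-px moat so 8-connected components stay distinct
        moat <- dilate_disc(`[<-`(matrix(FALSE, sz, sz), pxs, TRUE), 1)
        if (any(lab[moat] != 0L)) next
        lab[pxs] <- i
        centroids <- rbind(centroids, c(cr, cc))
        cells[[i]] <- tibble::tibble(
          label = i, centroid_row = cr, centroid_col = cc,
          target_area_um2 = draws$area[i],
          area_px = nrow(pxs), area_um2 = nrow(pxs) * um_per_pixel^2
        )
        placed <- TRUE
        break
      }
      if (!placed) {
        tj_abort("capacity", sprintf(
          "Could not place cell %d of %d after %d attempts (%d cells placed).",
          i, n_cells, max_tries, i - 1L),
          achieved = i - 1L)
      }
    }
  }
  img_px <- matrix(bg_intensity, sz, sz)
  img_px[lab > 0L] <- fg_intensity
  if (noise_sd > 0) {
    noise <- withr::with_seed(derive_seed(seed, "noise", "cells"),
                              stats::rnorm(sz * sz, 0, noise_sd))
    img_px <- img_px + matrix(noise, sz, sz)
  }
  img_px <- round(pmin(pmax(img_px, 0), 255))
  list(
    image = gray_image(img_px, um_per_pixel = um_per_pixel,
                       meta = list(phenotype = "cells", seed = seed)),
    truth = list(
      object_mask = lab,
      true_count = as.integer(n_cells),
      cells = if (length(cells)) dplyr::bind_rows(cells) else tibble::tibble()
    )
  )
}

#' Simulate a blob-foreground intensity field
#'
#' Fixture generator for the ROI intensity procedure: random discs are laid
#' down until the foreground covers approximately `fg_mask_fraction` of the
#' image, the foreground is set to `fg_mean` over a `bg_mean` background,
#' and clipped rounded Gaussian noise is added. The recorded true means are
#' the pre-noise, pre-clipping intensities; tests use intensities far from
#' the clip boundaries.
#'
#' @param image_size Image side in pixels (default 256).
#' @param fg_mean,bg_mean Foreground and background mean intensities;
#'   `fg_mean > bg_mean` required.
#' @param fg_mask_fraction Target foreground coverage in `[0, 1)` (default 0.2).
#' @param noise_sd Additive Gaussian noise SD (default 0).
#' @param um_per_pixel Calibration (default 1).
#' @param seed RNG seed.
#' @return List with `image` and `truth`: `fg_mask` (a [binary_mask()]),
#'   `true_fg_mean` (`NA` when the foreground is empty), `true_bg_mean`,
#'   `fg_fraction` realized.
#' @export
simulate_intensity_field <- function(image_size = 256, fg_mean = 180,
                                     bg_mean = 30, fg_mask_fraction = 0.2,
                                     noise_sd = 0, um_per_pixel = 1, seed = 1) {
  if (fg_mean <= bg_mean) tj_abort("param", "`fg_mean` must exceed `bg_mean`.")
  if (fg_mask_fraction < 0 || fg_mask_fraction >= 1) {
    tj_abort("param", "`fg_mask_fraction` must be in [0, 1).")
  }
  sz <- as.integer(image_size)
  fg <- matrix(FALSE, sz, sz)
  if (fg_mask_fraction > 0) {
    fg <- withr::with_seed(seed, {
      radius <- max(3, round(sz / 16))
      target <- fg_mask_fraction * sz^2
      guard <- 0L
      while (sum(fg) < target && guard < 5000L) {
        guard <- guard + 1L
        cr <- stats::runif(1, 1, sz); cc <- stats::runif(1, 1, sz)
        rs <- max(1L, floor(cr - radius)):min(sz, ceiling(cr + radius))
        cs <- max(1L, floor(cc - radius)):min(sz, ceiling(cc + radius))
        g <- expand.grid(r = rs, c = cs)
        inside <- (g$r - cr)^2 + (g$c - cc)^2 <= radius^2
        fg[as.matrix(g[inside, ])] <- TRUE
      }
      fg
    })
  }
  img_px <- matrix(bg_mean, sz, sz)
  img_px[fg] <- fg_mean
  if (noise_sd > 0) {
    noise <- withr::with_seed(derive_seed(seed, "noise", "field"),
                              stats::rnorm(sz * sz, 0, noise_sd))
    img_px <- img_px + matrix(noise, sz, sz)
  }
  img_px <- round(pmin(pmax(img_px, 0), 255))
  list(
    image = gray_image(img_px, um_per_pixel = um_per_pixel,
                       meta = list(phenotype = "intensity-field", seed = seed)),
    truth = list(
      fg_mask = binary_mask(fg, um_per_pixel = um_per_pixel,
                            method = "ground-truth"),
      true_fg_mean = if (any(fg)) fg_mean else NA_real_,
      true_bg_mean = bg_mean,
      fg_fraction = mean(fg)
    )
  )
}
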