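half_plane_fixture <- function(side = 256, fg = 100L, bg = 20L) {
  px <- matrix(bg, side, side)
  px[, (side / 2 + 1):side] <- fg
  img <- gray_image(px, um_per_pixel = 1)
  mask <- binary_mask(px == fg, um_per_pixel = 1)
  list(img = img, mask = mask)
}

test_that("rectangles land inside the image, inside/outside the mask, and never overlap within a class", {
  hp <- half_plane_fixture()
  rois <- place_rois(hp$img, hp$mask, seed = 11)
  expect_equal(nrow(rois$rects_fg), 10)
  expect_equal(nrow(rois$rects_bg), 5)
  in_mask <- function(rects, mask, inside) {
    all(vapply(seq_len(nrow(rects)), function(i) {
      block <- mask[rects$row[i]:(rects$row[i] + 6), rects$col[i]:(rects$col[i] + 6)]
      if (inside) all(block == 1L) else all(block == 0L)
    }, TRUE))
  }
  expect_true(in_mask(rois$rects_fg, hp$mask$pixels, inside = TRUE))
  expect_true(in_mask(rois$rects_bg, hp$mask$pixels, inside = FALSE))
  no_overlap <- function(rects) {
    if (nrow(rects) < 2) return(TRUE)
    pairs <- utils::combn(nrow(rects), 2)
    all(apply(pairs, 2, function(p) {
      abs(rects$row[p[1]] - rects$row[p[2]]) >= 7 ||
        abs(rects$col[p[1]] - rects$col[p[2]]) >= 7
    }))
  }
  expect_true(no_overlap(rois$rects_fg))
  expect_true(no_overlap(rois$rects_bg))
  expect_identical(place_rois(hp$img, hp$mask, seed = 11), rois)
})

test_that("infeasible placement raises a typed error naming the class", {
  img <- gray_image(matrix(100L, 64, 64), um_per_pixel = 1)
  all_fg <- binary_mask(matrix(TRUE, 64, 64), um_per_pixel = 1)
  expect_error(place_rois(img, all_fg, seed = 1),
               class = "tjquant_error_infeasible")
  no_fg <- binary_mask(matrix(FALSE, 64, 64), um_per_pixel = 1)
  expect_error(place_rois(img, no_fg, seed = 1),
               class = "tjquant_error_infeasible")
})

test_that("corrected intensity is the exact background-subtracted mean on constant regions", {
  img <- gray_image(matrix(50L, 128, 128), um_per_pixel = 1)
  mask <- binary_mask(cbind(matrix(TRUE, 128, 64), matrix(FALSE, 128, 64)),
                      um_per_pixel = 1)
  res <- measure_intensity(img, place_rois(img, mask, seed = 2))
  expect_equal(res$corrected, 0)
  hp <- half_plane_fixture(fg = 100L, bg = 20L)
  res2 <- measure_intensity(hp$img, place_rois(hp$img, hp$mask, seed = 2))
  expect_equal(res2$corrected, 80)
  expect_equal(res2$corrected, res2$mean_fg - res2$mean_bg)
})

test_that("the ROI estimator tracks ground truth contrast on noisy synthetic fields", {
  vals <- vapply(1:20, function(s) {
    f <- simulate_intensity_field(image_size = 192, fg_mean = 180, bg_mean = 30,
                                  fg_mask_fraction = 0.2, noise_sd = 5, seed = s)
    measure_intensity(f$image,
                      place_rois(f$image, f$truth$fg_mask, seed = s + 500))$corrected
  }, 1)
  expect_lt(abs(mean(vals) - 150), 2)
})

test_that("on noise-free fields corrected equals the true contrast exactly", {
  for (s in 1:5) {
    f <- simulate_intensity_field(image_size = 128, fg_mean = 170, bg_mean = 40,
                                  fg_mask_fraction = 0.25, noise_sd = 0, seed = s)
    res <- measure_intensity(f$image, place_rois(f$image, f$truth$fg_mask, seed = s))
    expect_identical(res$corrected, 130)
  }
})

test_that("corrected intensity is scale-equivariant", {
  hp <- half_plane_fixture(fg = 90L, bg = 30L)
  r1 <- measure_intensity(hp$img, place_rois(hp$img, hp$mask, seed = 4))
  doubled <- gray_image(hp$img$pixels * 2L, um_per_pixel = 1)
  r2 <- measure_intensity(doubled, place_rois(doubled, hp$mask, seed = 4))
  expect_equal(r2$corrected, 2 * r1$corrected)
})

test_that("quantile foreground mask isolates bright structures and feeds placement", {
  px <- matrix(20L, 40, 40)
  px[5:12, 5:16] <- 200L  # 96 of 1600 px = 6%... use quantile accordingly
  img <- gray_image(px, um_per_pixel = 1)
  m <- auto_foreground_mask(img, quantile = 0.94, min_blob_px = 5)
  expect_identical(m$pixels == 1L, px == 200L)
  # median split on a symmetric bimodal image covers the upper mode
  px2 <- matrix(c(40L, 210L), 32, 32)
  m2 <- auto_foreground_mask(gray_image(px2, um_per_pixel = 1), quantile = 0.5)
  expect_identical(m2$pixels == 1L, px2 == 210L)
  # blob filter can empty the mask, which then defeats placement downstream
  m3 <- auto_foreground_mask(img, quantile = 0.94, min_blob_px = 1e5)
  expect_equal(sum(m3$pixels), 0)
  expect_error(place_rois(img, m3, seed = 1), class = "tjquant_error_infeasible")
  expect_error(auto_foreground_mask(gray_image(matrix(9L, 8, 8), um_per_pixel = 1)),
               class = "tjquant_error_degenerate")
})
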