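test_that("skeletonization thins a wide bar to one pixel, keeps thin diagonals, and maps empty to empty", {
  expect_equal(sum(skeletonize_mask(binary_mask(matrix(FALSE, 10, 10)))$pixels), 0)
  bar <- matrix(FALSE, 20, 40); bar[8:12, 5:35] <- TRUE
  sk <- skeletonize_mask(binary_mask(bar))$pixels
  hit <- which(sk == 1L, arr.ind = TRUE)
  expect_equal(length(unique(hit[, 1])), 1)       # one-pixel-wide line
  expect_lte(abs(min(hit[, 2]) - 5), 3)           # end effects only
  expect_lte(abs(max(hit[, 2]) - 35), 3)
  dg <- matrix(FALSE, 12, 12); dg[cbind(2:11, 2:11)] <- TRUE
  expect_identical(skeletonize_mask(binary_mask(dg))$pixels == 1L, dg)
})

test_that("strand length, branch points and complexity are exact on worked cases", {
  line <- skeleton_metrics(binary_mask(line_mask(11)))
  expect_equal(line$strand_length_px, 10)
  expect_equal(line$n_branch_points, 0L)
  expect_equal(line$complexity_index, 0)

  cross <- skeleton_metrics(binary_mask(cross_mask(11)))
  expect_equal(cross$strand_length_px, 20)
  expect_equal(cross$n_branch_points, 1L)   # adjacent branch pixels merge
  expect_equal(cross$complexity_index, 1 / 20)

  diag_line <- matrix(FALSE, 10, 10); diag_line[cbind(2:8, 2:8)] <- TRUE
  expect_equal(skeleton_metrics(binary_mask(diag_line))$strand_length_px, 6 * sqrt(2))

  empty <- skeleton_metrics(binary_mask(matrix(FALSE, 5, 5)))
  expect_equal(empty$strand_length_px, 0)
  expect_true(is.na(empty$complexity_index))
})

test_that("raw pixel-count length metric is available for ImageJ-style reproduction", {
  expect_equal(skeleton_metrics(binary_mask(line_mask(11)), length_metric = "count")$strand_length_px, 11)
})

test_that("object statistics respect connectivity and satisfy the mean-size identity", {
  m <- matrix(FALSE, 20, 30)
  m[2:6, 2:3] <- TRUE    # 10 px
  m[10:13, 5:9] <- TRUE  # 20 px
  m[2:7, 20:24] <- TRUE  # 30 px
  os <- object_stats(binary_mask(m))
  expect_equal(os$n_objects, 3L)
  expect_equal(os$mean_object_size, 20)
  expect_equal(os$mean_object_size * os$n_objects, os$total_size_px)

  full <- object_stats(binary_mask(matrix(TRUE, 7, 9)))
  expect_equal(full$n_objects, 1L)
  expect_equal(full$mean_object_size, 63)

  two <- matrix(FALSE, 4, 4); two[2, 2] <- TRUE; two[3, 3] <- TRUE
  expect_equal(object_stats(binary_mask(two), connectivity = 8)$n_objects, 1L)
  expect_equal(object_stats(binary_mask(two), connectivity = 4)$n_objects, 2L)

  expect_true(is.na(object_stats(binary_mask(matrix(FALSE, 3, 3)))$mean_object_size))
})

test_that("entropy matches closed forms: constant 0, uniform 8, binary split", {
  expect_equal(image_entropy(gray_image(matrix(42L, 16, 16), um_per_pixel = 1)), 0)
  u <- gray_image(matrix(rep(0:255, 8), 32, 64), um_per_pixel = 1)
  expect_identical(image_entropy(u), 8)
  px <- matrix(0L, 16, 16); px[1:4, ] <- 200L  # 25% / 75%
  h <- image_entropy(gray_image(px, um_per_pixel = 1))
  expect_equal(h, -0.25 * log2(0.25) - 0.75 * log2(0.75), tolerance = 1e-12)
})

test_that("entropy is a histogram statistic: permutation-invariant, bounded by occupied bins", {
  for (s in 1:5) {
    img <- random_gray(24, 24, seed = s)
    shuffled <- withr::with_seed(s + 100,
      gray_image(matrix(sample(img$pixels), 24, 24), um_per_pixel = 1))
    expect_identical(image_entropy(img), image_entropy(shuffled))
    occupied <- sum(gray_histogram(img)$p > 0)
    expect_lte(image_entropy(img), log2(occupied) + 1e-12)
    expect_equal(sum(gray_histogram(img)$p), 1)
  }
})

test_that("entropy agrees with an independent tabulation oracle on random images and coarse bins", {
  for (s in 1:10) {
    img <- random_gray(64, 64, seed = s)
    expect_equal(image_entropy(img), entropy_oracle(img$pixels), tolerance = 1e-12)
    expect_equal(image_entropy(img, n_bins = 16),
                 entropy_oracle(img$pixels, n_bins = 16), tolerance = 1e-12)
  }
})

test_that("junction_metrics bundles the per-image junction statistics", {
  sim <- simulate_junction_image(image_size = 128, n_seeds = 2, noise_sd = 0, seed = 3)
  jm <- junction_metrics(sim$image)
  expect_named(jm, c("strand_length_px", "n_branch_points", "complexity_index",
                     "n_objects", "mean_object_size", "entropy_bits"))
  expect_gt(jm$strand_length_px, 0)
  expect_equal(jm$complexity_index, jm$n_branch_points / jm$strand_length_px)
})
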