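test_that("generators are bit-reproducible given the same parameters and seed", {
  a <- simulate_junction_image(image_size = 160, seed = 7)
  b <- simulate_junction_image(image_size = 160, seed = 7)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$branch_points, b$truth$branch_points)
  c1 <- simulate_cell_image(image_size = 160, n_cells = 10, seed = 7)
  c2 <- simulate_cell_image(image_size = 160, n_cells = 10, seed = 7)
  expect_identical(c1$image$pixels, c2$image$pixels)
  expect_identical(c1$truth$object_mask, c2$truth$object_mask)
  f1 <- simulate_intensity_field(image_size = 96, noise_sd = 4, seed = 7)
  f2 <- simulate_intensity_field(image_size = 96, noise_sd = 4, seed = 7)
  expect_identical(f1$image$pixels, f2$image$pixels)
})

test_that("junction generator honours its parameter contracts", {
  expect_error(simulate_junction_image(fragmentation = 1.2), class = "tjquant_error_param")
  expect_error(simulate_junction_image(fg_intensity = 20, bg_intensity = 30),
               class = "tjquant_error_param")
  # a single straight non-branching path has no branch points
  st <- simulate_junction_image(image_size = 128, n_seeds = 1, branch_prob = 0,
                                turn_prob = 0, noise_sd = 0, seed = 2)
  expect_equal(st$truth$n_branch_points, 0L)
  # full fragmentation leaves pure background
  f1 <- simulate_junction_image(image_size = 128, fragmentation = 1,
                                noise_sd = 0, bg_intensity = 30, seed = 3)
  expect_true(all(f1$image$pixels == 30L))
  expect_equal(sum(f1$truth$skeleton_mask$pixels), 0)
})

test_that("junction ground truth is self-consistent under the 8-neighbor junction rule", {
  for (s in 1:5) {
    sim <- simulate_junction_image(image_size = 192, fragmentation = 0,
                                   noise_sd = 0, seed = s)
    redone <- skeleton_metrics(sim$truth$skeleton_mask)
    expect_identical(redone$n_branch_points, sim$truth$n_branch_points)
    expect_identical(attr(redone, "junctions"), sim$truth$branch_points)
    expect_equal(redone$strand_length_px, sim$truth$true_strand_length)
    # branch points lie on the centerline mask
    bp <- sim$truth$branch_points
    if (nrow(bp)) {
      expect_true(all(sim$truth$skeleton_mask$pixels[cbind(bp$row, bp$col)] == 1L))
    }
  }
})

test_that("mean realized strand length decreases with fragmentation", {
  mean_len <- function(fr) {
    mean(vapply(1:20, function(s) {
      simulate_junction_image(image_size = 160, fragmentation = fr,
                              noise_sd = 0, seed = s)$truth$true_strand_length
    }, 1))
  }
  lens <- vapply(c(0, 0.3, 0.6), mean_len, 1)
  expect_true(lens[1] > lens[2] && lens[2] > lens[3])
})

test_that("cell fields place the requested count with calibrated areas", {
  z <- simulate_cell_image(image_size = 96, n_cells = 0, noise_sd = 0, seed = 1)
  expect_equal(z$truth$true_count, 0L)
  expect_equal(length(unique(as.vector(z$image$pixels))), 1L)

  s5 <- simulate_cell_image(image_size = 192, n_cells = 5, noise_sd = 0, seed = 2)
  expect_equal(max(s5$truth$object_mask), 5L)
  expect_equal(s5$truth$true_count, 5L)
  expect_equal(dplyr::n_distinct(s5$truth$object_mask[s5$truth$object_mask > 0]), 5L)

  # circular cells: rasterized region area tracks the sampled target area
  circ <- simulate_cell_image(image_size = 256, n_cells = 10,
                              aspect_range = c(1, 1), noise_sd = 0, seed = 4)
  expect_true(all(abs(circ$truth$cells$area_px - circ$truth$cells$target_area_um2) <= 2))
})

test_that("impossible cell placement raises a capacity error reporting progress", {
  err <- expect_error(
    simulate_cell_image(image_size = 48, n_cells = 60, area_range = c(80, 120),
                        noise_sd = 0, seed = 1, max_tries = 10),
    class = "tjquant_error_capacity")
  expect_true(err$achieved < 60)
})

test_that("intensity fields honour the stated means and coverage", {
  f <- simulate_intensity_field(image_size = 128, fg_mean = 100, bg_mean = 20,
                                fg_mask_fraction = 0.25, noise_sd = 0, seed = 6)
  fg <- f$truth$fg_mask$pixels == 1L
  expect_true(all(f$image$pixels[fg] == 100L))
  expect_true(all(f$image$pixels[!fg] == 20L))
  expect_equal(f$truth$true_fg_mean - f$truth$true_bg_mean, 80)
  expect_equal(f$truth$fg_fraction, 0.25, tolerance = 0.08)

  empty <- simulate_intensity_field(image_size = 64, fg_mask_fraction = 0,
                                    noise_sd = 0, seed = 1)
  expect_true(is.na(empty$truth$true_fg_mean))
  expect_true(all(empty$image$pixels == empty$truth$true_bg_mean))
})
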