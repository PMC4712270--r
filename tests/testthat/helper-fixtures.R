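# in-code fixtures shared across test files

# horizontal line of n pixels centred in a square mask
line_mask <- function(n = 11, pad = 4) {
  side <- n + 2 * pad
  m <- matrix(FALSE, side, side)
  m[pad + ceiling(n / 2), pad + seq_len(n)] <- TRUE
  m
}

# "+" cross: two n-pixel lines sharing their centre pixel (2n - 1 pixels)
cross_mask <- function(n = 11, pad = 4) {
  side <- n + 2 * pad
  m <- matrix(FALSE, side, side)
  mid <- pad + ceiling(n / 2)
  m[mid, pad + seq_len(n)] <- TRUE
  m[pad + seq_len(n), mid] <- TRUE
  m
}

# brute-force entropy oracle: direct tabulation over gray levels, no binning
# code shared with the implementation
entropy_oracle <- function(px, n_bins = 256) {
  width <- 256 / n_bins
  idx <- pmin(floor(px / width), n_bins - 1)
  p <- as.vector(table(idx)) / length(px)
  -sum(p * log2(p))
}

random_gray <- function(h, w, seed) {
  withr::with_seed(seed, gray_image(matrix(sample(0L:255L, h * w, TRUE), h, w),
                                    um_per_pixel = 1))
}

# well-formed EM annotation table: n images per capillary, fixed categories
em_fixture <- function() {
  base <- tidyr::expand_grid(
    region = c("frontal_cortex", "hippocampus"),
    group = c("control", "1d"),
    capillary_id = 1:2,
    image_id = 1:5
  )
  base$luminal_membrane <- rep(c("smooth", "smooth", "smooth", "protrusions", "smooth"), 8)
  base$tight_junction <- rep(c("intact", "intact", "discontinuous", "discontinuous", "intact"), 8)
  base$basal_membrane <- rep(c("intact", "intact", "intact", "intact", "increased_thickness"), 8)
  base$astroglia <- rep(c("intact", "edematous", "intact", "intact", "intact"), 8)
  base
}
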