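---
title: "Morphometry of tight-junction immunostaining: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry of tight-junction immunostaining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tjquant)
```

## The problem

Brain endothelial tight junctions (TJ) appear in claudin-5 and occludin
immunofluorescence as thin, branched strands along vessel walls. Barrier
injury shows up as fragmentation of those strands, loss of branching, and a
less ordered staining pattern, alongside intensity changes of endothelial
and glial markers, altered neuronal density, and categorical ultrastructure
changes visible by electron microscopy. `tjquant` implements the full
measurement chain for this kind of study — per-image metrics, synthetic
ground-truthed test images, and the group-comparison layer — so that every
step that was manual in the original workflow is an explicit, seeded
algorithm.

## Per-image metrics

**Corrected intensity.** `place_rois()` samples ten 7 × 7-pixel foreground
rectangles uniformly among positions fully inside the foreground mask and
five background rectangles fully outside it, without overlap within a
class (so no pixel is double-counted). `measure_intensity()` averages the
per-rectangle mean intensities and subtracts background from foreground.
The published procedure places rectangles by eye; we automate it because
reproducibility demands an algorithmic rule, and we accept a user-supplied
mask to mimic manual workflows. The default automatic mask
(`auto_foreground_mask()`) keeps the brightest `1 − quantile` fraction of
pixels (default quantile 0.95), removes blobs below `min_blob_px` (default
5 px), and excludes a dilated margin (default 5 px) from background
eligibility. On noisy images a pure intensity-quantile mask is scattered
and may admit no 7 × 7 window; for such images pass a thresholded mask
(`threshold_image(img, "otsu")`), which is what `run_pipeline()` does. The
background rectangles are assumed to be the same 7 × 7 size as the
foreground ones; the procedure's description fixes only their count and
equality.

**Complexity index.** The staining mask (Otsu threshold by default —
the binarization rule for this metric is not pinned down by the published
procedure, so it is configurable and logged) is thinned by Zhang–Suen
two-subiteration thinning (`skeletonize_mask()`). Strand length sums
adjacent skeleton-pixel pairs with weight 1 (4-neighbours) and √2
(diagonals); diagonal pairs that merely shortcut a 4-connected corner are
skipped, which makes the length rotation-tolerant. A raw pixel count is
available (`length_metric = "count"`) for strict ImageJ-style
reproduction. Branch points are skeleton pixels with at least three
skeleton neighbours in 8-connectivity; 8-connected clusters of such pixels
are merged into a single junction because raw neighbour counting
over-counts at thick crossings. The complexity index is junctions per unit
strand length; it is `NA` on an empty skeleton. Note that thinning
algorithms shorten blunt strand ends by roughly half the strand width (2–3
px per end for the defaults), which is immaterial for the ratio.

**Mean object size and entropy.** `object_stats()` labels the mask
(8-connectivity by default, 4 available) and reports total size over
object count. `image_entropy()` computes `−Σ p log₂ p` over a 256-bin
histogram of the full gray range; zero-probability bins contribute zero
(the standard limit convention), and the statistic is computed on the
grayscale image, never on the thresholded mask. The source procedure
mentions a Markov model but quotes the zeroth-order Shannon formula of the
gray-level histogram; the quoted formula is what is implemented.

**Cell density.** `detect_particles()` labels the 1-bit image, measures
area (pixel count × calibration²) and perimeter by boundary tracing
(chain code of the traced contour, diagonal steps √2 — the estimator is
stated because circularity depends on it; it puts a rasterized disk of
radius 10 px at circularity ≈ 0.92). "Particles larger than 50 µm²" is
read as a strict inequality and is configurable. Rasterization can push
`4πA/P²` slightly above 1, so circularity is clamped to 1 before the
(0, 1) window is applied — the window then excludes nothing by shape, but
it is implemented and configurable because it is part of the published
procedure. Density counts particles whose centroid lies in the region of
interest (centroid rule, to avoid double counting across adjacent fields;
an ROI polygon is optional and the full frame is the default) per 1000 µm².

## The synthetic generators

The study's raw micrographs are not deposited, so the package carries
generators for the three staining phenotypes the analysis assumes; their
defaults are the fixed test-bed conditions of the package's own validation.

`simulate_junction_image()` grows strand centerlines as
direction-persistent random walks (single 45° bends, several straight
steps between bends) that fork with probability `branch_prob` per step and
stop at the border or near existing strands. The geometry is constrained so
that the scene is *identifiable*: strands keep a minimum separation of
`2·strand_width + 2` px from anything that is not their own fork
vicinity, forks occur only on straight runs away from borders and foreign
strands, both arms leave a fork straight, walks may never approach their
own older path, and a deterministic repair pass prunes the rare walk that
violates separation plus any child orphaned by pruning. Under these
constraints thresholding and re-skeletonizing the rendered image recovers
the ground-truth junction count exactly, which is what makes the
generator-oracle tests sharp rather than approximate. Fragmentation
deletes contiguous runs (geometric lengths, mean ≈ 6 px) from the ordered
centerline paths before dilation — gaps, not salt-and-pepper noise —
mimicking discontinuous staining. Ground truth (branch points, strand
length) is computed from the centerline mask by the same published
definitions the detector uses, but on the *undilated, noise-free*
centerlines, so recovery through rendering, thresholding and re-thinning
is a genuine round trip rather than a shared code path. Defaults (256 px,
4 seed vessels, fork probability 0.05, strand dilation radius 1,
intensities 180/30, noise SD 8) give a few dozen junctions per image —
a realistic density for capillary-wall junction networks at this scale.

`simulate_cell_image()` places non-overlapping ellipses with areas uniform
in 60–120 µm² and axis ratios 1–1.6 (defaults chosen as plausible
neuron-soma cross sections at 1 µm/px). All random draws are made in
physical units with a fixed per-cell budget of candidate positions, so one
seed renders the same physical scene at any resolution — that is what the
calibration-covariance test exercises. Each ellipse's rasterization radius
is tuned over a fine grid so the pixel count matches the sampled target
area (within ~2 px²). A placement that exhausts its candidate budget
raises a capacity error reporting how many cells fit.

`simulate_intensity_field()` lays random discs until a target foreground
fraction is covered, then composes two intensity levels plus optional
Gaussian noise (clipped to [0, 255] and rounded; recorded true means are
pre-clipping, and tests keep intensities far from the clip boundaries so
clipping bias is nil).

What the generators do *not* emulate: optics (no point-spread function),
uneven illumination, out-of-focus light, 3-D vessel geometry, touching
cells, or autofluorescence. Passing tests therefore show the measurement
chain is correct on images whose structure matches its assumptions; they
do not certify performance on real, artifact-laden micrographs.

## The statistics layer

The gate ("KS normality test" in the source, implemented as the
Lilliefors-corrected Kolmogorov–Smirnov test because population mean and
SD are unknown a priori; Shapiro–Wilk is available via `gate = "shapiro"`)
is applied per group, and the parametric branch is taken only if *no*
group rejects at α = 0.05 — the conservative reading of a procedure whose
granularity is not stated. Groups too small to test (n < 5 for
Lilliefors, which is the test's own minimum, n < 3 for Shapiro–Wilk) or
with zero variance force the rank branch with a warning.

The parametric branch is one-way ANOVA with all-pairs t-tests on the
pooled error variance, Bonferroni-adjusted over the C(k, 2) pairs; on two
groups this reduces exactly to the pooled t-test (F = t²). The rank branch
is Kruskal–Wallis with mid-ranks and the standard tie correction, followed
by Dunn's all-pairs z-tests; Dunn's multiplicity adjustment is
Bonferroni-style over all pairs, the common default where the source names
only "Dunn's multiple comparison tests". Some figure legends of the source
read "ANOVA followed by Kruskal–Wallis"; the package treats Kruskal–Wallis
as *replacing* ANOVA on the rank branch, which is the only coherent
reading. Percent-of-control rescales by the control-group mean (sign
preserved; a zero control mean is an error), and stars follow the
conventional cuts.

Under a 2000-replicate Gaussian null of the study's 4-group, n = 10
design, the gated workflow's familywise error (any significant pair) stays
at or below 0.05 plus simulation error; the acceptance script recomputes
this rate.

## Ultrastructure tally

Annotations are one row per analyzed image with a capillary identifier and
four closed-vocabulary features. Percentages are reported per
region × group × feature with exact fractions retained beside the
integer-rounded percentages the report layout uses. The published table
does not state whether denominators are images or capillaries; the package
defaults to image-level denominators (which best explain non-integer-ratio
percentages given the reported image counts) and offers capillary-level
ones, collapsing each capillary to its majority category with ties going
to the first category in vocabulary order.

## Numerical and interface conventions

- Coordinates are `(row, col)`, 1-based in R code, origin top-left;
  masks carry their source calibration.
- Grayscale conversion of RGB input uses ITU-R BT.601 weights
  (0.299/0.587/0.114, rounded); single-marker channels are effectively
  monochrome so the choice is immaterial, but it is fixed and documented.
- 16-bit TIFF input is linearly rescaled so 0 → 0 and 65535 → 255.
- Thresholds are exclusive: a pixel must exceed the threshold to be
  foreground; the applied threshold is recorded in the mask's provenance.
- Missing calibration defaults to 1 µm/pixel with a warning so pure-pixel
  workflows still run.
- Every stochastic operation takes an explicit seed and runs inside
  `withr::with_seed()`; nothing touches the global RNG state. Pipeline
  child seeds are a stable polynomial hash of (master seed, module,
  image id), so adding images never perturbs existing ones.
- The pipeline and all generators are byte-deterministic: identical
  configuration and master seed reproduce identical CSV outputs.

Problem sizes used by the test-bed: 256-px synthetic images (the study's
nominal 512-px frames carry no additional structure for these metrics),
20 seeds per monotonicity or recovery check, 100 seeds for estimator-bias
checks, and 2000 replicates for the null simulation of the statistics
layer.

## Known limitations

- The ROI procedure requires structures at least as wide as the rectangle
  (7 px); on thin-strand images the foreground class is infeasible by
  construction and the placement raises a typed error rather than
  silently degrading.
- The quantile-based automatic mask assumes noise-free or lightly noisy
  staining; noisy images should use a thresholded mask for placement.
- Thinning-based strand length underestimates blunt strand ends by
  roughly the strand half-width per end.
- The EM module tallies human annotations; it does not analyze raw
  electron micrographs.
- Per-image values are treated as independent in the statistics layer, as
  in the study design; animal-level clustering is out of scope.
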