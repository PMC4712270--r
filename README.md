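# tjquant

Quantitative morphometry of blood–brain barrier (BBB) immunostaining for
studies of stress-induced barrier change. The package implements, as tested
and reusable R functions, the image-analysis and statistics procedures used
to quantify how restraint stress remodels brain capillaries: the staining
pattern of the tight-junction (TJ) proteins claudin-5 and occludin, the
fluorescence intensity of endothelial and glial markers (GLUT-1, GFAP),
neuronal density from NeuN staining, and categorical electron-microscopy
scores of capillary ultrastructure.

It is aimed at microscopy labs that want these semiquantitative procedures
to be reproducible: every manual step of the published workflow (rectangle
placement, thresholding, particle filtering) is replaced by a seeded,
documented algorithm, and ground-truthed synthetic image generators make
every metric testable without any real micrograph.

## The metrics

For a grayscale 8-bit image `I` (512 × 512 px nominal, calibrated in
µm/pixel):

- **Corrected fluorescence intensity.** Ten 7 × 7-px rectangles are placed
  at random on immunolabeled structures and five on unstained background;
  `corrected = mean_fg − mean_bg`, the background-subtracted mean
  intensity per pixel.
- **Complexity index** of the TJ network. The thresholded staining mask is
  thinned to one-pixel strands; with `B` the number of branch points
  (skeleton pixels with ≥ 3 skeleton neighbours, adjacent branch pixels
  merged into one junction) and `L` the strand length (step weights 1 and
  √2), `complexity = B / L`. Lower values mean a less-branched, fragmented
  junction network.
- **Mean object size**: total foreground area divided by the number of
  8-connected components of the mask.
- **Image entropy**: `H = −Σ p log₂ p` over the 256-bin gray-level
  histogram, in bits (0 for a constant image, 8 for a uniform one). Higher
  entropy means a less ordered staining pattern.
- **Cell density**: particles of the thresholded image with area > 50 µm²
  and circularity `4πA/P²` in (0, 1] (clamped), counted per 1000 µm².
- **Ultrastructure tally**: per-capillary/per-image categorical annotations
  (luminal membrane, tight junctions, basal membrane, astroglial endfeet)
  aggregated into percentage tables by region × group.

Group comparison follows the study design: a Kolmogorov–Smirnov
(Lilliefors) normality gate chooses between one-way ANOVA with Bonferroni
post-hoc tests and Kruskal–Wallis with Dunn's tests; results are reported
as mean ± SEM in percent of the unstressed control group with `*`/`**`/`***`
stars at p < 0.05/0.01/0.001.

## Worked example

```r
library(tjquant)

# a synthetic claudin-5-like image: branched strands, 20% fragmentation
sim <- simulate_junction_image(image_size = 256, branch_prob = 0.05,
                               fragmentation = 0.2, noise_sd = 8, seed = 42)
junction_metrics(sim$image)
#>   strand_length_px n_branch_points complexity_index n_objects mean_object_size entropy_bits
#> 1             2277              26          0.01142        73            114.6          5.6
```

2277 px of junction strands carry 26 branch points — a complexity index of
0.011 junctions per pixel of strand; the staining histogram has 5.6 bits of
entropy. Group tables of such per-image rows go through the statistics
layer:

```r
d <- data.frame(group = rep(c("control", "1d", "3d", "21d"), each = 8),
                value = withr::with_seed(5, rnorm(32, rep(c(100, 92, 80, 85), each = 8), 6)))
fit <- compare_groups(d, "value", "group")
glance(fit)
#>       branch        method statistic df1 df2  p_value n_groups n_obs alpha
#> 1 parametric one-way ANOVA      13.4   3  28 1.29e-05        4    32  0.05
report_figure_table(fit)
#>     group n pct_mean pct_sem p_adj_vs_control stars
#> 1 control 8    100.0    2.29               NA
#> 2      1d 8     90.8    1.62         2.83e-02     *
#> 3      3d 8     81.3    2.47         5.68e-06   ***
#> 4     21d 8     87.9    1.99         2.34e-03    **
```

The gate accepted normality, the omnibus ANOVA is significant, and each
stressed group differs from control after Bonferroni adjustment — the
format of the study's figures. Ultrastructure annotations tally the same
way:

```r
ann <- validate_annotations(system.file("extdata", "example_annotations.csv",
                                        package = "tjquant"))
em_table_wide(tally_ultrastructure(ann))
#>        region        feature      category 1d 21d 3d control
#> 2 hippocampus       n_images         count 12  12 12      12
#> 3 hippocampus tight_junction        intact 33  67 42     100
#> 4 hippocampus tight_junction discontinuous 67  33 58       0
#> ...
```

`run_pipeline()` chains simulate → measure → normalize → test into one
seeded run that writes tidy CSVs and a provenance file; rerunning an
identical configuration reproduces every output byte for byte.

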