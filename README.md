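# ColocProx

Quantification of protein recruitment to an organelle network in
two-channel confocal images — for example, a small GTPase relocalizing to
depolarized mitochondria. Classic pixel-overlap measures miss biology in
which the protein sits *next to* the organelle (rings around mitochondria,
adjacent puncta) rather than directly on it. `ColocProx` implements two
complementary statistics on segmented binary masks:

- **Percent overlap.** With masks $A$ (e.g. mitochondria) and $B$ (protein),

  $$\mathrm{overlap} = \frac{|A \wedge B|}{|A \vee B|} \in [0, 1],$$

  the pixel count of the logical AND over the logical OR (the Jaccard
  index of the two segmentations), reported as a percentage. 1 means
  complete overlap, 0 means none.

- **Proximity index.** The masks are averaged per pixel (1 where both
  structures exist, 0.5 where one does, 0 where neither), then a
  $2^k \times 2^k$ window ($2 \le k \le 10$) sweeps the averaged image
  from top left to bottom right. In each window with foreground counts
  $c_A, c_B$, the *ratio factor* $\min(c_A/c_B,\, c_B/c_A)$ (0 if either
  count is 0) multiplies every pixel, and the mean of the non-zero
  weighted pixels is that window's index. The image's index is the sum of
  the window indices divided by the number of windows with a non-zero
  index. It lies in $[0,1]$: 1 for completely overlapping structures, 0
  for no similarity or an absent channel. Unlike the overlap it rewards
  structures that share a window without sharing pixels, at the
  granularity set by the window size; window 64 ($k=6$) is the default.

Around the statistics the package provides the full pipeline: TIFF
input/output, median + white top-hat preprocessing, threshold segmentation
(Otsu / fixed / quantile), per-cell ROI restriction, a window-size sweep
that picks the $k$ separating treatment groups most widely, a batch driver
with tidy per-image tables and group mean ± SEM summaries, and a synthetic
scene generator with ground-truth masks that makes every stage testable
without microscope data. Hypothesis testing is deliberately left to
downstream tools; the pipeline exports the per-image tables.

## Worked example

Render a scene in which the protein forms rings *around* the mitochondria
(no direct overlap), segment both channels, and compare the two
statistics:

```r
library(ColocProx)

scene <- generateScene(SceneConfig(proteinMode = "mito_ring", seed = 42))
masks <- segmentPair(sceneImage(scene), "mito", "protein")
masks$mito
#> BinaryMask: 256 x 256 px, 12351 foreground px, channel 'mito', threshold 82.494

percentOverlap(masks$mito, masks$protein)
#> OverlapResult: common 2641 / union 24637 = 0.1072 (10.72%)

proximityIndex(masks$mito, masks$protein)
#> ProximityResult: window 64 px (k = 6), index 0.4075 over 16 non-zero window(s) of 16
```

The ring geometry overlaps the network on barely 11% of the union — mostly
PSF blur at the mask boundary — yet the proximity index is 0.41 because
ring and network occupy the same 64-px windows with similar pixel counts.
That gap between the two numbers is exactly the adjacent-recruitment
signal the index is designed to capture.

The synthetic benchmark runs the whole pipeline on two matched groups
(protein on mitochondria vs on the plasma membrane) and sweeps the window
size:

```r
bm <- runSyntheticBenchmark(baseSeed = 1, nPerGroup = 4, imageSize = 128)
print(bm$summaries, digits = 3)
#>         group n mean_proximity sem_proximity mean_overlap_percent sem_overlap_percent
#> 1 colocalized 4          0.960       0.00288                93.72               0.214
#> 2     control 4          0.144       0.00357                 6.99               1.190
show(bm$sweep)
#> SweepResult: selected k = 7 (window 128 px), separation 0.82632
```

A shell entry point with `analyze`, `simulate` and `sweep` subcommands is
installed at `inst/scripts/colocprox`; see its header for the run-config
YAML keys.

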