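---
title: "Quantifying organelle-protein colocalization with percent overlap and the proximity index"
author: "ColocProx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying organelle-protein colocalization with percent overlap and the proximity index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ColocProx)
```

## The measurement problem

When a cytosolic protein is recruited to an organelle, confocal imaging
shows several distinct geometries: direct colocalization on the organelle,
ring-like shells around it, or puncta sitting just beside it. A
pixel-coincidence statistic treats the last two as "no colocalization"
even though they are the biologically interesting signal. `ColocProx`
therefore computes two statistics on segmented binary masks: the percent
overlap, which is strict pixel coincidence, and the proximity index, which
credits two structures for occupying the same neighbourhood with
comparable amounts of signal.

Both statistics operate on binary masks, so everything upstream —
filtering and thresholding — is part of the measurement and is kept
explicit and logged.

## The model

### Percent overlap

For masks $A$ and $B$ on the same grid,
$\mathrm{overlap} = |A \wedge B| / |A \vee B|$, i.e. the Jaccard index,
times 100 when reported as a percentage. It is symmetric, independent of
window size, equals 1 only when the masks coincide and 0 only when they
are disjoint. When both masks are empty the ratio is 0/0; we define the
result as 0 and emit a warning, since the input carries no information.

### Proximity index

1. Average the two masks per pixel: 1 where both structures exist, 0.5
   where exactly one does, 0 elsewhere.
2. Sweep a $2^k \times 2^k$ window ($2 \le k \le 10$) over the averaged
   image from top left to bottom right.
3. In each window compute the two count ratios $c_A/c_B$ and $c_B/c_A$ of
   the channels' foreground pixels inside the window and keep the minimum
   (the *ratio factor*, in $[0,1]$). If either count is zero the factor is
   0: a window with only one channel scores nothing, which reproduces the
   global limit that an absent channel yields an index of 0.
4. Multiply every pixel in the window by the ratio factor and average the
   non-zero weighted pixels; this is the window's index (0 for an empty
   window).
5. The image's index is the sum of window indices divided by the number of
   windows with a non-zero index; if no window is non-zero the index is
   defined as 0 (avoiding 0/0).

The index is symmetric and bounded in $[0,1]$. Identical masks give 1 at
every window size. The window size sets the scale of "proximity": at
window 64 two structures up to a few tens of pixels apart can share
windows and score, while at window 4 the index approaches strict
coincidence.

### Reading of "sliding"

The window sweep is implemented as a non-overlapping tiling (stride =
window size) by default. With overlapping strides the denominator "number
of windows with a non-zero index" would count the same image region many
times, making the normalisation ambiguous; the tiling keeps one window per
region and still scans the whole image. The stride is nevertheless
configurable (`ProximityConfig(stride = ...)`) for sensitivity analysis.
Images whose side is not a multiple of the window keep truncated edge
windows (`edgePolicy = "partial"`, the default) so every pixel is scanned;
`"pad"` zero-pads instead — numerically identical, since zero pixels
contribute to neither counts nor the non-zero average — and `"drop"`
discards incomplete windows.

### Window-size selection

`windowSizeSweep()` averages the index per treatment group at each $k$ and
scores each $k$ by the largest absolute difference between two group
means. The selected $k$ maximises this separation, with ties broken toward
the smaller window (finer granularity carries more spatial information at
equal separation). The "widest distinction" criterion is deliberately
simple — a maximum pairwise gap — because the sweep is a design tool, not
an inferential procedure.

## Segmentation

Each channel is median-filtered (square window of side
$2 \cdot \texttt{medianRadius} + 1$, default radius 1) and then
background-corrected with a white top-hat (image minus its grayscale
opening with a disc of radius `tophatRadius`, default 15 px). The median
removes shot noise before the top-hat flattens slowly varying background;
the defaults suit tubular organelles a few pixels wide imaged at roughly
100 nm/px, and both radii are configurable. The top-hat is invariant to a
constant offset, so a fixed threshold after top-hat is offset-invariant
too.

Thresholds in the original workflow this automates were chosen by eye per
image; the package defaults to Otsu's method (maximising between-class
variance over a 256-bin histogram of the channel range) as a reproducible
surrogate, with `fixed` and upper-tail `quantile` overrides. The realized
threshold is stored on every mask and written to the run log, so any
segmentation can be reconstructed. A constant channel has no Otsu
threshold; it yields an empty mask plus a warning rather than an error, so
one blank channel does not abort a batch. An optional per-cell ROI zeroes
pixels outside the region after filtering and before thresholding.

## Parameters at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| `medianRadius` | 1 | px | 3×3 median suppresses single-pixel noise without eroding 3-px tubules |
| `tophatRadius` | 15 | px | disc larger than any tubule cross-section, smaller than background variation |
| threshold method | Otsu | — | reproducible stand-in for manual per-image levels |
| `k` | 6 (window 64) | — | the granularity adopted for the mitochondria-recruitment analyses |
| `stride` | $2^k$ | px | non-overlapping tiling keeps the window-count denominator well defined |
| `edgePolicy` | partial | — | every pixel is scanned; pad is numerically identical |

## The synthetic generator

No raw imaging data accompanies the analyses this package automates, so
the generator is the test bed: it renders two-channel scenes with known
ground truth. The cell is a filled ellipse covering ~60% of the frame.
Mitochondria are either a tubular network — persistent random walks inside
the cell, dilated to ~3 px width — or fragmented perinuclear clusters of
small discs around a nucleus-offset centre. The protein channel is drawn
in one of five geometries: membrane annulus, random cytosolic puncta, a
fraction `colocFraction` of pixels sampled from the mitochondrial mask
(remainder as puncta), a ring hugging the mitochondria, or puncta confined
to a band just outside them. The pattern is then shifted horizontally by
`displacement` pixels with toroidal wrap, which conserves its area.

Rendering scales each binary pattern to peak intensity 200, convolves with
a Gaussian PSF (`psfSigma` 1 px, the scale of a confocal PSF at ~100
nm/px), adds a linear background ramp (peak 20, i.e. 10% of signal) and
applies Poisson-like shot noise plus Gaussian read noise, both gained by
`noiseScale` (default 5; 0 disables noise). Intensities are quantised to
16-bit integers, so written scenes round-trip bit-exactly through TIFF.

Two design points matter for the generator's invariants:

- **Coupled sampling.** All random draws happen in a fixed order — the
  mitochondria first, then the full permutation of candidate on-mito
  pixels and the full set of candidate puncta — and `colocFraction` or
  `displacement` merely select from them. Scenes differing only in those
  parameters therefore share everything else, which makes percent overlap
  exactly non-decreasing in `colocFraction` (the on-mito prefix grows
  while the puncta set shrinks, nested both ways) and lets the proximity
  index decay smoothly with displacement.
- **Field size and density.** The default scene is 256×256 px with 24
  tubules, i.e. a 4×4 tiling of 64-px windows and a network dense enough
  that the spatial autocorrelation decays smoothly out to the largest
  displacement exercised (32 px). On small sparse fields the window-64
  index sits on a noisy floor at large shifts and monotone decay is a
  coin flip; the defaults were chosen so the decay is a property of the
  geometry, not of a lucky seed.

What the generator does **not** emulate: photon-physics detail, 3D PSFs,
chromatic shift, cell-to-cell morphology variation, or touching cells.
Passing tests on these scenes therefore demonstrate correctness of the
measurement pipeline and its stated invariants — they do not validate
biological conclusions on real images, where segmentation quality is the
dominant uncertainty.

## Numerical choices

- The per-window quantities are computed from summed-area tables of the
  two masks and their union: within a window the mean of the non-zero
  averaged pixels equals $(c_A + c_B) / (2\,|A \cup B|)$, so no per-pixel
  loop is needed. The test suite checks this engine against a naive
  window-by-window reference to $10^{-12}$ on random masks.
- The morphology and median backends operate on intensities in $[0,1]$;
  the package rescales by the channel maximum around each call. Grayscale
  opening commutes with positive scaling, so the top-hat is exact up to
  floating-point rounding; the median filter quantises to $2^{16}$ levels
  of the channel range, a relative error below $2 \times 10^{-5}$.
- Integer TIFFs are read at native scale (no division by the bit-depth
  maximum), so thresholds are in raw intensity units; interleaved RGB
  planes are split into three channels in R, G, B order and restored to
  native scale.
- Group summaries report the standard error of the mean as sample SD /
  $\sqrt{n}$; a single-image group has an undefined SEM (`NA`), not 0.

## Problem sizes used in the test suite

The packaged checks run on desk-scale inputs chosen to exercise every code
path: 64×64 to 128×128 random masks for the oracle-equivalence and
analytic-limit properties (200 random pairs), default 256×256 scenes for
the generator invariants, and a 10-vs-10 scene benchmark (protein on
mitochondria vs on the membrane) for the end-to-end group-separation and
window-sweep determinism checks. The benchmark sweep scans $k = 2..8$; the
upper half of the nominal $k \le 10$ range needs fields of at least
1024 px, larger than the default study scenes, and adds no discrimination
at this field size.

## Limitations

- Global thresholding assumes reasonably uniform staining within a
  channel after top-hat; heavily vignetted fields need an ROI or a
  quantile threshold.
- The proximity index depends on the window size by construction; values
  are comparable only at equal $k$, which is why the sweep and the
  reported `window_size` column exist.
- The index treats the two channels symmetrically; it does not distinguish
  "protein around mitochondria" from "mitochondria around protein".
- Statistical comparison between groups (ANOVA, multiple-comparison
  corrections) is out of scope; export `results.csv` to your preferred
  framework.
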