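---
title: "Texture descriptors for leaf-epidermis identification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture descriptors for leaf-epidermis identification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidermtex)
```

## The problem

Dissociated leaf epidermis, imaged under an optical microscope, shows a
characteristic spatial pattern: a mosaic of pavement cells interrupted by
stomatal complexes whose density, size and orientation vary between
species. `epidermtex` treats species identification as a texture
classification problem: each grayscale image is summarized by a numeric
descriptor of its intensity pattern, and a classifier assigns species
labels under stratified cross-validation. The alternative it is compared
against is the conventional morphometric route — manually measured
stomatal density, guard-cell length and stomatal-complex width — which
this package consumes as a three-column trait table.

The central scientific question the evaluation protocols address is
robustness to *phenotypic plasticity*: individuals of one species grown
in different environments (say a gallery forest versus a marsh) shift
their stomatal traits, so a method keyed to those traits can fail on
material from an unseen environment, while descriptors of the overall
epidermal texture may not.

## Preprocessing

Images are converted to grayscale (BT.601 luma weights 0.299, 0.587,
0.114 for RGB input — the weights are conventional; nothing downstream
depends on the exact choice) and contrast-stretched so that 1% of the
pixel mass saturates at each end of the 8-bit range. With `n` pixels and
`k = floor(0.01 n)`, the stretch limits are the `(k+1)`-th smallest and
largest intensities and each pixel maps by
`round((p - lo) * 255 / (hi - lo))`, clipped to `[0, 255]`. The
quantile is a nearest-rank rule on the sorted pixel multiset: it makes
"at most 1% strictly outside the limits" exact up to intensity ties, and
it keeps the operation idempotent to within one gray level. A constant
image has `hi == lo`; it passes through unchanged with a warning rather
than erroring, so degenerate synthetic edge cases flow through the
pipeline.

## The four descriptors

**Fourier circular.** The 2-D DFT magnitude `|F(u, v)|` (unnormalized
forward transform) is shifted so zero frequency sits at the central bin
`(floor(M/2), floor(N/2))` in 0-based coordinates. For integer radii
`g = 1, ..., G` with `G = floor(min(M, N)/2) - 1`, the descriptor entry
is the sum of all magnitudes within Euclidean distance `g` of the
center. At the 2080 × 1540 acquisition geometry this gives 769 values.
The sequence is cumulative, hence non-decreasing; the DC bin is included
(the sums run "from the origin" outward, and a cumulative profile with a
constant offset classifies identically).

**Fourier circular-angular.** The same spectrum is partitioned into 64
sectors: eight annuli bounded by radii 3, 6, ..., 24 pixels, crossed
with eight 45° wedges measured counterclockwise from the positive
horizontal-frequency axis. Annuli are half-open, `(r_{k-1}, r_k]`, so
every bin is counted exactly once; the DC bin is excluded because its
angle is undefined. Sector sums are ordered ring-major. The combined
Fourier vector (circular followed by circular-angular) has 833 entries
at the acquisition geometry. The sector sums recompose the total
magnitude in the `(0, 24]` annulus exactly — a conservation law the test
suite asserts.

**Corrosion descriptor (CITA).** The image is treated as a metal
surface: each pixel is a cellular-automaton cell whose state is its gray
level, read as corrosion depth. Synchronously for every cell,
`d = s - min(neighbors)` over the Moore 8-neighborhood (border cells use
their in-grid neighbors only); if `d` exceeds the roughness threshold
`v` the cell corrodes by `C = floor(gamma * d)` with pitting power
`gamma` in `[0, 1]`. The descriptor is the running cumulative corroded
mass `sum(C)` after each of `T` iterations — by default `v = 2`,
`gamma = 0.05`, `T = 200`, giving a 200-point non-decreasing curve.
Because `floor(gamma * d) = 0` whenever `d < 1/gamma`, the automaton has
a guaranteed fixed point once all local reliefs fall below
`max(v, ceiling(1/gamma) - 1)`; the implementation detects a zero-mass
iteration and fills the remaining curve without further sweeps. The
update kernel is compiled (Rcpp) and computes the neighborhood minimum
separably (vertical 3-min then horizontal 3-min, i.e. the min over the
full 3 × 3 block); that is equivalent to excluding the center because a
cell that is its own block minimum has `d <= 0` and never corrodes
either way. A scalar double-loop reference automaton lives in the test
helpers and the two must agree bitwise.

Two conventions had to be fixed: corrosion *lowers* the state toward the
local pit (the descriptor is invariant to the opposite convention under
intensity inversion, but one must be pinned), and the corroded mass is
the sum of `C`, not the count of corroding cells.

**Local binary patterns.** The classic 3 × 3 operator: each interior
pixel is compared with its 8 unit-radius neighbors, neighbor `p`
contributing `2^p` when it is greater than or equal to the center
(so `s(0) = 1` and a constant patch codes to 255). Bit 0 sits east of
the center and bits proceed counterclockwise — any fixed order gives an
equivalent descriptor up to permutation, but the order is pinned so the
brute-force oracle can match codes exactly. The descriptor is the
256-bin histogram of raw counts over all interior pixels; the counts
total `(M - 2)(N - 2)` exactly, and the codes are invariant to any
strictly increasing intensity remapping. Border pixels are skipped
rather than padded, so every code uses real pixels only.

## Classification pipeline

Features are assembled into a `feature_table` (sample id, species,
environment, uniform-length vector). The pipeline then applies, in
order and always fitted on training data only:

1. **z-score standardization** (default on). Texture and trait features
   have incommensurate scales, and fusion would otherwise be dominated
   by whichever block has larger variance. Constant features are
   centered but left unscaled.
2. **PCA** to a chosen component count, or `"auto"`, which scores a
   grid of counts by cross-validation accuracy and keeps the best. PCA
   is fitted per training fold; the variant that fits PCA on the full
   table before splitting leaks test information into the projection
   and is deliberately not offered.
3. **1-NN or regularized LDA.** k-NN uses Euclidean distance with
   deterministic ties (equal distances go to the lower training-row
   index; vote ties to the smallest class label), so runs are
   reproducible bit-for-bit. LDA uses class means, empirical priors and
   a pooled within-class covariance with a ridge of
   `1e-6 * trace(S)/p` on the diagonal — after aggressive PCA the
   pooled covariance can still be near-singular, and the ridge keeps
   the solve stable without noticeably moving well-conditioned
   solutions (the suite cross-checks predictions against an independent
   LDA implementation on clean data).

**Cross-validation** is stratified: within each class the members are
canonically ordered by sample id, shuffled with a per-repeat seed
derived from the master seed, and dealt onto a randomly rotated fold
sequence, so fold sizes per class are within one sample of
proportionality and the whole scheme is invariant to row order. Each
fold serves once as the test set; accuracy is pooled over the folds
(every sample classified exactly once per repeat) rather than averaged
per fold. The default design is 6 folds repeated 10 times; the repeat
standard deviation is the reported spread. Per-class success rates,
weighted by class size, recompose the overall accuracy to machine
precision.

**Plasticity protocols.** Two evaluations probe robustness to
environment-driven trait shifts. *Joint*: samples from both
environments enter one stratified CV and the per-class rate of the
focal species is read off. *Split*: the full base-environment table is
the training set and the held-out environment's samples of the focal
species are the test set. The drop from joint to split isolates the
direct effect of plasticity on each feature family.

**Trait fusion** appends the three manual measurements (density,
guard-cell length, complex width) to the texture vector, matched by
sample id; feature length grows by exactly 3, and a zero-column texture
table yields the trait-only (quantitative) feature set.

## The synthetic generator

No epidermis image collection is bundled, so the package carries a
seeded generator whose draws stand in for the study material. Each
image composes:

- a **pavement-cell mosaic**: a jittered-grid nearest-seed partition
  (jitter amplitude 0.45 of the cell spacing; the nearest seed is
  searched over the pixel's 3 × 3 block of grid cells, which is the
  partition's definition and keeps full-size images tractable), with
  per-cell intensity variation and darker 2-pixel walls;
- an isotropic **`1/f^exponent` Gaussian field** (amplitude filter
  applied in the frequency domain) at 12% of the contrast scale,
  providing the micro-texture whose spectral slope distinguishes
  species with otherwise identical traits;
- **stomata** as dark ellipses with a lighter pore slit, count drawn
  Poisson with the model's density, axes from normals truncated at zero
  (truncated normals rather than lognormals because their moments are
  trivial to verify in tests), orientations uniform or concentrated von
  Mises-like around a preferred angle.

Rendering is at 2× resolution with box downsampling, so descriptor
tests measure texture rather than aliasing jaggies. The generator
returns the realized stomata count and mean realized axes as the
sample's "manual measurement" — the synthetic analogue of the trait
table (model means are substituted when the Poisson draw is zero, to
keep trait vectors complete). Everything is deterministic given
`(model, size, seed)`; dataset-level seeds derive per-image seeds from
one master seed.

A plasticity pair draws environment 2 from a trait-shifted copy of the
model — density, length and width multiplied by stated factors, sds
scaled with means — while the mosaic scale, spectral exponent and
intensity parameters stay fixed. That is the generator's encoding of
the biological claim under test: plasticity moves stomatal morphometry
much more than it moves the epidermal micro-texture. The default
evaluation shift (0.5, 1.5, 1.3) halves density and enlarges stomata.

What the generator does *not* emulate: staining variability, uneven
illumination, trichomes and other appendages, cell-wall undulation, and
the heavy within-species variation of real material. Passing the
synthetic benchmarks therefore demonstrates that the descriptors and
pipeline are implemented correctly and can exploit the intended cues
(spectral slope, stomatal geometry, local contrast steps,
micro-patterns); it does not certify field accuracy on real epidermis
collections.

## Study sizes used in the shipped analyses

The packaged experiments use an 8-species panel at 256 × 256 pixels —
12 images per species for the identification benchmark (96 samples) and
9 per species plus 9 held-out second-environment images for the
plasticity protocol, mirroring a few-individuals-per-species collection
design. Fourier circular features with 20 principal components and 1-NN
reach ≥ 95% mean accuracy under 6-fold × 10 stratified CV on this
panel, label permutation drops to the 12.5% chance level, and the
trait-only split-environment rate collapses while the texture rate
degrades far less — the direction, not the magnitude, is the asserted
result. Structural descriptor lengths (769 / 64 / 833 / 200 / 256) are
checked at the full 2080 × 1540 geometry.

## Known limitations

- The circular descriptor's length depends on image size, so images of
  mixed sizes cannot share a feature table; `run_extract()` rejects
  them rather than resampling silently.
- `"auto"` PCA selection scores candidate counts on the same table it
  then reports on; for unbiased accuracy estimates choose the count on
  an independent split.
- LDA needs more training samples than classes; very small per-class
  counts should use 1-NN.
- The corrosion descriptor's runtime grows linearly in `iters` and
  pixel count; at 2080 × 1540 and `T = 200` the compiled kernel runs in
  a few seconds, but the pure-R reference in the test helpers is for
  small grids only.
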