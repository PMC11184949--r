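---
title: "Methods: canopy uniformity from binned trait rasters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy uniformity from binned trait rasters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyuniformity)
```

## The model

A plot's trait raster is treated as a finite population of pixel values.
Uniformity is quantified by discretising those values into classes of
width `w` (the *classification parameter*) anchored at an origin (default
0), and summarising the class proportions `P_i` over the `S` nonempty
classes with entropy-based evenness statistics alongside the classical
dispersion battery:

* `H' = −Σ P_i ln P_i` (Shannon entropy, nats),
* `J' = H'/ln S` (Pielou), `E = (1/Σ P_i² − 1)/(exp H' − 1)` (Alatalo),
* mean, sample variance and `CV = sd/mean`.

The central assumption is that growth uniformity manifests as pixels
concentrating in few trait classes. The indices deliberately ignore the
spatial arrangement of pixels — two plots with identical value multisets
score identically (this permutation invariance is tested). That is what
makes the approach applicable to closed canopies where plant positions
are unobservable, and it is also its key limitation: banding or gradients
with the same marginal distribution are indistinguishable.

Fractional vegetation cover is binary per pixel (vegetation/background),
so its class distribution is `(1 − FVC, FVC)` with no bin width. Across
the four traits (FVC, LAI, SPAD, PH) the battery yields 24 statistics per
plot and stage: 20 uniformity indices plus the 4 trait means.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| bin width LAI / SPAD / PH | 0.5 / 2 / 2 | trait units (PH cm) | the operating points of the workflow; the sweep grids (`default_sweep_widths()`) bracket them by a factor of ~15 either way |
| bin origin | 0 | trait units | fixed so results are reproducible; see "translation dependence" below |
| NDVI histogram bin / smoothing | 0.02 / 5 bins | NDVI / bins | fine enough to resolve modes ~0.1 apart, coarse enough that 2,000-pixel plots give stable histograms |
| FVC rule | `NDVI > threshold` | — | strict inequality; ties count as background |
| PH percentile | 97 | % | robust proxy for canopy top that rejects isolated high returns |
| regressor | 10 (LAI) / 20 (SPAD) hidden units, 5,000 iterations, learning rate 0.005, 2:1 split | — | single hidden layer of tanh units, linear output, full-batch gradient descent on standardised data |
| MLR split | 7:3, seeded | — | validation metrics use the untouched 30% only |

The stated regressor sizes are hidden *neurons* in one hidden layer: with
plain backprop at learning rate 0.005, stacks of 10–20 actual layers
would not train, and a single hidden layer is the standard idiom for this
network family. Inputs and target are standardised before training and
predictions de-standardised; a constant target is flagged as degenerate
(R² undefined) and predicted exactly.

## Numerical conventions

* **`S = 1`:** Pielou and Alatalo are 0/0 when all pixels share one
  class. Both are defined as 0, so that perfectly uniform growth sits at
  the low end of the index scale, consistent with the negative
  index–yield relationship the pipeline is built to detect. The same
  convention applies to the binary FVC distribution at cover 0 or 1.
* **Logarithms:** natural throughout; Pielou's normalisation makes any
  base-inconsistency between `H'` and `ln S` visible immediately.
* **Variance:** sample variance (n − 1). Pixels are treated as a sample
  of the plot's growth process, and the convention must be fixed for CV
  to be reproducible.
* **Percentile:** linear interpolation between order statistics
  (`quantile(..., type = 7)`); `z = 0, 0.01, …, 1` gives exactly 0.97 at
  the 97th percentile.
* **Valley threshold:** two highest local maxima of the smoothed
  histogram (plateau-safe run-length comparison), then the lowest bin
  strictly between them; ties — common when the modes are well separated
  and the inter-mode counts are all zero — resolve to the centre of the
  lowest plateau, which matches the density minimum of a symmetric
  two-mode mixture.
* **ROI rasterisation:** a pixel belongs to a plot iff its centre lies
  inside the polygon (even-odd rule).
* **Undefined statistics** (CV at zero mean, correlations of
  zero-variance indices) are explicit `NA` markers, never dropped rows.
* **Mean crowding:** Lloyd's `m* = x̄ + S²/x̄ − 1`. It and the clustering
  index are optional extras outside the 20-index battery.
* **Masking:** when a crop mask is supplied, the continuous traits (LAI,
  SPAD, PH) are summarised over vegetation pixels only; FVC always uses
  all ROI pixels (its classes *are* vegetation vs background).
  `use_crop_mask = FALSE` exposes the alternative.

## The synthetic field simulator

The generator emulates a dense-sown small-plot trial: 1.5 × 1.25 m plots
at 3 cm GSD with 0.25 m row spacing. Within-plot trait surfaces are
stationary Gaussian random fields realised by kernel-smoothing white
noise (bandwidth = correlation length, default 0.2 m) and rescaling to
the configured field sd, plus independent pixel noise (exact covariance
family is immaterial to the indices, which see only the value
distribution). Row structure is rendered as vegetated stripes half a row
period wide; truth masks and exact cover fractions are emitted so
segmentation can be scored against ground truth. Reflectance scenes draw
pixel NDVI around a soil mode (0.1) and a vegetation mode (0.8) with sd
0.05 and back-compute the two bands, so the NDVI histogram is bimodal by
construction. Yield and biomass are affine in the plot's trait mean and
uniformity index with Gaussian noise:
`yield = 1.5·LAI_mean − 3·J'_LAI + ε, sd(ε) = 0.3 Mg/ha` (biomass:
3.5/6/0.6), centring yields near typical wheat values of ~6 Mg/ha.

`sim_uniformity_study()` fixes the canonical study conditions used by the
package's checks: 100 closed-canopy plots whose LAI field sd is graded
from 0.1 to 1.0 across the trial, LAI mean 3, Pielou computed at bin
width 0.5.

What the generator does **not** emulate: phenology (stages are
independent draws), mixed border pixels, lodging, radiometric or
geometric error, and — importantly — an *emergent* uniformity–yield
mechanism. The negative index–yield correlation in simulated data is
planted through the yield coefficients, so passing checks demonstrate
that the pipeline recovers a known signal (sign, ordering, decay under
coarsening), not that uniformity drives yield in real fields.

## Sensitivity analyses

Two sweeps probe the method's operating point. Coarsening the bin width
merges classes and can only lower Shannon entropy (tested as a
monotonicity property on nested grids); at the coarsest widths every plot
collapses to one class, the index variance vanishes and the correlation
with yield is reported `NA` — the analysis stops being meaningful rather
than silently returning 0. Degrading the GSD by block-averaging (factors
2/4/8 over the native 3 cm) smooths within-plot variation away, and the
absolute index–yield correlation decays accordingly on simulated trials.

## Known limitations

* **Translation dependence of binning.** The class grid is anchored, so
  indices are not invariant to shifting all values by a fraction of a
  bin. A trait mean sitting exactly on a bin edge splits an almost
  uniform plot into two near-even classes and inflates Pielou towards 1;
  at a bin centre the same plot collapses towards one class and Pielou
  towards 0. Comparisons across plots are safe when plots share the grid
  (they always do here), but absolute index values should not be
  compared across different origins or bin widths.
* Entropy indices ignore spatial structure (see above).
* The bin-width sweep on simulated data inherits the planted operating
  point: the width used to generate yields is necessarily the most
  correlated one.
* The frozen reference equations apply their coefficients to raw
  (unstandardised) predictor values, as printed; they are shipped for
  exact evaluation and comparison, not refitted.
* Pearson correlation is used throughout (signed, linear
  interpretation); a rank alternative would need only a one-line change
  but is not what the reported coefficients mean.
* No multiple-testing correction is applied to the correlation matrices
  by default, matching the descriptive use of these screens.

## Problem sizes

The package's own checks run at desk scale, chosen to keep the full suite
under a minute while leaving the Monte-Carlo margins comfortable: 100
plots × ~2,000 pixels for recovery and sweep checks, 20 seeded
replicates for sign recovery, 50 replicate plots for variance-scaling
checks, 1,000 null replicates for the ANOVA type-I calibration, and 100
random distributions for the index/formula equivalence at `1e-10`.
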