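---
title: "Methods: synthetic drone-vs-ground habitat-degradation assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic drone-vs-ground habitat-degradation assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dronecover` compares two ways of measuring vegetation loss in goose-degraded
salt marsh — walked step-point transects and classified drone RGB imagery —
inside a fully synthetic, seeded sandbox. This vignette records the models,
the tunable parameters, the numerical choices, and the places where the
design was genuinely open and a decision had to be made.

## The synthetic landscape

The generator's job is to reproduce the *statistical* structure of a damaged
coastal marsh, not its appearance. A white-noise field is smoothed by a
Gaussian kernel (circular FFT convolution) whose standard deviation is the
`spatial_corr_length_m` (default 4 m — patch sizes of metres to tens of
metres, the scale of goose grubbing scars), then cut at the empirical
quantiles of the smoothed field so the three classes hit `target_props`
almost exactly (the realized error is of order 1/n_pixels; the contract
tested is ±0.02). Classes occupy quantile bins in label order, so non-shrub
forms transition bands between barren lows and shrub highs — ecologically
sensible for remnant graminoid fringes.

Rendering draws every pixel from its class's spectral distribution:

* class means (8-bit RGB) default to pale dry sediment (186, 172, 150),
  dark graminoid mat (96, 88, 62) and green shrub canopy (70, 110, 58),
  with a dark-soil barren sub-spectrum at (92, 84, 70);
* isotropic noise with SD `noise_sd` (default 12 counts), optionally shaped
  by a common 3 × 3 spectral covariance;
* **confusability** `c` in [0, 1] interpolates the non-shrub mean toward the
  dark-soil spectrum, while a `dark_soil_fraction` (default 0.2) of barren
  pixels is rendered at the matching sub-spectrum mean
  `(1 − c)·barren + c·dark_soil`. At `c = 0` barren stays spectrally uniform
  (the noiseless limit renders every pixel exactly at its class mean); at
  `c = 1` dark-soil barren and non-shrub coincide and no RGB classifier can
  separate them. This staged engagement is a deliberate design choice: it
  preserves the exact-mean noiseless contract while making classification
  difficulty provably monotone in `c`;
* **shadows**: a seeded fraction `shadow_fraction` (default 0.08) of the
  pixels immediately south-east of shrub canopy (fixed bearing, one-pixel
  one-sided dilation) has its intensity multiplied by 0.45. Shadow prevalence
  and spectral separability are not quantified anywhere for the real site;
  these defaults are calibration knobs of the sandbox, chosen once, not
  estimates of the marsh.

Determinism is a contract: the same `scene_spec` (including its seed)
produces bit-identical rasters, and every stage of the pipeline draws its
seed from a named substream of one master seed.

## Survey geometry and scale choices

The default design is 92 adjacent 50 × 50 m cells (23 ha) in five rectangular
plots (24/20/20/16/12 cells). Real plot outlines vary; only the totals enter
any downstream computation, so the partition is configurable. Each cell
carries two diagonal transects (NW→SE, NE→SW, length 50√2 ≈ 70.71 m) sampled
every metre from the start corner: ⌊L/s⌋ + 1 = 71 points per transect, 142
per cell, 13,064 over the design. "Approximately every meter" in the field
becomes exactly 1.000 m here — determinism beats verisimilitude for a test
fixture.

GSD scales linearly with altitude (`gsd_m = k · altitude`). Calibrated at
(100 m, 3.2 cm) the model returns the familiar 2.4 / 3.2 / 3.8 cm at
75 / 100 / 120 m (half-away-from-zero rounding to 1 decimal). The *synthetic*
study instead flies the finest altitude at 10 cm GSD (k = 0.1/75): a 23-ha
study is then ~24 M pixels at 75 m, which one CPU classifies and cleans in a
few minutes, while 2.4 cm imagery would be 400 M+ pixels with no change in
what the tests demonstrate. The truth map is generated once at the finest
GSD and resampled to coarser altitudes by nearest neighbour, so all
altitudes see the same landscape.

Coordinates are planar metres from the study's SW corner. Rasters use
half-open pixel intervals (west/south edges inclusive) and points on the
raster's outer east/north boundary belong to the last pixel, so cell-corner
sample points are always valid and shared cell edges are never double
counted.

## Classification

The mosaic is clustered into K = 30 spectral classes by Lloyd's k-means with
k-means++ seeding on raw RGB triplets — no texture, no position. Each plot
gets its own cluster model (light conditions differ between plots in real
surveys); pixels outside every plot become no-data. For large mosaics the
centroids are fitted on a seeded 200,000-pixel subsample — commercial
ISO-cluster tools subsample similarly — and every pixel is then assigned to
its nearest centroid in compiled code. Iteration stops at a 10⁻⁴ relative
drop in the within-cluster sum of squares or 100 iterations.

The field workflow has an analyst inspect each cluster and assign it a cover
class. In synthetic mode that inspection is replaced by a plurality vote of
the cluster's pixels against the reference truth map (ties break
barren > shrub > non-shrub, the prior-abundance order); a user-supplied
cluster→class map is accepted for real imagery. This stand-in is the single
largest idealization in the pipeline: it makes the "analyst" exactly as good
as the spectral partition allows, so synthetic accuracies are upper bounds
on what a human photointerpreter would produce.

## Post-processing

High-resolution classifications are speckled with isolated misclassified
pixels, so the standard clean-up chain is applied:

1. **Majority filter** — strict-majority vote in the 3 × 3 neighbourhood
   (centre included, no-data ignored, pixel kept when no strict majority);
   a 4-neighbour kernel is available.
2. **Boundary clean** — per class, one-pixel morphological closing
   (dilate–erode, 3 × 3 box), composited so higher-priority classes
   overwrite lower and unclaimed pixels keep their label; two passes by
   default. The published description of the proprietary tool (expand/shrink
   by priority) is reimplemented here; priority defaults to descending class
   area. Kernel size, priority and pass count are not documented for the
   original workflow — these defaults are declared, not inferred.
3. **MMU sieve** — 8-connected components smaller than 0.25 m² are dissolved
   pixel-by-pixel into the class of the nearest surviving patch (exact
   Euclidean distance transform per donor class; ties go to the lowest class
   label). Donors are pre-pass survivors, so removal within a pass is
   order-independent; passes repeat (max 10) until no sub-MMU patch remains.
   At 2.4 cm GSD the threshold is 0.25/0.024² = 434.03 pixels: a 434-pixel
   patch dies, a 435-pixel patch survives.

Components, distance transforms, morphology, the majority vote and
nearest-centroid assignment are small Rcpp kernels — the one place this
package uses compiled code, as raster packages generally do.

## Cover estimators and accuracy

Per-cell proportions come from (a) full pixel enumeration
(pixel-centre-in-cell, half-open edges; `n` = pixels in the cell) and
(b) virtual step-point transects read off the classified raster at the same
1-m spacing as the field protocol (`n` = 142). Study-wide proportions pool
all cell pixels and are therefore the n-weighted mean of the per-cell values
and invariant to the plot partition.

Accuracy uses 100 stratified random points per plot (500 per altitude):
class allocations by largest-remainder apportionment of the class area
shares — the field convention says "proportional" without naming a rule, and
largest remainder is the apportionment that sums exactly while staying
within one seat of proportionality — then uniform sampling without
replacement within each class. The reference label at each point is the
synthetic truth (standing in for manual photointerpretation; a hand-labelled
point file can be supplied for real data). From each plot's 3 × 3 confusion
matrix: overall accuracy, Cohen's kappa, and per-class omission
(1 − diag/column) and commission (1 − diag/row) errors; across plots the
mean, sample SD (n − 1) and range are reported. A single plot reports SD = 0
with an explicit flag.

## The beta GLMM

Proportions in [0, 1] with exact zeros and ones are pulled inside the unit
interval by the Smithson–Verkuilen transform y′ = (y(n − 1) + 0.5)/n, using
each cell's own count n (142 transect points, or the cell's pixel count).
The model is

  logit(μ_ij) = x_ij'β + b_i,  y_ij ~ Beta(μ_ij φ, (1 − μ_ij) φ),
  b_i ~ N(0, σ²_cell),

with one fixed factor per model — altitude (baseline 75 m) within each drone
method, or method (baseline ground) at the reference altitude — and a common
precision φ (the reported tables carry a single scale, so no per-level
dispersion is modelled). The marginal likelihood integrates each cell's
random intercept by *adaptive* Gauss–Hermite quadrature (15 nodes; the
per-cell mode and curvature are found by a vectorized, backtracking Newton
inner loop and the nodes recentred there). The outer optimizer is BFGS on
(β, log σ², log φ) from the fixed start β = 0, σ² = 0.5, φ = 10, with one
polishing restart; standard errors come from the observed information, with
the delta method for σ² and φ. Doubling the nodes moves the estimates by
less than 10⁻⁴, and on simulated data the fit matches glmmTMB (an
independent engine, used only as a test oracle) to ~3 decimals.

The fixed factor is tested with a Wald F, numerator df = p − 1 = 2 and a
containment-style denominator df = N − n_cells − (p − 1), which is 182 for
the default 276-observation / 92-cell layout — the convention of the mixed
-model software whose output format the report mirrors. The exact
denominator-df algorithm of that engine is not published; the containment
rule is adopted because it reproduces the documented df for this design, and
the same df is used to scale the Pearson χ² dispersion diagnostic (≈1 for a
well-specified fit, since the conditional modes absorb roughly one degree of
freedom per cell). Exact numeric parity with other engines is a soft goal:
cross-engine agreement to 2–3 decimals, not bit equality. σ̂² estimates that
collapse below 10⁻⁶ are flagged as boundary fits and, as a test verifies,
reproduce a plain fixed-effects beta regression to 10⁻⁴.

Empirical operating characteristics are checked by simulation in the test
suite at the study's size (92 cells × 3 levels): parameter recovery and
~95% Wald coverage over 200 replicates, and type-I error of the F test
within [0.03, 0.08] at nominal 0.05 over 200 null replicates.

## What the synthetic study does and does not show

The generator reproduces cover proportions, patch structure, spectral
confusability and shadows — the features that drive the comparison of
estimators — but not radiometric realism, mosaicking artifacts, sun-angle
physics or species-level texture. Passing tests therefore demonstrate that
the *pipeline* is correct and that the qualitative signature (drone methods
over-reading barren and under-reading non-shrub when dark mats and dark soil
converge) follows from spectral confusion alone; they do not certify
accuracy numbers for any real sensor or site. The plurality reclassifier
makes synthetic accuracies optimistic by construction. Real per-cell tables
in the documented layout (CSV, or XLSX via readxl) can be ingested with
`read_s1_data()` and pushed through the same correlation and GLMM machinery;
when such a table carries no per-cell n, the transect count (142) is
reconstructed but pixel-count models then need the user to supply n, and
exact reproduction of published coefficients is not guaranteed.

## Problem sizes used by the tests

Unit tests run on one- to eight-cell designs at 0.25–0.5 m GSD (seconds);
the simulation-based model checks use the full 92-cell statistical layout;
the acceptance script runs the complete default study — 92 cells at 10 cm
GSD, three altitudes, per-plot classification — in a few minutes on one CPU.
These sizes were chosen so a full check remains desk-scale while every
contract is exercised at the study's real dimensions where it matters
(the GLMM df and the design bookkeeping).
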