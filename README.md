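# dronecover

Quantifying habitat degradation from drone RGB imagery, and testing whether
drone-based land-cover estimates can stand in for ground-based field
transects.

## The problem

Overabundant lesser snow geese strip coastal salt-marsh vegetation, leaving
a mosaic of barren sediment, remnant graminoid/forb mats ("non-shrub") and
dwarf shrub. Field crews map this damage with step-point transects: two
diagonals walked across each 50 × 50 m grid cell, recording the dominant
cover underfoot every metre. A fixed-wing drone can photograph the same plots
in minutes — but its RGB ortho-mosaics must be classified, cleaned and
sampled before the two data sources can be compared.

`dronecover` implements that comparison end to end as a seeded, fully
synthetic and therefore fully testable pipeline:

1. **Synthetic landscape** — a Gaussian random field, smoothed to a chosen
   correlation length and thresholded at empirical quantiles, yields a true
   class map with prescribed cover proportions (default 0.755 / 0.035 /
   0.210 barren / non-shrub / shrub over 92 cells = 23 ha in 5 plots).
   Rendering to 8-bit RGB adds class spectra, noise, cast shadows and a
   tunable *confusability* between dark graminoid mats and dark soil.
2. **Survey geometry** — the 92-cell grid, 184 diagonal transects, and the
   linear altitude→GSD model (calibrated at 100 m → 3.2 cm it reproduces
   2.4 / 3.2 / 3.8 cm at 75 / 100 / 120 m).
3. **Ground sampling** — simulated step-point records with optional observer
   error; per-cell proportions with their counts `n`.
4. **Classification** — unsupervised k-means (K = 30, k-means++ seeding,
   Lloyd iterations) on raw RGB, fitted per plot, with clusters reclassified
   to the three cover categories by plurality against a reference.
5. **Post-processing** — majority filter, expand/shrink boundary cleaning by
   class priority, and a 0.25 m² minimum-mapping-unit sieve with
   nearest-neighbour replacement.
6. **Cover estimators** — per-cell proportions by full pixel enumeration
   (`drone_pixels`) and by virtual 1-m step-point transects
   (`drone_transects`).
7. **Accuracy assessment** — 100 stratified random points per plot
   (allocation proportional to class area), confusion matrices, overall
   accuracy OA = trace/total and Cohen's kappa
   κ = (p_o − p_e)/(1 − p_e), with mean ± SD and range across plots.
8. **Statistics** — per-cell proportions are Smithson–Verkuilen transformed,
   y′ = (y(n−1) + 0.5)/n, and modelled with a beta GLMM:
   logit(μ_ij) = x_ij'β + b_i, y_ij ~ Beta(μφ, (1−μ)φ), b_i ~ N(0, σ²_cell),
   fitted by maximum marginal likelihood with adaptive Gauss–Hermite
   quadrature. Fixed-factor Wald F tests use the containment denominator
   df = N − n_cells − (p−1) (= 182 for 276 observations over 92 cells), and
   Pearson χ²/df is reported as the dispersion diagnostic, alongside Pearson
   correlations between the three methods.

## Worked example

```r
library(dronecover)

cfg <- pipeline_config(master_seed = 7,
                       scene  = scene_spec(gsd_m = 0.25),
                       design = survey_design(list(c(2, 2), c(2, 2))),
                       altitudes_m = c(75, 100, 120))
res <- run_pipeline(cfg, verbose = FALSE)
table1_summary(res)
#> # A tibble: 5 x 4
#>   metric                alt_75                          alt_100 alt_120
#> 1 Proportion Barren     0.758                           0.759   0.758
#> 2 Proportion Non-Shrubs 0.015                           0.018   0.018
#> 3 Proportion Shrubs     0.226                           0.223   0.223
#> 4 Overall Accuracy      97.0%+/-0.014 Range: 0.96-0.98  ...     ...
#> 5 Kappa Coefficient     0.92+/-0.024 Range: 0.91-0.94   ...     ...

res$stats$f_tests[res$stats$f_tests$family == "method", c("class", "F", "df1", "df2", "p_value")]
#>   class        F   df1  df2   p_value
#> 1 barren    39549     2   14  5.4e-27
#> 2 nonshrub   9.36     2   14  2.6e- 3
#> 3 shrub      0.667    2   14  5.3e- 1
```

Reading the output: the classified mosaics recover barren and shrub cover
closely, but non-shrub cover is under-read relative to the simulated ground
transects (0.015–0.018 against a true 0.035) because the dark graminoid
spectrum has been pulled toward dark soil — the method models flag exactly
this class. With the default 92-cell design the denominator df becomes 182.

A thin command-line driver with verbs `simulate`, `classify`, `postprocess`,
`estimate`, `assess`, `stats`, `run-all` and `read-s1` lives at
`inst/cli/dronecover.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "dronecover.R", package = "dronecover"))')" run-all --seed 7 --out out/
```

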