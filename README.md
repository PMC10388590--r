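# wetlandAGB

Species-level aboveground biomass (AGB) estimation for emergent wetland
vegetation from UAV RGB orthomosaics.

Harvest surveys of wetland stands measure fresh-weight AGB (g/m²) at a
handful of 0.6 m quadrats; a consumer drone delivers centimetre-scale RGB
imagery over the whole stand. This package implements the inversion chain
between the two, for wetland ecologists and remote-sensing practitioners
working with species like *Zizania latifolia*:

1. **Resample** the orthomosaic to the plot scale (area-weighted block
   mean, default 0.6 m).
2. **Indices** — 17 visible-band vegetation indices per pixel, e.g.
   ExG = 2G − R − B, CIVE = 0.44R − 0.88G + 0.39B + 18.79,
   COM2 = 0.36·ExG + 0.47·CIVE + 0.17·VEG.
3. **Plot features** — the 5×5-pixel window mean of each index at every
   field plot.
4. **Selection** — Pearson correlation of AGB with each index; indices
   with |r| > 0.8 feed univariate models, significantly correlated ones
   (p < 0.05) feed the network.
5. **Models** — univariate fits y = b₁x + b₀, y = b₂x² + b₁x + b₀ and
   y = a·e^(bx) on a 30-plot modeling set, plus a feedforward network
   (n inputs → 3 tanh hidden units → 1 linear output) trained by
   Levenberg–Marquardt least squares.
6. **Evaluation** on the 8 held-out plots: MAE = Σ|Yᵢ−yᵢ|/n,
   RMSE = √(Σ(Yᵢ−yᵢ)²/n), R² = 1 − Σ(Yᵢ−yᵢ)²/Σ(Yᵢ−Ȳ)².
7. **Inversion** — the best model applied per pixel inside a species mask,
   with map summaries.

A synthetic scene generator (`generate_scene()`,
`generate_feature_table_direct()`) emulates the whole study design —
38 quadrats split 30/8, AGB in the 3000–7600 g/m² range, greenness
coupled to biomass, 10 g scale rounding — so every stage is testable end
to end against known ground truth without any field data.

## Worked example

```r
library(wetlandAGB)

scene <- generate_scene(scene_config(seed = 1))   # known ground truth
res <- run_pipeline(scene$rgb, scene$truth$plots,
                    mask = scene$truth$mask, seed = 1)

res$correlation
#> <agb_correlation> AGB vs 17 indices on 30 modeling plots
#>  index      r        p  n
#>  RGBVI  0.811 5.59e-08 30
#>   BGRI -0.810 5.97e-08 30
#>  RGBRI -0.810 6.00e-08 30
#>   RGRI -0.810 6.03e-08 30
#>      G  0.807 7.27e-08 30
#>   CIVE -0.807 7.36e-08 30
#>    ExG  0.807 7.36e-08 30
#>  ...
```

AGB correlates positively with greenness indices (ExG, RGBVI, G) and
negatively with CIVE and the red/blue ratios, as expected for a canopy
whose green signal rises with biomass. On this synthetic scene the colour
ramp is driven by a single latent density, so many indices tie near
|r| ≈ 0.81; real data spread these correlations out more.

```r
res$models$quadratic_CIVE
#> <agb_univariate> quadratic model, AGB ~ CIVE
#>   y = -0.2846 x^2 + -67.44 x + 3212
#>   modeling R2 = 0.659 on n = 30 plots

res$models$bpnn
#> <agb_bpnn> 8-3-1 feedforward network (tanh hidden, linear output)
#>   inputs: RGBVI, BGRI, RGBRI, RGRI, G, CIVE, ExG, B
#>   LM training: 1000 iterations, MSE (scaled) 0.084, stopped on max_iterations

head(res$comparison[, c("model_id", "mae", "rmse", "r2_fit", "rank")], 3)
#>            model_id      mae     rmse    r2_fit rank
#> 1  exponential_BGRI 566.0279 629.5323 0.6668488    1
#> 2 exponential_RGBRI 566.1988 629.5743 0.6669650    2
#> 3  exponential_RGRI 566.3818 629.6213 0.6670882    3
```

The comparison table ranks every fitted model by holdout RMSE (g/m²) on
the 8 validation plots; `d_mae`, `d_rmse`, `d_r2` columns (not shown)
give paired differences against the best quadratic baseline. The winner
is inverted into a map:

```r
res$map
#> <agb_map> agb_univariate:exponential BGRI, masked
#>   957 valid px: min 2842.1, mean 5052.6, max 7637.4 g/m2

mean(band(scene$truth$agb_field), na.rm = TRUE)   # the truth
#> [1] 5083.682
```

The mapped mean (5052.6 g/m²) sits within 0.7% of the true masked field
mean, and predictions exist only where the species mask is 1 and all
required indices are valid. `summarize_map(res$map, zones)` gives
per-area min/max/mean when a zone raster is supplied.

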