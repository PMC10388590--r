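---
title: "Estimating species-level wetland biomass from UAV RGB imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating species-level wetland biomass from UAV RGB imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetlandAGB)
```

## The estimation problem

Emergent wetland plants such as *Zizania latifolia* root underwater and
carry their stems and leaves above the surface; the fresh weight of that
above-water portion per unit area (aboveground biomass, AGB, g/m²) is a
standard indicator of wetland condition. Harvest surveys measure it
directly but destructively and only at a handful of 0.6 m quadrats. A
consumer UAV flying at ~100 m yields centimetre-scale RGB orthomosaics
over whole stands. This package implements the inversion chain that links
the two: plot-scale greenness features are extracted from the imagery,
statistical models are fitted on the harvested plots, and the chosen
model is applied per pixel inside a species mask to map AGB.

The chain is, in order: resample the orthomosaic to the plot scale →
compute visible-band vegetation indices → extract windowed plot features
→ select predictors by Pearson correlation → fit univariate regressions
and a small neural network → evaluate on held-out plots → invert the best
model into a map. `run_pipeline()` executes the whole chain; every stage
is also exported on its own.

## Data model and rasters

Rasters are carried by a light S3 container (`agb_raster`): a matrix or
band array, the map coordinate of the top-left corner, a square pixel
size (ground sampling distance, m), an optional CRS label and a nodata
sentinel. Pixels are addressed by the pixel-area convention with map
coordinates at pixel centres. Band values are used exactly as stored
(8-bit digital numbers for imagery); no reflectance calibration is
attempted, because the method is defined on raw RGB.

Two plain interchange formats cover I/O: ESRI ASCII grid (`.asc`) for
float layers (indices, AGB maps, truth fields) with georeferencing in the
header, and TIFF with an ESRI world file for 8-bit imagery. A JSON
sidecar records nodata and CRS for both.

Resampling to the working grid (default 0.6 m, the plot edge) uses an
area-weighted block mean: each output pixel is the overlap-weighted mean
of the source pixels it covers, skipping missing values. This conserves
the radiometry that plot features are built from — with an integer factor
and no missing data the global mean is conserved exactly — which is why a
nearest-neighbour kernel was not used. Species masks are aligned to the
working grid by area-weighted majority, with exact ties resolved to 0
(conservative: outside the species).

## The seventeen indices

`index_registry()` lists the seventeen visible-band indices: the raw
bands R, G, B; ratio indices RGRI = R/G, BGRI = B/G, RGBRI = (R+B)/2G;
the Woebbecke index WI = (G−B)/(R−G); normalised differences NGRDI,
NGBDI, VDVI, RGBVI; VEG = G/(R^0.67 B^0.33); CIVE = 0.44R − 0.88G +
0.39B + 18.79; ExG = 2G − R − B; ExGR; and the combinations
COM = 0.25ExG + 0.3ExGR + 0.33CIVE + 0.12VEG and
COM2 = 0.36ExG + 0.47CIVE + 0.17VEG.

Two formula families circulate for ExGR and CIVE. The default
`"as-printed"` dialect reads ExGR literally as ExG − 1.4R − G and applies
the CIVE coefficients to raw band values; the `"canonical"` dialect uses
ExG − (1.4R − G) and CIVE on chromatic coordinates r = R/(R+G+B) (with
coefficients 0.441, −0.811, 0.385, 18.78745). Both are first-class; the
composites are always assembled from same-dialect components. Singular
pixels — zero denominators in the ratio and normalised-difference
indices, R = G for WI, a zero base under the fractional powers of VEG —
become nodata rather than infinities, and nodata in any band propagates
to all indices.

## Plot features and the sample split

Field plots are 0.6 m quadrats with a map coordinate, a mean canopy
height (carried but unused by the models) and a weighed AGB. Features are
the mean of the 5×5-pixel window centred on the pixel containing the plot
coordinate, computed on the resampled grid. Sub-pixel interpolation is
deliberately not used: the extraction protocol is defined on whole
pixels. Windows overhanging the raster edge are truncated to their
in-bounds part and flagged rather than dropped, so small scenes keep
their full sample size; a window whose in-bounds part is more than half
nodata marks the plot missing for that index, and plots missing any index
are excluded from the feature table with a recorded reason.

The 38 plots split 30/8 into modeling and validation sets by a seeded
draw (`split_samples()`); rows with a preassigned role are honoured and
only unassigned rows are drawn. All downstream fitting uses the modeling
rows only; the correlation stage does too, by default, so the validation
plots stay untouched until evaluation (a `rows = "all"` switch exists and
is recorded in the result).

## Correlation and predictor selection

`pearson_matrix()` computes product-moment correlations of AGB with each
index and the full index-by-index matrix, with two-sided p-values from
the t distribution on n − 2 degrees of freedom, unadjusted by default
(Holm or any `p.adjust` method by argument). Two selection rules follow
the study design: univariate models are built on indices with |r|
strictly greater than 0.8; the network takes every index significant at
α = 0.05, capped in the pipeline at the eight strongest, because with ~30
modeling plots more inputs would push the weight count past the sample
count. When no index clears 0.8 the pipeline falls back to the three
highest-|r| indices with a warning, so small or noisy scenes still
produce the full model battery.

## Univariate models

Three families relate one index x to AGB y: linear (y = b₁x + b₀),
quadratic (y = b₂x² + b₁x + b₀), both by ordinary least squares, and
exponential (y = a·e^{bx}) by least squares of log y on x with
a = exp(intercept) — the convention of the vegetation-index literature —
optionally refined by nonlinear least squares (`refine = TRUE`, via
minpack.lm). The modeling R² is always computed on the original AGB
scale, including for the exponential family, so families are comparable.
Fits return classed objects with `print`, `summary`, `coef`, `predict`
(vectors, data frames or rasters), `residuals`, `plot` and `simulate`
methods. A separate `fit_validation_line()` regresses measured on
predicted over the validation pairs — the conventional scatter-line
diagnostic — and reports slope, intercept and the squared correlation.

## The inversion network

`train_bpnn()` trains a fully connected feedforward network with one
hidden layer (n inputs → m hidden → 1 output; tanh hidden units, linear
output; m = 3 by default) on the modeling rows, by full-batch
Levenberg-Marquardt: each step solves (JᵀJ + μI)δ = −Jᵀe with the
Jacobian assembled analytically per sample, accepts the step only if the
objective falls, and adapts the damping μ (×0.1 on acceptance, ×10 on
rejection, defaults 10⁻³ start, 10¹⁰ cap, 1000 iterations). Features and
target are min-max scaled to [−1, 1] and the scaling parameters live in
the model, because LM on raw g/m² targets is numerically fragile. Weight
initialisation is a seeded uniform draw in [−0.5, 0.5] (Nguyen-Widrow by
option) and training is bit-for-bit reproducible per seed.

With ~31 free weights, ~30 samples and strongly collinear index inputs,
plain LM run to its iteration cap interpolates the training plots and
grows weights along near-null input directions; predictions then degrade
sharply off the training points. We measured validation errors two to
three times the noise floor in that regime. The default therefore trains
on the Bayesian-evidence objective β·SSE + α·SSW, re-estimating α and β
after every accepted step from the effective number of parameters
(MacKay's update; the training log reports that number, typically ~10 of
31 here). This shrinks exactly the unconstrained directions and needs no
tuning constant. `regularization = "none"` restores the plain
sum-of-squares objective, guarded by the other standard control: a
seeded 15% random-divide monitor with patience 6, returning the
best-monitored weights. The hidden-layer size can be chosen by
`select_hidden_neurons()`, which sweeps the conventional range
m = round(√(n_inputs + 1)) + 1…10 with seeded repeats, scores by
validation RMSE and breaks ties toward the smaller network.

## Evaluation

`evaluate()` reports MAE = Σ|Yᵢ − yᵢ|/n, RMSE = √(Σ(Yᵢ − yᵢ)²/n) and
R² = 1 − Σ(Yᵢ − yᵢ)²/Σ(Yᵢ − Ȳ)², with Yᵢ measured and yᵢ predicted. Ȳ is
the mean of the measured values — the standard coefficient of
determination, which can be negative on a holdout set; a variant centring
on the mean prediction is available (`r2_variant = "predicted-mean"`)
because that reading also circulates. The squared Pearson correlation of
the pair (`r2_fit`, always in [0, 1]) is reported alongside, as holdout
R² values quoted with validation-line slopes are often of that kind.
`compare_models()` assembles metrics and paired differences against a
baseline, guarded by a fingerprint of the measured vector so reports from
different validation sets cannot be mixed.

## Mapping

`invert_map()` applies any fitted model per pixel inside the mask;
outside-mask or any-nodata pixels stay nodata. Negative predictions —
possible for regression families at extreme index values — are reported
as-is and counted, with `clamp0 = TRUE` to truncate. Inversion runs on
the resampled working grid, the grid the models were trained on; applying
a plot-scale model at the native 2.4 cm grid would extrapolate the
sampling protocol. `summarize_map()` gives min/max/mean/count over valid
pixels, per zone if a zone raster is supplied.

## The synthetic scene generator

Real flight data for this kind of survey are rarely releasable, so the
package ships a generator that emulates the study conditions end to end
and makes every pipeline property testable against known truth.
`generate_scene()` builds, reproducibly from a seed: a smooth AGB field
spanning 3000–7600 g/m² (the magnitude range of peak-season stands) over
a smoothly shaped species mask covering ~60% of a 24 m scene at 2.4 cm
GSD; RGB pixels whose colour ramps linearly from a water/background
endpoint to a dense-canopy endpoint with local AGB, plus Gaussian colour
noise — so ExG rises and CIVE falls with biomass by construction; and 38
plots placed at least one plot edge apart inside the mask, their AGB
readings perturbed by measurement noise (default σ = 15% of the AGB
range) and rounded to 10 g, the accuracy of a field scale. The field's
correlation length is ~5 m — larger than the 3 m extraction footprint —
because the windowed protocol presumes stands are locally homogeneous at
the plot scale. The colour ramp is a test harness, not a radiometric
model: it guarantees the correlation signs the analysis assumes, and
passing tests on it demonstrate the pipeline's mechanics, not performance
on real imagery (no shadows, water glint, mixed pixels or view-angle
effects are simulated).

`generate_feature_table_direct()` bypasses rasters for model-layer tests:
a latent canopy density drives CIVE exactly (placed on the scale where
the published-magnitude quadratic spans the AGB range) and every other
index with a target correlation to AGB following the observed wetland
pattern — strong for CIVE/ExG/COM2, moderate for the bands, ExGR and
COM, weak for the ratio indices and WI. The `"multi_index"` coupling adds
a bounded nonlinear term driven by the idiosyncratic components of ExGR
and COM, with amplitude chosen so the extra signal is roughly the size of
the noise — the proportion implied by a quadratic holdout R² near 0.4
improving to near 0.7 when a multi-input network captures that signal.
Because those two indices never pass the univariate selection rule, the
term is structurally invisible to single-index models; this is what makes
the model-ordering property (network ≤ best quadratic in most replicates)
a meaningful check rather than a coin flip.

## Numerical choices and problem sizes

Singular index denominators test exact equality with zero; resampling
weights clip negative overlaps at zero; the LM inner loop retries with
increased damping on any failed or non-finite step and stops on gradient
norm < 10⁻¹⁰, damping above 10¹⁰, the iteration cap, or (monitored mode)
patience exhaustion. Tests and the acceptance analysis run scenes of
1000×1000 native pixels (24 m at 2.4 cm), 38 plots split 30/8, 30
replicate tables for the model-ordering study and 20 seeds for the
scene-level recovery study — sizes chosen so the whole suite completes in
about a minute while keeping the study's sample geometry exact.

## Known limitations

The generator's colour model is linear and single-latent; real stands
decouple brightness from greenness in ways only partially emulated by the
direct generator's correlation targets. Fits assume homoskedastic noise;
no uncertainty raster accompanies the AGB map because the method defines
none. The 30/8 holdout is the study's own design — no cross-validation
scheme is provided. Multispectral indices, texture features and other
species' masks are out of scope.
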