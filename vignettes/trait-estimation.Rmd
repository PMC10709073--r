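---
title: "Estimating segment-scale biochemical traits from reflectance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating segment-scale biochemical traits from reflectance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectraits)
```

`spectraits` estimates four biochemical traits of chopped plant segments —
dry matter (M_dry, g), water content (C_w, %), nitrogen content (C_N,
g/kg) and chlorophyll content (C_ch, mg/g) — from 350–2500 nm reflectance
measured in a controlled dark chamber, and scales them to whole plants.
This vignette is the package's own account of the science: the models, the
assumptions they rest on, the tunable parameters, the synthetic study the
test-suite runs on, and the numerical and design choices that were
genuinely open.

## Measurement model and calibration

A bench instrument chops a plant into segments of configurable length
(default 5 cm), records each segment's raw spectral signal and fresh
weight (balance precision 0.01 g), and periodically scans a white
reference panel. Reflectance is the band-wise ratio of sample to panel
signal (`calibrate_reflectance()`); the canonical grid is 1-nm sampling
from 350 to 2500 nm, 2,151 bands (`canonical_grid()`). Two conventions
matter:

* Calibration-noise reflectance slightly above 1 is *retained* up to 1.5.
  Values above 1.5 indicate a failed calibration and raise an error rather
  than being clipped, because silent clipping would bias the downstream
  regression.
* Files use a wide CSV layout (first column `segment_id`, remaining
  columns named by integer wavelength) with 17-significant-digit numbers,
  so write/read round trips are lossless. Raw-scan files reserve the id
  `WHITE_REF` for the panel row.

Resampling onto the canonical grid is linear and never extrapolates;
whether a particular spectrometer's native sampling was already
interpolated to 1 nm by vendor software is outside the package's
knowledge — the canonical grid simply assumes a 1-nm product.

## Gaussian-process regression

Each trait is regressed on reflectance with exact GP regression. With
~10²–10³ training segments against 2,151 correlated bands, a per-band ARD
kernel would carry more hyperparameters than data points, so the kernel is
an isotropic squared exponential on per-band-standardized inputs:
k(x, x′) = σ_f² exp(−‖x − x′‖²/(2ℓ²)), plus observation noise σ_n².
Targets are standardized to zero mean and unit variance, which gives the
prior mean a meaningful value (the training mean) and conditions the
optimisation; predictions are de-standardized on output.

Hyperparameters maximize the log marginal likelihood in log space
(L-BFGS-B with analytic gradients). The default is 5 restarts: one
data-driven start (unit signal variance, length scale at the median
pairwise distance, σ_n² = 0.05) plus seeded Gaussian perturbations of it.
Inference is by Cholesky factorization of K + σ_n²I with jitter starting
at 1e-8 and escalating tenfold to at most 1e-4 before failing. Exact
(dense) inference is deliberate: the intended data scale (≤ a few thousand
segments) is well within dense-solve range, and sparse approximations
would complicate the reproducibility contract — refitting with the same
data and seed is exactly reproducible. The predictive variance reported is
the latent-function variance k** − ‖L⁻¹k*‖², floored at zero.

Cross-validation folds are *warm-started*: `run_validation()` first fits
each trait on the full training table, then starts every fold's optimiser
at that optimum. With 33 of 34 treatments shared between folds the per-fold
optimum is nearby, so one restart per fold suffices and the procedure
remains fully deterministic.

## The dry-matter estimator family

* **Direct**: the GP predictive mean for M_dry, floored at 0 g with a
  warning (a negative mass is a model artefact, not a measurement).
* **In-Direct**: predict C_w, clamp it to [0, 100] %, and convert the
  measured fresh weight through the mass balance
  M_dry = (1 − C_w/100) × FW. C_w is stored in percent throughout the
  package and divided by 100 exactly here.
* **Ensemble**: the convex combination in which each method's weight is
  proportional to the *other* method's RMSE —
  w_on_indirect = RMSE_dir/(RMSE_dir + RMSE_in) and symmetrically — so the
  lower-error method receives the larger weight. The cross-assignment is
  implemented exactly as stated; it is internally consistent with
  inverse-error weighting. Two zero RMSEs fall back to 0.5/0.5.

Where the weighting RMSEs come from is a genuine design choice: using
held-out performance would leak validation information into the estimator.
`inner_cv_rmse()` therefore runs a treatment-grouped k-fold CV (default
k = 5) strictly inside the training partition. By default the inner folds
reuse the outer model's hyperparameters and refit only the kernel weights
(a single Cholesky solve per fold); this makes the inner loop essentially
free, and the weights it produces differ negligibly from full refits
because the hyperparameter surface moves little between folds. Full
re-optimisation is available via `refit_hyperparams = TRUE`.

All predicted concentrations are clamped to physical ranges (C_w in
[0, 100] %, others ≥ 0) with warnings before any downstream use.

## Plant scale and residue control

Chopping loses a little material; the residual rate
RR = (1 − CFW/TFW) × 100 quantifies it from the pre-chop plant weight TFW
and the summed segment readings CFW. A CFW more than 5 % *above* TFW
cannot be balance noise and rejects the plant.

Aggregation follows the traits' units: CM_dry is the exact segment sum;
CC_w is the fresh-mass-weighted mean (total water weight over total fresh
weight); C_N and C_ch are expressed per unit dry mass, so their plant
values are dry-mass-weighted means — that weighting is this package's
decision where only "aggregating" is specified, and fresh-mass weighting
is available as a sensitivity switch. Estimated CC_w deduces each
segment's fresh weight from the *estimated* M_dry and C_w
(FW = M_dry/(1 − C_w/100), with C_w capped at 99.9 % to keep the deduced
weight finite), so the plant-scale estimate never touches measured
weights; measured plant aggregates apply the same formulas to measured
inputs.

## Validation and profile analysis

Validation is leave-one-treatment-out: one fold per cultivar × nitrogen ×
stage treatment, so no segment is ever predicted by a model that saw its
treatment. Metrics are pooled — all held-out predictions are concatenated
and R²/RMSE computed once — which is stable when treatments contribute
uneven segment counts; per-fold averaging was the alternative and is not
used. R² is defined as 1 − SSres/SStot rather than squared Pearson
correlation, so systematic bias in any value range lowers the score even
when rank order is preserved. Plant-scale validation (CM_dry, CC_w)
aggregates the held-out segment predictions per plant. Holding out by
treatment is used at both segment and plant scale.

Vertical profiles use segment midpoints converted to relative height
(0 = base, 1 = top) and linear interpolation onto 10 uniformly spaced
heights 0.1, 0.2, …, 1.0; outside the midpoint span the nearest end value
is held. Affine height–trait relations are reproduced exactly at the grid
points. Trait correlations are Pearson r with two-sided t-test
significance (flagged at P < 0.01). The factor analysis computes r within
each replicate group (segments sharing cultivar, nitrogen and stage),
Fisher-z transforms it, and runs a one-way ANOVA across the chosen
factor's levels; groups with fewer than 3 complete segments are dropped
with a warning.

## The virtual instrument

No reference dataset ships with the package, so `build_dataset()`
generates one. It emulates the structure of a two-block rice trial — a
3 cultivar × 3 nitrogen (270/135/0 kg hm⁻²) factorial plus a 25-cultivar
panel at 270 kg hm⁻², 34 treatments, optionally crossed with three growth
stages — with the following components, all seeded through named
substreams of one root seed so any part regenerates bit-exactly:

* **Gradients.** Each trait is linear in relative height: dry matter and
  water content increase toward the base (2.6 → 0.8 g and 84 → 68 % from
  base to top), nitrogen and chlorophyll increase toward the top (14 → 32
  g/kg, 1.2 → 3.2 mg/g). Nitrogen supply scales the traits (positive
  slopes for M_dry/C_N/C_ch, slightly negative for C_w) and stage
  multipliers shift them. Per-plant offsets and per-segment scatter are
  Gaussian at assay-repeatability scale (e.g. 0.04 g and 0.4 % per
  segment). Configurations that push C_w to 100 % are an error.
* **Mass balance.** Fresh weight is derived as FW = M_dry/(1 − C_w/100),
  balance readings are quantized to 0.01 g, and the recorded dry matter is
  the dry fraction of the weighed sample — so M_dry = (1 − C_w/100) × FW
  holds exactly for every stored segment.
* **Forward model.** Reflectance is a smooth bright baseline attenuated by
  Gaussian absorption features at each trait's known absorber wavelengths
  (chlorophyll ≈ 430/662 nm; water ≈ 970/1200/1450/1940 nm; dry matter ≈
  1720/2100/2300 nm; protein-bound nitrogen ≈ 2180/2350 nm):
  R(λ) = baseline(λ)·exp(−Σ strength·value·g(λ))·(1 + scatter) + noise,
  clipped to [0, 1.5]. Default feature strengths put trait effects roughly
  10× above the additive band noise (sd 0.002) at the feature centers, and
  reflectance is strictly decreasing in each trait there — the property
  that makes inversion well-posed. This is a deliberately simple
  exponential-absorption harness, not a radiative-transfer model, and it
  must not be read as reproducing any real instrument's spectra: passing
  tests show the *pipeline* recovers traits from spectra generated this
  way, not that it would reach the same accuracy on field data, where
  scattering, specular effects, moisture films and organ mixtures are far
  richer.
* **Residue.** RR is drawn from Gamma(shape 2, scale 1.25 %), capped at
  50 %, giving P(RR < 4 %) ≈ 0.83 — a right-skewed loss pattern with most
  plants nearly intact. The pre-chop weight is reconstructed as
  CFW/(1 − RR/100).
* **Labelling.** All segments carry M_dry and C_w truth; random subsets
  sized 250/1806 and 200/1806 of the segments carry C_N and C_ch truth,
  mirroring the practice of assaying nitrogen and chlorophyll on subsets.
  Full truth is retained in `true_*` columns for analysis code.

## Problem sizes and numerical choices

The reference study used by the test suite and `scripts/acceptance.R` is
34 treatments × 2 plants × ~10 segments (≈ 720 segments) with every 10th
band (216 bands), chosen as a desk-scale configuration that preserves the
structure of the full design; unit tests use 3–6 treatments and coarser
grids. On this study the leave-one-treatment-out R² exceeds 0.99 for all
four traits and the recovered mean profiles are monotone in the expected
direction for ≥ 97 % of treatment × trait combinations — comfortable
margins over the package's acceptance thresholds (0.85 segment scale,
0.90 plant-scale CC_w, 90 % monotone).

Numerical conventions collected in one place: jitter 1e-8 → 1e-4 tenfold;
optimiser bounds on log σ_f² ∈ [−10, 8], log ℓ within ±(6–8) of the median
distance heuristic, log σ_n² ∈ [log 1e-8, 4]; predictive variances floored
at 0; negative dry-matter means floored at 0 g with a warning; C_w clamped
to [0, 100] % (99.9 % when a fresh weight is deduced from it); inner-CV k
clamped to the number of treatments with a warning; Fisher z clipped at
|r| = 0.9999; interpolation holds end values outside the data span; all
random draws pass through per-purpose derived seeds, and every seeded
function restores the caller's RNG state.

## Limitations

* The forward model omits canopy structure, soil, specular reflection and
  detector artefacts; transfer to a physical instrument requires training
  on measured data.
* The isotropic kernel cannot express per-band relevance; band-selection
  or ARD variants are out of scope.
* Exact GP inference scales as O(n³); beyond ~5,000 segments a sparse
  method would be needed.
* Dry-mass weighting for plant-scale concentrations is a convention, not
  an inferred fact about any reference protocol; the fresh-mass switch
  exists precisely so users can test sensitivity.
* Spike/panicle organs and per-organ decomposition are out of scope; the
  generator models vegetative segments only.
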