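---
title: "Methods: multiway N-PLS soft sensors for fluorescence EEMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiway N-PLS soft sensors for fluorescence EEMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Phototrophic cultures (microalgae such as *Nannochloropsis*) are monitored
off-line: cell counts, pigment extractions and GC-based fatty-acid assays
take minutes to days. A fluorescence excitation-emission matrix (EEM) — the
emitted intensity over a grid of excitation × emission wavelengths — can be
acquired from the raw culture broth in minutes, non-destructively. The EEM
carries the signatures of the natural fluorophores (chlorophyll and other
pigments above 600 nm emission, aromatic amino acids below 400 nm) *and* of
the non-fluorescent compounds that absorb or quench that signal. `eemnpls`
turns a collection of EEMs plus reference assay values into a calibrated
soft sensor: a multiway regression that predicts culture parameters (cell
concentration, chlorophyll content, fatty-acid fractions) from a single
spectral acquisition.

The package covers four stages, each usable on its own:

1. **Pre-processing** of raw EEM grids (scatter, inner filter effect).
2. **Tri-linear N-PLS regression** on the `[sample × emission × excitation]`
   array.
3. **Nested double cross-validation** for honest error estimation and
   latent-variable selection.
4. **Regression-coefficient maps** that fold the model back onto the
   wavelength plane.

A synthetic generator (`simulate_eem_dataset()`) produces datasets with the
exact statistical structure the models assume, plus ground truth, so every
stage is verifiable without instrument data.

## Pre-processing

Culture samples are mostly water, so the dominant features of a raw EEM are
elastic scatter ridges, not fluorescence: the first-order Rayleigh ridge
along `em = ex` and its second order along `em = 2·ex`. Their intensity is
unrelated to the biology, and left in place they would dominate any
least-squares fit. The chain applied by `preprocess_sample()` is:

1. **Inner-filter correction** (`correct_inner_filter()`). At non-trivial
   optical density the excitation beam and the emitted light are themselves
   absorbed, attenuating the signal by roughly
   `10^(-(A(ex)+A(em))/2)` for a centred 1 cm cuvette, where `A` is the
   sample's absorbance spectrum. The correction multiplies each cell by
   `10^((A(ex)+A(em))/2)`. Absorbance is linearly interpolated to the cell's
   wavelengths; outside the measured range it is taken as 0 with a warning
   (long-wavelength absorbance of a dilute culture is negligible, and
   extrapolating baseline noise would be worse). Negative absorbance
   readings are baseline noise and are clipped to 0 by default
   (configurable to reject instead).
2. **First-order Rayleigh excision** (`excise_first_order_rayleigh()`):
   cells with `|em − ex| ≤ 15 nm` become *missing* — there is no
   fluorescence information under the ridge to recover.
3. **Second-order Rayleigh interpolation**
   (`interpolate_second_order_rayleigh()`): cells with `|em − 2·ex| ≤ 15 nm`
   are bridged by 1-D linear interpolation along the emission axis, per
   excitation column, between the nearest non-missing neighbours outside
   the band. The second-order ridge crosses the informative pigment region,
   so deleting it would cost signal; a linear bridge preserves the local
   intensity level (and, for a tri-linear signal, stays linear in the
   component concentrations, which is what the regression needs). If the
   band touches the grid edge and a neighbour is unavailable, the cells are
   set missing rather than extrapolated.
4. **Sub-diagonal zeroing** (`zero_below_diagonal()`): emission strictly
   shorter than excitation is physically empty; those cells are set to 0
   and marked *non-missing* (zero is a legitimate modelled value there).
   Where the excised first-order band dips below the diagonal, zeroing
   wins, giving the familiar clean lower triangle.

Design choices worth stating explicitly:

* **Band halfwidths** are instrument-dependent (slit widths, step size) and
  default to ±15 nm for both orders — a common choice for a 5 nm grid —
  exposed in `preprocess_config()`.
* **Stage order.** The inner-filter correction is applied *first*, on raw
  measured intensities, so that the second-order interpolation bridges
  already-corrected values; listing scatter handling before IFE in a
  protocol is descriptive, not algorithmic. The order is configurable
  (`order = "scatter_first"`) for users who want the other convention; for
  cells outside the interpolated band the two orders commute exactly,
  since excision, zeroing and the multiplicative correction act cell-wise.
* **Missing ≠ zero.** Missing cells are tracked by an explicit boolean
  mask, never a sentinel value, so post-zeroing intensities are never
  conflated with unmeasured cells.

Raman scatter, blank subtraction and Raman-unit normalisation are out of
scope: the modelling chain corrects only what the regression cannot absorb
(Rayleigh ridges, IFE non-linearity); a sample-constant Raman background is
removed by centering.

## Tri-linear N-PLS regression

`fit_npls()` implements the classical single-response tri-PLS1 with
deflation. Let `X` be the `I × J × K` array (sample × emission ×
excitation) and `y` the response on the modelling scale. `X` is centred
cell-wise over samples and `y` mean-centred; spectral cells are *not*
scaled to unit variance (standard for spectra: scaling would inflate noise
cells). For each latent variable (LV) `f = 1..F`:

1. Form the covariance matrix `Z[j,k] = Σ_i y_i · X[i,j,k]` from the
   current residuals, over included cells only.
2. Take the dominant singular pair of `Z` as the emission weight `wJ_f` and
   excitation weight `wK_f` (both unit norm). This is the rank-1 pair
   maximising the covariance between `y` and the scores.
3. Scores: `t_i = Σ_{j,k} X[i,j,k] · wJ_j · wK_k`.
4. Re-estimate the inner coefficients `b` by OLS of the centred `y` on
   *all* scores so far (tri-PLS scores are not orthogonal, so joint
   re-regression is required).
5. Deflate: `X ← X − t ⊗ (wJ ∘ wK)`, `y_res ← y − T b`.

The per-size coefficient vectors are retained, so a single fit at `F_max`
yields predictions at every smaller size — the sequential structure means
the first `F` LVs of a larger model *are* the `F`-LV model, which the
leave-one-out loop exploits.

Numerical conventions:

* **Sign.** The SVD pair `(wJ, wK)` is defined up to a joint sign flip; the
  largest-magnitude element of `wJ` is made positive (flipping `wK` with
  it), so repeated fits are bit-identical.
* **Rank exhaustion.** If a score norm collapses below `1e-12` of the first
  LV's score norm the model is truncated at the last usable LV with a
  warning (noiseless low-rank data exhausts its rank before `F_max`).
* **Missing cells.** Cells in the dataset's global missing mask — the union
  of per-sample masks, which after pre-processing is just the excised
  first-order band, identical across samples — are excluded from centering
  and from every inner product. No imputation is attempted. In *new* data,
  a cell that is missing but included in the model is treated as equal to
  the training mean (zero after centering), with a warning; this is the
  least-informative completion for a centred linear model.
* **Deflation variant.** Both `X` and `y` are deflated and `b` re-estimated
  at every step (the original tri-PLS1 formulation). With a single
  excitation column the procedure collapses to a PLS1 on the unfolded
  matrix: its fitted values and predictions coincide with classical NIPALS
  PLS1 (the score *bases* differ — weight- vs loading-deflation — but they
  span the same Krylov space, and the response is regressed on the full
  span). The test suite checks this equivalence against an independently
  written NIPALS oracle.

### Coefficient maps

The fitted model is linear in the centred intensities, so it folds into one
coefficient per wavelength pair (`coefficient_map()`). With
`r_f = vec(wJ_f ∘ wK_f)` restricted to included cells, the score of LV `f`
is the functional `v_f = (I − r_1 r_1′)…(I − r_{f−1} r_{f−1}′) r_f` applied
to the centred, unfolded sample, and the map is `Σ_f b_f v_f` — an `O(F²·JK)`
recursion, no large matrices. The map plus intercept reproduces
`predict()` to machine precision (asserted at `1e-8`, and independently by
finite-difference probing of single cells at `1e-6` relative). Maps export
in the same CSV grid dialect as an EEM, so any heat-map tool can draw them;
high-magnitude regions show which spectral bands drive each prediction
(for a pigment-loaded response, the emission band above 600 nm).

## Validation: nested double cross-validation

Reporting the training fit of a PLS model is meaningless — complexity `F`
can always be raised until the fit is perfect. `run_double_cv()` therefore
nests two loops:

* **Outer, 4-fold** (default): samples are split at random into four folds
  of near-equal size (exactly equal when `n` is divisible by 4 — e.g. 92
  samples give four folds of 23, i.e. 69 training / 23 validation per
  split; 76 give 57/19; 72 give 54/18). Each fold is held out once, so
  every sample receives exactly one out-of-fold prediction.
* **Inner, leave-one-out** on the 75% training portion: for each candidate
  `F` up to `max_lvs`, each training sample is left out, the model refitted
  and the sample predicted; `RMSECV(F)` is the root mean squared error of
  these predictions, and the chosen `F` minimises it, with ties broken
  toward fewer LVs (parsimony). `max_lvs` defaults to 12 and is clipped to
  `training size − 2`.

The held-out fold is then predicted by a model fitted at the chosen `F` on
the full training portion. Reported per fold and pooled: RMSECV, RMSEP,
R², slope, variance explained in `y`, and the relative error
(`100·RMSE/mean(obs)`). Conventions, stated because either choice is
defensible:

* R² and slope come from the simple OLS of **predicted on observed** (the
  R² is then the squared correlation; the slope orientation matters and is
  flagged here).
* All metrics are computed on the **log10 modelling scale** when the
  response was transformed (`log10_transform()`), matching how such models
  are reported (e.g. errors in log10 cells/mL).
* When folds disagree on `F`, the final full-data model
  (`fit_final_model()`) uses the **mode** across folds, ties to the
  smaller.
* The fold split is random but fully seeded; two runs with the same seed
  are bit-identical.

Responses spanning decades are log10-transformed before modelling to
normalise their distributions; the transform is recorded per column and
invertible.

## The synthetic generator

`simulate_eem_dataset()` draws datasets with the statistical structure the
pipeline assumes, plus ground truth. Per sample:

* **Signal**: a tri-linear mixture of Gaussian fluorophores. The default
  three components place a pigment-like band (ex 440/40 nm, em 683/12 nm),
  a protein-like band (ex 280/12 nm, em 340/25 nm) and an accessory pigment
  (ex 490/30 nm, em 660/20 nm) — the two regions that dominate a culture
  EEM — with brightnesses 1000/600/800 per concentration unit.
* **Concentrations**: log-uniform on `[0.5, 3]` per component. The range is
  a deliberate compromise: responses are modelled as log-linear in
  concentration while the spectra are linear in it, so over a log-range
  `[−h, h]` the best linear predictor of `log10(c)` from `c` has
  `corr²(u, 10^u)`, `u ~ U[−h, h]` — about 0.95 at the chosen ~6-fold
  range, 0.92 at a 10-fold range, 0.76 over two decades. A ~6-fold spread
  is a realistic within-campaign variation for pigment content and keeps
  the log-linearity mismatch subordinate to other error sources. This
  ceiling is intrinsic to any linear model on such data, not an artefact of
  this implementation.
* **Inner filter effect**: each component contributes a Gaussian absorbance
  band (peak 0.05 per concentration unit at its excitation peak), and the
  clean signal is attenuated by `10^(−(A(ex)+A(em))/2)` — the exact inverse
  of the correction, so pre-processing can undo it given the spectrum.
* **Scatter**: additive Gaussian ridges along `|em − ex|` and `|em − 2·ex|`
  (sd 5 nm), first-order amplitude 10× the brightest fluorophore
  (scatter dominates raw culture spectra; failures of scatter handling must
  be visible), second order at a quarter of that, per-sample amplitude
  jittered ±10%.
* **Noise**: white Gaussian, sd = 2% of the dataset's peak clean intensity
  (SNR 50).
* **Response**: `log10(raw) = 1 + log10(c_pigment) + N(0, 0.02)`; the raw
  (back-transformed) value is stored so the pipeline exercises its own
  log10 transform.

What the generator does **not** emulate — and what passing tests therefore
do not establish about instrument data: multi-peaked and temperature-
dependent pigment spectra, fluorophore–quencher interactions beyond the
inner filter effect, Raman scatter, photobleaching and drift, circadian
time-series correlation between samples, and non-Gaussian detector noise.
Recovery results on synthetic data bound what the algebra can do under its
own assumptions; they are not a validation on cultures.

## Problem sizes and runtime choices

The test suite exercises the full acquisition geometry (109 × 109 grids)
where grid arithmetic matters, and 10–20 nm grids for end-to-end runs,
which keeps the default suite under a minute without changing any
algorithmic path. The headline recovery check runs the complete pipeline —
generation at the default study conditions (n = 60, three components,
SNR 50), pre-processing, log10 transform, 4-fold double CV with
leave-one-out selection — with the inner loop capped at 6 LVs: the
generator contains three tri-linear components, so 6 gives the selector
twice the true complexity to choose from while keeping the
`4 × 45` leave-one-out refits economical. The pooled out-of-fold R²
requirement there is ≥ 0.9, against the ~0.95 analytic ceiling discussed
above.

## Known limitations

* Single-response models only (one N-PLS per parameter); no PLS2, no
  PARAFAC decomposition of the spectra themselves.
* The missing-cell policy assumes the missing pattern is (near-)identical
  across samples, as produced by the scatter excision; datasets with
  heavy, sample-specific missingness would need imputation machinery this
  package deliberately omits.
* Second-order interpolation is 1-D along emission; a 2-D inpainting could
  do better near the band edges.
* The inner-filter correction assumes 1 cm pathlength and absorbance
  measured on (or interpolable to) the EEM wavelength range.
* `arnaud_chlorophyll()` returns mg/L of extract; conversion to per-cell
  content requires the user's cell counts.
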