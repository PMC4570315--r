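---
title: "Methods: simulating and analysing colorimetric wine taste-sensor arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing colorimetric wine taste-sensor arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

A colorimetric taste sensor reads the composition of a liquid sample from
the colour changes of an array of non-specific indicator dyes. Eight
dye-bead conjugates (alizarin, calconcarboxylic acid, cresol red, crystal
violet, fluorescein, methylthymol blue, phenol red, xylenol orange) sit in
separate wells; a camera photographs the array before and a few minutes
after the sample is loaded, and the mean red, green and blue intensity of
each well is differenced between the two images. That yields a 24-value
colour fingerprint (8 dyes × 3 channels) per sample. The chemometric task
is to map this fingerprint to three taste quantities defined from the
sample's chemistry:

* **sweetness** = 0.75·glucose + 1·sucrose + 1.5·fructose (mg/L), the
  sugar content weighted by perceived sweetness relative to sucrose;
* **sourness** = Σ acid concentration / molar mass, i.e. total organic
  acid molarity in mmol/L, over citric, malic, tartaric, succinic, lactic,
  acetic and (by default) formic acid;
* **astringency** = total tannin in mg/L tannic-acid equivalents, measured
  by a Folin-Ciocalteu assay: transmittance at 410 nm is converted to
  absorbance (−log₁₀ T), read off a tannic-acid standard curve
  (1.25–30 ppm), and multiplied by the 100-fold sample dilution.

Because no raw colour or chromatography measurements from a real wine
panel are publicly available, the package is built around a synthetic-data
generator with known ground truth, so every stage of the analysis —
image colorimetry, principal component analysis, neural-network
regression and model selection — can be validated quantitatively.

# The synthetic panel

`generate_panel()` emulates a two-cluster white-wine panel: a fraction of
roughly 7/23 of the base wines are "sweet" wines with high sugar and high
acid, the rest "dry". The literature panel this emulates showed sweetness
1029–19,705 and sourness 36–100 (mmol/L) for dry wines against sweetness
46,800–123,019 and sourness 220–478 for sweet wines, with similar tannin
(72–573 mg/L) in both groups.

The generator draws each wine's *total* sweetness and sourness
log-uniformly within its cluster band and then partitions the total over
the individual chemicals (fructose the dominant sugar; malic and tartaric
the dominant acids), clipping to the observed per-chemical extremes. We
chose this construction over independent per-chemical draws because only
the totals are constrained by the published cluster structure; independent
draws cannot guarantee that the two clusters remain strictly separated in
score space, which is the property the downstream classification and
regression analyses rely on. Mixture samples are convex combinations of
two distinct base wines with a uniform random weight — the real mixing
proportions were never reported, so no fidelity is claimed — and since all
three score formulas are linear in concentrations, mixture scores always
lie between the parent scores.

# The dye response model

No functional form for dye-bead colour response is published, so the
generator uses a Langmuir-form saturating dose response, the natural
choice for equilibrium dye binding: chemical *c* at concentration *x*
shifts channel *ch* of dye *d* by

$$\Delta_{d,ch} = \sum_c S_{d,ch,c} \, \frac{x_c}{x_c + K_c},$$

with signed sensitivities \(S\) and per-chemical half-saturation
constants \(K_c\). The default model fixes \(K_c\) at the **top** of each
chemical's observed concentration range, so the dyes operate below half
saturation throughout the panel. This mirrors the strong, near-linear
absorbance-versus-concentration relationships reported for the real
dye-bead conjugates; placing \(K\) in the middle of the (log-scale) range
instead would park the sweet cluster deep in saturation and destroy
exactly the concentration information that the real sensor demonstrably
carried. Each dye responds appreciably to a different 4–6 chemical subset
(no two dyes share a response pattern). Sensitivities, peak positions and
response subsets are drawn once from a fixed internal seed, so
`default_dye_model()` is a constant; users may supply their own
`dye_model()`.

The same Langmuir term drives the spectral model: each dye carries two to
three Gaussian absorbance peaks in 400–780 nm whose heights are modulated
monotonically with concentration, which supports band-averaged absorbance
analysis (red 620–780 nm, green 500–580 nm, blue 450–500 nm).

# Image rendering and colorimetry

`render_image_pair()` paints a 2×4 grid of circular wells (radius 20 px,
pitch 60 px by default) on a uniform dark background: baseline dye
colours in the *before* frame, baseline plus colour change (clipped to
the 8-bit range, with clipping flagged per well) in the *after* frame,
plus independent per-pixel Gaussian noise. Geometry is a package
convention — no well layout was ever published. The model is linear
8-bit RGB; camera gamma and illumination gradients are deliberately out
of scope, so passing tests say nothing about detection robustness under
uneven lighting.

`detect_wells()` finds wells by thresholding the per-pixel deviation from
the border-estimated background colour, labelling connected components
(`EBImage::bwlabel`), and filtering by area, aspect ratio and fill
fraction of the bounding circle; template matching would be
over-engineered for flat-lit arrays. Wells are returned in canonical
row-major order, and the dye-to-well assignment is a documented
convention (alphabetical dye order, left to right, top to bottom).
`extract_features()` averages pixels within 80 % of each well radius — a
guard against edge artefacts and anti-aliasing — and returns
after-minus-before differences, dye-major (`alizarin_R, alizarin_G,
alizarin_B, …`), exactly 24 values. PNG I/O quantises to 8 bits
(±0.5 counts); in-memory rasters are doubles, and the pipeline's
image-free re-rendering path applies the same quantisation so results are
identical either way.

# Principal component analysis

`fit_pca()` is mean-centred PCA by singular value decomposition. No
unit-variance scaling is applied by default because all 24 features share
units (RGB counts); `scale = TRUE` enables autoscaling. Explained
variance percentages are reported in calibration mode over all
`min(n−1, 24)` components and always total 100 %. Loadings carry a
deterministic sign convention (largest-magnitude element positive) so
score plots are reproducible across platforms. The cross-validated
variance mode of the commercial software historically used for this kind
of analysis is under-specified and not reimplemented.

# The neural-network engine

`ann_train()` fits a fully connected feed-forward network (24 inputs, one
or two hidden layers, scalar output) by back-propagation, written from
scratch because the four training algorithms are the analytical core of
the package:

* **incremental** — per-sample gradient descent, configured learning rate;
* **batch** — mean-gradient descent per epoch;
* **rprop** — iRPROP⁻ with the standard constants (η⁺ = 1.2, η⁻ = 0.5,
  Δ₀ = 0.1, Δ_max = 50, Δ_min = 10⁻⁶); no learning rate;
* **quickprop** — Fahlman's quadratic-approximation update with growth
  limit μ = 1.75 and weight decay 10⁻⁴, FANN-style slopes.

Activations are sigmoid, linear, Gaussian (e^{−x²}), sine and cosine,
with steepness fixed at 1. Weights initialise uniform(−0.5, 0.5) from the
configuration seed; training is bit-reproducible given the seed.

Two scaling choices matter. Targets are min–max scaled into the output
activation's working range with a guard band — (0.1, 0.9) for sigmoid and
Gaussian, (−0.9, 0.9) for sine/cosine, (0, 1) for linear — because
bounded activations cannot reach raw taste scores (sweetness spans five
orders of magnitude); predictions are mapped back to target units.
Inputs are standardised to training-set mean and unit variance: ΔRGB
features of magnitude ±50 would otherwise saturate sigmoid units under
the uniform(−0.5, 0.5) initialisation and gradients would vanish at
epoch 1. With validation data, training stops after 50 epochs (default)
without validation improvement and the best-validation weights are kept;
an optional `target_mse` stops training once the scaled-target MSE
reaches a desired error, and a non-finite MSE aborts with a diagnostic
rather than returning a broken model.

# Model selection

`make_split()` reproduces the published protocol at the canonical panel
size: 35 of 45 samples form the calibration set, split 7:3 into training
and validation; the remaining 10 are the held-out test set. Other sizes
use a 78 % calibration fraction.

`ann_grid()` enumerates the standard configuration pools — four
algorithms × learning rates {0.5, 0.7, 0.9} × first hidden layer
{9, 11, 13} × second hidden layer {0, 9, 11, 13} × five activations per
layer (14,400 configurations in full). The restricted grid is four
curated configurations: the three best-performing published patterns
(incremental/0.9/9-sigmoid/11-sigmoid/sin; quickprop/0.9/9-sigmoid/
11-gaussian/sin; batch/0.7/13-sigmoid/11-gaussian/cos) plus an RPROP
analogue so all four algorithms appear.

`ann_grid_search()` trains every configuration from `n_restarts = 5`
seeded initialisations, evaluates every trained model on the held-out
samples, and ranks by R² (squared Pearson correlation, the
measured-vs-predicted convention; the 1 − SS_res/SS_tot form is stored
alongside) with RMSEP

$$\mathrm{RMSEP} = \sqrt{\tfrac1N\sum_i (k_{E,i}-k_{P,i})^2}$$

as the tie-breaker, mirroring the published procedure in which each
developed model predicts the 10 test samples and the best is kept.
Restarts are enumerated because back-propagation on 25-sample training
sets is strongly initialisation-dependent (single-init test R² varied by
0.2 across seeds in development); each restart is simply another
developed model offered to the same selection rule. The published
ranking criteria ("highest R², smallest RMSEP") do not state an order;
R²-first is our choice. Whether selection should use the validation set
instead of the test set is genuinely ambiguous in the source protocol;
both are supported (`eval_on`), test-set selection being the default as
the protocol text reads. Diverged configurations receive sentinel scores
(R² = 0, RMSEP = ∞) and rank last instead of aborting the sweep. RMSEP
is also reported as a percentage of the observed target range,
100·RMSEP/(max − min).

# Default study conditions and what the tests show

Defaults throughout are the published panel conditions: 23 base wines +
22 mixtures, colour-response noise 0.5 RGB counts (flat-lit LED imaging
with well-averaging justifies sub-count measurement noise), pixel noise
1 count, 2000-epoch training budget, restricted grid, five restarts.
Under these conditions the end-to-end run (images included) reaches
held-out R² ≈ 0.95–0.99 for all three tastes, the same accuracy regime
as the published models, and pure-noise targets give mean grid R² well
below 0.3, confirming that the split leaks nothing. These results
validate the pipeline's internal consistency on data whose generative
process matches its assumptions — additive Gaussian noise, flat
illumination, Langmuir responses, linear score formulas. They cannot
certify performance on real wines, where dye chemistry, camera gamma and
matrix effects are unmodelled; the published real-data headline numbers
(R² 0.96/0.95/0.83, PC variances 55.96/14.94/11.66 %) are not
reproducible without the unpublished raw measurements, and the package
does not attempt to match them beyond arithmetic consistency checks.

# Numerical notes

* Tannin curve fitting requires transmittance in (0, 1]; negative curve
  inversions clamp to zero with a warning, and a zero-slope calibration
  is rejected as non-invertible.
* R² is undefined for constant vectors (error in `r_squared()`, defined
  as 0 with a warning in `concentration_response_r2()`, where a flat
  band response is a meaningful outcome).
* Well detection needs the well/background contrast to exceed the
  threshold (default 25 counts) and fails loudly, reporting the
  candidate count, rather than guessing.
* All generator functions accept a seed and restore the caller's RNG
  state on exit.
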