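---
title: "Estimating canopy leaf chlorophyll content from simulated and synthetic hyperspectral data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating canopy leaf chlorophyll content from simulated and synthetic hyperspectral data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`canopylcc` implements a complete retrieval study for leaf chlorophyll
content (LCC, µg/cm²) of orchard tree canopies from 1-nm visible/near-infrared
reflectance: a physically based forward simulator generates canopy spectra, a
derivative-preprocessing + regularized band-selection + kernel-regression
pipeline estimates LCC, and a synthetic field-campaign generator emulates a
SPAD-characterised orchard survey so the measured-data arm of the pipeline is
fully testable offline. This vignette records the models, the tunable
parameters, and the design decisions, including the ones that were genuinely
open.

## The forward simulator

The simulator chains three classical components.

**Leaf optics (generalized plate model).** A leaf is modelled as a stack of
`N` absorbing plates (`N` ≥ 1, the mesophyll structure parameter; fractional
`N` via the Stokes system). Per-wavelength absorption is the content-weighted
sum of specific absorption coefficients for chlorophyll a+b (`cab`, µg/cm²),
carotenoids (`car`), water (`cw`, g/cm², i.e. cm of equivalent water
thickness) and dry matter (`cm`, g/cm²), divided by `N`. Interface
reflectances follow from the refractive index through Stern's average
transmissivity integral (light incident within 40° at the upper surface), and
the single-plate transmissivity uses the exponential-integral closed form
`τ(k) = (1-k)e^{-k} + k²E₁(k)`. The canopy grid varies only (`N`, `cab`);
carotenoids default to the realistic pigment ratio `car = cab/4` (overridable)
and brown pigments are 0.

**Optical constants are synthetic.** Published specific-absorption tables are
data files of other software packages and are not redistributable here, so
`synthetic_optical_constants()` builds smooth analytic stand-ins: sums of
Gaussian absorption features with the qualitative shape and magnitude of
in-vivo spectra (chlorophyll Soret and red bands vanishing past ~740 nm,
carotenoids confined to 400–560 nm, water overtones rising through the NIR, a
weak dry-matter continuum), plus a slowly decreasing refractive index. The
same applies to the reference dry-soil spectrum
(`synthetic_soil_spectrum()`), which the scene parameter `soil_scale`
multiplies. Consequently simulated spectra are *physically plausible rather
than instrument-accurate*: absolute reflectance values and fine spectral
structure differ from any real leaf, while every qualitative property the
pipeline relies on (pigment sensitivity at 670 nm, the red edge, NIR
structure scattering, soil brightness effects) is present. All downstream
statistics are agnostic to this choice.

**Canopy layer (SAILH).** The four-stream turbid-medium solution for a
homogeneous leaf layer over a soil background, with an ellipsoidal
(mean-angle) leaf inclination distribution over the 13 standard angle classes
and the hot-spot correction of the single-scattering bidirectional term
(hot-spot parameter `q`, default 0.01; not part of the varied grid). The
observed reflectance mixes the direct and diffuse incident streams with
diffuse fraction 0.1. One point worth recording: with a nonzero hot-spot
parameter the bidirectional term keeps growing slowly with LAI (its
correlated-path exponent scales like `√(k_s k_o)·LAI/α`), so "infinite"
canopy reflectance saturates to ~10⁻³ only; with `q = 0` the turbid-medium
solution saturates to machine precision by LAI 15. The tests check soil
independence at LAI 15 and exact saturation at `q = 0`.

**Forest composition (FLIM-style).** Scene reflectance mixes an optically
infinite crown layer (SAILH at LAI 15) with the background (understory layer
over scaled soil) through directional crown cover:

`R = ρ∞·(1 − T_s·T_o) + ρ_bg·T_s·T_o`, with `T_d = 1 − C_d·(1 − τ_d)`,

where `C_view = min(1, stems·π·(d/2)²/10000)`, `C_sun = min(1,
C_view/cos θ_s)`, and `τ_sun`, `τ_view` are the crown's direct-beam gap
fractions (`e^{-k_s·LAI}`, `e^{-k_o·LAI}`) from the single-tree LAI. The
exact coupling of the crown transmittances was an open choice (the literature
admits variants that include scattered streams); the direct gap fractions are
the simplest physically bounded convention, and the composition is isolated
in `flim_compose()` so it can be swapped. Defaults: 500 stems/ha, 2.5 m
trees, 2 m crowns, understory LAI 0.1, sun zenith 30°, nadir view.

The simulated grid covers `cab` 25–50 by 5, `N` 1–1.5 by 0.5, single-tree LAI
1–7 by 1, soil scale 0.6–1 by 0.1, and average leaf angle 0–60° by 15° —
6·2·7·5·5 = 2100 scenes, enumerated with `cab` slowest. The simulated range
is 400–1050 nm at 1 nm (651 bands): the leaf optical constants are defined
from 400 nm, so the 350–399 nm part of the instrument range exists only in
the synthetic field arm, filled by boundary extension and flagged.

## Preprocessing

Spectra are cropped to the analysis window (inclusive), optionally smoothed
with a Savitzky–Golay filter (order 2, window 5; edges handled by the
off-centre evaluation of the edge-window polynomial), and differentiated by
central finite differences, `FD_i = (R_{i+1} − R_{i−1}) / (λ_{i+1} −
λ_{i−1})`; the second derivative applies the operator twice. Edge bands where
the central estimate is undefined are dropped (one per edge per order) so
every retained band is a true central estimate. Simulated spectra are
noiseless and pass through unsmoothed; synthetic field spectra are smoothed
at generation, matching the stated measurement protocol, and derivatives are
computed before splitting (a per-sample, target-free transform — it cannot
leak labels).

## Band selection

`lasso_path()` minimizes the elastic-net objective

`(1/2n)·Σ(y − Xβ)² + λ·(α‖β‖₁ + (1−α)/2·‖β‖₂²)`

by cyclic coordinate descent in covariance (Gram) form, with warm starts
down a descending λ path and an active-set strategy (inner sweeps on the
active set, full sweeps as KKT checks). Predictors are centred and scaled to
unit 1/n-variance, the response is centred, and coefficients are reported
back on the original scale; this standardization contract is what makes the
printed penalty meaningful and gives exact scale equivariance (scaling `y` by
`c` scales both the coefficients and the selected λ by `c`). Convergence is
declared when the largest squared coordinate update falls below
`tol·var(y)` (`tol = 1e-7`), the convention of the reference convex solver
against which the tests verify coefficients to 1e-6 at fixed (α, λ).

Cross-validation selects λ at the minimum of the mean k-fold MSE (the λ-min
rule, deliberately not the one-standard-error rule), with ties broken toward
the sparsest λ. Defaults: 100 log-spaced λ from the all-zero threshold
`max|x_jᵀy|/n/α` down to 10⁻⁴ of it; 10 folds. The elastic net searches α
over the 99 interior values 0.01…0.99 ("dividing (0, 1) into 100 parts" —
interior because the mixing parameter is defined strictly between the ridge
and LASSO limits) and returns the (α, λ) pair with the smallest CV MSE.
Per-fold Gram matrices are computed once and shared across the whole α grid,
which is what makes the 99-point search affordable.

Bands with nonzero coefficients at the chosen (α, λ) are the "important
bands"; `selected_band_report()` lists them with a red-edge (670–760 nm)
flag.

**A consequence worth understanding.** On the *noiseless* simulated grid the
CV error decreases monotonically with model size — more bands always help
when there is no noise floor — so the λ-min rule lands at the dense end of
the path (several hundred bands) rather than at the sparse interior minima
reported for comparable real-data studies. This is a property of the study
conditions, not of the solver (it persists under 10⁻¹¹ convergence
tolerance): an interior CV minimum requires noise. The package reproduces
sparse interior selection on the noisy synthetic field arm.

## Support vector regression

`fit_svr()` standardizes features *and* the response (fitted on the training
folds only; the ε = 0.1 tube is therefore in response-sd units, the usual
libsvm convention) and grid-searches (C, γ) for an RBF kernel by k-fold CV
MSE, refitting the winner on the full training set. Defaults: C ∈ 2^{−2…12},
γ ∈ 2^{−14…0} (step 2 in the exponent), 5 folds. For large training sets the
search cross-validates on a seeded random subsample (cap 800) at a looser QP
tolerance, per the libsvm practical guide; the final refit always uses the
full data and standard tolerance. With the full published-practice grid
(C up to 2¹⁵, γ up to 2³, 399 combinations) a single full-spectrum model
costs tens of minutes; the narrowed grid changes none of the selected models
on this problem family. All knobs are exposed in `svr_config()`.

## Evaluation

`r_squared()` implements the squared Pearson correlation between observed
and predicted values — the printed form of the study's determination
coefficient. Its affine invariance is a documented consequence: a model
whose predictions are a linear rescaling of the truth still scores 1, which
is why RMSE is reported alongside. `run_experiment()` fits the nine models
(3 derivative orders × {full spectrum, LASSO bands, EN bands}, all through
SVR) on one shared split, with selection and tuning confined to the training
partition; any single model failure is recorded as an NA row rather than
aborting the report.

## The synthetic field campaign

`generate_field_campaign()` stands in for an undeposited 69-tree orchard
survey. Per tree: SPAD is drawn from a truncated normal (mean 36.00, sd
2.69, bounds 29.50–42.00; exact inverse-CDF sampling), converted to LCC by
the published calibration `LCC = 0.709·SPAD − 1.576` (exact inverse
provided; the formula extrapolates to negative LCC below SPAD ≈ 2.22 and
warns there), and used as the simulator's `cab`. Nuisance parameters (N,
LAI, soil scale, leaf angle) are drawn uniformly over the full simulation
grid ranges — the least-informative choice, since the survey reports no
per-tree values — and the spectrum receives measurement noise: per scan,
multiplicative Gaussian (sd 0.02) plus an additive floor (sd 0.002), five
scans averaged, matching the stated protocol. Noise is spectrally
correlated (Gaussian scale 3.5 nm): a field spectroradiometer resamples an
optical bandwidth of several nanometres onto the 1-nm grid, so its noise is
not white at 1 nm — and white noise would annihilate every
derivative-based model, which contradicts how such instruments behave.
Spectra are extended from 400 nm down to 350 nm by boundary extension
(flagged via the `extended_below_nm` attribute) and Savitzky–Golay smoothed.

What passing tests on this arm do and do not show: the generator reproduces
the campaign's SPAD distribution and the qualitative model orderings
(full-spectrum overfitting, selection lifting validation accuracy), but it
is *not* a claim to reproduce the real orchard's accuracy numbers — the real
data are not deposited, the real nuisance variation was plainly narrower
than the full simulation ranges, and under these conditions the
first/second-derivative arms remain noise-limited at n = 69 (a zero-noise
control reaches validation R² ≈ 0.99 there, isolating the noise level as the
binding constraint).

## Numerical choices and degenerate inputs

* LAI = 0 returns the soil spectrum exactly (the four-stream solution is
  bypassed rather than evaluated at a removable singularity); the eigenvalue
  `m` is floored at 10⁻⁶ against cancellation when leaf absorption vanishes.
* The average-leaf-angle 0° limit is evaluated at 10⁻⁴ degrees (the
  ellipsoidal distribution's planophile limit).
* Zero-variance bands are dropped from design matrices with a warning;
  constant responses yield a constant predictor with a warning rather than an
  error; non-finite inputs are rejected.
* A LASSO/EN fit that selects zero bands fails that model's row only (this
  genuinely happens for second-derivative field data at n = 52, where no λ
  beats the null model — an honest CV outcome).
* All randomness (splits, folds, subsamples, SPAD draws, noise) flows from
  explicit integer seeds through isolated RNG scopes; identical seeds give
  bit-identical artifacts.

## Problem sizes used by the test suite

The routine test suite runs the full nine-model experiment on the complete
2100-spectrum simulated dataset and a 69-tree synthetic campaign, with
search grids scaled for a routine run: a 19-point α grid (0.05…0.95), 5
selection folds, and an SVR search over C ∈ 2^{0,3,6,9,12}, γ ∈ 2^{−14…−2}
with 3 folds on a 400-sample subsample. The acceptance script uses the full
99-point α grid and 10 selection folds. These sizes are the package's
choices for its own checks; every grid is configurable.

## Known limitations

* Synthetic optical constants and soil: simulated spectra are not
  instrument-accurate (see above).
* The noiseless simulated grid is deterministic and densely sampled, so
  *every* well-tuned model interpolates it (validation R² ≈ 1) and λ-min
  selection is dense; overfitting collapse and sparse band counts, reported
  for the original study's pipeline, require an effective noise floor that
  the study conditions do not specify.
* No atmosphere, sensor band synthesis, topography, or multi-date phenology;
  no fractional derivatives, continuum removal, or wavelet denoising.
* The 350–399 nm region of field spectra is boundary extension, not
  radiative transfer.
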