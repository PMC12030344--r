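---
title: "Monitoring fed-batch CHO cultures from in-line Raman spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring fed-batch CHO cultures from in-line Raman spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(ramanpls)
library(dplyr)
```

# The problem

An in-line Raman probe immersed in a bioreactor records a spectrum every
20–30 minutes without sampling the culture. Off-line reference assays for
glucose (Glc), lactate (Lac), glutamine (Gln), glutamate (Glu), IgG titer
and viable/total cell densities (VCD/TCD) are available only once or twice
a day and consume material. If a regression model can map spectra to
reference values, the seven quantities become observable continuously —
the core promise of process analytical technology (PAT) for mammalian cell
culture.

ramanpls implements the full chemometric workflow for this problem —
spectral preprocessing, PLS1 calibration with cross-validated
latent-variable (LV) selection, variable-importance (VIP) specificity
analysis and batch-wise blind validation — together with a synthetic
fed-batch data generator that reproduces the statistical structure such
campaigns exhibit, so every part of the pipeline can be exercised and
tested without access to proprietary bioreactor data.

# The synthetic fed-batch campaign

## Culture kinetics

No mechanistic metabolic network is attempted. The generator integrates
the simplest difference system (forward Euler, step `dt` ≤ 1 h, default
20 min) that reproduces the canonical shapes of a 10 L fed-batch IgG
campaign:

* logistic biomass growth: `dVCD/dt = µ·VCD·(1 − TCD/K)·Monod(Glc)` minus
  first-order death; `dTCD/dt` receives the growth term only, so dead
  cells accumulate and `TCD ≥ VCD` always;
* death at a baseline rate (0.0015 h⁻¹) that switches to a starved rate
  (0.03 h⁻¹) when glucose falls below 0.15 g/L;
* per-viable-cell glucose/glutamine uptake with Monod saturation at low
  substrate, glutamate and IgG production proportional to viable density,
  and lactate produced as a glycolytic-overflow yield on glucose uptake
  until a metabolic shift (default 168 h) turns net production into
  consumption;
* once-daily bolus feeding from day 2 that restores glucose **up to** the
  5 g/L target (nothing is removed when glucose sits above it); stopping
  the feed on day 10 (`feed_stop_day`) starves the culture and induces
  cell death.

Default rates were chosen once so the trajectories match the ranges a real
campaign reports: inoculation at 0.6×10⁶ viable cells/mL, a viable plateau
near 20×10⁶ cells/mL around day 7–8, post-feed glucose within 5 ± 1 g/L
and pre-feed troughs near 1–2 g/L (daily swings of several g/L), lactate
peaking near 2 g/L before the shift, glutamine exhausted from 4.8 mM,
glutamate accumulating to ~11 mM and titer reaching ~4.5 g/L over 14–16
days.

```{r kinetics, eval = FALSE}
k <- simulate_batch_kinetics(kinetics_params())
plot_kinetics(k)
```

The induced-death scenario exists for a statistical reason: under normal
operation VCD and TCD are almost perfectly correlated, so no regression on
spectra can tell them apart. One starved batch in the calibration set
breaks that cross-correlation (the Pearson correlation between the two
density series drops from >0.95 to ~0.4) and gives the calibration data
the contrast the VCD and TCD models need.

## From state to spectrum

Raw counts at wavenumber ν (grid 250–3200 cm⁻¹, 1 cm⁻¹ spacing) are

    Ti·Nscan · [ atten(TCD) · ( Σ_a c_a·s_a(ν) + w(ν) ) + b(ν, t) ] + ε

* `s_a` — Gaussian band sets at the literature positions for each analyte
  (glucose ring modes at 1033/1060/1117 cm⁻¹ plus CH₂ modes, lactate
  carboxylate/C–C bands in 830–872 cm⁻¹, glutamine CH₃ rocking at
  934 cm⁻¹, glutamate NH₂ rocking near 1075 cm⁻¹, IgG
  tryptophan/tyrosine bands and amide I near 1648 cm⁻¹). Cellular
  material contributes two *distinct* sets: lipid/cholesterol bands
  (702/717/1450 cm⁻¹) scaling with viable density and nucleic-acid
  debris bands (783/811/1100 cm⁻¹) scaling with the dead-cell density
  TCD − VCD, emulating material released on cell death. Because
  TCD = VCD + dead, total density is a linear functional of band space —
  without this split the two densities would be spectrally
  indistinguishable in the linear regime.
* `w` — broad water bands at 1640 and 3150 cm⁻¹ with constant driver: the
  apparent decline of the water signal over a culture is an attenuation
  effect, not a concentration change.
* `atten(TCD) = 1/(1 + k·TCD)` — saturating turbidity attenuation
  (default k = 0.04 per 10⁶ cells/mL), the nonlinear fingerprint of total
  cell density in real spectra and the mechanism behind the late-culture
  plateau of predicted TCD.
* `b(ν, t)` — a broad low-order polynomial fluorescence baseline whose
  amplitude grows linearly in culture time (default +8 %/day).
* `ε` — i.i.d. Gaussian detector noise with raw-count standard deviation
  `noise_sd·Ti·Nscan`, i.e. constant in counts/s after acquisition-time
  normalization. The default `noise_sd = 0.133` counts/s puts the
  mid-culture net glucose band height at 1033 cm⁻¹ near 20 times the
  single-spectrum noise; band amplitudes put all analyte peak
  signal-to-noise ratios in the 10–50 range.

Off-line references are the true kinetics values multiplied by lognormal
noise with unit mean and relative standard deviation `assay_cv` (default
12%, inside the 10–15% standard error bracket quoted for bench analyzers).
Sampling follows the bench plan: one sample at inoculation, then two per
day from day 2, one hour before and one hour after the feed. The one-hour
offset (rather than minutes) is deliberate: with three-spectrum block
averaging at 20–30 min cadence it keeps each sample's paired spectrum
entirely on one side of the instantaneous feed bolus, as in a real
campaign where operations are kept outside acquisition windows.

## The five-batch study preset

`simulate_study()` emulates a full monitoring campaign: five batches,
of which B1, B3, B4 and the induced-death B5 calibrate the models and B2
is held out for blind validation. Durations (B1 15, B2 16, B3 15, B4 14,
B5 14 days) were chosen so the calibration set holds exactly 112 off-line
samples and the blind batch 31 — a realistic campaign size. Acquisition
settings vary across batches (30 min cadence with 60 s × 9 scans on B1;
20 min with 90 s × 10 or 45 s × 16 elsewhere), which exercises the
acquisition-time normalization that makes batches comparable.

What the generator does **not** emulate: cosmic-ray spikes, wavelength
drift or calibration transfer between instruments, medium lot-to-lot
variability, pH/DO/temperature excursions, antifoam events, probe fouling,
and non-Gaussian band shapes. Passing tests on this generator therefore
demonstrate the correctness and statistical behavior of the chemometric
pipeline under controlled, campaign-like conditions — not robustness to every
artifact of plant data.

# Preprocessing

The operator menu is the standard chemometric one: Savitzky–Golay
smoothing `SG(width, order)` and derivatives `D1`/`D2`, standard normal
variate (SNV), linear detrending, and area (1-norm) normalization, written
in the compact table notation `"D1(23,2)+SNV"`. Operators run in listed
order on the 700–1700 cm⁻¹ fingerprint working region, then the model's
wavenumber window is cut out, then columns are mean-centered.

Numerical choices worth stating:

* **SG edges** are handled by evaluating the first/last window's
  polynomial (no padding, no shortening), so the grid length is preserved
  without edge discontinuities; derivatives are per cm⁻¹ and include the
  factorial scaling. The implementation is verified against a brute-force
  per-window least-squares fit.
* **SNV** uses the sample (n − 1) standard deviation; it is idempotent and
  affine-invariant, and rejects constant rows by index.
* **Centering is the only statistics-bearing step**: its column means are
  learned from calibration rows only (inside cross-validation, from the
  training folds only) and applied unchanged to test rows. The test suite
  includes a leak detector that verifies a deliberate leak changes RMSECV.
* **Pairing** matches each off-line sample to the temporally nearest
  averaged spectrum, ties resolved toward the earlier spectrum, with a
  1 h default lag budget; unmatched samples are skipped with a warning.
* **Averaging** uses non-overlapping blocks of three so no spectrum
  contributes to two paired samples; the block timestamp is the member
  mean and a trailing partial block is dropped.

# The PLS1 engine

Calibration solves `y = X b` by NIPALS PLS1: per component the weight
`w_a ∝ X'y` (unit norm), scores `t_a = X w_a`, loadings
`p_a = X't_a/t_a't_a`, y-loading `q_a = y't_a/t_a't_a`, then X and y are
deflated. Predictions use the assembled regression vector
`b = W(P'W)⁻¹q`, which equals sequential score-space prediction; both
paths are asserted equivalent to 1e-8 in the tests, and the whole engine
is checked against an independently implemented SIMPLS oracle and, at full
rank, against ordinary least squares. A component is refused when the
deflated `X'y` norm falls below 1e-12 of its initial scale; the caller
either fails with the achievable rank (default) or truncates with a
warning (inside cross-validation and the pipeline).

**VIP** scores follow the standard Wold definition,
`VIP_j = sqrt(p·Σ_a SSY_a (w_ja/‖w_a‖)² / Σ_a SSY_a)` with
`SSY_a = q_a²·t_a't_a`, so the mean of VIP² is exactly 1 and scores above
1 flag variables contributing more than average. `significant_regions()`
turns a VIP profile into maximal runs of consecutive retained wavenumbers
strictly above the threshold, which are then compared against the known
band positions — the specificity check for each analyte model.

**Diagnostics** report leverage `h_i = 1/n + t_i'(T'T)⁻¹t_i` (the 1/n
term accounts for centering, so Σh = A + 1) and standardized residuals
`e_i/s` with `s² = Σe²/(n − A − 1)` — the standard residual-vs-leverage
outlier view.

# Model selection and figures of merit

RMSECV is computed by k-fold cross-validation (default k = 3) with folds
**contiguous in time within each batch**. Bioprocess trajectories are
strongly autocorrelated; random folds would let each training set
interpolate its own neighborhood and flatter RMSECV. Contiguous blocking
is conservative — it scores partial extrapolation — which is the behavior
wanted from a model-order criterion. A seeded random scheme is available.
The chosen LV count minimizes RMSECV with ties toward the smaller model;
no 1-SE rule is applied.

The per-analyte recipes of `default_model_configs()` (derivative/SNV
combinations and wavenumber windows per analyte) are applied as given, but
the LV count is re-derived by cross-validation by default. The preset
reference counts (5, 4, 6, 8, 6, 6, 5) remain available via
`lv_mode = "fixed"` for replication; on synthetic data they measurably
overfit reference-assay noise. The effect is easy to demonstrate: fitting
glucose against noise-free calibration references gives a blind-test error
against true kinetics of ~0.04 g/L at any reasonable component count,
while fitting against the 12%-noise references makes that error grow
monotonically with the component count — model-order selection is
protecting against reference noise, not spectral complexity, and should
therefore be data-driven.

Reported figures of merit are RMSEC/RMSECV/RMSEP (root-mean-square errors
on calibration, cross-validation and the blind batch), R² = 1 − SS_res/SS_tot
(reported as-is, so test-set values may be negative), and RMSEP(%) in both
conventions — relative to the validation mean or to the validation maximum,
the latter customary for low-concentration analytes.

One consequence of validating against noisy references deserves emphasis:
with relative assay noise `cv`, even a perfect model scores
`RMSEP ≥ cv·sqrt(E[y²])`, i.e. `RMSEP(%) ≥ cv·sqrt(1 + cv_y²)·100` in
average mode, where `cv_y` is the coefficient of variation of the analyte
over the validation samples. For a titer that ramps from 0 to its final
value (`cv_y ≈ 0.75`), 12% assay noise alone floors RMSEP(%) near 15% —
reported accuracies below that level imply reference assays better than
their quoted worst-case precision.

# The exact-recovery limit

The `noise_free` preset switches off detector noise, assay noise, the
fluorescence baseline, turbidity attenuation and block averaging, and
aligns sampling with the acquisition grid. Spectra are then *exactly*
linear in the seven monitored quantities, whose time courses span a
rank-7 subspace, so mean-centering plus PLS1 with 7 components recovers
every analyte to numerical precision (blind-test RMSEP below 1e-9 in
analyte units). This is the strongest end-to-end correctness check the
pipeline admits: any leakage, misalignment, off-by-one pairing or
preprocessing defect breaks exactness immediately. Attenuation must be
off in this limit — with `atten(TCD)` active the forward model is not
linear in concentrations and no linear calibration can be exact, which is
precisely why the default (realistic) preset keeps it on.

`noise_free_model_configs()` fixes 7 components rather than selecting by
RMSECV because the subspace dimension is known by construction in this
limit; cross-validated selection under exact fits reduces to comparing
rounding errors.

# Problem sizes and runtime

The full default study — five batches of 700–1150 spectra of 2951 points,
112 paired calibration samples, seven analyte models with 3-fold CV —
runs in about one to two minutes on a single core; the noise-free preset
in about one. The unit-test suite uses three-batch, 6–8-day campaigns at
60 min cadence for pipeline checks and small random matrices for the
algebraic oracles.

# Known limitations

* The PLS engine is PLS1 only (one response per model); no PLS2, O-PLS or
  kernel variants, and no prediction intervals.
* The simulator's nonlinearities (turbidity, baseline) are smooth and
  mild; real plant spectra contain artifacts (spikes, fouling, lot
  changes) that this package's preprocessing menu does not address.
* VCD/TCD models rely on indirect signatures (debris bands, turbidity);
  their specificity is process-dependent, and the default study shows
  visibly weaker blind-test accuracy for them than for glucose or IgG —
  consistent with cells lacking distinct Raman bands of their own.
* Validation metrics are computed against noisy references because that
  is all a real campaign has; the assay-noise floor discussed above is
  inherent to that choice.
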