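---
title: "Model-observer detectability rates for fluoroscopy QC: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-observer detectability rates for fluoroscopy QC: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorosnr)
```

## The detection task and the observer

Low-contrast detectability in live x-ray imaging is naturally expressed
as a *rate*: the viewer integrates information over time, so the relevant
index is how fast squared signal-to-noise ratio accumulates per second of
fluoroscopy. `fluorosnr` measures that rate on recorded frame stacks
under the SKE/BKE paradigm — the signal (a disc detail of known position
and shape) and the background are known exactly, and only stochastic
noise varies between frames.

Two stacks are acquired under identical conditions, one with the
low-contrast detail (H1) and one without (H0). The measurement chain is:

1. **DC suppression.** Every ROI frame has its spatial mean subtracted
   (`dc_suppress()`). This makes all downstream quantities invariant to
   frame-to-frame offset drift — gain and offset changes of the detector
   cancel exactly, which the test suite asserts as an affine-invariance
   property.
2. **Template.** `build_template()` forms the matched filter
   `T = mean(dc(H1)) − mean(dc(H0))`. The template has exactly zero
   spatial mean. Optionally a radially symmetric 4th-order Butterworth
   low-pass at a chosen fraction of Nyquist (`hf_cutoff`) suppresses the
   high-spatial-frequency band, where a finite-stack template carries
   mostly noise; the applied filter is recorded in `filter_applied`.
3. **Scoring.** Each frame's conditional decision variable (CDV) is the
   zero-lag cross-correlation `sum(T * dc(frame))` (`score_frame()`).
   CDVs are deliberately *not* normalised by template energy: the final
   index is scale-free, and the raw correlation is the matched-filter
   form.
4. **Leave-one-out.** `compute_cdv_series()` scores each frame against
   the template rebuilt with that frame excluded. Without this, a frame
   correlates with its own contribution to the template and the
   separation is biased upward. The exclusion is implemented as a
   running-sum downdate (O(n) total) and is tested to equal naive
   re-estimation at machine precision.
5. **Single-frame index.**
   `SNR²_sf = (ΔCDV)² / (½(s²_H1 + s²_H0))` with unbiased sample
   variances — the squared separation of the two conditional
   distributions (d′² under normality).
6. **Lag factor.** Successive pulses are correlated (detector lag,
   temporal filtering), so `SNR²_sf` does not accumulate at the pulse
   rate `f_p`. `lag_factor()` estimates
   `F = f_p / (1 + 2 Σ_k ρ_k)`, the effective independent-frame rate,
   from the autocorrelation of the CDV noise series, and
   `SNR²_rate = SNR²_sf · F` (an exact identity in every `snr_result`).

### The lag-factor estimator

`F` is defined through the integrated autocorrelation time
`τ = 1 + 2 Σ ρ_k` of the CDV sequence. This time-domain form equals the
noise-power-spectrum formulation for stationary series while operating
directly on the observer's decision variable, and it has a closed-form
oracle for AR(1) noise: `τ = (1+α)/(1−α)`, i.e.
`F = f_p (1−α)/(1+α)` (`analytic_lag_ar1()`).

The empirical sum over `ρ_k` must be truncated, otherwise the noise tail
dominates. We use the initial-positive-pair-sequence rule: consecutive
pair sums `Γ_m = ρ_{2m} + ρ_{2m+1}` (starting with `Γ_0 = 1 + ρ_1`) are
accumulated while they remain positive. Starting at `Γ_0` keeps
anti-correlated series meaningful: with `ρ_1 < 0` the estimator can and
does return `F > f_p`, which is correct for noise that partially cancels
between frames. If no lags can be estimated the documented fallback is
`F = f_p`. `τ` is floored at `1/N` so pathological input cannot produce
an infinite rate.

By default the H0 series is pooled with the mean-removed H1 series
(`include_h1 = TRUE`): after mean removal both carry the same noise
process, and pooling halves the estimator variance. Autocorrelations are
pooled per segment (each series demeaned separately, autocovariances
summed, normalised by the pooled lag-0 term) so no spurious correlation
is introduced across the H0/H1 junction. The truncated-sum estimator has
a sampling SD of roughly `2/√N` on `τ` for near-independent series —
with 2 × 2000 CDVs that is ~3–5% on `F`, which is why short QC series
should not over-interpret small lag-factor differences.

### Statistical uncertainty

`bootstrap_sigma_stat()` runs a moving-block bootstrap over the paired
CDV sequences, with block length `⌈f_p / F⌉` frames so correlated
neighbours are resampled together, recomputing `SNR²_rate` per replicate
and reporting `sd/mean` of the replicates. It is seed-deterministic. The
relative uncertainty scales as `1/√N` in the total frame count `N`; the
acceptance suite fits this scaling over `N ∈ {125 … 2000}` and requires a
zero-intercept fit with `R² > 0.95`. At ~1000 frames per hypothesis the
statistical uncertainty of a single measurement is in the 6–9% range.

### Dose normalisation and the uncertainty budget

`compute_fom()` divides `SNR²_rate` by the incident air kerma rate
(`FOM_K`, µGy⁻¹) and by the kerma-area-product rate (`FOM_KA`,
µGy⁻¹·m⁻²). Dose indices enter only through `dose_indices()`, which
pins their units and stores uncertainties at coverage factor k = 1 (a
k = 2 calibration quote must be declared via `coverage_factor = 2` and is
halved on entry). FOM uncertainties treat the rate and the dose index as
independent and add their relative uncertainties in quadrature.

When a setup parameter X (dose index, squared magnification, field size)
varies between experiments, `combined_uncertainty()` extends the budget
by root-sum-square terms `B_X · X · σ_rel,X`, where `B_X` is the slope of
the linear relation of `SNR²_rate` with X, expressed relative to
`SNR²_rate`. The slopes are instrument-specific; the package never
invents them, so with no configured terms the budget degenerates to the
statistical term alone.

## The synthetic phantom simulator

No public fluoroscopy stacks with known ground truth exist, so
`simulate_stack()` generates the study conditions end-to-end:

* uniform quantum-noise background, mean count `N0` per pixel (proxy for
  the detector air-kerma per frame);
* a disc detail of signed relative contrast `C` and diameter
  `detail_diameter_px` at the detector plane, rasterized by pixel-centre
  inclusion (`render_disc_mask()` — deterministic and brute-force
  checkable). Magnification only rescales the projected area, so it
  enters through the diameter;
* per-frame Poisson noise about the mean image when frames are
  independent;
* Gaussian AR(1) noise with stationary per-pixel variance equal to the
  mean when a lag-1 frame correlation `α > 0` is requested. An exact
  Poisson AR(1) process is awkward; the Gaussian surrogate preserves the
  variance–mean relation (excellent for `N0 ≳ 20`) and gives the lag
  factor its closed-form oracle. Negative values are clipped at zero and
  counted, with a warning;
* optional Gaussian blur applied to the *mean image only* (via
  `EBImage::gblur`), so the noise stays white and the analytic
  single-frame oracle `SNR²_sf = A_px C² N0` remains exact for the
  unblurred case.

The defaults mirror a typical pulsed acquisition: 15 pulses/s, 64×64
analysis ROI, ~10³ frames per hypothesis.

What the simulator deliberately omits: scatter, beam hardening, detector
MTF/DQE, anti-scatter grid, automatic dose-rate control, anatomical
backgrounds and object motion. Passing tests therefore demonstrate that
the *estimators* are correct under controlled quantum-noise conditions;
they do not certify absolute values on clinical hardware, where those
physics terms and the equipment's dose-control loop dominate the trends.

## Validation design and problem sizes

The validation experiments pin every check to an analytic oracle, with
simulation sizes chosen — once, from the estimator's error analysis — so
that the known finite-sample biases are small against each tolerance:

* **Ideal-observer convergence.** A finite-stack template adds
  `≈ P·(2N0/n) / (C²N0²A)` relative variance to the CDVs (`P` ROI
  pixels, `n` frames, `A` disc pixels), and per-frame DC suppression
  removes an `A/P` fraction of signal energy. At the convergence
  conditions (`N0 = 100`, `C = 0.1`, `A = 49`, `n = 2000`) the ROI is
  sized 41×41 — near the optimum of that bias trade-off — giving an
  expected shortfall of ~6%, within the 10% tolerance.
* **Rose sweeps.** The ROI side tracks ~4× the disc diameter across the
  area sweep so both bias ratios stay constant and the response stays
  proportional; 4000 frames/point keeps the expected slope shortfall
  (template noise + DC loss + lag truncation, ~8%) well inside the 15%
  slope check against the oracle slope `C²N0·f_p`.
* **Lag factors.** 5000-frame stacks make the ±5% (independent) and
  ±10% (AR(1), oracle 5 s⁻¹) checks meaningful given the estimator's
  ~2–3% sampling SD at that size.

Numerical conventions worth stating: ROIs are 0-based, top-left origin,
half-open extents; disc rasterization uses pixel-centre inclusion with
ties (centres exactly on the rim) counted inside; sample variances use
the n−1 denominator; a control-chart point exactly on a ±k·SD limit is
*not* flagged; the Butterworth template filter is self-adjoint, so the
implementation filters the frames once instead of every leave-one-out
template (tested equal to the naive path); all simulation randomness
flows from a single seed, and the caller's RNG state is restored.

## Known limitations

* The high-frequency-suppression kernel of the classical quasi-ideal
  observer implementations is not standardised; the Butterworth low-pass
  here is an explicit, recorded stand-in and is off by default so that
  results remain comparable to the unfiltered analytic oracle.
* The lag factor assumes a stationary CDV noise process; strong trends
  (e.g. dose-control transients at the start of a run) should be trimmed
  before analysis.
* `SNR²_sf` is a biased estimator at small frame counts (template noise
  deflates it); comparisons across settings should use comparable stack
  sizes.
* Stack IO covers raw-binary-with-sidecar and multi-page 16-bit TIFF;
  frame rates are never guessed — supply them via the sidecar or an
  explicit override.
* Moving test objects, pulse-length effects and focal-spot unsharpness
  are outside the model.
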