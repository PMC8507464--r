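# fluorosnr

Objective low-contrast detectability measurement for pulsed fluoroscopy,
with dose-normalised figures of merit and constancy-check trending.

## The problem

Judging low-contrast detail visibility on a fluoroscopy unit with human
observers is slow and noisy. A model observer applied to recorded frame
sequences measures the same thing objectively and with a precision of a
few percent — good enough to detect small drifts in image quality during
quality control, and to compare the dose efficiency of different imaging
settings.

`fluorosnr` implements a **quasi-ideal model observer** for the SKE/BKE
(signal and background known exactly) detection task on paired frame
stacks, one containing a low-contrast disc detail (hypothesis H1) and one
without it (H0):

1. The **observer template** is the difference between the mean
   DC-suppressed H1 frames and the mean DC-suppressed H0 frames — the
   matched filter of the task. Optional high-spatial-frequency suppression
   (4th-order Butterworth low-pass) discards the template band that
   carries mostly noise.
2. Each frame is **cross-correlated** with the template to produce a
   conditional decision variable (CDV). Frames are scored **leave-one-out**:
   each analysed frame is removed from the stack before its template is
   formed, eliminating the optimistic bias of testing a frame against a
   template it helped build.
3. The **single-frame detectability** is
   `SNR²_sf = (mean CDV_H1 − mean CDV_H0)² / (½(var CDV_H1 + var CDV_H0))`.
4. Neighbouring frames in a sequence are not independent, so a **lag
   factor** `F` (s⁻¹) — the effective number of independent frames per
   second, estimated from the autocorrelation of the CDV noise series — 
   converts the per-frame index into a rate:
   `SNR²_rate = SNR²_sf · F`.
5. Dose-normalised **figures of merit** (`FOM_K = SNR²_rate / K_rate`,
   `FOM_KA = SNR²_rate / P_KA,rate`) measure dose efficiency; a
   root-sum-square **uncertainty budget** and a moving-block bootstrap
   supply the error bars; **control charts** (mean ± k·SD) trend repeated
   QC measurements.

For an unblurred quantum-noise detail, `SNR²_rate` follows the Rose model
`SNR²_rate ∝ M² C² A · K_rate`, which the bundled synthetic phantom
simulator reproduces and the test suite verifies against analytic oracles
(`SNR²_sf = A C² N₀` per frame; `F = f_p (1−α)/(1+α)` for AR(1)
frame correlation).

## Worked example

Simulate a contrast-detail acquisition (8-pixel disc, contrast 0.1, mean
background count 100, 15 pulses/s, 1000 frames per hypothesis), measure
it, and normalise by measured dose rates:

```r
library(fluorosnr)

cfg <- sim_config(n_frames = 1000, rows = 41, cols = 41, N0 = 100, C = 0.1,
                  detail_diameter_px = 8, center = c(20, 20),
                  frame_rate_fp = 15, seed = 1)
pair <- simulate_stack(cfg)

res <- measure_snr(pair, n_boot = 400, seed = 2)
res
#> snr_result: SNR2_sf = 42.31, F = 13.6 s^-1, SNR2_rate = 575.2 s^-1
#>   sigma_stat = 8.14% (2000 frames)

analytic_ideal_snr_sf(cfg)   # ideal-observer oracle A * C^2 * N0
#> [1] 49

compute_fom(res, dose_indices(102, 0.98, sigma_rel_dose = 0.02))
#> fom_result: FOM_K = 5.639 uGy^-1 (+/- 8.4%), FOM_KA = 586.9 uGy^-1.m^-2 (+/- 8.4%)
```

The measured `SNR²_sf = 42.3` sits below the ideal-observer value 49
because the template is estimated from a finite stack (template noise
inflates the CDV variance) and per-frame DC suppression removes a small
fraction of the signal energy; both effects shrink as frames accumulate.
`F = 13.6 s⁻¹` is the effective independent-frame rate of the 15 s⁻¹
pulse sequence estimated from this finite series. The statistical
uncertainty (8.1% at 1000 frames/hypothesis) comes from a moving-block
bootstrap of the CDV series, and the FOM error bar adds the 2% dose-index
uncertainty in quadrature.

A thin command-line front end with `simulate`, `measure`, `fom`, `qc` and
`sweep` subcommands is installed at
`system.file("cli", "fluorosnr", package = "fluorosnr")`.

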