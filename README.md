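# hepiron

Hepatic iron quantification from multi-echo gradient-echo MRI at 1.5 T:
simulation, fitting, calibration and method-agreement statistics in one
tested R package.

## The problem

Liver iron concentration (LIC) is measured non-invasively through the
effective transverse relaxation rate R2\* = 1/T2\*, which rises with tissue
iron. In practice three things complicate the measurement:

1. **Fat.** The liver signal is a mixture of water and fat; fat's chemical
   shift makes the magnitude signal oscillate across echo times, so R2\*
   and the proton density fat fraction (PDFF = f/(w+f)) must be estimated
   jointly (the Dixon approach).
2. **Noise.** Magnitude images carry Rician noise, whose mean exceeds the
   true signal at low SNR. Heavily iron-loaded livers decay into this
   noise floor within a few echoes, biasing naive exponential fits and
   capping the measurable R2\*.
3. **Calibration.** Published LIC calibrations (Henninger, Wood, Garbowski,
   Hankins) are affine maps Fe\[µmol/g\] = a·R2\* + b obtained with
   *particular* sequences; using them with another sequence requires a
   cross-calibration via the regression between the two sequences' R2\*.

The package models a clinical comparison of three acquisitions — a 2D
fat-saturated multi-echo GRE reference (initial TE 0.99 ms, 12 echoes), a
product 3D multi-echo Dixon sequence (initial TE 2.38 ms, 6 echoes) and an
improved prototype (initial TE 1.04 ms, 6 echoes) — and the estimators
that go with them.

## The model

The magnitude signal at echo time TEₙ is

```
|sₙ| = E_σ{ |(w + cₙ·f) · exp(−R2*·TEₙ)| }
```

where w, f are water and fat amplitudes, cₙ = Σₚ aₚ·exp(2πi·Δfₚ·TEₙ) is the
multi-peak fat dephasing factor (six-peak liver spectrum, main peak
−3.4 ppm), and E_σ is the expectation of a Rice(ν, σ) variate at the known
noise level σ — evaluated in closed form via scaled Bessel functions.
Three estimators are implemented:

- `truncation_fit()` — mono-exponential fit that iteratively discards
  trailing echoes below the noise floor (reference method);
- `dixon_magnitude_fit()` — variable-projection grid search over R2\* with
  water/fat solves per node (naive magnitude Dixon, product emulation,
  optional 400 1/s cap);
- `noise_corrected_fit()` — full model above with E_σ, removing the floor
  bias (prototype emulation).

Downstream: ROI summaries (`patient_r2star()`), calibration algebra
(`compose_calibration()`, `lic()`, `classify_iron()`), and agreement
statistics (`linear_regression()`, `bland_altman()`, `lin_ccc()`,
`cohens_kappa()`, `overall_agreement()`).

## Worked example

```r
library(hepiron)

proto  <- protocol_preset("qdixon-wip")            # 1.04/1.17 ms, 6 echoes
truth  <- tissue_state(w = 90, f = 10, r2star = 320)
series <- expected_signal(truth, default_fat_spectrum(), proto, sigma = 0)
round(series$magnitude, 2)
#> [1] 66.62 40.53 30.35 22.88 14.67  9.22

noise_corrected_fit(series, default_fat_spectrum(), proto, sigma = 0)
#> <fit> R2* = 320.00 1/s, pdff = 0.100, echoes used = 6, residual = 8.18e-23

eq <- calibration_registry()$qdixon_cross          # Fe = 0.434*R2* + 6.135
lic(eq, 320)                                       # 145.0 umol/g = 8.1 mg/g
classify_iron(lic(eq, 320), easl_boundaries = c(36, 125, 270))
#>   yes_no easl_group
#> 1    yes          2
```

The six echo magnitudes are the forward model of a liver with 10% fat and
R2\* = 320 1/s; the fit recovers the truth exactly in the noiseless limit,
and the cross-calibrated LIC of 145 µmol/g (8.1 mg/g) is pathologic
(severity group 2 of 3).

A full synthetic study — simulate a cohort, fit all three arms, exclude
fat/water-swapped product scans, compare sequences and calibrations:

```r
rep <- run_pipeline(pipeline_config(cohort = cohort_spec(n_patients = 40, seed = 7)))
rep$n_excluded
#> [1] 7                                  # product-arm fat/water swaps
rep$pairwise[["me-gre vs qdixon-wip"]]
#> n = 40: slope 1.009, r^2 1.000, mean diff 0.68 1/s (SD 2.29), CCC 1.000
rep$lic_agreement[["henninger vs wood (yes_no)"]]
#> agreement 93.94 %, kappa 0.874
```

The published agreement tables reproduce exactly from their printed
counts:

```r
reproduce_tables()        # 12 rows, all agreement_ok and kappa_ok TRUE
```

## Command line

An installed `exec/hepiron` script exposes `simulate`, `fit`, `rois`,
`compare`, `tables` and `run` subcommands (JSON config, `--seed`,
`--verbose`; NIfTI-1 in/out with JSON sidecars). See
`hepiron <subcommand> --help`.

## Vignette

`vignettes/hepatic-iron-quantification.Rmd` documents the signal model and
its assumptions, the synthetic-data generator's stated world, numerical
choices and known limitations.
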