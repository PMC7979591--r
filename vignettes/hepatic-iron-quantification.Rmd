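---
title: "Hepatic iron quantification from multi-echo GRE: model, estimators and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hepatic iron quantification from multi-echo GRE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepiron)
```

## Scope

`hepiron` implements, as reusable and tested code, the analysis chain of a
clinical comparison of three R2\*-based liver iron protocols at 1.5 T: a
fat-saturated 2D multi-echo GRE reference fitted with a truncation model,
a product 3D multi-echo Dixon sequence with inline magnitude water/fat
fitting, and a prototype successor with noise-corrected fitting and
fat/water-swap reversal. Patient data of such a study are not publishable,
so the package pairs the estimators with a synthetic cohort generator that
reproduces the statistical structure the comparison assumes, plus the
agreement-statistics layer that operates on published contingency counts.

## Signal model

The magnitude signal of a voxel containing water amplitude $w$, fat
amplitude $f$ and relaxation rate $R_2^*$ at echo time $TE_n$ is modelled
as

$$|s_n| \;=\; E_\sigma\!\left\{\,\bigl|(w + c_n f)\,
  e^{-R_2^* TE_n}\bigr|\,\right\},$$

with two ingredients:

- **Multi-peak fat dephasing.** $c_n = \sum_p a_p e^{2\pi i \Delta f_p TE_n}$,
  where $\Delta f_p = \delta_p \cdot 10^{-6}\,\bar\gamma B_0$
  ($\bar\gamma = 42.577$ MHz/T). The default spectrum
  (`inst/extdata/fat_spectrum_6peak.json`) is a standard six-peak liver
  triglyceride spectrum with the methylene main peak at $-3.4$ ppm and
  amplitudes normalized to 1. The vendor's in-product peak table is not
  public; results obtained with the default are labelled as such, and the
  spectrum is shipped as data so it can be swapped without code changes.
- **Rician expectation.** $E_\sigma$ is the first moment of a
  Rice$(\nu, \sigma)$ variate,
  $E_\sigma(\nu) = \sigma\sqrt{\pi/2}\, L_{1/2}(-\nu^2/2\sigma^2)$,
  evaluated with exponentially scaled Bessel functions
  ($L_{1/2}(-x) = e^{-x/2}[(1+x)I_0(x/2) + x I_1(x/2)]$), switching to the
  two-term asymptotic $\nu + \sigma^2/2\nu - \sigma^4/8\nu^3$ above
  $\nu/\sigma = 300$, where both branches agree to about $10^{-11}$
  relative. The closed form is validated against numeric quadrature to
  $10^{-6}$ relative over $\nu/\sigma \in [0, 50]$ in the acceptance
  suite.

There is deliberately **no T1 term**: the model has none, so TR and flip
angle are carried by `protocol()` objects as inert metadata only. Units
are seconds and 1/s internally; milliseconds are accepted at the
constructor boundary and converted once.

## The three estimators

All three are deterministic functions of their inputs and share a
`fit_config()` (R2\* grid 0–1200 1/s, step 2, with local refinement —
the step controls search cost only, since the best node is polished by
box-constrained quasi-Newton refinement; nonnegativity is enforced by box
constraints so that zero boundaries are attainable exactly).

**Truncation fit** (reference arm). Nonnegative least squares of
$A e^{-R_2^* t}$, iteratively dropping trailing echoes whose *fitted model
value* falls below $k\sigma$ (default $k = 2$; the original criterion is
not published, so this is a documented assumption), refitting until the
echo set is stable or three echoes remain. This removes the floor-biased
tail that otherwise drags fast decays down.

**Magnitude Dixon fit** (product arm). Variable projection: at each grid
node $R$, the squared-magnitude model
$s_n^2 \approx (w^2 + 2wf\,\mathrm{Re}\,c_n + f^2 |c_n|^2) e^{-2R t_n}$
is solved linearly in $(w^2, wf, f^2)$, projected to $w, f \ge 0$, and
scored by the exact magnitude residual; the best node seeds the joint
refinement. An optional `r2star_cap` (400 1/s in the pipeline's product
configuration) reproduces the product's reported output ceiling as an
explicit clamp, in addition to the emergent saturation described below —
whether the clinical limitation is a hard clamp or emergent is not
documented, so both mechanisms exist and are labelled.

**Noise-corrected fit** (prototype arm). Minimizes
$\sum_n \bigl(|s_n| - E_\sigma\{\ldots\}\bigr)^2$ with $\sigma$ a known
input, initialized from the magnitude Dixon fit. Because the model itself
reproduces the noise floor, late echoes buried in noise constrain fast
decay instead of biasing it.

### Fat/water swaps

Magnitude data are nearly blind to exchanging the roles of water and fat:
across representative liver states we measured residual gaps between the
water-dominant and fat-dominant minima of only 0.01–0.5 % of the signal
energy, in both directions. This is exactly why clinical reconstructions
(which resolve the ambiguity from complex data) occasionally deliver
globally swapped water/fat images, and why the vendor's prototype needed
an image-based swap classifier. Consequently:

- `swap_flag` reports *evidence* of a swap — the better basin is
  fat-dominant — not ambiguity, which would fire always;
- `resolve = "prefer_water"` emulates the water bias of clinical
  reconstructions: when the basins are degenerate within `swap_tol`
  (2 % of signal energy, chosen an order of magnitude above the measured
  noiseless gaps), the water-dominant solution is returned even if the
  fat-dominant one is better — the classic swap failure;
- `detect_and_reverse_swap()` is the organ-level rule-based surrogate for
  the classifier: if the median fitted PDFF over the liver exceeds 0.5,
  water and fat maps are exchanged (R2\* untouched).

In the pipeline, product-arm patients whose detector fires are *excluded*
(mirroring the study's exclusion of swapped patients), while the
prototype arm *reverses* and keeps them. On simulated cohorts the
detector separates swapped from unswapped patients cleanly.

## The synthetic cohort: a stated world

`cohort_spec()` defaults encode the population the study describes, and
are fixed once:

| parameter | default | rationale |
|---|---|---|
| true R2\* | log-normal, median 70 1/s, sdlog 0.8, truncated [20, 700] | the study reports only ranges (≈21–670 1/s across sequences) and means ≈80 1/s; a 369-draw sample from this law typically spans ≈21–600 1/s |
| true PDFF | Beta(1.5, 20) truncated below 0.45 | iron work-up patients, not a steatosis cohort; median ≈6 % fat |
| total signal | 100 a.u. | scale free |
| noise σ | 2.5 | SNR 40 relative to the TE→0 signal, a realistic liver SNR |
| swap rate | 46/415 | the observed product-arm swap frequency |
| residual fat after CHESS | 5 % | saturation efficiency unquantified; documented assumption |

Swaps are global (whole liver, by exchanging the w/f maps before
acquisition of the product arm only); noise is independent across voxels
and echoes. The phantom is a 2D ellipse-with-vessels stand-in for
anatomy; ROIs (two right-lobe, one left-lobe, 10 mm diameter at 2.5 mm
pixels → 0.81 cm², inside the protocol's 0.72–1.15 cm² band) are placed
off-vessel and applied identically to every sequence, emulating manual
co-registration.

What a green test therefore establishes: the estimators recover the
parameters of *this* forward model under *this* noise. What it does not:
B0 inhomogeneity, T1 bias, k-space/parallel-imaging artifacts, motion,
inter-reader ROI variability, or the vendor's exact spectrum — all are
out of scope, and the real-data path (NIfTI echo stacks + known σ) exists
precisely so the same estimators can be run on data that do contain those
effects.

## Measurement level and the noise-floor bias

The study's statistic is the mean R2\* over three ROIs. The pipeline's
default `fit_mode = "roi_mean"` fits the ROI-averaged echo series:
averaging $N$ voxels shrinks the noise on the mean like $1/\sqrt{N}$ but
leaves the Rician floor in place, so at ROI level the floor is a
*systematic* error — exactly what the noise-corrected model removes and
the naive fit cannot. Two consequences, both reproduced in the acceptance
suite:

- at truth 500 1/s (short-TE protocol, first-echo SNR 40) the naive
  ROI-level bias is ≈ −4 1/s while the noise-corrected fit is unbiased to
  within Monte-Carlo error;
- at truth 600 1/s and the cohort's default noise, the long-TE product
  protocol saturates near 400 1/s (mean ≈ 409 across replicates —
  matching the clinically reported ceiling of "around 400"), while the
  short-TE noise-corrected fit tracks truth within 0.2 %.

A caveat worth recording: at the *single-voxel* level with only six
echoes, both magnitude objectives have a global minimum that slightly
overfits fat, giving all global-minimum estimators a finite-sample bias
of order −10 1/s at 500 1/s regardless of noise correction (refits
initialized at the truth are unbiased but sit in a higher-residual
basin). This is an identifiability property of 6-echo magnitude data, not
an optimizer defect; it is why the bias comparison is made at the
measurement (ROI) level, and why the voxel-wise `fit_map()` mode is the
noisier of the two.

## Calibration algebra and classification

`compose_calibration()` transfers a calibration
$Fe = a x + b$ through a cross-sequence regression $y = m x + c$ by
substituting the inverted regression: slope $a/m$, intercept $b - ac/m$.
With the Henninger equation (0.436, +4.964) and the study's printed
regression (1.00564, −2.7) this yields 0.434 and 6.135 after 3-decimal
rounding — the published qDixon cross-calibration. Unit conversion uses
the iron molar mass 55.845 g/mol (2 mg/g ≈ 36 µmol/g).

Classification is strict at thresholds ("> 36 µmol/g" reads as strictly
greater; ties fall in the lower class). The EASL-style severity
boundaries are **configuration, not constants** — the guideline's numbers
are not printed in the source — and must be passed explicitly
(`easl_boundaries`); the pipeline default 36/125/270 µmol/g (≈2/7/15
mg/g) is an assumption of this package. The published 4×4 severity tables
are accordingly consumed as data, never regenerated from LIC values.

## Agreement statistics

Percent agreement is $100\,\mathrm{tr}(T)/n$ (reported to 2 decimals,
half-up); Cohen's kappa uses identity ("equal") weights with the
Fleiss–Cohen–Everitt asymptotic SE — identity weighting is verified to
reproduce every published kappa from the published counts, which linear
weighting would not, and the published SEs reproduce within ±0.005.
Lin's concordance correlation coefficient uses n-denominator moments with
a Fisher-z confidence interval; the published patient-data CCC intervals
are not reproducible (no patient data), so only the formula is under
test. Bland–Altman limits use the n−1 SD and ±1.96.

## Numerical and I/O choices

- Rounding for reporting: percentages 2 decimals, kappa/CCC 3 decimals,
  half away from zero (`round_half_up()`).
- Degenerate inputs: all-zero echo series return `converged = FALSE`
  rather than a number; degenerate grids and empty masks are errors;
  kappa with degenerate marginals is `NA`-flagged.
- The boundary $R_2^* = 0$ is attainable exactly (candidate comparison
  against the grid/boundary after refinement).
- NIfTI-1 I/O is a minimal self-contained float32 implementation (no R
  NIfTI package is assumed); volumes written here load in nibabel, which
  the test suite checks when Python is available. Configs and sidecars
  are JSON — a strict subset of YAML — because no YAML parser is part of
  the supported stack.
- The cohort generator draws truncated distributions by inverse-CDF, so
  the RNG stream alignment (hence bitwise reproducibility under a seed)
  is independent of rejection counts.

## Known limitations

Complex-valued (phase-aware) reconstruction, field maps, the vendor's AI
swap classifier, CAIPIRINHA undersampling, scanner noise-map acquisition
and biopsy recalibration of the reference equation are all out of scope;
σ is always a known input. The generator does not attempt to match the
per-sequence range differences of the study's subsets, only the overall
spread. Patient-level correlations printed in the source study
(r² = 0.92/0.95, CCC 0.955–0.976) depend on unavailable patient data and
are emulated only qualitatively on synthetic cohorts.
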