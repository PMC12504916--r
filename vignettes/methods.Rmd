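---
title: "Quantifying muscle 31P-MRS biomarkers: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying muscle 31P-MRS biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p31quant)
```

## What the package computes

Phosphorus-31 spectroscopy of resting skeletal muscle resolves seven
resonances of interest: phosphocreatine (PCr, the 0-ppm reference), the
three ATP moieties (gamma, alpha, beta), phosphodiesters (PDE), and two
inorganic-phosphate components (Pi_a, Pi_b). Three biomarkers are
derived from their fitted amplitudes and chemical shifts:

* **Intracellular pH** from the Pi-PCr shift difference `sigma1` via the
  modified Henderson-Hasselbalch relation
  `pH = 6.75 + log10((3.27 - sigma1)/(sigma1 - 5.69))`, evaluated per Pi
  component and combined into an amplitude-weighted pH
  `pH_wt = pH_a Pi_a/Pi_tot + pH_b Pi_b/Pi_tot`.
* **Free ionised magnesium** from the alpha-beta ATP shift difference.
  The observed difference is the population-weighted mean of the
  limiting shifts of the five ATP species (ATP, HATP, MgATP, MgHATP,
  Mg2ATP) with populations set by formation constants, `[H+] = 10^-pH_wt`
  and free `[Mg2+]`; the package inverts this strictly monotone forward
  model by Newton iteration (bisection fallback), with a
  cleared-denominator quadratic solve as a cross-checked fast path
  (the two routes agree to better than 1e-8 mM in the test suite).
* **PDE/gamma-ATP**, a membrane-damage marker, corrected for steady-state
  T1 saturation with `f = sin(theta)(1 - E)/(1 - E cos(theta))`,
  `E = exp(-TR/T1)`.

Everything upstream of these formulas — simulation, preprocessing and
prior-knowledge fitting — exists so that each number can be validated
against exact ground truth.

## Synthetic data: what it emulates, and what it does not

`synthesize_fid()` builds Lorentzian-damped complex FIDs,
`FID(t) = sum_k A_k exp(i(2 pi f_k t + phi_k)) exp(-pi lw_k t)` plus
circularly-symmetric complex Gaussian noise; the Pi and beta-ATP
frequencies are slaved to the pH and Mg models so the biomarkers have
exact known values. `synthesize_csi()` places voxel FIDs on an 8 x 10
grid and stores their 2D spatial DFT as k-space. The cohort generator
draws per-muscle ground truth from group distributions whose defaults
are the study conditions this package targets: group medians 0.72 /
0.63 / 0.62 mM free Mg2+, weighted pH 7.05 / 7.08 / 7.07 and
PDE/gamma-ATP 0.37 / 0.45 / 0.46 for controls, preserved and progressing
dystrophic muscle, with the corresponding IQRs (normal shapes), at a
conservative spectral SNR of 30.

Generator choices that the literature does not pin down, made once:

* Pi_b carries 20% of the Pi_a amplitude at `pH_b = pH_a + 0.3` — a
  generator convention, not a literature claim. It fixes the offset
  between compartmental and weighted pH at +0.05/-0.25 units.
* Relative concentrations: PCr:ATP = 4:1, Pi_a:PCr = 1:10, physiological
  for resting muscle; PDE scales with the target PDE/gamma-ATP ratio.
* Linewidths: PCr 12 Hz, Pi 20 Hz, ATP 30-32 Hz, PDE 40 Hz before
  apodisation, jittered +-15% per spectrum; per-spectrum zero-order
  phases U(-30, 30) degrees and first-order phases U(-3, 3) degrees/ppm.
* Amplitudes are scaled by the steady-state saturation factors of the
  shipped T1 table, so the pipeline's T1 correction is exercised as a
  true round trip.
* By default the generator assigns scrambled plug-in quantiles
  ("balanced" sampling) rather than i.i.d. draws: a finite cohort then
  reproduces its group median essentially exactly, which separates
  pipeline error from sampling error in recovery experiments; i.i.d.
  sampling remains available (`sampling = "iid"`).

The synthetic data deliberately omit: baseline humps from bone and
membrane phospholipids, B0 inhomogeneity beyond a global linewidth,
frequency drift, ATP J-coupling multiplets (a doublet option exists but
singlet priors are the default), nuclear Overhauser effects, and
extracellular/intracellular compartmentation beyond the two Pi pools.
Passing recovery tests therefore demonstrates correctness of the
estimation chain under the stated model, not robustness to every
artefact of in-vivo data.

## The preprocessing chain

The order is fixed: Hann k-space filter, voxel reconstruction
(optionally with half-voxel grid shifts as a k-space phase ramp), SNR
estimation and QC, automatic phasing, 20 Hz Lorentzian apodisation with
two-times zero-filling, PCr referencing, then alignment and averaging
where a muscle has several spectra.

**SNR** is estimated conservatively as the PCr peak height over the
standard deviation of the real and imaginary samples in the final
quarter of the raw FID. Two conventions make that ratio well defined:
the spectrum uses orthonormal (`1/sqrt(n)`) FFT scaling, so the raw
time-domain noise SD equals the per-bin frequency-domain noise SD, and
the peak height is measured after the same 20 Hz filter the chain
applies (measuring the filtered height against raw noise understates
the narrow PCr peak's raw prominence — the conservative choice; both
are available via `apodize_hz`). Spectra with SNR strictly below 10 are
excluded; an SNR of exactly 10 is retained.

**Automatic phasing** minimises the Shannon entropy of the first
derivative of the real part plus a penalty on negative intensity
(weight 1000), by Nelder-Mead from a coarse multi-start over the
zero-order phase, with a fresh-simplex polish at the optimum. One
numerical subtlety matters: the DFT of a one-sided FID carries a
constant baseline equal to half the first time-domain sample, which
masks the negative dispersion lobes the penalty relies on. The
objective is therefore evaluated on a first-point-corrected copy
(subtract `mean(values)/2`); the found correction is applied to the
uncorrected spectrum. Noiseless recovery of known dephasings is then
accurate to about a degree, against roughly six degrees without the
correction.

**Referencing** sets the PCr magnitude maximum (three-point parabolic
interpolation) to 0 ppm, flagging spectra whose search window holds no
credible peak. Downstream metrics do not actually depend on this
calibration: `sigma1` and the alpha-beta difference are computed from
differences of fitted shifts, so a common ppm-axis offset cancels.

**Alignment** registers magnitude spectra by cross-correlation (sub-bin
by parabolic interpolation, applied as a time-domain phase ramp) and
zero-order phases each spectrum onto the highest-SNR member (ties:
first index) before arithmetic averaging; a rival correlation maximum
within 95% of the best, more than five bins away, flags an alignment
failure and drops that spectrum from the mean.

## Prior-knowledge fitting

The AMARES-style engine fits the complex time-domain model by
Levenberg-Marquardt with analytic Jacobian, box constraints from the
prior set, and residuals multiplied by a quarter-sine weight
`w_j = sin(pi j / (2 L))` over the first `L = 12` points (16 in the
broad-PDE re-fit variant) to de-emphasise rapidly-decaying baseline
components; `L = 0` reproduces the unweighted fit exactly. The model
carries two shared phase terms: a zero-order phase and a first-order
("begin time") phase linear in frequency. The second is essential in
practice — entropy-based autophasing leaves a residual ramp of a degree
or two per ppm, and without a begin-time term that ramp aliases into
shift and amplitude errors large enough to break the noiseless
round-trip budget of 1e-4.

Starting values: shifts at prior centres, linewidths at the geometric
mean of their bounds, amplitudes from a linear complex solve at the
starting shifts, and phases from an amplitude-weighted regression of
the per-peak coefficient phases on chemical shift (this last choice
removes a local minimum in which the begin-time term sticks at zero).
One seeded, jittered restart runs on non-convergence. The fit uses the
first 1024 points of the processed FID — at muscle linewidths the
signal has decayed to numerical zero well before that.

The default prior boxes are deliberately informative: shift windows
cover the physiological ranges (Pi_a tracking pH 6.8-7.15, beta-ATP
tracking 0.2-2 mM Mg2+), and linewidth boxes tightly bracket the
linewidths expected for this protocol after apodisation, with the PDE
width essentially fixed at its expected 60 Hz. This mirrors how scanner
prior files are written, and it matters quantitatively: with loose
linewidth boxes the weak, broad components (PDE, Pi_b) act as noise
sponges at SNR 30, acquiring 5-12% positive amplitude bias under the
quarter-sine weighting, and box-edge pinning is asymmetric (about +0.12
mean ratio error when the PDE width pins high versus -0.03 when it pins
low). A near-fixed width makes the PDE amplitude an almost linear
parameter and removes the bias at the cost of a few percent symmetric
scatter from residual width mismatch.

A PDE width pinned at its bound flags a possibly broad PDE peak. The
automated pipeline then re-fits with 16-point weighting, phases clamped
at the main fit's correction and a widened PDE box, but adopts the
re-fit only if it confirms a genuinely broad peak (fitted width more
than twice the default bound) — the automated analogue of reviewing
flagged fits manually. Unconditional adoption would let noise-triggered
re-fits (about 17% of SNR-30 spectra) inflate the cohort PDE/gamma-ATP
median by 0.02-0.03.

## Constants and T1 values are data, not code

The magnesium model needs formation constants and limiting shifts; the
T1 correction needs metabolite T1 values. Neither set is printed in the
primary literature this package models, so the package ships synthetic,
physiologically plausible sets — `mg_constants_synthetic()` and
`t1_table_synthetic()`, both labelled synthetic in name and
documentation — and refuses to compute magnesium without an explicitly
supplied constants object. All magnesium validation is by round trip
and grid oracle, which holds for any admissible constants set;
substituting a published set changes the numbers, not the correctness.
The shift-difference sign convention is `delta(alpha) - delta(beta) > 0`,
with a `flip_sign` flag for sources using the opposite.

## Staging

Fat fraction is `SI_fat/(SI_fat + SI_water) x 100%` per slice,
aggregated as the area-weighted mean over the five slices of a muscle
ROI. Muscles are preserved at fat fraction <= 13.5%, progressing
strictly between 13.5% and 81.5%, and end-stage (excluded from
analysis) at >= 81.5%; these printed thresholds are the authoritative
defaults.

`derive_thresholds()` re-derives such thresholds from longitudinal
records. The design here was genuinely open. A monotone four-parameter
logistic fitted to fat-fraction *change* versus baseline, minus an
uncertainty band, cannot cross zero at two interior points under
realistic data — yet two crossings are exactly what the staging
construction requires, because observed change versus baseline is an
inverted U (muscles near 0% and near 100% cannot progress). The package
therefore models the change as the 24-month increment of logistic
fat-replacement growth,
`change(x) = C x g / (C + x (g - 1)) - x` with `g = exp(24 r)` —
two parameters (rate `r` per month, ceiling `C`), zero change at both
ends, a rapid-progression arch in between. The lower bound is the fit
minus a one-SE prediction band (delta-method fit variance plus residual
variance; a confidence-only band is the main alternative and would
narrow the derived window), and the thresholds are its two zero
crossings found by bracketing and bisection. Constant change profiles
are rejected as degenerate rather than fitted.

## Descriptive outputs

Group summaries report the median and IQR per category and biomarker
using linear interpolation between order statistics (the type-7
quantile rule; the convention matters at these cohort sizes and is
documented rather than assumed). Spearman correlations use average
ranks on ties with the large-sample t approximation for p-values.
Between-group inference (ANOVA, post-hoc ranges, mixed models) is
deliberately left to standard statistical tooling on the exported
analysis-ready table.

## Problem sizes and numerical setpoints

Recovery experiments in the tests and the acceptance script use 2048
complex points at 4 kHz bandwidth, cohorts of up to 200 muscle spectra
at SNR 30, 100-replicate Monte-Carlo checks of amplitude bias, and a
1e-4 mM brute-force grid as the magnesium inversion oracle — sizes
chosen so the full suite completes comfortably on a single CPU while
keeping Monte-Carlo standard errors well below the tolerances being
asserted. Key numerical setpoints: Newton convergence at 1e-10 ppm
forward residual with bisection fallback on (1e-6, 10) mM;
Levenberg-Marquardt with `ftol = ptol = 1e-15` and at most 500
iterations; ACME penalty weight 1000 with relative tolerance 1e-12;
threshold roots by `uniroot` at 1e-6.

## Known limitations

* The estimator of the weak Pi_b component remains the noisiest link;
  its amplitude noise propagates into weighted pH scatter (the fitted
  two-peak Pi model is retained because the weighted-pH definition
  requires it).
* Lineshapes are purely Lorentzian end to end; Voigt or susceptibility
  broadening would bias fitted linewidths against the tight priors.
* The begin-time phase absorbs linear phase ramps only; higher-order
  phase errors (e.g. from eddy currents) are not modelled.
* Staging thresholds derived from the increment model depend on the
  chosen band definition; the shipped defaults (13.5, 81.5) should be
  preferred for comparability.
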