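# p31quant

Quantitative phosphorus-31 magnetic resonance spectroscopy (³¹P-MRS)
biomarkers of skeletal muscle, for spectroscopists and neuromuscular
researchers who need a fully testable pipeline from raw free induction
decays to analysis-ready biomarker tables. The package targets the
biomarkers used to characterise dystrophic muscle at 7 T — intracellular
pH, free ionised magnesium, and the PDE/γ-ATP membrane-damage marker —
together with Dixon fat-fraction staging of muscles as preserved,
progressing or end-stage.

Because raw patient data of this kind are rarely shareable, the package
is built around a synthetic-data module with exact ground truth: every
stage of the pipeline (k-space Hann filtering, CSI voxel reconstruction,
SNR-based quality control, automatic phase correction, apodisation,
referencing, alignment, prior-knowledge time-domain fitting, biomarker
computation, staging, cohort summaries) is validated by round trips
against what was simulated.

## The models at the core

* **pH** from the inorganic-phosphate chemical shift σ₁ (ppm, relative
  to PCr):

  pH = 6.75 + log₁₀((3.27 − σ₁)/(σ₁ − 5.69)),

  applied to both fitted Pi components and combined as the
  amplitude-weighted pH, pH_wt = pH_a·Pi_a/Pi_tot + pH_b·Pi_b/Pi_tot.

* **Free [Mg²⁺]** from the observed α−β ATP shift difference δ_obs^(α−β),
  modelled as the population-weighted mean of the limiting shifts of the
  ATP, HATP, MgATP, MgHATP and Mg₂ATP species with [H⁺] = 10^(−pH_wt);
  the strictly monotone forward model is inverted by Newton iteration
  (quadratic fast path cross-checked in the tests). Formation constants
  and limiting shifts are supplied explicitly; the shipped set is a
  synthetic, physiologically plausible one (`mg_constants_synthetic()`).

* **PDE/γ-ATP** corrected for steady-state T1 saturation,
  f = sinθ(1−E)/(1−E cosθ), E = exp(−TR/T1).

* **Staging** by baseline fat fraction: preserved ≤ 13.5%, progressing
  strictly between, end-stage ≥ 81.5% (excluded from analysis);
  thresholds re-derivable from longitudinal records as the zero
  crossings of the lower uncertainty bound of a logistic-growth
  increment fit.

The AMARES-style fitting engine does nonlinear least squares on the
complex time-domain model Σ A_k e^{i(2πf_k t + φ)} e^{−π lw_k t} with
box-constraint prior knowledge, quarter-sine weighting of the first 12
points (16 in the broad-PDE re-fit), shared zero- and first-order
("begin time") phases, and an analytic Jacobian.

## Worked example

```r
library(p31quant)

acq <- acq_params()                      # 7 T, 2048 pts, 4 kHz, TR 2 s, FA 45
truth <- ground_truth(ph_a = 7.00, mg = 0.72)
truth$noise_sd <- noise_sd_for_snr(truth, acq, snr = 30)
fid <- synthesize_fid(truth, acq)

res <- quantify_fid(fid)                 # QC -> phase -> apodise -> fit -> metrics
res$metrics
#>       ph_a     ph_b   ph_wt        mg  pde_gatp delta_ab      snr flags
#> 1 7.010791 7.314416 7.06726 0.6944884 0.4617305 8.533316 28.66972
```

The fitted weighted pH (7.067) and free magnesium (0.694 mM) sit within
per-spectrum noise of the simulated truth (7.05, 0.72 mM); `delta_ab`
is the fitted α−β ATP shift difference in ppm and `snr` the conservative
PCr-based estimate used for quality control. (The PDE/γ-ATP here differs
from 0.37 because this quick example did not saturation-scale the
simulated amplitudes; the cohort generator does, and then the corrected
ratio recovers the simulated value.)

A cohort-scale run:

```r
res <- run_pipeline(cohort_spec("CTRL", n_spectra = 200, snr_target = 30), seed = 1)
res$summary
#>   category   metric    median        iqr   n
#> 1     CTRL       mg 0.7205463 0.11389496 200
#> 2     CTRL    ph_wt 7.0578430 0.05343235 200
#> 3     CTRL pde_gatp 0.3804936 0.16684934 200
```

against generator medians of 0.72 mM, 7.05 and 0.37.

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate.R` (cohorts + a CSI phantom),
`02_preprocess_fit.R` (QC ledger + per-muscle metrics),
`03_stage_summarize.R` (staging, medians/IQRs, Spearman correlations),
`04_staging_thresholds.R` (threshold derivation demo). Each writes its
tables under `results/`.

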