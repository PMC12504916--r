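# Shared fixtures, built in code at test time.

acq_default <- function() acq_params()

acq_small <- function() acq_params(n_points = 512L)

# ground truth whose amplitudes carry the steady-state saturation the
# cohort generator applies, so T1-corrected ratios compare to `pde_ratio`
saturated_truth <- function(ph_a = 7.00, mg = 0.72, pde_ratio = 0.37,
                            acq = acq_default(),
                            t1s = t1_table_synthetic(), ...) {
  sat <- vapply(names(t1s), function(p)
    saturation_factor(t1s[[p]], acq$tr, acq$flip_angle), 0)
  conc <- p31quant:::default_amplitudes()
  conc[["PDE"]] <- pde_ratio * conc[["gATP"]]
  ground_truth(ph_a = ph_a, mg = mg, amplitudes = conc * sat[names(conc)], ...)
}

# processed spectrum ready for fitting, bypassing automatic phasing
# (synthesis used zero phases)
processed_spectrum <- function(fid) {
  reference_to_pcr(spectrum_from_fid(apodize_zerofill(fid)))
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_true(all(abs(actual - expected) <= rel_tol * pmax(abs(expected), 1e-12)))
}
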