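# Synthetic FID / CSI / cohort generator.

test_that("noiseless single-resonance FID peaks at its prescribed shift", {
  acq <- acq_default()
  sp <- spectrum_from_fid(synthesize_fid(ground_truth(amplitudes = c(PCr = 10)), acq))
  expect_lt(abs(sp$ppm[which.max(Mod(sp$values))]), acq$bandwidth / acq$n_points /
              acq$reference_frequency)
  # Pi_a peak lands at the pH-implied shift (zero-filled readout)
  fid <- apodize_zerofill(synthesize_fid(
    ground_truth(ph_a = 7.05, amplitudes = c(Pi_a = 1)), acq), lw = 0)
  spz <- spectrum_from_fid(fid)
  got <- spz$ppm[which.max(Mod(spz$values))]
  expect_lt(abs(got - shift_from_ph(7.05)), 2 * diff(spz$ppm[1:2]))
})

test_that("synthesis is bit-reproducible given the seed and differs across seeds", {
  acq <- acq_small()
  tr <- ground_truth(noise_sd = 0.3, seed = 99L)
  expect_identical(synthesize_fid(tr, acq)$samples, synthesize_fid(tr, acq)$samples)
  tr2 <- tr; tr2$seed <- 100L
  expect_false(identical(synthesize_fid(tr, acq)$samples,
                         synthesize_fid(tr2, acq)$samples))
})

test_that("resonances outside the sampled bandwidth are rejected", {
  acq <- acq_params(bandwidth = 1000, n_points = 256)   # +-500 Hz only
  expect_error(synthesize_fid(ground_truth(), acq), "bandwidth")
})

test_that("noise targeting hits the estimator's SNR scale", {
  acq <- acq_default()
  tr <- ground_truth()
  tr$noise_sd <- noise_sd_for_snr(tr, acq, 30)
  snrs <- vapply(1:6, function(s) {
    tr$seed <- s
    estimate_snr(synthesize_fid(tr, acq))
  }, 0)
  expect_lt(abs(median(snrs) - 30), 3)
})

test_that("CSI synthesis localises an impulse and inverts exactly", {
  acq <- acq_small()
  tr <- ground_truth(amplitudes = c(PCr = 10))
  truths <- vector("list", 80)
  truths[[(4 - 1) * 8 + 3]] <- tr            # voxel (3, 4)
  grid <- synthesize_csi(csi_phantom(truths), acq)
  vox <- reconstruct_voxels(grid)
  energy <- apply(Mod(vox)^2, c(1, 2), sum)
  expect_equal(which(energy == max(energy)), (4 - 1) * 8 + 3)
  expect_lt(sum(energy) - max(energy), 1e-20 * max(energy))
  expect_lt(max(Mod(vox[3, 4, ] - synthesize_fid(tr, acq)$samples)), 1e-12)
})

test_that("uniform phantom reconstructs identical voxels", {
  acq <- acq_small()
  mask <- matrix(TRUE, 8, 10)
  grid <- synthesize_csi(csi_phantom(ground_truth(amplitudes = c(PCr = 5)),
                                     mask = mask), acq)
  vox <- reconstruct_voxels(grid)
  ref <- vox[1, 1, ]
  for (i in c(2, 5, 8)) expect_lt(max(Mod(vox[i, 4, ] - ref)), 1e-10)
})

test_that("two-compartment phantom keeps per-voxel Pi shifts after reconstruction", {
  acq <- acq_default()
  mask <- matrix(FALSE, 8, 10); mask[3, 4] <- TRUE; mask[6, 7] <- TRUE
  truths <- vector("list", 80)
  truths[[(4 - 1) * 8 + 3]] <- ground_truth(ph_a = 6.90, amplitudes = c(Pi_a = 1))
  truths[[(7 - 1) * 8 + 6]] <- ground_truth(ph_a = 7.20, amplitudes = c(Pi_a = 1))
  vox <- reconstruct_voxels(synthesize_csi(csi_phantom(truths, mask = mask), acq))
  step <- acq$bandwidth / acq$n_points / acq$reference_frequency
  for (cs in list(list(3, 4, 6.90), list(6, 7, 7.20))) {
    sp <- spectrum_from_fid(voxel_fid(vox, cs[[1]], cs[[2]]))
    got <- sp$ppm[which.max(Mod(sp$values))]
    expect_lt(abs(got - shift_from_ph(cs[[3]])), 2 * step)
  }
})

test_that("phantom dimension mismatch is rejected", {
  expect_error(csi_phantom(vector("list", 7), nx = 8, ny = 10), "dimensions")
})

test_that("zero spread puts every muscle exactly at the group median", {
  sp <- cohort_spec("CTRL", n_spectra = 12, mg_iqr = 0, ph_iqr = 0, pde_iqr = 0,
                    snr_target = Inf)
  co <- make_cohort(sp, seed = 5)
  expect_true(all(co$manifest$true_mg == 0.72))
  expect_true(all(co$manifest$true_ph_wt == 7.05))
  expect_true(all(co$manifest$true_pde_ratio == 0.37))
})

test_that("cohort manifests converge to the printed group medians", {
  co <- make_cohort(cohort_spec("CTRL", n_spectra = 500, snr_target = Inf,
                                sampling = "iid"), seed = 3)
  m <- co$manifest
  # 3 x SE of the sample median for a normal population
  se_med <- function(iqr, n) 1.2533 * (iqr / 1.349) / sqrt(n)
  expect_lt(abs(median(m$true_mg) - 0.72), 3 * se_med(0.10, 500))
  expect_lt(abs(median(m$true_ph_wt) - 7.05), 3 * se_med(0.04, 500))
  expect_lt(abs(median(m$true_pde_ratio) - 0.37), 3 * se_med(0.18, 500))
  # balanced sampling pins the median essentially exactly
  cob <- make_cohort(cohort_spec("CTRL", n_spectra = 200, snr_target = Inf),
                     seed = 3)
  expect_lt(abs(median(cob$manifest$true_mg) - 0.72), 1e-3)
})

test_that("group defaults reproduce the printed between-group differences", {
  ctrl <- cohort_spec("CTRL"); prog <- cohort_spec("BMD_prog")
  expect_equal(ctrl$mg_median - prog$mg_median, 0.10)
  expect_equal(ctrl$pde_median, 0.37)
  expect_equal(prog$pde_median, 0.46)
  co <- make_cohort(list(cohort_spec("CTRL", n_spectra = 40, mg_iqr = 0,
                                     snr_target = Inf),
                         cohort_spec("BMD_prog", n_spectra = 40, mg_iqr = 0,
                                     snr_target = Inf)), seed = 2)
  m <- co$manifest
  expect_equal(median(m$true_mg[m$group == "CTRL"]) -
                 median(m$true_mg[m$group == "BMD_prog"]), 0.10)
})

test_that("empty muscle list is rejected", {
  expect_error(cohort_spec("CTRL", muscles = character(0)), "non-empty")
})

test_that("latent coupling induces the requested rank correlation sign", {
  co <- make_cohort(cohort_spec("CTRL", n_spectra = 300, snr_target = Inf,
                                latent_rho = -0.5), seed = 8)
  r <- cor(co$manifest$true_mg, co$manifest$true_ph_wt, method = "spearman")
  expect_lt(r, -0.3)
  expect_gt(r, -0.7)
})

test_that("FID text export round-trips data and acquisition metadata", {
  acq <- acq_small()
  fid <- synthesize_fid(ground_truth(noise_sd = 0.2, seed = 4), acq)
  path <- withr::local_tempfile(fileext = ".txt")
  write_fid_txt(fid, path)
  back <- read_fid_txt(path)
  expect_lt(max(Mod(back$samples - fid$samples)), 1e-10)
  expect_equal(back$acq$dwell_time, acq$dwell_time)
  expect_equal(back$acq$reference_frequency, acq$reference_frequency)
})

test_that("manifest CSV holds one row per generated spectrum", {
  co <- make_cohort(cohort_spec("CTRL", n_spectra = 9, snr_target = Inf), seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest_csv(co, path)
  expect_equal(nrow(read.csv(path)), 9)
})

test_that("ATP doublet option splits the moieties symmetrically and stays off by default", {
  acq <- acq_default()
  expect_identical(ground_truth()$atp_doublet_j, 0)
  tr <- ground_truth(amplitudes = c(gATP = 2), linewidths = c(gATP = 15),
                     atp_doublet_j = 60)
  sp <- spectrum_from_fid(apodize_zerofill(synthesize_fid(tr, acq), lw = 0))
  win <- which(abs(sp$ppm - tr$shifts[["gATP"]]) < 0.6)
  m <- Mod(sp$values[win])
  peaks <- win[which(diff(sign(diff(m))) == -2) + 1]
  expect_length(peaks, 2)
  sep_hz <- abs(diff(sp$ppm[peaks])) * acq$reference_frequency
  expect_lt(abs(sep_hz - 60), 3)
  # total area is preserved: the time-domain origin value matches the singlet
  tr0 <- ground_truth(amplitudes = c(gATP = 2), linewidths = c(gATP = 15))
  expect_equal(synthesize_fid(tr, acq)$samples[1],
               synthesize_fid(tr0, acq)$samples[1])
})
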