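# Preprocessing chain: Hann filter, voxel shifts, SNR, phasing,
# apodisation, referencing, alignment, QC.

test_that("Hann filter keeps the k-space centre sample and refuses double filtering", {
  acq <- acq_small()
  grid <- synthesize_csi(csi_phantom(ground_truth(amplitudes = c(PCr = 5))), acq)
  centre <- c(floor(8 / 2) + 1, floor(10 / 2) + 1)
  before <- grid$kspace[centre[1], centre[2], ]
  filtered <- hann_filter(grid)
  expect_identical(filtered$kspace[centre[1], centre[2], ], before)
  expect_true(filtered$filtered)
  expect_error(hann_filter(filtered), "already")
})

test_that("Hann filtering only rescales voxel spectra of a uniform phantom", {
  acq <- acq_small()
  grid <- synthesize_csi(csi_phantom(ground_truth(amplitudes = c(PCr = 5)),
                                     mask = matrix(TRUE, 8, 10)), acq)
  v0 <- reconstruct_voxels(grid)[4, 5, ]
  v1 <- reconstruct_voxels(hann_filter(grid))[4, 5, ]
  scale <- sum(Conj(v0) * v1) / sum(Mod(v0)^2)
  expect_lt(max(Mod(v1 - scale * v0)), 1e-10 * max(Mod(v0)))
})

test_that("Hann point-spread of an impulse equals the window's analytic transform", {
  acq <- acq_params(n_points = 64)
  nx <- 8; ny <- 10
  cx <- 5; cy <- 6
  truths <- vector("list", nx * ny)
  truths[[(cy - 1) * nx + cx]] <- ground_truth(amplitudes = c(PCr = 1))
  vox <- reconstruct_voxels(hann_filter(synthesize_csi(csi_phantom(truths), acq)))
  prof <- Mod(vox[, cy, 1])
  # an impulse at (cx, cy) reconstructs to the inverse DFT of the Hann
  # weights, circularly centred on (cx, cy)
  wx <- cos(pi * p31quant:::centred_index(nx) / nx)^2
  hx <- Mod(fft(p31quant:::ifftshift(wx), inverse = TRUE)) / nx
  expected <- hx[((seq_len(nx) - cx) %% nx) + 1]
  expect_equal(prof / max(prof), expected / max(expected), tolerance = 1e-10)
})

test_that("sub-voxel shifts: zero shift is exact, half shift mixes neighbours equally", {
  acq <- acq_small()
  tr <- ground_truth(amplitudes = c(PCr = 3))
  truths <- vector("list", 80)
  truths[[(4 - 1) * 8 + 3]] <- tr
  grid <- synthesize_csi(csi_phantom(truths), acq)
  v0 <- reconstruct_voxels(grid, c(0, 0))
  expect_lt(max(Mod(v0[3, 4, ] - synthesize_fid(tr, acq)$samples)), 1e-12)
  # two adjacent voxels with equal signal: the midpoint sees them equally
  tr2 <- ground_truth(amplitudes = c(PCr = 3), phase0 = 90)
  truths[[(4 - 1) * 8 + 4]] <- tr2
  gridc <- synthesize_csi(csi_phantom(truths), acq)
  vh <- reconstruct_voxels(gridc, c(0.5, 0))
  mid <- vh[3, 4, ]
  f1 <- synthesize_fid(tr, acq)$samples; f2 <- synthesize_fid(tr2, acq)$samples
  basis <- f1 + f2
  coef <- sum(Conj(basis) * mid) / sum(Mod(basis)^2)
  expect_lt(max(Mod(mid - coef * basis)), 1e-8 * max(Mod(mid)))
  expect_error(reconstruct_voxels(grid, c(0.6, 0)), "range")
})

test_that("SNR estimator matches a constructed peak-over-noise ratio", {
  acq <- acq_default()
  tr <- ground_truth(amplitudes = c(PCr = 10))
  tr$noise_sd <- noise_sd_for_snr(tr, acq, 50)
  snrs <- vapply(1:8, function(s) {
    tr$seed <- s
    estimate_snr(synthesize_fid(tr, acq))
  }, 0)
  expect_lt(abs(median(snrs) - 50) / 50, 0.10)
  # doubling the signal doubles the SNR (same noise realisation)
  tr$seed <- 1
  f1 <- synthesize_fid(tr, acq)
  tr2 <- tr; tr2$amplitudes <- tr$amplitudes * 2
  tr2$noise_sd <- tr$noise_sd
  f2 <- synthesize_fid(tr2, acq)
  expect_equal(estimate_snr(f2) / estimate_snr(f1), 2, tolerance = 0.02)
  # an exactly noise-free tail flags infinite SNR rather than erroring
  silent <- new_fid(c(rep(1 + 0i, 100), complex(length.out = acq$n_points - 100)),
                    acq)
  expect_identical(estimate_snr(silent), Inf)
})

test_that("ACME recovers pure-absorption spectra and known dephasings", {
  acq <- acq_default()
  spec <- spectrum_from_fid(synthesize_fid(ground_truth(ph_a = 7.0, mg = 0.72), acq))
  r0 <- autophase(spec)
  expect_lt(abs(r0$phase0), 1)
  for (ph in list(c(30, 0), c(20, 10), c(-45, 2))) {
    sp <- apply_phase(spec, ph[1], ph[2])
    sp$phase0 <- 0; sp$phase1 <- 0
    r <- autophase(sp)
    expect_true(r$converged)
    expect_lt(abs(r$phase0 + ph[1]), 2)
    expect_lt(abs(r$phase1 + ph[2]), 2)
  }
})

test_that("apodisation adds its width to a Lorentzian and zero-filling doubles the grid", {
  acq <- acq_default()
  fid <- synthesize_fid(ground_truth(amplitudes = c(PCr = 5),
                                     linewidths = c(PCr = 15)), acq)
  az <- apodize_zerofill(fid)
  expect_length(az$samples, 2 * acq$n_points)
  expect_identical(az$samples[(acq$n_points + 1):(2 * acq$n_points)],
                   complex(length.out = acq$n_points))
  sp <- spectrum_from_fid(az)
  expect_equal(diff(sp$ppm[1:2]),
               acq$bandwidth / (2 * acq$n_points) / acq$reference_frequency,
               tolerance = 1e-12)
  fit <- fit_spectrum(sp, list(peak_prior("PCr", 0, c(-0.2, 0.2), c(5, 90))),
                      weighting_length = 0, phases_fixed = c(0, 0))
  expect_equal(fit$linewidth, 35, tolerance = 1e-4)
  # zero input stays zero
  z <- fid; z$samples <- complex(length.out = acq$n_points)
  expect_identical(apodize_zerofill(z)$samples, complex(length.out = 2 * acq$n_points))
})

test_that("PCr referencing centres a deliberately offset peak and is idempotent", {
  acq <- acq_default()
  tr <- ground_truth(amplitudes = c(PCr = 10))
  tr$shifts[["PCr"]] <- 0.4
  sp <- spectrum_from_fid(apodize_zerofill(synthesize_fid(tr, acq)))
  ref <- reference_to_pcr(sp)
  step <- diff(ref$ppm[1:2])
  expect_lt(abs(ref$ppm[which.max(Mod(ref$values))]), step)
  again <- reference_to_pcr(ref)
  expect_lt(max(abs(again$ppm - ref$ppm)), step)
  expect_false("artefact" %in% again$flags)
})

test_that("a spectrum without a PCr resonance is flagged, not silently referenced", {
  acq <- acq_default()
  tr <- ground_truth(amplitudes = c(bATP = 2), mg = 0.72)
  tr$noise_sd <- 0.05
  sp <- spectrum_from_fid(synthesize_fid(tr, acq))
  out <- reference_to_pcr(sp)
  expect_true("artefact" %in% out$flags)
})

test_that("alignment registers offset copies and averaging raises SNR", {
  acq <- acq_default()
  tr <- ground_truth(ph_a = 7.0, mg = 0.72)
  s1 <- spectrum_from_fid(synthesize_fid(tr, acq))
  tr2 <- tr; tr2$shifts <- tr$shifts + 0.2
  s2 <- spectrum_from_fid(synthesize_fid(tr2, acq))
  al <- align_and_average(list(s1, s2), snrs = c(2, 1))
  expect_identical(al$reference, 1L)
  expect_equal(al$flags, c("none", "none"))
  step <- diff(s1$ppm[1:2])
  expect_lt(abs(al$shifts_ppm[2] + 0.2), step)
  p1 <- al$average$ppm[which.max(Mod(al$average$values))]
  expect_lt(abs(p1 - s1$ppm[which.max(Mod(s1$values))]), step)

  # N identical spectra average to any input
  same <- align_and_average(list(s1, s1, s1))
  expect_lt(max(Mod(same$average$values - s1$values)), 1e-8 * max(Mod(s1$values)))

  # averaged SNR grows like sqrt(N) (Monte-Carlo, fixed seeds)
  trn <- tr
  trn$noise_sd <- noise_sd_for_snr(tr, acq, 25)
  reps <- lapply(1:4, function(s) {
    trn$seed <- s
    spectrum_from_fid(synthesize_fid(trn, acq))
  })
  avg <- align_and_average(reps)$average
  snr_avg <- estimate_snr(new_fid(p31quant:::fft_inv(p31quant:::ifftshift(avg$values)),
                                  acq))
  expect_lt(abs(snr_avg / 25 - 2) / 2, 0.25)
})

test_that("alignment permutation-invariance with a fixed reference", {
  acq <- acq_default()
  tr <- ground_truth(ph_a = 7.0, mg = 0.72)
  tr$noise_sd <- noise_sd_for_snr(tr, acq, 40)
  specs <- lapply(1:3, function(s) {
    tr$seed <- s
    spectrum_from_fid(synthesize_fid(tr, acq))
  })
  a1 <- align_and_average(specs, snrs = c(3, 2, 1))
  a2 <- align_and_average(specs[c(2, 3, 1)], snrs = c(2, 1, 3))
  expect_lt(max(Mod(a1$average$values - a2$average$values)),
            1e-9 * max(Mod(a1$average$values)))
})

test_that("QC filter excludes strictly below threshold and is idempotent", {
  snrs <- c(12, 10, 9.99, 4, 30, 10.0001, 7, 15, 11, 3,
            8, 22, 10, 5, 40, 9, 13, 6, 18, 2)
  items <- lapply(snrs, function(s) list(qc = qc_report(s)))
  out <- qc_filter(items)
  expect_equal(unname(out$summary["retained"]), sum(snrs >= 10))
  expect_equal(unname(out$summary["low_snr"]), sum(snrs < 10))
  expect_equal(unname(out$summary["total"]), 20L)
  # SNR exactly at the threshold is retained
  expect_true(any(vapply(out$retained, function(it) it$qc$snr == 10, TRUE)))
  again <- qc_filter(out$retained)
  expect_equal(unname(again$summary["retained"]), unname(out$summary["retained"]))
  expect_equal(unname(again$summary["low_snr"]), 0L)
})

test_that("artefact and alignment flags exclude regardless of SNR", {
  items <- list(list(qc = qc_report(50, artefact = TRUE)),
                list(qc = qc_report(50, alignment_failure = TRUE)),
                list(qc = qc_report(50)))
  out <- qc_filter(items)
  expect_equal(unname(out$summary["retained"]), 1L)
  expect_equal(unname(out$summary["artefact"]), 1L)
  expect_equal(unname(out$summary["alignment_failure"]), 1L)
})
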