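#' @name spectra-sim
#' @title Synthetic 31P muscle spectra with known ground truth
#' @description
#' The simulator produces Lorentzian-damped free induction decays for the
#' seven muscle resonances (PCr; gamma-, alpha- and beta-ATP; PDE; and the
#' two inorganic-phosphate peaks Pi_a / Pi_b), with the Pi shifts driven by
#' the pH model ([shift_from_ph()]) and the beta-ATP shift by the magnesium
#' equilibrium model ([shift_from_mg()]). Every downstream stage of the
#' pipeline can therefore be tested against exact ground truth.
NULL

# default shift (ppm rel. PCr) and linewidth (Hz) table; Pi_a, Pi_b and
# bATP shifts are overridden from pH / Mg ground truth at synthesis time
peak_names <- function() c("PCr", "gATP", "aATP", "bATP", "PDE", "Pi_a", "Pi_b")

default_shifts <- function() {
  c(PCr = 0, gATP = -2.48, aATP = -7.52, bATP = -16.1,
    PDE = 3.00, Pi_a = 4.85, Pi_b = 5.15)
}

default_linewidths <- function() {
  c(PCr = 12, gATP = 30, aATP = 30, bATP = 32, PDE = 40, Pi_a = 20, Pi_b = 20)
}

default_amplitudes <- function() {
  c(PCr = 10, gATP = 2.5, aATP = 2.5, bATP = 2.5, PDE = 0.925,
    Pi_a = 1, Pi_b = 0.2)
}

#' Ground truth for one synthetic muscle spectrum
#'
#' Collects everything needed to synthesise a spectrum and to check the
#' pipeline against it: per-resonance amplitudes, shifts and Lorentzian
#' linewidths, global zero/first-order phase, the true pH of the two Pi
#' compartments, the true free Mg2+, and the noise level and seed.
#' The Pi_a, Pi_b and beta-ATP shifts are derived from `ph_a`, `ph_b` and
#' `mg` through the equilibrium models; the true weighted pH (amplitude
#' weighting of the two Pi compartments) drives the `[H+]` of the Mg model.
#' By default Pi_b carries 20% of the Pi_a amplitude at `ph_b = ph_a +
#' 0.3` — a generator choice, not a literature claim.
#'
#' @param ph_a pH of the main (acid-side) Pi compartment
#' @param ph_b pH of the minor Pi compartment (default `ph_a + 0.3`)
#' @param mg true free ionised Mg2+ in mM
#' @param amplitudes named vector of resonance amplitudes (a.u., >= 0)
#' @param linewidths named vector of Lorentzian FWHMs in Hz
#' @param shifts named vector of shifts (ppm rel. PCr); entries for
#'   Pi_a/Pi_b/bATP are recomputed from `ph_a`/`ph_b`/`mg`
#' @param phase0 global zero-order phase, degrees
#' @param phase1 global first-order phase, degrees/ppm (about PCr = 0)
#' @param noise_sd standard deviation of the complex Gaussian noise added
#'   per real/imaginary sample (0 = noiseless)
#' @param seed integer seed for the noise draw
#' @param constants [mg_constants()] set used for the beta-ATP shift
#' @param atp_doublet_j if positive, each ATP moiety is synthesised as an
#'   equal-amplitude doublet with this J splitting in Hz (default 0:
#'   singlets, matching the default fitting priors)
#' @return object of class `ground_truth`
#' @export
ground_truth <- function(ph_a = 7.00, ph_b = ph_a + 0.3, mg = 0.72,
                         amplitudes = default_amplitudes(),
                         linewidths = default_linewidths(),
                         shifts = default_shifts(),
                         phase0 = 0, phase1 = 0,
                         noise_sd = 0, seed = 1L,
                         constants = mg_constants_synthetic(),
                         atp_doublet_j = 0) {
  stopifnot(all(amplitudes >= 0), all(linewidths > 0), noise_sd >= 0,
            mg >= 0, atp_doublet_j >= 0)
  nm <- names(amplitudes)
  stopifnot(!is.null(nm), all(nm %in% peak_names()))
  shifts <- shifts[nm]
  linewidths <- linewidths[nm]
  if ("Pi_a" %in% nm) shifts[["Pi_a"]] <- shift_from_ph(ph_a)
  if ("Pi_b" %in% nm) shifts[["Pi_b"]] <- shift_from_ph(ph_b)
  amp_a <- if ("Pi_a" %in% nm) amplitudes[["Pi_a"]] else 1
  amp_b <- if ("Pi_b" %in% nm) amplitudes[["Pi_b"]] else 0
  ph_wt <- if (amp_a + amp_b > 0) (ph_a * amp_a + ph_b * amp_b) / (amp_a + amp_b) else ph_a
  if ("bATP" %in% nm && "aATP" %in% nm)
    shifts[["bATP"]] <- shifts[["aATP"]] - shift_from_mg(mg, ph_wt, constants)
  structure(
    list(amplitudes = amplitudes, shifts = shifts, linewidths = linewidths,
         phase0 = phase0, phase1 = phase1,
         ph_a = ph_a, ph_b = ph_b, ph_wt = ph_wt, mg = mg,
         noise_sd = noise_sd, seed = as.integer(seed),
         atp_doublet_j = atp_doublet_j),
    class = "ground_truth")
}

#' Synthesise a free induction decay from ground truth
#'
#' Time-domain model: `FID(t) = sum_k A_k exp(i(2 pi f_k t + phi_k))
#' exp(-pi lw_k t)` plus circularly-symmetric complex Gaussian noise.
#' Frequencies follow from the ground-truth ppm shifts and the carrier
#' position; the global first-order phase enters as a per-resonance phase
#' `phase1 * shift_k`. Noiseless synthesis is bit-reproducible; noisy
#' synthesis is reproducible given the ground-truth seed.
#'
#' @param truth a [ground_truth()] object
#' @param acq an [acq_params()] object
#' @return object of class `fid`
#' @export
synthesize_fid <- function(truth, acq) {
  stopifnot(inherits(truth, "ground_truth"), inherits(acq, "acq_params"))
  f <- ppm_to_hz(truth$shifts, acq)
  if (any(abs(f) >= acq$bandwidth / 2))
    stop("resonance outside the acquisition bandwidth")
  t <- time_axis(acq)
  jsplit <- truth$atp_doublet_j %||% 0
  sig <- complex(length.out = acq$n_points)
  for (k in seq_along(truth$amplitudes)) {
    phi <- (truth$phase0 + truth$phase1 * truth$shifts[[k]]) * pi / 180
    fk <- f[[k]]
    if (jsplit > 0 && names(truth$amplitudes)[k] %in% c("gATP", "aATP", "bATP"))
      fk <- fk + c(-0.5, 0.5) * jsplit     # equal-amplitude doublet
    for (fj in fk)
      sig <- sig + truth$amplitudes[[k]] / length(fk) *
        exp(1i * (2 * pi * fj * t + phi) - pi * truth$linewidths[[k]] * t)
  }
  if (truth$noise_sd > 0) {
    set.seed(truth$seed)
    sig <- sig + complex(real = stats::rnorm(acq$n_points, 0, truth$noise_sd),
                         imaginary = stats::rnorm(acq$n_points, 0, truth$noise_sd))
  }
  new_fid(sig, acq, provenance = truth)
}

#' Noise level required to hit a target SNR
#'
#' SNR here follows the pipeline's conservative estimator
#' ([estimate_snr()]): 20-Hz-filtered PCr peak height over the raw
#' time-domain noise SD. The required noise SD is computed from the
#' noiseless synthesis.
#'
#' @param truth a [ground_truth()] object (its `noise_sd` is ignored)
#' @param acq an [acq_params()] object
#' @param snr target signal-to-noise ratio (> 0)
#' @param apodize_hz filter used for the peak height (default 20, as in
#'   [estimate_snr()])
#' @return noise standard deviation (per real/imaginary sample)
#' @export
noise_sd_for_snr <- function(truth, acq, snr, apodize_hz = 20) {
  stopifnot(snr > 0)
  clean <- truth
  clean$noise_sd <- 0
  fid <- synthesize_fid(clean, acq)
  t <- (seq_len(acq$n_points) - 1) * acq$dwell_time
  spec <- Mod(fftshift(fft_fwd(fid$samples * exp(-pi * apodize_hz * t)))) /
    sqrt(acq$n_points)
  ppm <- ppm_axis_nominal(acq)
  height <- max(spec[abs(ppm) <= 3])
  height / snr
}

#' Voxelised phantom for 2D-CSI synthesis
#'
#' A rectangular grid of voxels, each either empty (`NULL`) or carrying a
#' [ground_truth()]. The default emulates a "lower leg" cross-section: an
#' elliptical mask of uniform muscle tissue inside an 8 x 10 grid.
#'
#' @param truths a list (length `nx * ny`, column-major) of
#'   [ground_truth()] objects or `NULL` for empty voxels; or a single
#'   `ground_truth` recycled over the mask
#' @param nx,ny grid dimensions (default 8 x 10)
#' @param mask logical `nx x ny` matrix of occupied voxels; default is an
#'   inscribed ellipse
#' @return object of class `csi_phantom`
#' @export
csi_phantom <- function(truths, nx = 8L, ny = 10L, mask = NULL) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.null(mask)) {
    cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
    mask <- outer(seq_len(nx), seq_len(ny), function(i, j)
      ((i - cx) / (nx / 2))^2 + ((j - cy) / (ny / 2))^2 <= 1)
  }
  stopifnot(identical(dim(mask), c(nx, ny)))
  if (inherits(truths, "ground_truth")) {
    tl <- vector("list", nx * ny)
    tl[which(mask)] <- list(truths)
    truths <- tl
  }
  if (length(truths) != nx * ny)
    stop("phantom dimensions do not match the grid")
  structure(list(truths = truths, nx = nx, ny = ny, mask = mask),
            class = "csi_phantom")
}

#' Synthesise a 2D-CSI k-space grid from a phantom
#'
#' Each occupied voxel contributes its FID; k-space is the 2D spatial
#' discrete Fourier transform of the voxel grid, stored centred (the
#' k-space centre sample sits at index `(floor(nx/2)+1, floor(ny/2)+1)`).
#' The inverse spatial transform of the unfiltered grid recovers the voxel
#' FIDs to numerical precision.
#'
#' @param phantom a [csi_phantom()]
#' @param acq an [acq_params()] object
#' @param field_of_view c(x, y) in mm (metadata only)
#' @return object of class `csi_grid`
#' @export
synthesize_csi <- function(phantom, acq, field_of_view = c(160, 200)) {
  stopifnot(inherits(phantom, "csi_phantom"), inherits(acq, "acq_params"))
  nx <- phantom$nx; ny <- phantom$ny; np <- acq$n_points
  vox <- array(0+0i, dim = c(nx, ny, np))
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    tr <- phantom$truths[[(j - 1) * nx + i]]
    if (!is.null(tr)) vox[i, j, ] <- synthesize_fid(tr, acq)$samples
  }
  ks <- array(0+0i, dim = c(nx, ny, np))
  for (p in seq_len(np)) {
    sl <- stats::fft(vox[, , p])               # 2D spatial DFT
    sl <- sl[fftshift_idx(nx), fftshift_idx(ny)]
    ks[, , p] <- sl
  }
  structure(list(kspace = ks, nx = nx, ny = ny, acq = acq,
                 field_of_view = field_of_view, filtered = FALSE),
            class = "csi_grid")
}

# index permutation implementing fftshift / its inverse along one dimension
fftshift_idx <- function(n) c((floor(n / 2) + 1):n, seq_len(floor(n / 2)))
ifftshift_idx <- function(n) c((ceiling(n / 2) + 1):n, seq_len(ceiling(n / 2)))

#' Group-level cohort specification
#'
#' Defines one study group (healthy control, or preserved / progressing
#' Becker-dystrophy muscles) for the synthetic-cohort generator: how many
#' muscle spectra, which muscles, and the group median and IQR of the
#' three biomarkers. The defaults reproduce the study conditions this
#' package targets: group medians (mg 0.72 / 0.63 / 0.62 mM, weighted pH
#' 7.05 / 7.08 / 7.07, PDE/gamma-ATP 0.37 / 0.45 / 0.46 for CTRL /
#' BMD_pre / BMD_prog) with the corresponding IQRs, at SNR 30.
#'
#' @param group one of `"CTRL"`, `"BMD_pre"`, `"BMD_prog"`
#' @param n_spectra number of muscle spectra to generate
#' @param muscles character subset of TA, TP, PER, SOL, GCL, GCM
#' @param mg_median,mg_iqr group median and IQR of true Mg2+ (mM)
#' @param ph_median,ph_iqr group median and IQR of true weighted pH
#' @param pde_median,pde_iqr group median and IQR of the true
#'   PDE/gamma-ATP concentration ratio
#' @param snr_target SNR of the synthesised spectra (pipeline estimator)
#' @param latent_rho rank correlation between the latent factors of pH and
#'   Mg2+ draws (default 0, independent)
#' @param sampling `"balanced"` (scrambled quantiles: finite cohorts
#'   reproduce the group median essentially exactly) or `"iid"`
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(group = c("CTRL", "BMD_pre", "BMD_prog"),
                        n_spectra = 60L,
                        muscles = c("TA", "TP", "PER", "SOL", "GCL", "GCM"),
                        mg_median = NULL, mg_iqr = NULL,
                        ph_median = NULL, ph_iqr = NULL,
                        pde_median = NULL, pde_iqr = NULL,
                        snr_target = 30,
                        latent_rho = 0,
                        sampling = c("balanced", "iid")) {
  group <- match.arg(group)
  sampling <- match.arg(sampling)
  if (!length(muscles)) stop("muscle list must be non-empty")
  stopifnot(all(muscles %in% c("TA", "TP", "PER", "SOL", "GCL", "GCM")),
            n_spectra >= 1)
  defaults <- list(
    CTRL     = list(mg = c(0.72, 0.10), ph = c(7.05, 0.04), pde = c(0.37, 0.18)),
    BMD_pre  = list(mg = c(0.63, 0.16), ph = c(7.08, 0.05), pde = c(0.45, 0.33)),
    BMD_prog = list(mg = c(0.62, 0.13), ph = c(7.07, 0.05), pde = c(0.46, 0.23)))[[group]]
  structure(list(
    group = group, n_spectra = as.integer(n_spectra), muscles = muscles,
    mg_median = mg_median %||% defaults$mg[1], mg_iqr = mg_iqr %||% defaults$mg[2],
    ph_median = ph_median %||% defaults$ph[1], ph_iqr = ph_iqr %||% defaults$ph[2],
    pde_median = pde_median %||% defaults$pde[1], pde_iqr = pde_iqr %||% defaults$pde[2],
    snr_target = snr_target, latent_rho = latent_rho, sampling = sampling),
    class = "cohort_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw n values with the given median and IQR (normal shape); "balanced"
# assigns scrambled plug-in quantiles ranked by a latent normal score
draw_metric <- function(n, med, iqr, z, sampling, lower = -Inf) {
  sdv <- iqr / (2 * stats::qnorm(0.75))
  if (sdv == 0) return(rep(med, n))
  v <- if (sampling == "balanced") {
    q <- stats::qnorm((seq_len(n) - 0.5) / n, med, sdv)
    q[order(order(z))]                  # value ranks follow latent ranks
  } else {
    stats::qnorm(stats::pnorm(z), med, sdv)
  }
  pmax(v, lower)
}

#' Generate a synthetic cohort of muscle spectra
#'
#' Draws per-muscle ground truth (Mg2+, weighted pH, PDE/gamma-ATP ratio,
#' linewidths, phases) from the group distributions in `spec`, applies
#' steady-state T1 saturation to the simulated amplitudes (so the
#' pipeline's T1 correction is exercised end to end), scales the noise to
#' the target SNR, and returns the FIDs together with a ground-truth
#' manifest. Fat fractions consistent with the group's staging category
#' are attached for the staging module.
#'
#' @param spec a [cohort_spec()] (or list of them, concatenated)
#' @param seed integer seed governing all randomness
#' @param acq an [acq_params()] object
#' @param t1s named T1 table (seconds) used for the saturation scaling,
#'   see [t1_table_synthetic()]
#' @param constants [mg_constants()] set for beta-ATP shift synthesis
#' @return list with `manifest` (data frame, one row per muscle spectrum,
#'   all ground-truth fields) and `fids` (list of `fid` objects)
#' @export
make_cohort <- function(spec, seed = 1L, acq = acq_params(),
                        t1s = t1_table_synthetic(),
                        constants = mg_constants_synthetic()) {
  if (inherits(spec, "cohort_spec")) spec <- list(spec)
  set.seed(as.integer(seed))
  manifests <- list(); fids <- list()
  for (sp in spec) {
    n <- sp$n_spectra
    muscles <- rep_len(sp$muscles, n)
    participant <- paste0(sp$group, "_", sprintf("P%02d",
      rep(seq_len(ceiling(n / length(sp$muscles))),
          each = length(sp$muscles))[seq_len(n)]))
    # latent scores: pH and Mg share a correlated factor, PDE independent
    z_ph <- stats::rnorm(n)
    z_mg <- sp$latent_rho * z_ph + sqrt(1 - sp$latent_rho^2) * stats::rnorm(n)
    z_pde <- stats::rnorm(n)
    mg <- draw_metric(n, sp$mg_median, sp$mg_iqr, z_mg, sp$sampling, lower = 0.05)
    ph <- draw_metric(n, sp$ph_median, sp$ph_iqr, z_ph, sp$sampling)
    pde <- draw_metric(n, sp$pde_median, sp$pde_iqr, z_pde, sp$sampling,
                       lower = 0.05)
    ff <- switch(sp$group,
                 CTRL = stats::runif(n, 1, 7),
                 BMD_pre = stats::runif(n, 2, 13.4),
                 BMD_prog = stats::runif(n, 14, 75))
    noise_seeds <- sample.int(.Machine$integer.max - 1L, n)
    sat <- vapply(peak_names(), function(p)
      saturation_factor(t1s[[p]], acq$tr, acq$flip_angle), 0)
    for (i in seq_len(n)) {
      conc <- default_amplitudes()
      conc[["PDE"]] <- pde[i] * conc[["gATP"]]
      amps <- conc * sat[names(conc)]
      lw <- default_linewidths()
      jit <- stats::runif(length(lw), 0.85, 1.15)
      lw <- lw * jit
      tr <- ground_truth(
        ph_a = ph[i] - 0.05, ph_b = ph[i] - 0.05 + 0.3, mg = mg[i],
        amplitudes = amps, linewidths = lw,
        phase0 = stats::runif(1, -30, 30), phase1 = stats::runif(1, -3, 3),
        noise_sd = 0, seed = noise_seeds[i], constants = constants)
      if (sp$snr_target > 0 && is.finite(sp$snr_target))
        tr$noise_sd <- noise_sd_for_snr(tr, acq, sp$snr_target)
      fid <- synthesize_fid(tr, acq)
      fid$provenance <- list(participant = participant[i], muscle = muscles[i],
                             group = sp$group)
      fids[[length(fids) + 1L]] <- fid
      manifests[[length(manifests) + 1L]] <- data.frame(
        participant = participant[i], group = sp$group, muscle = muscles[i],
        true_mg = mg[i], true_ph_wt = ph[i],
        true_ph_a = ph[i] - 0.05, true_ph_b = ph[i] + 0.25,
        true_pde_ratio = pde[i], ff_baseline = ff[i],
        noise_sd = tr$noise_sd, snr_target = sp$snr_target,
        phase0 = tr$phase0, phase1 = tr$phase1, seed = noise_seeds[i],
        stringsAsFactors = FALSE)
    }
  }
  list(manifest = do.call(rbind, manifests), fids = fids)
}
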