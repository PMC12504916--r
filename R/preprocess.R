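#' @name preprocess
#' @title Spectral preprocessing chain
#' @description
#' Reproduces the processing order used for 7 T muscle 2D-CSI data:
#' k-space Hann filtering, voxel reconstruction with sub-voxel grid
#' shifts, conservative SNR estimation and quality control, automatic
#' phase correction by entropy minimisation (ACME), 20 Hz Lorentzian
#' apodisation with two-times zero-filling, PCr referencing, and
#' frequency/phase alignment before averaging.
NULL

#' Construct an FID object
#'
#' @param samples complex vector of time-domain samples
#' @param acq an [acq_params()] object
#' @param provenance free-form origin tag (voxel index, muscle label, ...)
#' @return object of class `fid`
#' @export
new_fid <- function(samples, acq, provenance = NULL) {
  stopifnot(is.complex(samples), inherits(acq, "acq_params"))
  structure(list(samples = samples, acq = acq, provenance = provenance),
            class = "fid")
}

#' Fourier transform an FID into a spectrum
#'
#' Returns the centred complex spectrum with its nominal ppm axis
#' (carrier position known from the acquisition; PCr nominal at 0 ppm
#' before fine referencing).
#'
#' @param fid a [new_fid()] object (possibly zero-filled)
#' @return object of class `p31_spectrum` with fields `values`, `ppm`,
#'   `acq`, `phase0`, `phase1`, `flags`
#' @export
spectrum_from_fid <- function(fid) {
  stopifnot(inherits(fid, "fid"))
  n <- length(fid$samples)
  values <- fftshift(fft_fwd(fid$samples))
  structure(list(values = values,
                 ppm = ppm_axis_nominal(fid$acq, n),
                 acq = fid$acq, phase0 = 0, phase1 = 0,
                 flags = character(0)),
            class = "p31_spectrum")
}

#' Inverse transform a spectrum back to the time domain
#'
#' @param spectrum a `p31_spectrum`
#' @return object of class `fid` (length equals the spectrum length, so a
#'   zero-filled spectrum yields the zero-padded FID)
#' @export
fid_from_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "p31_spectrum"))
  new_fid(fft_inv(ifftshift(spectrum$values)), spectrum$acq)
}

#' Hann-filter a CSI k-space grid
#'
#' Applies separable Hann weights across the two spatial k-dimensions to
#' suppress signal contamination from adjacent voxels, at the cost of a
#' broader spatial point-spread (larger true voxel size). The k-space
#' centre sample keeps weight exactly 1. Filtering twice is rejected.
#'
#' @param grid a [synthesize_csi()] grid with `filtered = FALSE`
#' @return the filtered grid (`filtered = TRUE`)
#' @export
hann_filter <- function(grid) {
  stopifnot(inherits(grid, "csi_grid"))
  if (isTRUE(grid$filtered)) stop("grid is already Hann-filtered")
  wx <- cos(pi * centred_index(grid$nx) / grid$nx)^2
  wy <- cos(pi * centred_index(grid$ny) / grid$ny)^2
  w <- outer(wx, wy)
  for (p in seq_len(dim(grid$kspace)[3]))
    grid$kspace[, , p] <- grid$kspace[, , p] * w
  grid$filtered <- TRUE
  grid
}

#' Reconstruct voxel FIDs from a CSI grid
#'
#' Inverse 2D spatial DFT of the (optionally Hann-filtered) k-space, after
#' applying the linear phase ramp that implements a sub-voxel grid shift
#' of `shift = c(dx, dy)` voxels (|dx|, |dy| <= 0.5, the half-voxel
#' repositioning used to centre voxels within a muscle). Zero shift
#' reproduces the plain reconstruction exactly.
#'
#' @param grid a `csi_grid`
#' @param shift numeric length-2 sub-voxel shift in voxel units
#' @return array `nx x ny x n_points` of complex voxel FIDs, with the
#'   acquisition attached as attribute `acq`
#' @export
reconstruct_voxels <- function(grid, shift = c(0, 0)) {
  stopifnot(inherits(grid, "csi_grid"), length(shift) == 2)
  if (any(abs(shift) > 0.5)) stop("sub-voxel shift out of range [-0.5, 0.5]")
  kx <- centred_index(grid$nx); ky <- centred_index(grid$ny)
  ramp <- outer(exp(2i * pi * kx * shift[1] / grid$nx),
                exp(2i * pi * ky * shift[2] / grid$ny))
  np <- dim(grid$kspace)[3]
  vox <- array(0+0i, dim = dim(grid$kspace))
  for (p in seq_len(np)) {
    sl <- (grid$kspace[, , p] * ramp)[ifftshift_idx(grid$nx), ifftshift_idx(grid$ny)]
    vox[, , p] <- stats::fft(sl, inverse = TRUE) / (grid$nx * grid$ny)
  }
  attr(vox, "acq") <- grid$acq
  vox
}

#' Extract one voxel's FID from a reconstructed CSI array
#'
#' @param vox array returned by [reconstruct_voxels()]
#' @param ix,iy voxel indices
#' @return object of class `fid`
#' @export
voxel_fid <- function(vox, ix, iy) {
  new_fid(vox[ix, iy, ], attr(vox, "acq"),
          provenance = list(voxel = c(ix, iy)))
}

#' Conservative SNR estimate of an FID
#'
#' SNR = (height of the PCr peak in the magnitude spectrum) / (standard
#' deviation of the real and imaginary samples over the final quarter of
#' the raw FID). Two conventions make the ratio conservative and
#' self-consistent: the magnitude spectrum uses the orthonormal
#' (1/sqrt(n)) FFT scaling, under which the raw time-domain noise SD
#' equals the per-bin frequency-domain noise SD; and the peak height is
#' measured after the same 20 Hz Lorentzian filter the processing chain
#' applies (`apodize_hz = 0` gives the raw-spectrum height instead).
#' Measuring the filtered height against the raw noise understates the
#' narrow PCr peak's raw prominence, which is the conservative choice.
#' The PCr peak is the magnitude maximum within `search_ppm` of its
#' nominal position. Deterministic; a zero noise SD yields `Inf` rather
#' than an error.
#'
#' @param fid a `fid` object (raw: not apodised, not zero-filled)
#' @param search_ppm half-width of the PCr search window (default 3 ppm)
#' @param apodize_hz Lorentzian filter applied before measuring the peak
#'   height (default 20, matching the processing chain; 0 disables)
#' @return dimensionless SNR
#' @export
estimate_snr <- function(fid, search_ppm = 3, apodize_hz = 20) {
  stopifnot(inherits(fid, "fid"), length(fid$samples) > 0)
  n <- length(fid$samples)
  tail_idx <- seq.int(floor(0.75 * n) + 1L, n)
  noise <- stats::sd(c(Re(fid$samples[tail_idx]), Im(fid$samples[tail_idx])))
  t <- (seq_len(n) - 1) * fid$acq$dwell_time
  spec <- Mod(fftshift(fft_fwd(fid$samples * exp(-pi * apodize_hz * t)))) / sqrt(n)
  ppm <- ppm_axis_nominal(fid$acq, n)
  height <- max(spec[abs(ppm) <= search_ppm])
  if (noise == 0) return(Inf)
  height / noise
}

#' Apply zero- and first-order phase to a spectrum
#'
#' Multiplies the spectrum by `exp(i (phase0 + phase1 * ppm) * pi/180)`;
#' the first-order pivot is the PCr position (0 ppm).
#'
#' @param spectrum a `p31_spectrum`
#' @param phase0 zero-order phase, degrees
#' @param phase1 first-order phase, degrees/ppm
#' @return the phased spectrum (accumulates into `phase0`/`phase1` fields)
#' @export
apply_phase <- function(spectrum, phase0, phase1 = 0) {
  stopifnot(inherits(spectrum, "p31_spectrum"))
  spectrum$values <- spectrum$values *
    exp(1i * (phase0 + phase1 * spectrum$ppm) * pi / 180)
  spectrum$phase0 <- spectrum$phase0 + phase0
  spectrum$phase1 <- spectrum$phase1 + phase1
  spectrum
}

# ACME objective: Shannon entropy of the normalised |first derivative| of
# the real part, plus a scale-free penalty on negative real intensity.
acme_objective <- function(par, values, ppm, gamma = 1000) {
  r <- Re(values * exp(1i * (par[1] + par[2] * ppm) * pi / 180))
  h <- abs(diff(r))
  s <- sum(h)
  if (s == 0) return(Inf)
  p <- h / s
  ent <- -sum(p[p > 0] * log(p[p > 0]))
  neg <- r[r < 0]
  ent + gamma * sum(neg^2) / sum(r^2)
}

#' Automatic phase correction by entropy minimisation (ACME)
#'
#' Finds the zero- and first-order phase that minimise the Shannon entropy
#' of the first derivative of the real part, with a penalty on negative
#' real intensity, via Nelder-Mead from a coarse multi-start over the
#' zero-order phase. The objective is evaluated on a first-point-corrected
#' copy of the spectrum (the DFT of a one-sided FID carries a constant
#' baseline offset of half the first time-domain sample, which would
#' otherwise mask the negative dispersion lobes the penalty relies on);
#' the returned correction is applied to the original spectrum. On
#' optimizer failure the spectrum is passed through unphased with an
#' `artefact` flag.
#'
#' @param spectrum an unphased `p31_spectrum`
#' @param gamma weight of the negativity penalty (default 1000)
#' @param n_starts number of coarse zero-order starts kept (default 3)
#' @return list with `spectrum` (phased), `phase0`, `phase1` (the applied
#'   correction, degrees and degrees/ppm) and `converged`
#' @export
autophase <- function(spectrum, gamma = 1000, n_starts = 3) {
  stopifnot(inherits(spectrum, "p31_spectrum"))
  values <- spectrum$values - mean(spectrum$values) / 2
  values <- values / max(Mod(values))
  grid0 <- seq(-180, 165, by = 15)
  obj0 <- vapply(grid0, function(p0)
    acme_objective(c(p0, 0), values, spectrum$ppm, gamma), 0)
  starts <- grid0[order(obj0)][seq_len(n_starts)]
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(c(s, 0), acme_objective, values = values,
                   ppm = spectrum$ppm, gamma = gamma,
                   method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    spectrum$flags <- union(spectrum$flags, "artefact")
    return(list(spectrum = spectrum, phase0 = NA_real_, phase1 = NA_real_,
                converged = FALSE))
  }
  # polish: a fresh simplex around the minimum escapes premature collapse
  polish <- tryCatch(
    stats::optim(best$par, acme_objective, values = values,
                 ppm = spectrum$ppm, gamma = gamma,
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-13, maxit = 2000)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value < best$value) best <- polish
  p0 <- ((best$par[1] + 180) %% 360) - 180
  out <- apply_phase(spectrum, p0, best$par[2])
  list(spectrum = out, phase0 = p0, phase1 = best$par[2],
       converged = best$convergence == 0)
}

#' Lorentzian apodisation and two-times zero-filling
#'
#' Multiplies the FID by `exp(-pi * lw * t)` (adding `lw` Hz to every
#' Lorentzian linewidth) and appends zeros to `zf * n` points, doubling
#' the digital resolution of the spectrum for the default `zf = 2`.
#'
#' @param fid a `fid` object of raw length n
#' @param lw apodisation linewidth in Hz (default 20)
#' @param zf zero-fill factor (default 2: output length `2 n`)
#' @return the apodised, zero-filled `fid`
#' @export
apodize_zerofill <- function(fid, lw = 20, zf = 2) {
  stopifnot(inherits(fid, "fid"), lw >= 0, zf >= 1)
  n <- length(fid$samples)
  t <- (seq_len(n) - 1) * fid$acq$dwell_time
  out <- fid$samples * exp(-pi * lw * t)
  fid$samples <- c(out, complex(length.out = (zf - 1) * n))
  fid
}

#' Set the PCr peak to 0 ppm
#'
#' Locates the tallest magnitude peak within `search_ppm` of the nominal
#' PCr position, refines it by three-point parabolic interpolation, and
#' translates the ppm axis so that the interpolated maximum sits at 0.
#' If no credible peak is found (window maximum at the window edge, or
#' insufficient prominence over the spectrum median), the spectrum is
#' returned unchanged with an `artefact` flag.
#'
#' @param spectrum a `p31_spectrum`
#' @param search_ppm half-width of the search window (default 3 ppm)
#' @param min_prominence required ratio of peak height to the median
#'   magnitude of the full spectrum (default 5)
#' @return the referenced spectrum
#' @export
reference_to_pcr <- function(spectrum, search_ppm = 3, min_prominence = 5) {
  stopifnot(inherits(spectrum, "p31_spectrum"))
  m <- Mod(spectrum$values)
  win <- which(abs(spectrum$ppm) <= search_ppm)
  if (!length(win)) stop("empty PCr search window")
  i <- win[which.max(m[win])]
  at_edge <- i == win[1] || i == win[length(win)]
  if (at_edge || m[i] < min_prominence * stats::median(m)) {
    spectrum$flags <- union(spectrum$flags, "artefact")
    return(spectrum)
  }
  delta <- parabolic_vertex(m[i - 1], m[i], m[i + 1])
  step <- spectrum$ppm[2] - spectrum$ppm[1]
  spectrum$ppm <- spectrum$ppm - (spectrum$ppm[i] + delta * step)
  spectrum
}

# vertex offset (in bins, within [-0.5, 0.5]) of a parabola through three
# equally spaced samples
parabolic_vertex <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (den == 0) return(0)
  max(-0.5, min(0.5, 0.5 * (ym1 - yp1) / den))
}

#' Frequency- and phase-align spectra, then average
#'
#' The highest-SNR member (ties: first index) is the reference. Each
#' spectrum is frequency-shifted by the cross-correlation maximum of the
#' magnitude spectra (sub-bin by parabolic interpolation, applied as a
#' time-domain phase ramp) and zero-order phased onto the reference; the
#' arithmetic mean of the retained members is returned. A spectrum whose
#' correlation maximum is ambiguous (a secondary maximum within
#' `ambiguity_tol` of the best, more than 2 bins away, or a maximum at
#' the search boundary) receives an `alignment_failure` flag and is
#' dropped from the mean.
#'
#' @param spectra list of `p31_spectrum` objects on identical grids
#' @param snrs optional numeric SNRs used to pick the reference; default
#'   is the magnitude maximum of each spectrum
#' @param max_shift_ppm search half-range for the frequency shift
#'   (default 1 ppm)
#' @param ambiguity_tol relative secondary-peak height that triggers an
#'   alignment failure (default 0.95)
#' @return list with `average` (a `p31_spectrum`), `shifts_ppm`,
#'   `phases`, `flags` (character vector per input), `reference` (index)
#' @export
align_and_average <- function(spectra, snrs = NULL, max_shift_ppm = 1,
                              ambiguity_tol = 0.95) {
  stopifnot(length(spectra) >= 2,
            all(vapply(spectra, inherits, TRUE, "p31_spectrum")))
  n <- length(spectra[[1]]$values)
  if (!all(vapply(spectra, function(s) length(s$values), 0L) == n))
    stop("spectra must share one grid")
  if (is.null(snrs))
    snrs <- vapply(spectra, function(s) max(Mod(s$values)), 0)
  ref_i <- which.max(snrs)            # which.max takes the first on ties
  ref <- spectra[[ref_i]]
  step <- ref$ppm[2] - ref$ppm[1]
  max_lag <- max(1L, round(max_shift_ppm / step))
  mr <- Mod(ref$values)
  shifts <- numeric(length(spectra)); phases <- numeric(length(spectra))
  flags <- rep("none", length(spectra))
  aligned <- vector("list", length(spectra))
  for (j in seq_along(spectra)) {
    s <- spectra[[j]]
    ms <- Mod(s$values)
    lags <- -max_lag:max_lag
    cc <- vapply(lags, function(l) {
      i1 <- max(1, 1 + l):min(n, n + l)
      sum(mr[i1] * ms[i1 - l])
    }, 0)
    b <- which.max(cc)
    if (b == 1 || b == length(cc)) {
      flags[j] <- "alignment_failure"; next
    }
    # rival *local* maxima well away from the best lag mark ambiguity
    interior <- 2:(length(cc) - 1)
    lm <- interior[cc[interior] > cc[interior - 1] &
                   cc[interior] >= cc[interior + 1]]
    lm <- lm[abs(lm - b) > 5]
    if (length(lm) && max(cc[lm]) > ambiguity_tol * cc[b]) {
      flags[j] <- "alignment_failure"; next
    }
    sub <- parabolic_vertex(cc[b - 1], cc[b], cc[b + 1])
    lag_bins <- lags[b] + sub          # shift (in bins) to apply to s
    # move the spectrum by lag_bins: multiply the FID by a phase ramp
    td <- fft_inv(ifftshift(s$values))
    tt <- seq_len(n) - 1
    td <- td * exp(2i * pi * lag_bins * tt / n)
    sa <- s
    sa$values <- fftshift(fft_fwd(td))
    phi <- Arg(sum(ref$values * Conj(sa$values)))
    sa$values <- sa$values * exp(1i * phi)
    shifts[j] <- lag_bins * step
    phases[j] <- phi * 180 / pi
    aligned[[j]] <- sa
  }
  keep <- which(flags == "none")
  if (!length(keep)) stop("all spectra failed alignment")
  avg <- spectra[[ref_i]]
  avg$values <- Reduce(`+`, lapply(aligned[keep], `[[`, "values")) / length(keep)
  avg$ppm <- ref$ppm
  list(average = avg, shifts_ppm = shifts, phases = phases, flags = flags,
       reference = ref_i)
}

#' Quality-control report for one spectrum
#'
#' @param snr estimated SNR
#' @param artefact,alignment_failure logical manual/automatic flags
#' @param snr_threshold exclusion threshold (default 10; spectra with
#'   SNR strictly below it are excluded)
#' @param notes free text
#' @return object of class `qc_report`
#' @export
qc_report <- function(snr, artefact = FALSE, alignment_failure = FALSE,
                      snr_threshold = 10, notes = "") {
  reason <- if (snr < snr_threshold) "low_snr"
            else if (artefact) "artefact"
            else if (alignment_failure) "alignment_failure"
            else "none"
  structure(list(snr = snr, excluded = reason != "none",
                 exclusion_reason = reason, notes = notes),
            class = "qc_report")
}

#' Filter a batch of spectra on quality control
#'
#' Retains exactly the items whose SNR is at or above the threshold
#' (strict `< threshold` exclusion, so SNR exactly at the threshold is
#' retained) and which carry no artefact or alignment flag. Idempotent.
#'
#' @param items list of entries, each a list with a `qc` field holding a
#'   [qc_report()] (extra fields, e.g. the spectrum, pass through)
#' @param snr_threshold exclusion threshold (default 10)
#' @return list with `retained` (the surviving items) and `summary`
#'   (counts by exclusion reason, including `retained` and `total`)
#' @export
qc_filter <- function(items, snr_threshold = 10) {
  stopifnot(length(items) > 0)
  reasons <- vapply(items, function(it) {
    qc <- it$qc
    stopifnot(inherits(qc, "qc_report"))
    if (qc$snr < snr_threshold) "low_snr"
    else if (qc$exclusion_reason %in% c("artefact", "alignment_failure"))
      qc$exclusion_reason
    else "none"
  }, "")
  keep <- reasons == "none"
  summary <- c(total = length(items), retained = sum(keep),
               low_snr = sum(reasons == "low_snr"),
               artefact = sum(reasons == "artefact"),
               alignment_failure = sum(reasons == "alignment_failure"))
  list(retained = items[keep], summary = summary)
}
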