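#' Acquisition parameters for a pulse-acquire 31P experiment
#'
#' Describes the sampling of a free induction decay (FID): complex points,
#' bandwidth/dwell time, the 31P reference frequency used for ppm/Hz
#' conversion, repetition time and excitation flip angle. Defaults match a
#' 7 T lower-leg 2D-CSI protocol (TR 2 s, 2048 complex points, 4 kHz
#' bandwidth, 45 degree block excitation).
#'
#' The transmitter (carrier) is placed `carrier_offset_ppm` away from
#' phosphocreatine (PCr) so that all muscle resonances, from inorganic
#' phosphate near +5 ppm down to beta-ATP near -16 ppm, fall inside the
#' sampled bandwidth.
#'
#' @param n_points number of complex points sampled (default 2048)
#' @param bandwidth spectral width in Hz (default 4000); the dwell time is
#'   `1 / bandwidth`
#' @param dwell_time seconds per complex point; give either this or
#'   `bandwidth` (they must satisfy `bandwidth * dwell_time == 1`)
#' @param reference_frequency 31P Larmor frequency in MHz (default 120.66,
#'   i.e. 7 T), used for ppm/Hz conversion
#' @param tr repetition time in seconds (default 2)
#' @param flip_angle excitation flip angle in degrees (default 45)
#' @param carrier_offset_ppm position of the carrier on the ppm axis,
#'   relative to PCr = 0 (default -6)
#' @return an object of class `acq_params`
#' @export
acq_params <- function(n_points = 2048L, bandwidth = 4000,
                       dwell_time = 1 / bandwidth,
                       reference_frequency = 120.66,
                       tr = 2.0, flip_angle = 45,
                       carrier_offset_ppm = -6) {
  n_points <- as.integer(n_points)
  stopifnot(n_points > 0L, bandwidth > 0, dwell_time > 0,
            reference_frequency > 0, tr > 0)
  if (abs(bandwidth * dwell_time - 1) > 1e-9)
    stop("bandwidth * dwell_time must equal 1")
  if (!(flip_angle > 0 && flip_angle <= 90))
    stop("flip_angle must lie in (0, 90] degrees")
  structure(
    list(n_points = n_points, bandwidth = bandwidth, dwell_time = dwell_time,
         reference_frequency = reference_frequency, tr = tr,
         flip_angle = flip_angle, carrier_offset_ppm = carrier_offset_ppm),
    class = "acq_params")
}

# time axis (seconds) of the first n samples
time_axis <- function(acq, n = acq$n_points) (seq_len(n) - 1) * acq$dwell_time

# frequency axis (Hz, relative to carrier) of a centred length-n spectrum
freq_axis_hz <- function(acq, n = acq$n_points) {
  centred_index(n) * acq$bandwidth / n
}

# nominal ppm axis (relative to PCr = 0) of a centred length-n spectrum
ppm_axis_nominal <- function(acq, n = acq$n_points) {
  acq$carrier_offset_ppm + freq_axis_hz(acq, n) / acq$reference_frequency
}

# Hz offset from carrier of a resonance at `ppm` (relative to PCr = 0)
ppm_to_hz <- function(ppm, acq) {
  (ppm - acq$carrier_offset_ppm) * acq$reference_frequency
}
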