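#' Amplitude-weighted pH of the two Pi compartments
#'
#' `ph_wt = ph_a * Pi_a/Pi_tot + ph_b * Pi_b/Pi_tot` with
#' `Pi_tot = Pi_a + Pi_b`: the convex combination of the two
#' compartmental pH values, weighted by fitted Pi amplitudes. Invariant
#' to common rescaling of the amplitudes.
#'
#' @param ph_a,ph_b pH of the two Pi peaks
#' @param amp_a,amp_b fitted amplitudes (>= 0, not both zero)
#' @return weighted pH
#' @export
weighted_ph <- function(ph_a, ph_b, amp_a, amp_b) {
  stopifnot(amp_a >= 0, amp_b >= 0)
  if (amp_a + amp_b <= 0) stop("both Pi amplitudes are zero")
  (ph_a * amp_a + ph_b * amp_b) / (amp_a + amp_b)
}

#' T1-corrected PDE / gamma-ATP ratio
#'
#' The membrane-damage marker: the fitted PDE amplitude over the fitted
#' gamma-ATP amplitude, each corrected for steady-state T1 saturation.
#'
#' @param fit a converged `amares_fit` containing PDE and gATP rows
#' @param t1s named T1 table (see [t1_table_synthetic()])
#' @param acq an [acq_params()] object
#' @return dimensionless corrected ratio
#' @export
pde_gatp_ratio <- function(fit, t1s, acq) {
  stopifnot(inherits(fit, "amares_fit"))
  if (!isTRUE(attr(fit, "converged"))) stop("fit did not converge")
  a_pde <- fit$amplitude[fit$name == "PDE"]
  a_g <- fit$amplitude[fit$name == "gATP"]
  if (!length(a_pde) || !length(a_g)) stop("fit lacks PDE or gATP")
  if (a_g <= 0) stop("zero gamma-ATP amplitude")
  correct_ratio(a_pde, a_g, t1s[["PDE"]], t1s[["gATP"]], acq)
}

#' Biomarkers from one fitted spectrum
#'
#' Turns an AMARES fit into the analysis-ready record: pH of each Pi
#' compartment from the fitted Pi-PCr shift differences (so the result
#' does not depend on the absolute calibration of the ppm axis), the
#' amplitude-weighted pH, free Mg2+ from the fitted alpha-beta ATP shift
#' difference at that weighted pH, and the T1-corrected PDE/gamma-ATP
#' ratio. Borderline fits propagate `NA` plus a flag rather than raising.
#'
#' @param fit a converged `amares_fit` over the seven muscle resonances
#' @param constants an [mg_constants()] set (mandatory)
#' @param t1s named T1 table
#' @param acq an [acq_params()] object
#' @param qc a [qc_report()]; excluded input is refused
#' @return object of class `metabolite_metrics`: a one-row data frame
#'   with `ph_a`, `ph_b`, `ph_wt`, `mg`, `pde_gatp`, `snr`, `flags`
#' @export
compute_metrics <- function(fit, constants, t1s, acq, qc) {
  stopifnot(inherits(fit, "amares_fit"), inherits(qc, "qc_report"))
  if (isTRUE(qc$excluded))
    stop(sprintf("input excluded by quality control (%s)", qc$exclusion_reason))
  if (!isTRUE(attr(fit, "converged"))) stop("fit did not converge")
  g <- function(peak, col) {
    v <- fit[[col]][fit$name == peak]
    if (!length(v)) NA_real_ else v
  }
  flags <- character(0)
  s_pcr <- g("PCr", "shift")
  sigma_a <- g("Pi_a", "shift") - s_pcr
  sigma_b <- g("Pi_b", "shift") - s_pcr
  ph_a <- tryCatch(ph_from_shift(sigma_a), error = function(e) NA_real_)
  ph_b <- tryCatch(ph_from_shift(sigma_b), error = function(e) NA_real_)
  if (is.na(ph_a) || is.na(ph_b)) flags <- c(flags, "ph_out_of_range")
  amp_a <- g("Pi_a", "amplitude"); amp_b <- g("Pi_b", "amplitude")
  ph_wt <- if (!is.na(ph_a) && !is.na(ph_b) && amp_a + amp_b > 0)
    weighted_ph(ph_a, ph_b, amp_a, amp_b) else NA_real_
  delta_ab <- g("aATP", "shift") - g("bATP", "shift")
  mg <- if (!is.na(ph_wt) && !is.na(delta_ab))
    tryCatch(mg_from_shift(delta_ab, ph_wt, constants),
             error = function(e) { flags <<- c(flags, "mg_unattainable"); NA_real_ })
  else NA_real_
  ratio <- tryCatch(pde_gatp_ratio(fit, t1s, acq),
                    error = function(e) { flags <<- c(flags, "ratio_failed"); NA_real_ })
  structure(data.frame(ph_a = ph_a, ph_b = ph_b, ph_wt = ph_wt, mg = mg,
                       pde_gatp = ratio, delta_ab = delta_ab, snr = qc$snr,
                       flags = paste(flags, collapse = ";"),
                       stringsAsFactors = FALSE),
            class = c("metabolite_metrics", "data.frame"))
}
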