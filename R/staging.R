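#' @name staging
#' @title Dixon fat-fraction muscle staging
#' @description
#' Fat-replacement staging of Becker-dystrophy muscles: fat fraction from
#' water/fat signal intensities, area-weighted 5-slice muscle means,
#' category thresholds derived from the lower uncertainty bound of a
#' sigmoidal progression fit, and the preserved / progressing / end-stage
#' partition (boundary conventions: preserved at <= lower, end-stage at
#' >= upper, progressing strictly between).
NULL

#' Fat fraction from fat and water signal intensities
#'
#' `SI_fat / (SI_fat + SI_water) * 100` percent.
#'
#' @param si_fat,si_water non-negative signal intensities (vectorised;
#'   pairwise both-zero is an error)
#' @return fat fraction in percent
#' @export
fat_fraction <- function(si_fat, si_water) {
  stopifnot(all(si_fat >= 0), all(si_water >= 0))
  tot <- si_fat + si_water
  if (any(tot == 0)) stop("fat and water signal are both zero")
  100 * si_fat / tot
}

#' Area-weighted muscle-mean fat fraction
#'
#' `sum(ff * area) / sum(area)` over the (typically five) slices of one
#' muscle region of interest.
#'
#' @param per_slice_ff fat fractions in percent
#' @param per_slice_area slice ROI areas in mm^2 (> 0), same length
#' @return percent
#' @export
muscle_mean_ff <- function(per_slice_ff, per_slice_area) {
  if (length(per_slice_ff) != length(per_slice_area))
    stop("slice fat fractions and areas differ in length")
  stopifnot(all(per_slice_area > 0))
  sum(per_slice_ff * per_slice_area) / sum(per_slice_area)
}

# 24-month increment of logistic fat replacement: a muscle at baseline
# fat fraction x on a logistic trajectory with rate r (1/month) and
# ceiling C (%) reaches C x g / (C + x (g - 1)) after dt months, g =
# exp(r dt). The predicted change is that value minus x: zero at x = 0
# and x = C, positive between.
ff_change_model <- function(x, r, C, dt = 24) {
  g <- exp(r * dt)
  C * x * g / (C + x * (g - 1)) - x
}

#' Derive staging thresholds from longitudinal fat-fraction records
#'
#' Fits the 24-month logistic-growth increment model to fat-fraction
#' change versus baseline fat fraction (least squares over rate and
#' ceiling), forms the lower bound of the fit as the curve minus a one-SE
#' prediction band (delta-method fit variance plus residual variance),
#' and returns the two points where that lower bound crosses zero — the
#' boundaries of the rapid-progression phase. With no records, the
#' authoritative default thresholds (13.5, 81.5)% are returned.
#'
#' @param records data frame with columns `ff_baseline` and
#'   `ff_change_24m` (percent), at least 20 rows spanning the range; or
#'   `NULL` for the defaults
#' @param band_z band half-width in residual SD units (default 1)
#' @return object of class `sigmoid_fit` with fields `rate`, `ceiling`,
#'   `sigma`, `vcov`, `thresholds`, `band_z`
#' @export
derive_thresholds <- function(records = NULL, band_z = 1) {
  if (is.null(records)) {
    return(structure(list(rate = NA_real_, ceiling = NA_real_,
                          sigma = NA_real_, vcov = NULL,
                          thresholds = c(13.5, 81.5), band_z = band_z),
                     class = "sigmoid_fit"))
  }
  stopifnot(is.data.frame(records),
            all(c("ff_baseline", "ff_change_24m") %in% names(records)))
  if (nrow(records) < 20)
    stop("at least 20 records spanning the fat-fraction range are required")
  x <- records$ff_baseline; y <- records$ff_change_24m
  if (stats::sd(y) == 0)
    stop("threshold derivation failed: fat-fraction change is constant (no progression phase)")
  fit <- minpack.lm::nlsLM(
    y ~ ff_change_model(x, r, C),
    start = list(r = 0.05, C = 95),
    lower = c(1e-4, 50), upper = c(1, 100),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  sigma <- summary(fit)$sigma
  lower_bound <- function(xx) {
    pred <- ff_change_model(xx, cf["r"], cf["C"])
    h <- c(1e-6, 1e-3)
    gr <- cbind(
      (ff_change_model(xx, cf["r"] + h[1], cf["C"]) - pred) / h[1],
      (ff_change_model(xx, cf["r"], cf["C"] + h[2]) - pred) / h[2])
    se_fit <- sqrt(pmax(0, rowSums((gr %*% V) * gr)))
    pred - band_z * sqrt(se_fit^2 + sigma^2)
  }
  grid <- seq(0.05, 99.95, by = 0.05)
  lb <- lower_bound(grid)
  sign_change <- which(diff(sign(lb)) != 0)
  roots <- vapply(sign_change, function(i)
    stats::uniroot(function(z) lower_bound(z), c(grid[i], grid[i + 1]),
                   tol = 1e-6)$root, 0)
  roots <- roots[roots > 0 & roots < 100]
  if (length(roots) < 2)
    stop("threshold derivation failed: the lower bound does not cross zero twice in (0, 100)")
  structure(list(rate = unname(cf["r"]), ceiling = unname(cf["C"]),
                 sigma = sigma, vcov = V,
                 thresholds = c(min(roots), max(roots)), band_z = band_z),
            class = "sigmoid_fit")
}

#' Categorise a muscle by baseline fat fraction
#'
#' Preserved (`BMD_pre`) at fat fraction <= lower threshold, progressing
#' (`BMD_prog`) strictly between the thresholds, end-stage (`BMD_end`,
#' excluded from analysis) at >= upper threshold. The default thresholds
#' are (13.5, 81.5) percent.
#'
#' @param ff_baseline fat fraction(s) in percent, within `[0, 100]`
#' @param thresholds length-2 increasing vector (default `c(13.5, 81.5)`)
#' @return character vector of categories
#' @export
categorize <- function(ff_baseline, thresholds = c(13.5, 81.5)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2],
            all(ff_baseline >= 0), all(ff_baseline <= 100))
  ifelse(ff_baseline <= thresholds[1], "BMD_pre",
         ifelse(ff_baseline >= thresholds[2], "BMD_end", "BMD_prog"))
}
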