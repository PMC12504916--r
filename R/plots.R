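#' Plot a spectrum with the ppm axis in conventional direction
#'
#' @param x a `p31_spectrum`
#' @param part `"real"` (default) or `"magnitude"`
#' @param ... passed to [graphics::plot()]
#' @export
plot.p31_spectrum <- function(x, part = c("real", "magnitude"), ...) {
  part <- match.arg(part)
  y <- if (part == "real") Re(x$values) else Mod(x$values)
  graphics::plot(x$ppm, y, type = "l", xlim = rev(range(x$ppm)),
                 xlab = "chemical shift (ppm)", ylab = part, ...)
  invisible(x)
}

#' Diagnostic overlay of a fit: data, model and residual
#'
#' Draws the real part of the spectrum, the spectrum of the fitted model
#' (reconstructed from the fitted amplitudes, shifts, linewidths and
#' phases) and the residual, offset below.
#'
#' @param spectrum the `p31_spectrum` that was fitted
#' @param fit the corresponding `amares_fit`
#' @param n_fit number of time-domain points the fit used (for the model
#'   reconstruction; default 1024)
#' @export
plot_fit <- function(spectrum, fit, n_fit = 1024) {
  stopifnot(inherits(spectrum, "p31_spectrum"), inherits(fit, "amares_fit"))
  n <- length(spectrum$values)
  td <- fft_inv(ifftshift(spectrum$values))
  t <- (seq_len(n) - 1) * spectrum$acq$dwell_time
  ppm_centre <- spectrum$ppm[floor(n / 2) + 1]
  model <- complex(length.out = n)
  for (k in seq_len(nrow(fit))) {
    f <- (fit$shift[k] - ppm_centre) * spectrum$acq$reference_frequency
    model <- model + fit$amplitude[k] *
      exp(1i * (2 * pi * f * t + fit$phase[k] * pi / 180) -
            pi * fit$linewidth[k] * t)
  }
  keep <- seq_len(min(n_fit, n))
  mask <- c(rep(1, length(keep)), numeric(n - length(keep)))
  sp_model <- fftshift(fft_fwd(model * mask))
  sp_data <- fftshift(fft_fwd(td * mask))
  resid <- Re(sp_data) - Re(sp_model)
  off <- -0.15 * max(abs(Re(sp_data)))
  graphics::plot(spectrum$ppm, Re(sp_data), type = "l",
                 xlim = rev(range(spectrum$ppm)),
                 ylim = range(c(Re(sp_data), resid + off)),
                 xlab = "chemical shift (ppm)", ylab = "intensity")
  graphics::lines(spectrum$ppm, Re(sp_model), col = "red3", lty = 2)
  graphics::lines(spectrum$ppm, resid + off, col = "grey40")
  graphics::legend("topright", c("data", "model", "residual"),
                   col = c("black", "red3", "grey40"), lty = c(1, 2, 1),
                   bty = "n")
  invisible(list(residual = resid))
}
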