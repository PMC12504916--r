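# Internal FFT layout helpers. Spectra are stored "centred": after fftshift,
# index floor(n/2)+1 carries the zero-frequency (carrier) sample, so the
# frequency of index i is (i - 1 - floor(n/2)) * bandwidth / n.

fftshift <- function(x) {
  n <- length(x)
  h <- floor(n / 2)
  x[c((h + 1):n, seq_len(h))]
}

ifftshift <- function(x) {
  n <- length(x)
  h <- ceiling(n / 2)
  x[c((h + 1):n, seq_len(h))]
}

# Centred frequency index for a length-n axis (0 at floor(n/2)+1).
centred_index <- function(n) seq_len(n) - 1L - floor(n / 2)

fft_fwd <- function(x) stats::fft(x)
fft_inv <- function(x) stats::fft(x, inverse = TRUE) / length(x)
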