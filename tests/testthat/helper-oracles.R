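# Shared oracles and fixture builders, independent of the code paths they
# check.

# direct time-domain convolution with group-delay trim: the brute-force
# reference for the overlap-add filter
direct_filter <- function(x, taps) {
  full <- stats::convolve(x, rev(taps), type = "open")
  delay <- (length(taps) - 1L) / 2L
  full[(delay + 1L):(delay + length(x))]
}

# hand-built per-segment spectra for metric arithmetic checks
make_segments <- function(sxy, sxx = NULL, syy = NULL, freqs = NULL,
                          fs = 100) {
  sxy <- as.matrix(sxy)
  n_freq <- nrow(sxy)
  n_seg <- ncol(sxy)
  if (is.null(sxx)) sxx <- matrix(Mod(sxy) + 1, n_freq, n_seg)
  if (is.null(syy)) syy <- matrix(Mod(sxy) + 1, n_freq, n_seg)
  if (is.null(freqs)) freqs <- seq_len(n_freq)
  structure(
    list(freqs = freqs, sxx = sxx, syy = syy, sxy = sxy,
         n_segments = n_seg, nperseg = 2L * (n_freq - 1L),
         noverlap = 0L, window = "hann", fs = fs),
    class = "spectral_segments"
  )
}

# von Mises sampler by rejection (uniform proposal); mean direction 0
rvonmises <- function(n, kappa) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::runif(2 * n, -pi, pi)
    u <- stats::runif(2 * n)
    out <- c(out, x[u < exp(kappa * (cos(x) - 1))])
  }
  out[seq_len(n)]
}

# DFT magnitude-peak frequency of a real signal
dft_peak_freq <- function(x, fs) {
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))[seq_len(n %/% 2 + 1L)]
  ((which.max(spec)) - 1L) * fs / n
}

expect_no_flags <- function(report) {
  expect_length(report$bad, 0L)
  expect_setequal(report$good, report$labels)
}
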