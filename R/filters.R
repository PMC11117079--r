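#' Specify a linear-phase FIR filter
#'
#' Validates the cutoff geometry for a windowed-sinc FIR design. All edges
#' must lie strictly inside (0, fs/2), and each edge extended by the
#' transition width must stay inside that interval too.
#'
#' @param kind One of `"lowpass"`, `"highpass"`, `"bandpass"`, `"bandstop"`.
#' @param edges One cutoff (low/highpass) or two increasing cutoffs
#'   (bandpass/bandstop), in Hz.
#' @param transition_width Width of the transition band in Hz; controls the
#'   tap count (see [design_fir()]).
#' @param fs Sampling rate in Hz.
#' @param mode `"precise"` (64-bit) or `"fast"` (single-precision storage).
#' @return An object of class `fir_spec`.
#' @examples
#' fir_spec("bandpass", c(8, 12), transition_width = 2, fs = 250)
#' @export
fir_spec <- function(kind = c("lowpass", "highpass", "bandpass", "bandstop"),
                     edges, transition_width, fs,
                     mode = c("precise", "fast")) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  stopifnot(is.numeric(edges), is.numeric(transition_width),
            is.numeric(fs), fs > 0, transition_width > 0)
  n_edges <- if (kind %in% c("lowpass", "highpass")) 1L else 2L
  if (length(edges) != n_edges) {
    stop(kind, " requires ", n_edges, " edge(s), got ", length(edges),
         call. = FALSE)
  }
  nyq <- fs / 2
  if (any(edges <= 0)) {
    stop("filter edge ", min(edges), " Hz violates edge > 0", call. = FALSE)
  }
  if (any(edges >= nyq)) {
    stop("filter edge ", max(edges), " Hz violates edge < fs/2 = ", nyq,
         " Hz", call. = FALSE)
  }
  if (n_edges == 2L && diff(edges) <= 0) {
    stop("bandpass/bandstop edges must be strictly increasing", call. = FALSE)
  }
  if (min(edges) - transition_width <= 0) {
    stop("edge - transition_width = ", min(edges) - transition_width,
         " Hz violates the > 0 Hz bound", call. = FALSE)
  }
  if (max(edges) + transition_width >= nyq) {
    stop("edge + transition_width = ", max(edges) + transition_width,
         " Hz violates the < fs/2 = ", nyq, " Hz bound", call. = FALSE)
  }
  structure(
    list(kind = kind, edges = edges, transition_width = transition_width,
         fs = fs, mode = mode),
    class = "fir_spec"
  )
}

#' @export
print.fir_spec <- function(x, ...) {
  cat(sprintf("<fir_spec> %s %s Hz, transition %g Hz, fs %g Hz, %s mode\n",
              x$kind, paste(x$edges, collapse = "-"),
              x$transition_width, x$fs, x$mode))
  invisible(x)
}

#' Design a Hamming-windowed sinc FIR filter
#'
#' Produces type-I (odd-length, symmetric) linear-phase taps. The tap count
#' is the smallest odd integer of at least `3.3 * fs / transition_width`,
#' the classic Hamming-window rule that places the full passband-to-stopband
#' transition inside one `transition_width`. Low-pass kernels are normalized
#' to unit DC gain; high-pass and band-stop kernels are spectral inversions,
#' band-pass the difference of two low-pass kernels (hence zero DC gain).
#'
#' @param spec A [fir_spec()].
#' @return An object of class `fir_coefficients` with elements `taps`
#'   (numeric, odd length, symmetric) and `spec`.
#' @examples
#' coef <- design_fir(fir_spec("bandpass", c(8, 12), 2, fs = 250))
#' length(coef$taps)  # odd
#' @export
design_fir <- function(spec) {
  stopifnot(inherits(spec, "fir_spec"))
  n_taps <- ceiling(3.3 * spec$fs / spec$transition_width)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  taps <- switch(
    spec$kind,
    lowpass  = windowed_sinc(spec$edges[1L], n_taps, spec$fs),
    highpass = unit_impulse(n_taps) -
      windowed_sinc(spec$edges[1L], n_taps, spec$fs),
    bandpass = windowed_sinc(spec$edges[2L], n_taps, spec$fs) -
      windowed_sinc(spec$edges[1L], n_taps, spec$fs),
    bandstop = unit_impulse(n_taps) -
      (windowed_sinc(spec$edges[2L], n_taps, spec$fs) -
         windowed_sinc(spec$edges[1L], n_taps, spec$fs))
  )
  structure(list(taps = taps, spec = spec), class = "fir_coefficients")
}

# Hamming-windowed sinc low-pass kernel, unit DC gain
windowed_sinc <- function(fc, n_taps, fs) {
  m <- (n_taps - 1L) / 2
  n <- seq_len(n_taps) - 1L - m
  h <- 2 * fc / fs * sinc(2 * fc / fs * n)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n_taps - 1L)) / (n_taps - 1L))
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

unit_impulse <- function(n_taps) {
  d <- numeric(n_taps)
  d[(n_taps + 1L) / 2L] <- 1
  d
}

#' Frequency response of FIR taps
#'
#' @param coeffs A `fir_coefficients` object (or bare tap vector).
#' @param freqs Frequencies (Hz) at which to evaluate the response.
#' @param fs Sampling rate; taken from the spec when `coeffs` carries one.
#' @return A tibble with columns `freq`, `gain` (magnitude response).
#' @export
fir_response <- function(coeffs, freqs, fs = NULL) {
  taps <- if (inherits(coeffs, "fir_coefficients")) coeffs$taps else coeffs
  if (is.null(fs)) fs <- coeffs$spec$fs
  n <- seq_along(taps) - 1L
  gain <- vapply(freqs, function(f) {
    Mod(sum(taps * exp(-2i * pi * f / fs * n)))
  }, numeric(1L))
  tibble::tibble(freq = freqs, gain = gain)
}

#' Zero-phase FIR filtering via FFT overlap-add
#'
#' Applies the taps by block-wise FFT convolution (overlap-add) and
#' compensates the linear-phase group delay of `(n_taps - 1) / 2` samples,
#' so the output is aligned with the input and has the same length. Edge
#' samples are computed against zero-padded context and are
#' transient-contaminated for `(n_taps - 1) / 2` samples at each end.
#'
#' In `"fast"` mode the input and taps are quantized once to IEEE single
#' precision (and the output again on the way out), trading roughly seven
#' significant digits for a smaller memory footprint; `"precise"` keeps
#' full double precision throughout.
#'
#' @param x Numeric vector (one channel).
#' @param coeffs A `fir_coefficients` from [design_fir()].
#' @param mode `"precise"` or `"fast"`; defaults to the spec's mode.
#' @return Numeric vector, same length as `x`.
#' @examples
#' coef <- design_fir(fir_spec("lowpass", 30, 5, fs = 250))
#' y <- apply_overlap_add(rnorm(1000), coef)
#' @export
apply_overlap_add <- function(x, coeffs, mode = NULL) {
  stopifnot(inherits(coeffs, "fir_coefficients"))
  if (length(x) < 1L) stop("input signal is empty", call. = FALSE)
  if (is.null(mode)) mode <- coeffs$spec$mode
  mode <- match.arg(mode, c("precise", "fast"))
  taps <- coeffs$taps
  if (mode == "fast") {
    x <- quantize_single(x)
    taps <- quantize_single(taps)
  }
  n <- length(x)
  n_taps <- length(taps)
  nfft <- 2^ceiling(log2(4 * n_taps))       # block policy: pow2 >= 4 * taps
  block <- nfft - n_taps + 1L
  h_fft <- stats::fft(c(taps, numeric(nfft - n_taps)))
  full <- numeric(n + n_taps - 1L)
  start <- 1L
  while (start <= n) {
    stop_ <- min(start + block - 1L, n)
    seg <- c(x[start:stop_], numeric(nfft - (stop_ - start + 1L)))
    conv <- Re(stats::fft(stats::fft(seg) * h_fft, inverse = TRUE)) / nfft
    span <- start:(start + nfft - 1L)
    keep <- span <= length(full)
    full[span[keep]] <- full[span[keep]] + conv[keep]
    start <- start + block
  }
  delay <- (n_taps - 1L) / 2L
  out <- full[(delay + 1L):(delay + n)]
  if (mode == "fast") out <- quantize_single(out)
  out
}

# round-trip through IEEE 754 binary32
quantize_single <- function(v) {
  readBin(writeBin(as.double(v), raw(), size = 4L), "double",
          n = length(v), size = 4L)
}

#' Design and apply an FIR filter in one call
#'
#' Convenience wrapper: designs the filter with [design_fir()] and applies it
#' with [apply_overlap_add()] to a vector, matrix (channels in rows) or
#' [recording()].
#'
#' @inheritParams fir_spec
#' @param x Numeric vector, channels-by-samples matrix, or `recording`.
#' @return Filtered object of the same type as `x`.
#' @export
apply_fir <- function(x, kind, edges, transition_width, fs = NULL,
                      mode = "precise") {
  if (inherits(x, "recording")) {
    fs <- x$fs
    coeffs <- design_fir(fir_spec(kind, edges, transition_width, fs, mode))
    out <- t(apply(x$data, 1L, apply_overlap_add, coeffs = coeffs))
    return(recording(out, fs = fs, labels = x$labels,
                     positions = x$positions))
  }
  if (is.null(fs)) stop("`fs` is required for vector/matrix input",
                        call. = FALSE)
  coeffs <- design_fir(fir_spec(kind, edges, transition_width, fs, mode))
  if (is.matrix(x)) {
    return(t(apply(x, 1L, apply_overlap_add, coeffs = coeffs)))
  }
  apply_overlap_add(x, coeffs)
}

#' Zero-phase Butterworth (IIR) filtering
#'
#' Wraps a Butterworth design applied forward and backward
#' (`signal::filtfilt`), giving zero phase distortion and twice the nominal
#' order's attenuation. The design is checked for stability (all poles
#' strictly inside the unit circle) before use.
#'
#' @param x Numeric vector.
#' @param kind `"lowpass"`, `"highpass"`, `"bandpass"` or `"bandstop"`.
#' @param edges Cutoff(s) in Hz, inside (0, fs/2).
#' @param order Filter order, >= 1 (effective attenuation is doubled by the
#'   forward-backward pass).
#' @param fs Sampling rate in Hz.
#' @return Filtered numeric vector, same length as `x`.
#' @export
apply_iir <- function(x, kind = c("lowpass", "highpass", "bandpass",
                                  "bandstop"),
                      edges, order, fs) {
  kind <- match.arg(kind)
  stopifnot(order >= 1, all(edges > 0), all(edges < fs / 2))
  type <- switch(kind, lowpass = "low", highpass = "high",
                 bandpass = "pass", bandstop = "stop")
  bf <- signal::butter(order, edges / (fs / 2), type = type)
  poles <- polyroot(rev(bf$a))
  if (any(Mod(poles) >= 1)) {
    stop("unstable IIR design: pole magnitude ",
         format(max(Mod(poles))), " >= 1; reduce the order", call. = FALSE)
  }
  as.numeric(signal::filtfilt(bf, x))
}
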