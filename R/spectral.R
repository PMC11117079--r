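#' Segmented cross- and auto-spectra
#'
#' Splits two equal-length signals into overlapping tapered segments and
#' returns per-segment one-sided auto-spectra and complex cross-spectra
#' (Welch-style, density scaling). These per-segment products are the shared
#' precursor of every same-frequency coupling metric in the package; in
#' particular the weighted phase lag index must average over segments
#' *before* normalizing, so the segment dimension is kept.
#'
#' The cross-spectrum convention is `S_xy(f) = X(f) * Conj(Y(f))`: a
#' positive phase of `S_xy` means `x` leads `y`. The directionality
#' contracts of [psi()] and [dac()] are defined against this convention.
#'
#' No detrending is applied, so a DC offset shows up in the 0 Hz bin.
#'
#' @param x,y Equal-length numeric vectors.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length in samples (default: `fs`, i.e. 1-s
#'   windows).
#' @param noverlap Overlap between consecutive segments in samples
#'   (default: 50%).
#' @param window Taper; only `"hann"` is provided.
#' @return An object of class `spectral_segments` with elements `freqs`,
#'   `sxx`, `syy` (frequency-by-segment real matrices), `sxy` (complex
#'   matrix), `n_segments`, `nperseg`, `noverlap`, `window`, `fs`.
#' @examples
#' t <- (0:4999) / 250
#' seg <- cross_spectra(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t), fs = 250)
#' seg
#' @export
cross_spectra <- function(x, y, fs, nperseg = fs, noverlap = nperseg %/% 2,
                          window = "hann") {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  nperseg <- as.integer(nperseg)
  noverlap <- as.integer(noverlap)
  if (length(x) < nperseg) {
    stop("signal shorter than one segment (", nperseg, " samples)",
         call. = FALSE)
  }
  if (noverlap >= nperseg) {
    stop("`noverlap` must be smaller than `nperseg`", call. = FALSE)
  }
  window <- match.arg(window, "hann")
  step <- nperseg - noverlap
  n_seg <- 1L + (length(x) - nperseg) %/% step
  w <- hann_window(nperseg)
  scale <- 1 / (fs * sum(w^2))            # density scaling
  n_freq <- nperseg %/% 2L + 1L
  freqs <- (seq_len(n_freq) - 1L) * fs / nperseg
  # one-sided doubling for all bins except DC (and Nyquist when present)
  dbl <- rep(2, n_freq)
  dbl[1L] <- 1
  if (nperseg %% 2L == 0L) dbl[n_freq] <- 1
  sxx <- matrix(0, n_freq, n_seg)
  syy <- matrix(0, n_freq, n_seg)
  sxy <- matrix(0i, n_freq, n_seg)
  for (s in seq_len(n_seg)) {
    i0 <- (s - 1L) * step
    xf <- stats::fft(x[(i0 + 1L):(i0 + nperseg)] * w)[seq_len(n_freq)]
    yf <- stats::fft(y[(i0 + 1L):(i0 + nperseg)] * w)[seq_len(n_freq)]
    sxx[, s] <- dbl * scale * Mod(xf)^2
    syy[, s] <- dbl * scale * Mod(yf)^2
    # form the complex product first: for y == x its imaginary part is
    # exactly zero, and real scaling afterwards must preserve that
    sxy[, s] <- (dbl * scale) * (xf * Conj(yf))
  }
  structure(
    list(freqs = freqs, sxx = sxx, syy = syy, sxy = sxy,
         n_segments = n_seg, nperseg = nperseg, noverlap = noverlap,
         window = window, fs = fs),
    class = "spectral_segments"
  )
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / n)

#' @export
print.spectral_segments <- function(x, ...) {
  cat(sprintf(
    "<spectral_segments> %d segments of %d samples (%s, %d overlap), %d frequency bins 0-%g Hz\n",
    x$n_segments, x$nperseg, x$window, x$noverlap,
    length(x$freqs), max(x$freqs)))
  invisible(x)
}

#' @export
tidy.spectral_segments <- function(x, ...) {
  tibble::tibble(
    freq = x$freqs,
    sxx = rowMeans(x$sxx),
    syy = rowMeans(x$syy),
    sxy_re = rowMeans(Re(x$sxy)),
    sxy_im = rowMeans(Im(x$sxy))
  )
}

#' Complex coherency from segmented spectra
#'
#' Computes the segment-averaged complex coherency
#' \deqn{C(f) = \frac{\langle S_{xy}(f)\rangle}
#'                   {\sqrt{\langle S_{xx}(f)\rangle\,\langle S_{yy}(f)\rangle}},}
#' whose magnitude measures linear coupling strength and whose argument is
#' the phase lag between the signals at frequency `f`. With segment
#' averaging, `|C| <= 1`. Frequencies with zero power in either signal get
#' `C = 0` with a warning.
#'
#' @param seg A `spectral_segments` object from [cross_spectra()], or two
#'   signals via `complex_coherency(x, y, fs = ...)`.
#' @param ... Passed to [cross_spectra()] when raw signals are given.
#' @return An object of class `coherency_spectrum`: `freqs`, `coh`
#'   (complex), `n_segments`, and the generating `segments` (kept for
#'   jackknife-based normalization in [psi()]).
#' @examples
#' x <- rnorm(2500)
#' C <- complex_coherency(cross_spectra(x, x, fs = 250))
#' max(Mod(C$coh))  # 1: identical signals
#' @export
complex_coherency <- function(seg, ...) {
  if (!inherits(seg, "spectral_segments")) {
    seg <- cross_spectra(seg, ...)
  }
  sxx_m <- rowMeans(seg$sxx)
  syy_m <- rowMeans(seg$syy)
  denom <- sqrt(sxx_m * syy_m)
  coh <- rep(0 + 0i, length(denom))
  ok <- denom > 0
  if (!all(ok)) {
    warning(sum(!ok), " frequency bin(s) with zero power; coherency set to 0",
            call. = FALSE)
  }
  coh[ok] <- rowMeans(seg$sxy)[ok] / denom[ok]
  new_coherency_spectrum(seg$freqs, coh, seg$n_segments, segments = seg)
}

#' Construct a coherency spectrum from raw values
#'
#' Useful for analytic checks and for re-entering the analysis from an
#' exported coherency table (see [write_coherency()]).
#'
#' @param freqs Increasing frequency grid (Hz).
#' @param coh Complex coherency values, `|coh| <= 1`.
#' @param n_segments Number of segments behind the estimate.
#' @param segments Optional originating `spectral_segments` (required for
#'   the jackknife normalization of [psi()]).
#' @return A `coherency_spectrum`.
#' @export
new_coherency_spectrum <- function(freqs, coh, n_segments = 1L,
                                   segments = NULL) {
  stopifnot(length(freqs) == length(coh), !is.unsorted(freqs))
  if (any(Mod(coh) > 1 + 1e-9)) {
    stop("|coherency| exceeds 1; not a valid averaged-segment estimate",
         call. = FALSE)
  }
  structure(
    list(freqs = freqs, coh = as.complex(coh),
         n_segments = as.integer(n_segments), segments = segments),
    class = "coherency_spectrum"
  )
}

#' @export
print.coherency_spectrum <- function(x, ...) {
  cat(sprintf(
    "<coherency_spectrum> %d frequency bins 0-%g Hz, %d segments, max |C| = %.3f\n",
    length(x$freqs), max(x$freqs), x$n_segments, max(Mod(x$coh))))
  invisible(x)
}

#' @export
tidy.coherency_spectrum <- function(x, ...) {
  tibble::tibble(
    freq = x$freqs,
    coherency_re = Re(x$coh),
    coherency_im = Im(x$coh),
    magnitude = Mod(x$coh),
    phase = Arg(x$coh)
  )
}

#' @export
glance.coherency_spectrum <- function(x, ...) {
  tibble::tibble(
    n_freqs = length(x$freqs), n_segments = x$n_segments,
    max_magnitude = max(Mod(x$coh)),
    has_segments = !is.null(x$segments)
  )
}

#' @export
#' @rdname new_coherency_spectrum
#' @param C A `coherency_spectrum`.
#' @param path CSV output path (columns freq, real, imag, n_segments).
write_coherency <- function(C, path) {
  stopifnot(inherits(C, "coherency_spectrum"))
  utils::write.csv(
    data.frame(freq = C$freqs, real = Re(C$coh), imag = Im(C$coh),
               n_segments = C$n_segments),
    path, row.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname new_coherency_spectrum
read_coherency <- function(path) {
  df <- utils::read.csv(path)
  new_coherency_spectrum(df$freq, complex(real = df$real,
                                          imaginary = df$imag),
                         n_segments = df$n_segments[1L])
}

#' Plot a coherency spectrum
#'
#' @param object A `coherency_spectrum`.
#' @param ... Unused.
#' @return A ggplot: coherency magnitude and phase against frequency.
#' @export
autoplot.coherency_spectrum <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df[, c("freq", "magnitude", "phase")],
                              c("magnitude", "phase"),
                              names_to = "component")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$freq, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "Frequency (Hz)", y = NULL,
                  title = "Complex coherency") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
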