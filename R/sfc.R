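#' Magnitude squared coherence
#'
#' `MSC(f) = |C(f)|^2`, the squared modulus of the complex coherency:
#' undirected linear coupling strength per frequency, bounded to \[0, 1\].
#' MSC cannot distinguish genuine interaction from volume conduction.
#'
#' @param C A `coherency_spectrum` (see [complex_coherency()]).
#' @return A tibble with columns `freq`, `metric` (`"msc"`), `value`.
#' @export
msc <- function(C) {
  stopifnot(inherits(C, "coherency_spectrum"))
  tibble::tibble(freq = C$freqs, metric = "msc", value = Mod(C$coh)^2)
}

#' Imaginary coherence
#'
#' `Im C(f)`: the imaginary part of the complex coherency, bounded to
#' \[-1, 1\]. Zero-lag (volume-conducted) coupling is purely real and does
#' not contribute, which makes this metric robust against a common source
#' seen by both sensors.
#'
#' @inheritParams msc
#' @return A tibble with columns `freq`, `metric` (`"imcoh"`), `value`.
#' @export
imaginary_coherence <- function(C) {
  stopifnot(inherits(C, "coherency_spectrum"))
  tibble::tibble(freq = C$freqs, metric = "imcoh", value = Im(C$coh))
}

#' Weighted phase lag index
#'
#' \deqn{wPLI(f) = \frac{\langle \mathrm{Im}\,S_{xy}(f)\rangle}
#'                      {\langle |\mathrm{Im}\,S_{xy}(f)|\rangle},}
#' where the averages run over segments. Consistent non-zero phase lags
#' drive the value toward ±1; lags near 0°/180° (the volume-conduction
#' regime) drive it toward 0. When every segment's imaginary cross-spectrum
#' is zero the ratio is 0/0 and the value is defined as 0, consistent with
#' the zero-lag limit.
#'
#' @param seg A `spectral_segments` object with at least 2 segments.
#' @return A tibble with columns `freq`, `metric` (`"wpli"`), `value` in
#'   \[-1, 1\].
#' @export
wpli <- function(seg) {
  stopifnot(inherits(seg, "spectral_segments"))
  if (seg$n_segments < 2L) {
    stop("wPLI needs at least 2 segments", call. = FALSE)
  }
  im <- Im(seg$sxy)
  num <- rowMeans(im)
  den <- rowMeans(abs(im))
  # imaginary mass at the floating-point noise floor (e.g. the Nyquist bin
  # of a real signal) is the 0/180-degree case, not evidence of lag
  tol <- 1e-12 * rowMeans(Mod(seg$sxy))
  val <- ifelse(den <= tol, 0, num / den)
  tibble::tibble(freq = seg$freqs, metric = "wpli", value = val)
}

#' Phase slope index
#'
#' Measures which signal temporally leads via the slope of the coherency
#' phase across a frequency band:
#' \deqn{\tilde\psi = \mathrm{Im}\sum_{f \in B} C^*(f)\, C(f + \delta f),}
#' normalized by its standard deviation estimated with a
#' leave-one-segment-out jackknife. A positive value means the first signal
#' precedes (drives) the second under this package's `X * Conj(Y)`
#' cross-spectrum convention.
#'
#' The normalized value is reported unclipped: a standardized slope is a
#' z-like quantity and is not intrinsically confined to \[-1, 1\].
#'
#' @param C A `coherency_spectrum` carrying its originating segments
#'   (required for the jackknife; see [complex_coherency()]).
#' @param band Two-element numeric `(low, high)` in Hz; must contain at
#'   least 3 frequency bins.
#' @param df Frequency step in Hz; defaults to one bin.
#' @param normalize If `FALSE`, return the raw (unnormalized) slope; this is
#'   the only form available when `C` has no attached segments.
#' @return A one-row tibble: `metric`, `value`, `raw`, `sd`, `band_lo`,
#'   `band_hi`, `n_segments`.
#' @export
psi <- function(C, band, df = NULL, normalize = TRUE) {
  stopifnot(inherits(C, "coherency_spectrum"), length(band) == 2L)
  step_hz <- if (is.null(df)) diff(C$freqs[1:2]) else df
  step <- as.integer(round(step_hz / diff(C$freqs[1:2])))
  if (step < 1L) stop("`df` must be at least one frequency bin",
                      call. = FALSE)
  idx <- which(C$freqs >= band[1L] & C$freqs <= band[2L])
  if (length(idx) < 3L) {
    stop("band [", band[1L], ", ", band[2L], "] Hz contains fewer than 3 ",
         "frequency bins", call. = FALSE)
  }
  idx <- idx[idx + step <= length(C$freqs)]
  raw <- psi_raw(C$coh, idx, step)
  if (!normalize) {
    return(tibble::tibble(metric = "psi", value = raw, raw = raw,
                          sd = NA_real_, band_lo = band[1L],
                          band_hi = band[2L], n_segments = C$n_segments))
  }
  seg <- C$segments
  if (is.null(seg)) {
    stop("normalized PSI needs the originating segments; compute the ",
         "coherency with complex_coherency() or pass normalize = FALSE",
         call. = FALSE)
  }
  n <- seg$n_segments
  if (n < 4L) stop("jackknife normalization needs at least 4 segments",
                   call. = FALSE)
  sxy_s <- rowSums(seg$sxy)
  sxx_s <- rowSums(seg$sxx)
  syy_s <- rowSums(seg$syy)
  loo <- vapply(seq_len(n), function(i) {
    num <- (sxy_s - seg$sxy[, i]) / (n - 1L)
    den <- sqrt((sxx_s - seg$sxx[, i]) * (syy_s - seg$syy[, i])) / (n - 1L)
    coh_i <- ifelse(den > 0, num / den, 0 + 0i)
    psi_raw(coh_i, idx, step)
  }, numeric(1L))
  sd_jack <- sqrt((n - 1L) / n * sum((loo - mean(loo))^2))
  val <- if (sd_jack > 0) raw / sd_jack else 0
  tibble::tibble(metric = "psi", value = val, raw = raw, sd = sd_jack,
                 band_lo = band[1L], band_hi = band[2L], n_segments = n)
}

psi_raw <- function(coh, idx, step) {
  Im(sum(Conj(coh[idx]) * coh[idx + step]))
}

#' Directional absolute coherency
#'
#' Combines three coherency-derived quantities into one signed, bounded
#' score: the band-mean coherency magnitude gives the strength, the sign of
#' the phase slope (PSI) gives the direction, and the imaginary coherence
#' provides a volume-conduction check. The value is
#' `sign(raw PSI) * mean(|C(f)|)` over the band, hence in \[-1, 1\];
#' positive means the first signal drives the second. When the band-mean
#' `|C|` is high (>= `vc_coh`) while the band-mean `|Im C|` is low
#' (<= `vc_imcoh`) — strong coupling at near-zero lag — the score is
#' flagged as likely volume conduction, but never silently zeroed.
#'
#' @param x,y Equal-length numeric signals.
#' @param fs Sampling rate (Hz).
#' @param band Two-element frequency band (Hz) inside (0, fs/2).
#' @param vc_coh,vc_imcoh Volume-conduction flag thresholds on band-mean
#'   `|C|` and `|Im C|` (defaults 0.5 and 0.05).
#' @param ... Spectral estimation parameters passed to [cross_spectra()].
#' @return A one-row tibble: `metric`, `value`, `band_lo`, `band_hi`,
#'   `volume_conduction`, plus the constituent band means `mean_coh`,
#'   `mean_imcoh`, `mean_msc` and the normalized `psi`.
#' @export
dac <- function(x, y, fs, band, vc_coh = 0.5, vc_imcoh = 0.05, ...) {
  stopifnot(length(band) == 2L, band[1L] > 0, band[2L] < fs / 2)
  C <- complex_coherency(cross_spectra(x, y, fs, ...))
  idx <- which(C$freqs >= band[1L] & C$freqs <= band[2L])
  if (length(idx) < 3L) stop("band too narrow for the spectral resolution",
                             call. = FALSE)
  p <- psi(C, band)
  mean_coh <- mean(Mod(C$coh[idx]))
  mean_imcoh <- mean(abs(Im(C$coh[idx])))
  vc <- mean_coh >= vc_coh && mean_imcoh <= vc_imcoh
  sgn <- sign(p$raw)
  tibble::tibble(
    metric = "dac",
    value = sgn * mean_coh,
    band_lo = band[1L], band_hi = band[2L],
    volume_conduction = vc,
    mean_coh = mean_coh,
    mean_imcoh = mean_imcoh,
    mean_msc = mean(Mod(C$coh[idx])^2),
    psi = p$value
  )
}

#' Compute a same-frequency coupling metric by name
#'
#' Dispatcher used by the command-line interface; accepts time-domain
#' signals and routes to the individual metric functions.
#'
#' @param x,y Equal-length numeric signals.
#' @param fs Sampling rate (Hz).
#' @param metric One of `"msc"`, `"imcoh"`, `"wpli"`, `"psi"`, `"dac"`.
#' @param band Frequency band (Hz); required for `"psi"` and `"dac"`.
#' @param ... Spectral parameters passed to [cross_spectra()].
#' @return The metric's tibble.
#' @export
sfc_metric <- function(x, y, fs, metric = c("msc", "imcoh", "wpli", "psi",
                                            "dac"),
                       band = NULL, ...) {
  metric <- match.arg(metric)
  if (metric %in% c("psi", "dac") && is.null(band)) {
    stop("`band` is required for ", metric, call. = FALSE)
  }
  if (metric == "dac") return(dac(x, y, fs, band, ...))
  seg <- cross_spectra(x, y, fs, ...)
  switch(metric,
         msc = msc(complex_coherency(seg)),
         imcoh = imaginary_coherence(complex_coherency(seg)),
         wpli = wpli(seg),
         psi = psi(complex_coherency(seg), band))
}
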