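#' Instantaneous phase and amplitude via the analytic signal
#'
#' Builds the analytic signal by the FFT method (zeroing negative
#' frequencies) and returns the instantaneous phase and amplitude envelope.
#' The input must already be band-limited to the band of interest — the
#' cross-frequency metrics never filter internally; compose with
#' [apply_fir()] first.
#'
#' @param x Numeric vector, band-limited, non-constant.
#' @return A tibble with columns `phase` (radians, in (-pi, pi\]) and
#'   `amplitude` (>= 0).
#' @examples
#' t <- (0:999) / 250
#' pa <- analytic_phase_amp(cos(2 * pi * 10 * t))
#' range(pa$amplitude[100:900])  # ~1
#' @export
analytic_phase_amp <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  if (stats::sd(x) == 0) {
    stop("constant signal: amplitude is zero and phase undefined",
         call. = FALSE)
  }
  z <- analytic_signal(x)
  tibble::tibble(phase = Arg(z), amplitude = Mod(z))
}

analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Phase-amplitude histogram
#'
#' Bins the low-frequency phase into `n_bins` equal-width bins over
#' (-pi, pi\] and averages the high-frequency amplitude within each bin.
#' This histogram is the shared precursor of the modulation index and the
#' direct modulation index. Empty bins get a mean of 0 and raise a warning.
#'
#' @param phase Phases in radians (any values are wrapped to (-pi, pi\]).
#' @param amplitude Amplitude envelope, same length as `phase`.
#' @param n_bins Number of phase bins (default 18, i.e. 20 degrees).
#' @return An object of class `phase_amp_histogram` with fields `n_bins`,
#'   `bin_edges`, `bin_center`, `mean_amp`, `counts`.
#' @export
phase_amp_histogram <- function(phase, amplitude, n_bins = 18L) {
  if (n_bins < 2L) stop("`n_bins` must be at least 2", call. = FALSE)
  if (length(phase) != length(amplitude)) {
    stop("`phase` and `amplitude` must have equal length", call. = FALSE)
  }
  if (length(phase) < n_bins) {
    stop("need at least `n_bins` samples", call. = FALSE)
  }
  ph <- wrap_phase(phase)
  width <- 2 * pi / n_bins
  # bins are left-open/right-closed; -pi maps into the first bin
  bin <- pmin(pmax(ceiling((ph + pi) / width), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  sums <- vapply(seq_len(n_bins),
                 function(b) sum(amplitude[bin == b]), numeric(1L))
  mean_amp <- ifelse(counts > 0L, sums / pmax(counts, 1L), 0)
  if (any(counts == 0L)) {
    warning(sum(counts == 0L), " empty phase bin(s); mean amplitude set to 0",
            call. = FALSE)
  }
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  structure(
    list(n_bins = as.integer(n_bins), bin_edges = edges,
         bin_center = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
         mean_amp = mean_amp, counts = counts),
    class = "phase_amp_histogram"
  )
}

wrap_phase <- function(phase) {
  ph <- (phase + pi) %% (2 * pi) - pi
  ph[ph == -pi] <- pi
  ph
}

#' @export
print.phase_amp_histogram <- function(x, ...) {
  cat(sprintf(
    "<phase_amp_histogram> %d bins, %d samples, mean amplitude %.3g\n",
    x$n_bins, sum(x$counts), mean(x$mean_amp)))
  invisible(x)
}

#' @export
tidy.phase_amp_histogram <- function(x, ...) {
  tibble::tibble(bin_center = x$bin_center, mean_amp = x$mean_amp,
                 count = x$counts)
}

#' @rdname tidy.phase_amp_histogram
#' @param object,x A `phase_amp_histogram`.
#' @param ... Unused.
#' @export
autoplot.phase_amp_histogram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center, y = .data$mean_amp)) +
    ggplot2::geom_col(width = 2 * pi / object$n_bins, fill = "steelblue") +
    ggplot2::labs(x = "Phase (rad)", y = "Mean amplitude",
                  title = "Phase-amplitude histogram") +
    ggplot2::theme_minimal()
}

as_histogram_means <- function(h) {
  if (inherits(h, "phase_amp_histogram")) return(h)
  stopifnot(is.numeric(h), length(h) >= 2L)
  edges <- seq(-pi, pi, length.out = length(h) + 1L)
  structure(
    list(n_bins = length(h), bin_edges = edges,
         bin_center = (edges[-1L] + edges[-(length(h) + 1L)]) / 2,
         mean_amp = as.numeric(h), counts = rep(1L, length(h))),
    class = "phase_amp_histogram"
  )
}

#' Modulation index
#'
#' Entropy-deficit PAC score of the phase-amplitude histogram: normalize
#' the bin means to a probability vector `P`, compute the Shannon entropy
#' `H = -sum(P log P)` (natural log, `0 log 0 := 0`), and report
#' `MI = (log N - H) / log N`. A flat histogram (no coupling) gives 0; all
#' amplitude concentrated at one phase gives 1.
#'
#' @param h A `phase_amp_histogram`, or a bare numeric vector of bin means.
#' @return A one-row tibble: `metric` (`"mi"`), `value` in \[0, 1\],
#'   `n_bins`.
#' @export
modulation_index <- function(h) {
  h <- as_histogram_means(h)
  tot <- sum(h$mean_amp)
  if (tot <= 0) stop("all-zero phase-amplitude histogram", call. = FALSE)
  p <- h$mean_amp / tot
  p <- p[p > 0]
  entropy <- -sum(p * log(p))
  tibble::tibble(metric = "mi",
                 value = (log(h$n_bins) - entropy) / log(h$n_bins),
                 n_bins = h$n_bins)
}

#' Direct modulation index
#'
#' A statically bounded PAC score based on a sinusoidal fit: the
#' phase-amplitude histogram is normalized by its mean level and a sinusoid
#' `A sin(phi + phi0) + c` is fitted over the bin centers by least squares
#' (the fit is linear in `A cos(phi0)`, `A sin(phi0)` and `c`, so `A >= 0`
#' automatically). The score is
#' `DMI = clip(A * max(0, 1 - RMSE / 0.5), 0, 1)`.
#'
#' Normalizing by the mean — rather than the histogram's own min-max range —
#' keeps the score sensitive to modulation *depth*: a full-depth sinusoidal
#' histogram (envelope touching zero at the opposite phase, i.e.
#' `m(phi) = c (1 + sin(phi + phi0))`) has `A / c = 1` and scores 1, a flat
#' histogram scores 0, and shallow sinusoidal modulation scores in between
#' instead of being rescaled to full swing. Non-sinusoidal shapes are
#' penalized through the residual RMSE (normalized by 0.5, the half-swing of
#' a full-depth histogram).
#'
#' @param h A `phase_amp_histogram` with at least 4 non-empty bins, or a
#'   bare numeric vector of bin means.
#' @return A one-row tibble: `metric` (`"dmi"`), `value` in \[0, 1\],
#'   `n_bins`, `amplitude` (fitted `A` relative to the mean level),
#'   `nrmse`.
#' @export
direct_modulation_index <- function(h) {
  h <- as_histogram_means(h)
  if (sum(h$counts) <= 0) stop("empty histogram", call. = FALSE)
  if (sum(h$counts > 0L) < 4L) {
    stop("need at least 4 non-empty phase bins for the sinusoidal fit",
         call. = FALSE)
  }
  lvl <- mean(h$mean_amp)
  if (lvl <= 0) stop("all-zero histogram", call. = FALSE)
  m <- h$mean_amp / lvl
  X <- cbind(sin(h$bin_center), cos(h$bin_center), 1)
  beta <- stats::lm.fit(X, m)$coefficients
  amp <- sqrt(beta[1L]^2 + beta[2L]^2)
  rmse <- sqrt(mean((m - X %*% beta)^2))
  nrmse <- rmse / 0.5
  val <- min(max(amp * max(0, 1 - nrmse), 0), 1)
  tibble::tibble(metric = "dmi", value = val, n_bins = h$n_bins,
                 amplitude = unname(amp), nrmse = nrmse)
}

#' Phase-locking value for phase-amplitude coupling
#'
#' Compares the low-frequency phase with the phase of the high-frequency
#' amplitude envelope:
#' `PLV = |mean(exp(i (phi_low - phi_amp)))|`, where `phi_amp` is the
#' analytic phase of the mean-centred envelope (the envelope's DC level
#' carries no phase information and would otherwise dominate the analytic
#' signal). A constant envelope has no defined phase and errors.
#'
#' @param phase_low Low-band instantaneous phase (radians).
#' @param amp_high High-band amplitude envelope, same length.
#' @return A one-row tibble: `metric` (`"plv"`), `value` in \[0, 1\].
#' @export
pac_plv <- function(phase_low, amp_high) {
  if (length(phase_low) != length(amp_high)) {
    stop("`phase_low` and `amp_high` must have equal length", call. = FALSE)
  }
  if (stats::sd(amp_high) == 0) {
    stop("constant amplitude envelope: its phase is undefined",
         call. = FALSE)
  }
  phi_amp <- Arg(analytic_signal(amp_high - mean(amp_high)))
  val <- Mod(mean(exp(1i * (phase_low - phi_amp))))
  tibble::tibble(metric = "plv", value = val)
}

#' Mean vector length
#'
#' `MVL = |mean(amplitude * exp(i * phase))|`: the magnitude of the
#' amplitude-weighted mean phase vector. Large when the amplitude peaks at
#' a preferred phase; scales linearly with amplitude gain and is therefore
#' not bounded to a fixed interval.
#'
#' @param phase Instantaneous phase (radians).
#' @param amplitude Amplitude envelope, same length.
#' @return A one-row tibble: `metric` (`"mvl"`), `value` >= 0.
#' @export
mean_vector_length <- function(phase, amplitude) {
  if (length(phase) == 0L) stop("empty input", call. = FALSE)
  if (length(phase) != length(amplitude)) {
    stop("`phase` and `amplitude` must have equal length", call. = FALSE)
  }
  tibble::tibble(metric = "mvl",
                 value = Mod(mean(amplitude * exp(1i * phase))))
}

#' Compute a phase-amplitude coupling metric by name
#'
#' Dispatcher over pre-filtered band signals: extracts phase from the
#' low-band signal and amplitude from the high-band signal, then routes to
#' the requested metric.
#'
#' @param low Low-band (phase-providing) signal, already band-pass
#'   filtered.
#' @param high High-band (amplitude-providing) signal, already band-pass
#'   filtered.
#' @param metric One of `"mi"`, `"dmi"`, `"plv"`, `"mvl"`.
#' @param n_bins Phase bins for the histogram-based metrics.
#' @return The metric's one-row tibble.
#' @export
cfc_metric <- function(low, high, metric = c("mi", "dmi", "plv", "mvl"),
                       n_bins = 18L) {
  metric <- match.arg(metric)
  phase <- analytic_phase_amp(low)$phase
  amp <- analytic_phase_amp(high)$amplitude
  switch(metric,
         mi = modulation_index(phase_amp_histogram(phase, amp, n_bins)),
         dmi = direct_modulation_index(
           phase_amp_histogram(phase, amp, n_bins)),
         plv = pac_plv(phase, amp),
         mvl = mean_vector_length(phase, amp))
}
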