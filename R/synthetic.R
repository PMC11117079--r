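#' Generate a coupled signal pair with known ground truth
#'
#' Produces two signals sharing a common band-limited source, with a
#' controlled temporal delay and/or per-frequency phase lag between them
#' and independent Gaussian observation noise. All connectivity oracles in
#' the package are computable from the returned ground truth.
#'
#' Two source flavors are available:
#' * `freq` (default): a sinusoidal source at `freq` Hz; `phase_lag`
#'   shifts `y`'s oscillation phase (radians, positive = `y` lags).
#' * `band`: broadband white noise band-pass filtered into `band`;
#'   `delay` shifts `y` backwards in time by whole samples (positive =
#'   `x` leads `y`), without wrap-around.
#'
#' `snr` is the ratio of source variance to added noise variance
#' (linear; `Inf` for noise-free).
#'
#' @param fs Sampling rate (Hz). Default 250, typical for EEG/LFP work.
#' @param duration Length in seconds (default 60).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param freq Source frequency (Hz) for the sinusoidal flavor.
#' @param band Two-element band (Hz) for the broadband flavor; overrides
#'   `freq` when given.
#' @param delay Temporal delay of `y` behind `x`, in seconds.
#' @param phase_lag Phase lag of `y` behind `x` in radians (sinusoidal
#'   flavor).
#' @param snr Linear signal-to-noise ratio (default 10).
#' @return A list: `x`, `y`, `fs`, and `truth` (delay in s and samples,
#'   phase lag, snr, source description).
#' @export
gen_coupled_pair <- function(fs = 250, duration = 60, seed = 1,
                             freq = 10, band = NULL, delay = 0,
                             phase_lag = 0, snr = 10) {
  stopifnot(fs > 0, duration > 0, snr > 0)
  if (delay >= duration) stop("`delay` must be below `duration`",
                              call. = FALSE)
  set.seed(seed)
  n <- round(fs * duration)
  delay_smp <- round(delay * fs)
  t <- (seq_len(n) - 1L) / fs
  if (is.null(band)) {
    stopifnot(freq < fs / 2)
    phi0 <- stats::runif(1L, -pi, pi)
    src_x <- sin(2 * pi * freq * t + phi0)
    src_y <- sin(2 * pi * freq * (t - delay) + phi0 - phase_lag)
    source_desc <- list(type = "sine", freq = freq)
  } else {
    stopifnot(length(band) == 2L, band[2L] < fs / 2)
    trans <- max(1, 0.2 * diff(band))
    raw <- stats::rnorm(n + delay_smp)
    filt <- apply_fir(raw, "bandpass", band, trans, fs = fs)
    src_x <- filt[(delay_smp + 1L):(delay_smp + n)]
    src_y <- filt[seq_len(n)]              # y = x delayed by delay_smp
    source_desc <- list(type = "filtered_noise", band = band)
  }
  sd_noise <- if (is.finite(snr)) sqrt(stats::var(src_x) / snr) else 0
  x <- src_x + stats::rnorm(n, sd = sd_noise)
  y <- src_y + stats::rnorm(n, sd = sd_noise)
  list(x = x, y = y, fs = fs,
       truth = list(delay_s = delay, delay_samples = delay_smp,
                    phase_lag = phase_lag, snr = snr,
                    source = source_desc,
                    clean_x = src_x, clean_y = src_y))
}

#' Generate a phase-amplitude-coupled signal
#'
#' Builds a composite of a low-frequency oscillation and a high-frequency
#' carrier whose envelope follows the low-frequency phase:
#' \deqn{c(t) = \cos\phi_{low}(t)
#'   + \big(1 - d + d\,\tfrac{1 + \cos\phi_{low}(t)}{2}\big)\cos\phi_{high}(t)
#'   + \varepsilon(t),}
#' where the modulation depth `d` interpolates linearly between no coupling
#' (`d = 0`: constant envelope) and full-depth sinusoidal coupling
#' (`d = 1`: envelope touching zero at the low-frequency trough). All
#' components are returned so metric oracles can be built against ground
#' truth.
#'
#' @param fs Sampling rate (Hz). Default 250.
#' @param duration Length in seconds (default 60).
#' @param seed Integer seed.
#' @param f_phase Low (phase-providing) frequency, Hz (default 6).
#' @param f_amp High (amplitude-providing) frequency, Hz (default 60);
#'   `f_phase < f_amp / 2` recommended so the bands separate cleanly.
#' @param depth Modulation depth in \[0, 1\].
#' @param snr Linear SNR of (low + high) component variance over noise
#'   variance (default 10, `Inf` for noise-free).
#' @return A list: `composite`, `low_component`, `high_component`,
#'   `modulator` (the envelope), `phase_low` (wrapped true phase), `fs`,
#'   `truth`.
#' @export
gen_pac_signal <- function(fs = 250, duration = 60, seed = 1,
                           f_phase = 6, f_amp = 60, depth = 1, snr = 10) {
  stopifnot(fs > 0, duration > 0, f_amp < fs / 2, snr > 0)
  if (!is.numeric(depth) || depth < 0 || depth > 1) {
    stop("`depth` must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  n <- round(fs * duration)
  t <- (seq_len(n) - 1L) / fs
  phi_low <- 2 * pi * f_phase * t
  low <- cos(phi_low)
  modulator <- 1 - depth + depth * (1 + cos(phi_low)) / 2
  high <- modulator * cos(2 * pi * f_amp * t)
  clean <- low + high
  sd_noise <- if (is.finite(snr)) sqrt(stats::var(clean) / snr) else 0
  composite <- clean + stats::rnorm(n, sd = sd_noise)
  list(composite = composite, low_component = low, high_component = high,
       modulator = modulator, phase_low = wrap_phase(phi_low), fs = fs,
       truth = list(f_phase = f_phase, f_amp = f_amp, depth = depth,
                    snr = snr))
}

#' Generate a multichannel recording with known bad channels
#'
#' Independent unit-variance white-noise channels; designated bad channels
#' are scaled by `factor`, inflating (or deflating) their variance so the
#' band-power detector has a known truth set.
#'
#' @param n_channels Channel count (>= 3; default 32).
#' @param fs Sampling rate (Hz), default 250.
#' @param duration Seconds (default 10).
#' @param seed Integer seed.
#' @param bad Integer indices of channels to corrupt.
#' @param factor Amplitude scale of bad channels (default 5, i.e. 25x
#'   variance).
#' @return A list: `rec` (a [recording()]) and `truth` (bad labels).
#' @export
gen_multichannel <- function(n_channels = 32, fs = 250, duration = 10,
                             seed = 1, bad = integer(), factor = 5) {
  stopifnot(n_channels >= 3L)
  if (length(bad) && (min(bad) < 1L || max(bad) > n_channels)) {
    stop("bad channel index out of range", call. = FALSE)
  }
  set.seed(seed)
  n <- round(fs * duration)
  data <- matrix(stats::rnorm(n_channels * n), nrow = n_channels)
  data[bad, ] <- data[bad, , drop = FALSE] * factor
  rec <- recording(data, fs = fs)
  list(rec = rec, truth = rec$labels[bad])
}

#' Generate a Gaussian sample with injected outliers
#'
#' A standard-normal base sample with `n_outliers` values replaced by
#' `+/- magnitude` (alternating sign), at seeded random positions.
#'
#' @param n Sample size (>= 10; default 10000).
#' @param seed Integer seed.
#' @param n_outliers Number of injected outliers (default 50).
#' @param magnitude Outlier magnitude in sd units (default 10).
#' @return A list: `x` and `truth_indices`.
#' @export
gen_outlier_sample <- function(n = 10000, seed = 1, n_outliers = 50,
                               magnitude = 10) {
  stopifnot(n >= 10L)
  if (n_outliers > n) stop("more outliers than samples", call. = FALSE)
  set.seed(seed)
  x <- stats::rnorm(n)
  idx <- sort(sample.int(n, n_outliers))
  if (n_outliers > 0L) {
    x[idx] <- magnitude * rep_len(c(1, -1), n_outliers)
  }
  list(x = x, truth_indices = idx)
}
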