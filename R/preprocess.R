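#' Common average re-referencing
#'
#' Subtracts the instantaneous mean across all channels from every channel,
#' removing the component shared by all sensors (typically reference-electrode
#' activity). After CAR the cross-channel mean is zero at every sample.
#'
#' CAR is only advisable with dense, head-covering montages; a warning is
#' emitted below 64 channels. Bad channels are not excluded automatically —
#' run the cleansing step first in a pipeline.
#'
#' @param rec A [recording()] with at least two channels.
#' @return A `recording` of identical shape, re-referenced.
#' @examples
#' rec <- recording(matrix(c(1, 2, 6), nrow = 3), fs = 100)
#' apply_car(rec)$data  # -2, -1, 3
#' @export
apply_car <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (n_channels(rec) < 2L) {
    stop("CAR is undefined for a single channel", call. = FALSE)
  }
  if (n_channels(rec) < 64L) {
    warning("CAR is recommended for dense montages (>= 64 channels); got ",
            n_channels(rec), call. = FALSE)
  }
  centred <- sweep(rec$data, 2L, colMeans(rec$data), "-")
  recording(centred, fs = rec$fs, labels = rec$labels,
            positions = rec$positions)
}

#' Downsample a recording by sample selection
#'
#' Reduces the sampling rate to `target_fs` by nearest-index selection on the
#' original time grid; integer decimation ratios reduce to taking every k-th
#' sample. No anti-aliasing filter is applied: the caller must low-pass the
#' signal below `target_fs / 2` first (see [apply_fir()]). A warning is
#' emitted when more than 1% of total signal power lies above the new
#' Nyquist frequency.
#'
#' @param rec A [recording()].
#' @param target_fs Target sampling rate in Hz, `0 < target_fs <= fs`.
#' @return A `recording` at `target_fs` with
#'   `floor(n_samples * target_fs / fs)` samples.
#' @examples
#' rec <- recording(matrix(sin(2 * pi * 10 * (0:999) / 1000), 1), fs = 1000)
#' downsample(rec, 250)
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "recording"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0) {
    stop("`target_fs` must be a single positive number", call. = FALSE)
  }
  if (target_fs > rec$fs) {
    stop("`target_fs` (", target_fs, ") exceeds the original rate (",
         rec$fs, ")", call. = FALSE)
  }
  frac <- aliasing_power_fraction(rec, target_fs)
  if (frac > 0.01) {
    warning(sprintf(
      "%.1f%% of signal power lies above target_fs/2 = %g Hz; low-pass filter before downsampling",
      100 * frac, target_fs / 2), call. = FALSE)
  }
  n_out <- floor(n_samples(rec) * target_fs / rec$fs)
  # nearest original index for each output instant i / target_fs
  idx <- round((seq_len(n_out) - 1L) * rec$fs / target_fs) + 1L
  idx <- pmin(idx, n_samples(rec))
  recording(rec$data[, idx, drop = FALSE], fs = target_fs,
            labels = rec$labels, positions = rec$positions)
}

# fraction of total (demeaned) power above target_fs / 2, pooled over channels
aliasing_power_fraction <- function(rec, target_fs) {
  if (target_fs == rec$fs) return(0)
  n <- n_samples(rec)
  freqs <- (seq_len(n %/% 2 + 1L) - 1L) * rec$fs / n
  above <- freqs > target_fs / 2
  tot <- 0
  hi <- 0
  for (ch in seq_len(n_channels(rec))) {
    x <- rec$data[ch, ] - mean(rec$data[ch, ])
    p <- Mod(stats::fft(x)[seq_along(freqs)])^2
    tot <- tot + sum(p)
    hi <- hi + sum(p[above])
  }
  if (tot == 0) 0 else hi / tot
}
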