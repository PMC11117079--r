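#' Multichannel recording container
#'
#' A `recording` bundles a channels-by-samples numeric matrix with its
#' sampling rate, channel labels and (optionally) 2-D scalp positions.
#' It is the input type of the preprocessing and cleansing functions.
#'
#' @param data Numeric matrix, channels in rows, samples in columns
#'   (microvolts by convention). A vector is treated as a single channel.
#' @param fs Sampling rate in Hz; must be finite and strictly positive.
#' @param labels Character vector of unique channel identifiers; defaults
#'   to `"ch1"`, `"ch2"`, ...
#' @param positions Optional data frame with columns `label`, `x`, `y`
#'   giving head-centered 2-D channel coordinates.
#'
#' @return An object of class `recording`.
#' @examples
#' rec <- recording(matrix(rnorm(200), nrow = 4), fs = 100)
#' rec
#' @export
recording <- function(data, fs, labels = NULL, positions = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  stopifnot(is.matrix(data), is.numeric(data))
  if (nrow(data) < 1L || ncol(data) < 1L) {
    stop("recording needs at least one channel and one sample", call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("recording data must not contain NA/NaN/Inf", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single finite positive number (Hz)", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data)) {
    stop("`labels` length must equal the number of channels", call. = FALSE)
  }
  if (anyDuplicated(labels)) stop("channel labels must be unique", call. = FALSE)
  if (!is.null(positions)) {
    positions <- as.data.frame(positions)
    stopifnot(all(c("label", "x", "y") %in% names(positions)))
    positions <- positions[match(labels, positions$label), , drop = FALSE]
    if (anyNA(positions$x)) {
      stop("`positions` must contain every channel label", call. = FALSE)
    }
  }
  structure(
    list(data = unname(data), fs = fs, labels = labels, positions = positions),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channel%s x %d samples @ %g Hz (%.2f s)\n",
    n_channels(x), if (n_channels(x) == 1L) "" else "s",
    n_samples(x), x$fs, n_samples(x) / x$fs
  ))
  cat("  channels:", paste(utils::head(x$labels, 8L), collapse = ", "),
      if (n_channels(x) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$data)

#' Number of channels / samples in a recording
#' @param rec A [recording()].
#' @return Integer count.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a recording into long format
#'
#' @param x A [recording()].
#' @param ... Unused.
#' @return A tibble with columns `time` (s), `channel`, `value`.
#' @export
tidy.recording <- function(x, ...) {
  tibble::tibble(
    time = rep((seq_len(n_samples(x)) - 1L) / x$fs, each = n_channels(x)),
    channel = rep(x$labels, times = n_samples(x)),
    value = as.vector(x$data)
  )
}

#' @rdname tidy.recording
#' @export
glance.recording <- function(x, ...) {
  tibble::tibble(
    n_channels = n_channels(x), n_samples = n_samples(x),
    fs = x$fs, duration = n_samples(x) / x$fs,
    has_positions = !is.null(x$positions)
  )
}

#' Read / write recordings as delimited text
#'
#' The on-disk layout is rows = samples, columns = channels, with a header
#' row of channel labels. The sampling rate travels in a JSON sidecar
#' (`<file>.json`) unless given explicitly.
#'
#' @param path CSV/TSV file path.
#' @param fs Sampling rate in Hz; if `NULL`, read from the sidecar.
#' @param sep Field separator; inferred from the extension by default.
#' @return [read_recording()] returns a `recording`;
#'   [write_recording()] returns `path` invisibly.
#' @export
read_recording <- function(path, fs = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (is.null(fs)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop("`fs` not given and sidecar ", sidecar, " not found", call. = FALSE)
    }
    fs <- jsonlite::read_json(sidecar)$fs
  }
  recording(t(as.matrix(df)), fs = fs, labels = names(df))
}

#' @rdname read_recording
#' @param rec A [recording()].
#' @export
write_recording <- function(rec, path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$labels
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = rec$fs), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}
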