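#' Identify bad channels by band-power z-score
#'
#' Estimates each channel's mean power spectral density inside `band`
#' (Welch, 1-s Hann windows, 50% overlap — the package's spectral
#' defaults), z-scores the band powers across channels (population
#' standard deviation), and flags channels whose |z| exceeds `z_thresh`
#' (default 3). User `overrides` are applied last and recorded, replacing
#' any interactive confirmation step: the report is machine-readable and a
#' channel can be forced `"good"` or `"bad"` regardless of its z-score.
#'
#' Pick a detection band that does not overlap the bands analyzed
#' afterwards, otherwise genuine effects can masquerade as artifacts.
#'
#' @param rec A [recording()] with at least 3 channels.
#' @param band Two-element frequency band (Hz) inside (0, fs/2).
#' @param z_thresh Flagging threshold in z units (default 3).
#' @param overrides Named character vector, e.g.
#'   `c(ch7 = "bad", ch12 = "good")`.
#' @return A `cleansing_report`: per-channel powers and z-scores, `bad` and
#'   `good` label lists, threshold and band. Has [tidy()] and [glance()]
#'   methods.
#' @export
identify_bad_channels <- function(rec, band, z_thresh = 3, overrides = NULL) {
  stopifnot(inherits(rec, "recording"), length(band) == 2L)
  if (n_channels(rec) < 3L) {
    stop("bad-channel detection needs at least 3 channels", call. = FALSE)
  }
  if (band[1L] <= 0 || band[2L] >= rec$fs / 2 || band[1L] >= band[2L]) {
    stop("`band` must be increasing and inside (0, fs/2)", call. = FALSE)
  }
  power <- vapply(seq_len(n_channels(rec)), function(ch) {
    x <- rec$data[ch, ]
    seg <- cross_spectra(x, x, fs = rec$fs,
                         nperseg = min(length(x), round(rec$fs)))
    sel <- seg$freqs >= band[1L] & seg$freqs <= band[2L]
    mean(rowMeans(seg$sxx)[sel])
  }, numeric(1L))
  s <- pop_sd(power)
  if (s == 0) {
    warning("all channels have identical band power; no channel flagged",
            call. = FALSE)
    z <- rep(0, length(power))
  } else {
    z <- (power - mean(power)) / s
  }
  flagged <- abs(z) > z_thresh
  source <- ifelse(flagged, "zscore", "none")
  if (!is.null(overrides)) {
    bad_ov <- !overrides %in% c("good", "bad")
    if (any(bad_ov)) {
      stop("overrides must be 'good' or 'bad'", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), rec$labels)
    if (length(unknown)) {
      stop("override for unknown channel(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    i <- match(names(overrides), rec$labels)
    flagged[i] <- overrides == "bad"
    source[i] <- "override"
  }
  structure(
    list(labels = rec$labels, power = power, power_z = z,
         bad = rec$labels[flagged], good = rec$labels[!flagged],
         threshold = z_thresh, band = band, source = source),
    class = "cleansing_report"
  )
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.cleansing_report <- function(x, ...) {
  cat(sprintf(
    "<cleansing_report> band %g-%g Hz, |z| > %g: %d bad / %d channels\n",
    x$band[1L], x$band[2L], x$threshold, length(x$bad), length(x$labels)))
  if (length(x$bad)) cat("  bad:", paste(x$bad, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy / summarize a cleansing report
#'
#' @param x A `cleansing_report`.
#' @param ... Unused.
#' @return [tidy()]: one row per channel (`channel`, `power`, `power_z`,
#'   `bad`, `source`); [glance()]: one-row summary.
#' @export
tidy.cleansing_report <- function(x, ...) {
  tibble::tibble(channel = x$labels, power = x$power, power_z = x$power_z,
                 bad = x$labels %in% x$bad, source = x$source)
}

#' @rdname tidy.cleansing_report
#' @export
glance.cleansing_report <- function(x, ...) {
  tibble::tibble(n_channels = length(x$labels), n_bad = length(x$bad),
                 threshold = x$threshold,
                 band_lo = x$band[1L], band_hi = x$band[2L])
}

#' @rdname tidy.cleansing_report
#' @param report A `cleansing_report`.
#' @param path JSON output path.
#' @export
write_cleansing_report <- function(report, path) {
  jsonlite::write_json(
    list(threshold = report$threshold, band = report$band,
         channels = tidy(report)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write channel adjacency matrices
#'
#' Adjacency is a symmetric 0/1 matrix with a zero diagonal, stored as CSV
#' with header labels (first column = row labels).
#'
#' @param path CSV file.
#' @return A logical matrix with dimnames.
#' @export
read_adjacency <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df) != 0
  validate_adjacency(m)
  m
}

#' @rdname read_adjacency
#' @param adj Logical/0-1 square matrix with dimnames.
#' @export
write_adjacency <- function(adj, path) {
  validate_adjacency(adj)
  utils::write.csv(adj * 1L, path, row.names = TRUE)
  invisible(path)
}

validate_adjacency <- function(adj) {
  if (!isSymmetric(unname(adj * 1L))) {
    stop("adjacency matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(adj) != 0)) {
    stop("adjacency matrix must have a zero diagonal (no self-neighbors)",
         call. = FALSE)
  }
  invisible(adj)
}

#' Restore bad channels from their neighbors
#'
#' Replaces each bad channel with the unweighted mean of its currently
#' non-faulty neighbors, iteratively: at each step the not-yet-restored bad
#' channel with the most non-faulty neighbors is restored first (ties go to
#' the lowest channel index), and a restored channel counts as non-faulty
#' in subsequent steps. Channels with no path to a good channel cannot be
#' restored and raise an error naming them.
#'
#' @param rec A [recording()].
#' @param bad Character vector of bad channel labels.
#' @param adj Adjacency: logical/0-1 symmetric matrix whose rows/columns
#'   align with `rec$labels` (dimnames, if present, are checked).
#' @return A `recording` with bad channels replaced; good channels are
#'   bit-identical to the input.
#' @export
restore_channels <- function(rec, bad, adj) {
  stopifnot(inherits(rec, "recording"))
  adj <- adj != 0
  validate_adjacency(adj)
  nc <- n_channels(rec)
  if (!all(dim(adj) == c(nc, nc))) {
    stop("adjacency dimensions do not match the recording", call. = FALSE)
  }
  if (!is.null(rownames(adj)) && !identical(rownames(adj), rec$labels)) {
    stop("adjacency labels do not match the recording's labels",
         call. = FALSE)
  }
  unknown <- setdiff(bad, rec$labels)
  if (length(unknown)) {
    stop("unknown bad channel(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  data <- rec$data
  faulty <- rec$labels %in% bad
  todo <- which(faulty)
  while (length(todo)) {
    n_good_nb <- vapply(todo, function(ch) sum(adj[ch, ] & !faulty),
                        integer(1L))
    if (max(n_good_nb) == 0L) {
      stop("unrestorable channel(s) with no non-faulty neighbors: ",
           paste(rec$labels[todo], collapse = ", "), call. = FALSE)
    }
    pick <- todo[which.max(n_good_nb)]     # which.max ties -> lowest index
    nb <- which(adj[pick, ] & !faulty)
    data[pick, ] <- colMeans(data[nb, , drop = FALSE])
    faulty[pick] <- FALSE
    todo <- setdiff(todo, pick)
  }
  recording(data, fs = rec$fs, labels = rec$labels,
            positions = rec$positions)
}

#' Iterative z-score outlier removal
#'
#' Repeatedly z-scores the kept samples (population standard deviation) and
#' drops every sample with |z| > `z_thresh` (default 2), until no sample
#' exceeds the threshold, the spread collapses to zero, or dropping would
#' leave fewer than `min_keep` samples — in that case only the most extreme
#' samples are dropped, down to exactly `min_keep`, and the bound is
#' reported via `min_keep_hit`. The procedure assumes roughly Gaussian
#' data; an all-identical input is returned unchanged with a warning.
#'
#' @param x Numeric vector, length >= 3.
#' @param z_thresh Removal threshold in z units (default 2).
#' @param min_keep Minimum retained sample count; a value < 1 is read as a
#'   fraction of `length(x)` (default 0.2).
#' @return A list: `values` (kept samples), `indices` (their positions in
#'   `x`), `n_iterations`, `min_keep_hit`.
#' @examples
#' res <- remove_outliers(c(rep(0, 9), 100))
#' res$values  # nine zeros
#' @export
remove_outliers <- function(x, z_thresh = 2, min_keep = 0.2) {
  stopifnot(is.numeric(x), length(x) >= 3L, z_thresh > 0)
  n <- length(x)
  min_keep_n <- if (min_keep < 1) max(1L, floor(min_keep * n))
                else as.integer(min_keep)
  if (min_keep_n >= n) stop("`min_keep` must be below length(x)",
                            call. = FALSE)
  keep <- seq_len(n)
  if (pop_sd(x) == 0) {
    warning("all samples identical; outlier removal is a no-op",
            call. = FALSE)
    return(list(values = x, indices = keep, n_iterations = 0L,
                min_keep_hit = FALSE))
  }
  iter <- 0L
  min_keep_hit <- FALSE
  repeat {
    v <- x[keep]
    s <- pop_sd(v)
    if (s == 0) break
    z <- abs(v - mean(v)) / s
    viol <- z > z_thresh
    if (!any(viol)) break
    iter <- iter + 1L
    if (length(keep) - sum(viol) < min_keep_n) {
      n_drop <- length(keep) - min_keep_n
      drop <- order(z, decreasing = TRUE)[seq_len(n_drop)]
      keep <- keep[-drop]
      min_keep_hit <- TRUE
      break
    }
    keep <- keep[!viol]
  }
  list(values = x[keep], indices = keep, n_iterations = iter,
       min_keep_hit = min_keep_hit)
}
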