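#' Three-level significance classification
#'
#' Classifies each channel as `"corrected"` (significant after multiple
#' comparison correction), `"uncorrected_only"` (significant only before
#' correction) or `"none"`. Because corrected p-values are never smaller
#' than the raw ones under standard correction procedures, a corrected
#' channel would also pass uncorrected.
#'
#' @param p_raw Raw per-channel p-values in \[0, 1\].
#' @param p_corrected Corrected per-channel p-values (e.g. from
#'   [stats::p.adjust()]), same length.
#' @param alpha Significance level (default 0.05).
#' @param labels Optional channel labels.
#' @return A tibble: `channel`, `p_raw`, `p_corrected`, `category`
#'   (factor with levels none < uncorrected_only < corrected).
#' @export
classify_significance <- function(p_raw, p_corrected, alpha = 0.05,
                                  labels = NULL) {
  if (length(p_raw) != length(p_corrected)) {
    stop("`p_raw` and `p_corrected` must have equal length", call. = FALSE)
  }
  p <- c(p_raw, p_corrected)
  if (any(p < 0 | p > 1 | is.na(p))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  category <- ifelse(p_corrected <= alpha, "corrected",
                     ifelse(p_raw <= alpha, "uncorrected_only", "none"))
  if (is.null(labels)) labels <- paste0("ch", seq_along(p_raw))
  tibble::tibble(
    channel = labels, p_raw = p_raw, p_corrected = p_corrected,
    category = factor(category,
                      levels = c("none", "uncorrected_only", "corrected"))
  )
}

#' Topographic scalp map with significance markers
#'
#' Interpolates per-channel values over the head disk (thin-plate radial
#' basis functions on positions normalized to the unit circle, masked
#' outside the head) and overlays one marker per channel encoding its
#' significance category: filled white dots for channels surviving multiple
#' comparison correction, grey ("half-filled") dots for channels
#' significant only before correction, black dots otherwise. The color
#' scale is symmetric about zero by default.
#'
#' Alongside any rendered file a JSON *marker manifest* (`label`, `x`, `y`,
#' `category` per channel) is written, so the marker logic is testable
#' without pixel inspection.
#'
#' @param values Per-channel numeric values.
#' @param positions Data frame with columns `label`, `x`, `y` (see
#'   [default_montage()]).
#' @param marking Optional tibble from [classify_significance()] (matched
#'   by position order); defaults to all-`"none"`.
#' @param out_path Optional image path (`.png` / `.svg` / `.pdf`); when
#'   given, the plot and the manifest (`<stem>_markers.json`) are written.
#' @param grid_n Interpolation grid resolution per axis (default 67).
#' @param symmetric_scale Center the fill scale on 0 (default `TRUE`).
#' @return The ggplot object, invisibly, with the manifest attached as
#'   attribute `"manifest"`.
#' @export
topoplot <- function(values, positions, marking = NULL, out_path = NULL,
                     grid_n = 67L, symmetric_scale = TRUE) {
  positions <- as.data.frame(positions)
  stopifnot(all(c("label", "x", "y") %in% names(positions)))
  nc <- nrow(positions)
  if (length(values) != nc) {
    stop("`values` length must match the number of positions", call. = FALSE)
  }
  if (nc < 3L) stop("interpolation needs at least 3 channels",
                    call. = FALSE)
  if (anyDuplicated(positions[, c("x", "y")])) {
    stop("duplicate channel positions", call. = FALSE)
  }
  r_max <- max(sqrt(positions$x^2 + positions$y^2))
  px <- positions$x / max(r_max, 1e-12)
  py <- positions$y / max(r_max, 1e-12)
  if (is.null(marking)) {
    category <- factor(rep("none", nc),
                       levels = c("none", "uncorrected_only", "corrected"))
  } else {
    category <- marking$category
    stopifnot(length(category) == nc)
  }
  g <- seq(-1, 1, length.out = grid_n)
  grid <- expand.grid(x = g, y = g)
  inside <- grid$x^2 + grid$y^2 <= 1
  z <- rep(NA_real_, nrow(grid))
  z[inside] <- thin_plate_interp(px, py, values,
                                 grid$x[inside], grid$y[inside])
  grid$value <- z
  lim <- if (symmetric_scale) c(-1, 1) * max(abs(values), 1e-12) else NULL
  theta <- seq(0, 2 * pi, length.out = 181L)
  head_df <- data.frame(x = cos(theta), y = sin(theta))
  chan_df <- data.frame(x = px, y = py, category = category)
  fills <- c(none = "black", uncorrected_only = "grey70",
             corrected = "white")
  plt <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = grid[!is.na(grid$value), ],
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$value)) +
    ggplot2::geom_path(data = head_df,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       linewidth = 0.6) +
    ggplot2::geom_point(data = chan_df,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$category),
                        fill = fills[as.character(chan_df$category)],
                        size = 2.4, stroke = 0.4, color = "black") +
    ggplot2::scale_shape_manual(
      values = c(none = 21, uncorrected_only = 21, corrected = 21),
      drop = FALSE) +
    ggplot2::scale_fill_distiller(palette = "RdBu", limits = lim,
                                  na.value = "transparent") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "value", shape = "significance")
  manifest <- lapply(seq_len(nc), function(i) {
    list(label = positions$label[i], x = px[i], y = py[i],
         category = as.character(category[i]))
  })
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, plt, width = 5, height = 5, dpi = 150)
    jsonlite::write_json(
      manifest,
      paste0(tools::file_path_sans_ext(out_path), "_markers.json"),
      auto_unbox = TRUE, digits = NA)
  }
  attr(plt, "manifest") <- manifest
  invisible(plt)
}

# thin-plate spline interpolation: phi(r) = r^2 log r, affine part included
thin_plate_interp <- function(px, py, v, qx, qy) {
  n <- length(px)
  tp <- function(r2) {
    out <- numeric(length(r2))
    pos <- r2 > 0
    out[pos] <- 0.5 * r2[pos] * log(r2[pos])   # r^2 log r = (r^2 log r^2)/2
    out
  }
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    K[i, ] <- tp((px[i] - px)^2 + (py[i] - py)^2)
  }
  P <- cbind(1, px, py)
  A <- rbind(cbind(K + diag(1e-10, n), P),
             cbind(t(P), matrix(0, 3L, 3L)))
  coef <- solve(A, c(v, numeric(3L)))
  w <- coef[seq_len(n)]
  a <- coef[n + 1:3]
  vapply(seq_along(qx), function(j) {
    sum(w * tp((qx[j] - px)^2 + (qy[j] - py)^2)) +
      a[1L] + a[2L] * qx[j] + a[3L] * qy[j]
  }, numeric(1L))
}

#' Standard 10-20 electrode positions
#'
#' A 19-channel approximation of the international 10-20 montage projected
#' onto the unit circle, shipped as a package resource for quick topomaps.
#'
#' @return A tibble with columns `label`, `x`, `y`.
#' @export
default_montage <- function() {
  path <- system.file("extdata", "montage_1020.csv", package = "neuroconn")
  tibble::as_tibble(utils::read.csv(path))
}
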