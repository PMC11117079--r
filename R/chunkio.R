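#' Write an array to disk in checksummed chunks
#'
#' Splits a numeric vector/matrix/array along its first axis into several
#' raw little-endian binary files plus a JSON manifest. Reading and writing
#' proceed one chunk at a time, so the transient buffer never exceeds one
#' chunk beyond the destination array — loading a large recording cannot
#' cause a whole-object memory spike.
#'
#' Within each chunk, elements are stored rows-first (first axis slowest
#' varying is split across chunks, remaining axes flattened column-major as
#' in R), so a chunk is exactly a contiguous slab of first-axis rows.
#' Each chunk carries an MD5 checksum, verified on read.
#'
#' @param array Numeric vector, matrix or array.
#' @param dir Output directory (created if missing).
#' @param chunk_bytes Target chunk size in bytes; must hold at least one
#'   first-axis row.
#' @param element_width 64 (double) or 32 (single precision; lossy for
#'   general doubles).
#' @return The manifest, invisibly (a list mirroring `manifest.json`).
#' @examples
#' d <- tempfile(); m <- matrix(rnorm(1000), 100)
#' chunk_write(m, d, chunk_bytes = 2000)
#' all.equal(chunk_read(d), m)
#' @export
chunk_write <- function(array, dir, chunk_bytes, element_width = 64) {
  stopifnot(is.numeric(array), element_width %in% c(32, 64))
  shape <- if (is.null(dim(array))) length(array) else dim(array)
  mat <- matrix(as.double(array), nrow = shape[1L])
  bytes_per_el <- element_width / 8
  row_bytes <- ncol(mat) * bytes_per_el
  if (chunk_bytes < row_bytes) {
    stop("`chunk_bytes` (", chunk_bytes, ") must hold at least one row (",
         row_bytes, " bytes)", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  rows_per_chunk <- max(1L, floor(chunk_bytes / row_bytes))
  n_chunks <- ceiling(nrow(mat) / rows_per_chunk)
  paths <- sprintf("chunk_%04d.bin", seq_len(n_chunks))
  checksums <- character(n_chunks)
  for (k in seq_len(n_chunks)) {
    r0 <- (k - 1L) * rows_per_chunk + 1L
    r1 <- min(k * rows_per_chunk, nrow(mat))
    slab <- as.vector(t(mat[r0:r1, , drop = FALSE]))  # rows contiguous
    con <- file(file.path(dir, paths[k]), "wb")
    writeBin(slab, con, size = bytes_per_el, endian = "little")
    close(con)
    checksums[k] <- unname(tools::md5sum(file.path(dir, paths[k])))
  }
  manifest <- list(
    n_chunks = n_chunks,
    chunk_paths = as.list(paths),
    total_shape = as.list(shape),
    rows_per_chunk = rows_per_chunk,
    element_width = element_width,
    byte_order = "little",
    checksum_algo = "md5",
    checksums = as.list(checksums)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a chunked array back from disk
#'
#' Reconstructs the array written by [chunk_write()], verifying every
#' chunk's checksum and the element counts against the manifest before and
#' during assembly. A missing, truncated or corrupted chunk raises an error
#' naming it.
#'
#' @param dir Directory containing `manifest.json` and the chunk files.
#' @return The reconstructed numeric vector/matrix/array.
#' @export
chunk_read <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir, call. = FALSE)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  shape <- as.integer(man$total_shape)
  n_el <- prod(shape)
  n_cols <- n_el %/% shape[1L]
  bytes_per_el <- man$element_width / 8
  if (length(man$chunk_paths) != man$n_chunks) {
    stop("manifest inconsistent: n_chunks = ", man$n_chunks, " but ",
         length(man$chunk_paths), " chunk paths listed", call. = FALSE)
  }
  mat <- matrix(0, nrow = shape[1L], ncol = n_cols)
  row0 <- 0L
  for (k in seq_along(man$chunk_paths)) {
    path <- file.path(dir, man$chunk_paths[k])
    if (!file.exists(path)) {
      stop("missing chunk ", man$chunk_paths[k], call. = FALSE)
    }
    if (unname(tools::md5sum(path)) != man$checksums[k]) {
      stop("checksum mismatch for chunk ", man$chunk_paths[k],
           call. = FALSE)
    }
    n_rows_k <- file.size(path) / (bytes_per_el * n_cols)
    if (n_rows_k != round(n_rows_k)) {
      stop("chunk ", man$chunk_paths[k], " has a partial row", call. = FALSE)
    }
    con <- file(path, "rb")
    slab <- readBin(con, "double", n = n_rows_k * n_cols,
                    size = bytes_per_el, endian = "little")
    close(con)
    if (row0 + n_rows_k > shape[1L]) {
      stop("chunks contain more rows than the manifest shape declares",
           call. = FALSE)
    }
    mat[(row0 + 1L):(row0 + n_rows_k), ] <-
      matrix(slab, nrow = n_rows_k, byrow = TRUE)
    row0 <- row0 + as.integer(n_rows_k)
  }
  if (row0 != shape[1L]) {
    stop("chunk rows (", row0, ") do not cover the declared shape (",
         shape[1L], " rows)", call. = FALSE)
  }
  if (length(shape) == 1L) as.vector(mat)
  else if (length(shape) == 2L) mat
  else array(mat, dim = shape)
}
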