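# TRK (TrackVis) and TCK (MRtrix) tractogram readers/writers.
#
# TCK stores points in world (scanner) mm as little-endian float32, with a
# NaN triplet between streamlines and an Inf triplet at the end of file.
# TRK stores points in "voxmm" (corner-based voxel coordinate times voxel
# size); the 1000-byte header carries dimensions, voxel size and a
# voxel-centre vox_to_ras affine (version 2). Conversions here follow those
# public layouts. Coordinates survive a round trip to float32 precision
# (~1e-5 relative), which is what the writers emit.

#' Write a bundle as a TCK tractogram
#'
#' @param bundle a [streamline_bundle()].
#' @param path output `.tck` path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(bundle, path) {
  lines <- c("mrtrix tracks",
             "datatype: Float32LE",
             sprintf("count: %d", n_streamlines(bundle)))
  # the 'file' line states the data offset, which depends on its own length
  offset <- 0L
  for (i in 1:4) {
    file_line <- sprintf("file: . %d", offset)
    header <- paste0(paste(c(lines, file_line, "END"), collapse = "\n"), "\n")
    new_offset <- nchar(header, type = "bytes")
    if (new_offset == offset) break
    offset <- new_offset
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  for (s in bundle$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a TCK tractogram
#'
#' @param path `.tck` path.
#' @param grid optional [vox_grid()] to attach; if `NULL`, a 1 mm grid
#'   bounding the streamlines (5-voxel margin) is built.
#' @param bundle_id bundle name.
#' @return a [streamline_bundle()].
#' @export
read_tck <- function(path, grid = NULL, bundle_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  head_raw <- readBin(con, "raw", 8192L)
  # header ends at the first "END\n"; bytes after it are binary track data
  h <- as.integer(head_raw)
  e <- as.integer(charToRaw("END\n"))
  n <- length(h)
  if (n < 4) stop("not a TCK file: ", path)
  cand <- which(h[seq_len(n - 3)] == e[1] & h[seq(2, n - 2)] == e[2] &
                  h[seq(3, n - 1)] == e[3] & h[seq(4, n)] == e[4])
  if (!length(cand)) stop("TCK header terminator 'END' not found in ", path)
  head_txt <- rawToChar(head_raw[seq_len(cand[1] + 3L)])
  hdr_lines <- strsplit(head_txt, "\n", fixed = TRUE)[[1]]
  if (!identical(hdr_lines[1], "mrtrix tracks")) stop("not a TCK file: ", path)
  file_line <- grep("^file:", hdr_lines, value = TRUE)
  if (length(file_line) != 1) stop("TCK header lacks a single 'file:' line")
  offset <- as.integer(sub("^file:\\s*\\.\\s*", "", file_line))
  dtype <- sub("^datatype:\\s*", "", grep("^datatype:", hdr_lines, value = TRUE))
  if (length(dtype) && !identical(dtype, "Float32LE"))
    stop("unsupported TCK datatype: ", dtype)
  seek(con, offset)
  n_float <- (file.size(path) - offset) %/% 4
  vals <- readBin(con, "numeric", n = n_float, size = 4, endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  is_sep <- is.nan(pts[, 1])
  is_end <- is.infinite(pts[, 1])
  breaks <- which(is_sep | is_end)
  streamlines <- list()
  start <- 1L
  for (b in breaks) {
    if (b > start) streamlines[[length(streamlines) + 1L]] <- pts[start:(b - 1L), , drop = FALSE]
    if (is_end[b]) break
    start <- b + 1L
  }
  if (is.null(bundle_id))
    bundle_id <- sub("\\.tck$", "", basename(path))
  if (is.null(grid)) grid <- bounding_grid(streamlines)
  streamline_bundle(streamlines, grid, bundle_id)
}

#' Write a bundle as a TRK tractogram
#'
#' Points are converted to TrackVis voxmm using the bundle grid; the grid's
#' voxel-centre affine is stored as `vox_to_ras` (TRK version 2).
#'
#' @param bundle a [streamline_bundle()].
#' @param path output `.trk` path.
#' @return `path`, invisibly.
#' @export
write_trk <- function(bundle, path) {
  g <- bundle$grid
  M <- grid_affine(g)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)
  writeBin(as.integer(g$dim), con, size = 2, endian = "little")
  writeBin(as.numeric(g$vox), con, size = 4, endian = "little")
  writeBin(rep(0, 3), con, size = 4, endian = "little")          # origin (unused)
  writeBin(0L, con, size = 2, endian = "little")                  # n_scalars
  writeBin(raw(200), con)                                         # scalar names
  writeBin(0L, con, size = 2, endian = "little")                  # n_properties
  writeBin(raw(200), con)                                         # property names
  writeBin(as.numeric(t(M)), con, size = 4, endian = "little")    # vox_to_ras, row-major
  writeBin(raw(444), con)                                         # reserved
  writeBin(c(charToRaw("RAS"), as.raw(0)), con)                   # voxel_order
  writeBin(raw(4), con)                                           # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4, endian = "little") # orientation
  writeBin(raw(2), con)                                           # pad1
  writeBin(raw(6), con)                                           # invert/swap flags
  writeBin(n_streamlines(bundle), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")                  # version
  writeBin(1000L, con, size = 4, endian = "little")               # hdr_size
  Minv <- solve(M)
  for (s in bundle$streamlines) {
    vox <- t(Minv %*% rbind(t(s), 1))[, 1:3, drop = FALSE]        # centre-based voxel coords
    voxmm <- sweep(vox + 0.5, 2, g$vox, "*")
    writeBin(nrow(s), con, size = 4, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a TRK tractogram
#'
#' @param path `.trk` path.
#' @param bundle_id bundle name; defaults to the file stem.
#' @return a [streamline_bundle()] with the grid rebuilt from the header.
#' @export
read_trk <- function(path, bundle_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(rawToChar(magic[1:5]), "TRACK")) stop("not a TRK file: ", path)
  dim <- readBin(con, "integer", 3, size = 2, endian = "little")
  vox <- readBin(con, "numeric", 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", 3, size = 4, endian = "little"))
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  n_properties <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  M <- matrix(readBin(con, "numeric", 16, size = 4, endian = "little"),
              4, 4, byrow = TRUE)
  invisible(readBin(con, "raw", 444 + 4 + 4 + 24 + 2 + 6))
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr_size != 1000L) stop("unexpected TRK header size: ", hdr_size)
  if (version >= 2 && all(M == 0)) stop("TRK vox_to_ras affine is all zero")
  if (all(M == 0)) { M <- diag(4); diag(M)[1:3] <- vox }
  streamlines <- vector("list", max(n_count, 0L))
  i <- 0L
  repeat {
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(n) == 0) break
    pts <- matrix(readBin(con, "numeric", n * (3 + n_scalars), size = 4,
                          endian = "little"), ncol = 3 + n_scalars, byrow = TRUE)
    if (n_properties > 0)
      invisible(readBin(con, "numeric", n_properties, size = 4, endian = "little"))
    vox_c <- sweep(pts[, 1:3, drop = FALSE], 2, vox, "/") - 0.5
    world <- t(M %*% rbind(t(vox_c), 1))[, 1:3, drop = FALSE]
    i <- i + 1L
    streamlines[[i]] <- world
  }
  streamlines <- streamlines[seq_len(i)]
  origin <- M[1:3, 4] - 0.5 * diag(M[1:3, 1:3])
  grid <- vox_grid(dim, diag(M[1:3, 1:3]), origin)
  if (is.null(bundle_id)) bundle_id <- sub("\\.trk$", "", basename(path))
  streamline_bundle(streamlines, grid, bundle_id)
}

#' Read a tractogram by extension
#' @param path `.trk` or `.tck` path.
#' @param ... passed to [read_trk()] or [read_tck()].
#' @return a [streamline_bundle()].
#' @export
read_tractogram <- function(path, ...) {
  switch(tolower(tools::file_ext(path)),
         trk = read_trk(path, ...),
         tck = read_tck(path, ...),
         stop("unsupported tractogram extension: ", path))
}

#' Write a tractogram by extension
#' @param bundle a [streamline_bundle()].
#' @param path `.trk` or `.tck` path.
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(bundle, path) {
  switch(tolower(tools::file_ext(path)),
         trk = write_trk(bundle, path),
         tck = write_tck(bundle, path),
         stop("unsupported tractogram extension: ", path))
}

bounding_grid <- function(streamlines, vox = c(1, 1, 1), margin = 5) {
  pts <- do.call(rbind, streamlines)
  lo <- apply(pts, 2, min) - margin * vox
  hi <- apply(pts, 2, max) + margin * vox
  vox_grid(ceiling((hi - lo) / vox) + 1L, vox, origin = lo)
}
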