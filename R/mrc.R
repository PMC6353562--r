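# MRC-2014 volume I/O (little-endian; modes 0, 1, 2, 6).

MRC_HEADER_BYTES <- 1024L

#' Read an MRC density volume
#'
#' Reads an MRC-2014 file into a [density_volume()]. The voxel size is
#' taken from the cell dimensions divided by the grid sampling (header
#' `cella / mx`, converted from Angstrom to nm); modes 0 (int8), 1 (int16),
#' 2 (float32) and 6 (uint16) are supported, in either byte order.
#'
#' @param path path to an MRC file.
#' @return a [density_volume()] (wedge descriptor unset).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sz <- file.info(path)$size
  if (sz < MRC_HEADER_BYTES)
    stop(sprintf("malformed MRC header in %s: expected at least %d bytes, found %d",
                 path, MRC_HEADER_BYTES, sz))
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  dims <- readBin(con, "integer", 3, size = 4, endian = endian)
  if (any(dims <= 0) || any(dims > 1e5)) {
    endian <- "big"
    seek(con, 0)
    dims <- readBin(con, "integer", 3, size = 4, endian = endian)
    if (any(dims <= 0) || any(dims > 1e5))
      stop(sprintf("malformed MRC header in %s: implausible dimensions at offset 0",
                   path))
  }
  mode <- readBin(con, "integer", 1, size = 4, endian = endian)
  readBin(con, "integer", 3, size = 4, endian = endian)  # nxstart..nzstart
  mxyz <- readBin(con, "integer", 3, size = 4, endian = endian)
  cella <- readBin(con, "numeric", 3, size = 4, endian = endian)
  seek(con, 208)
  map <- readChar(con, 4, useBytes = TRUE)
  if (!identical(substr(map, 1, 3), "MAP"))
    warning(sprintf("%s: missing 'MAP ' stamp at offset 208", path))

  bytes_per <- switch(as.character(mode), "0" = 1L, "1" = 2L, "2" = 4L,
                      "6" = 2L, NULL)
  if (is.null(bytes_per))
    stop(sprintf("unsupported MRC mode %d in %s", mode, path))
  n <- prod(dims)
  expected <- MRC_HEADER_BYTES + as.numeric(n) * bytes_per
  if (sz < expected)
    stop(sprintf("truncated MRC file %s: expected %.0f bytes, found %.0f",
                 path, expected, sz))

  seek(con, MRC_HEADER_BYTES)
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n, size = 1, signed = TRUE, endian = endian),
    "1" = readBin(con, "integer", n, size = 2, signed = TRUE, endian = endian),
    "2" = readBin(con, "numeric", n, size = 4, endian = endian),
    "6" = readBin(con, "integer", n, size = 2, signed = FALSE, endian = endian))
  if (length(vals) < n)
    stop(sprintf("truncated MRC data in %s: expected %d values, read %d",
                 path, n, length(vals)))
  vx <- if (all(mxyz > 0) && all(cella > 0)) cella / mxyz / 10 else
    rep(1, 3)  # Angstrom -> nm
  if (max(vx) - min(vx) > 1e-4 * mean(vx))
    warning(sprintf("%s: anisotropic voxel size, using the mean", path))
  density_volume(array(as.numeric(vals), dims), mean(vx))
}

#' Write a volume as MRC
#'
#' Writes a [density_volume()] as a little-endian MRC-2014 file, mode 2
#' (32-bit float), with the voxel size (in Angstrom) and the density
#' statistics (min / max / mean / rms) filled into the header.
#'
#' @param vol a [density_volume()].
#' @param path output path.
#' @param invert_contrast write `-grid`, matching the density-below-
#'   background convention of raw cryo-ET reconstructions.
#' @return invisibly, `path`.
#' @export
write_volume <- function(vol, path, invert_contrast = FALSE) {
  stopifnot(is_density_volume(vol))
  g <- vol$grid
  if (!all(is.finite(g))) stop("volume contains non-finite values")
  if (invert_contrast) g <- -g
  d <- dim(g)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d); wi(2)                 # nx ny nz, mode 2
  wi(c(0, 0, 0))               # nxstart
  wi(d)                        # mx my mz
  wf(d * vol$voxel_size_nm * 10)  # cella (Angstrom)
  wf(c(90, 90, 90))            # cellb
  wi(c(1, 2, 3))               # mapc mapr maps
  wf(c(min(g), max(g), mean(g)))  # dmin dmax dmean
  wi(c(0, 0))                  # ispg, nsymbt
  wi(rep(0, 25))               # extra
  wf(vol$origin_nm * 10)       # origin (Angstrom)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(stats::sd(g))             # rms
  wi(0)                        # nlabl
  writeBin(raw(800), con)      # labels
  writeBin(as.numeric(g), con, size = 4, endian = "little")
  invisible(path)
}
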