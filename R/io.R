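# File I/O: MRC2014 volumes/stacks (modes 0, 1, 2 read; mode 2 float32
# written; pixel size carried in the cell dimensions) and plain-text
# per-particle parameter tables.

#' Read an MRC file
#'
#' Supports MRC2014 modes 0 (int8), 1 (int16) and 2 (float32).  A cubic
#' file is returned as a [density_volume()]; a stack of square images as a
#' [particle_stack()].
#'
#' @param path File path.
#' @param what `"auto"`, `"volume"` or `"stack"`.
#' @return A [density_volume()] or [particle_stack()].
#' @export
read_mrc <- function(path, what = c("auto", "volume", "stack")) {
  what <- match.arg(what)
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 10, size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  mxyz <- hdr[8:10]
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  seek(con, 92)
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, 208)
  map <- rawToChar(readBin(con, "raw", 4))
  if (nx <= 0 || ny <= 0 || nz <= 0 || !(mode %in% c(0L, 1L, 2L)))
    stop_format("unsupported or corrupt MRC header")
  seek(con, 1024 + nsymbt)
  nvox <- as.numeric(nx) * ny * nz
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", nvox, size = 1, signed = TRUE,
                             endian = "little")),
    "1" = as.numeric(readBin(con, "integer", nvox, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", nvox, size = 4, endian = "little"))
  if (length(data) < nvox) stop_format("truncated MRC data block")
  px <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else 1
  arr <- array(data, c(nx, ny, nz))
  if (what == "volume" || (what == "auto" && nx == ny && ny == nz)) {
    if (nx != ny || ny != nz) stop_format("cubic volume required")
    density_volume(arr, px)
  } else {
    if (nx != ny) stop_format("square images required")
    particle_stack(arr, px)
  }
}

#' Write an MRC file (mode 2, float32)
#'
#' @param obj A [density_volume()], [particle_stack()], 3D array or image
#'   matrix.
#' @param path Output path.
#' @param pixel_size Angstrom per voxel (taken from the object when
#'   available).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(obj, path, pixel_size = NULL) {
  if (inherits(obj, "density_volume")) {
    arr <- obj$grid
    if (is.null(pixel_size)) pixel_size <- obj$pixel_size
  } else if (inherits(obj, "particle_stack")) {
    arr <- obj$images
    if (is.null(pixel_size)) pixel_size <- obj$pixel_size
  } else {
    arr <- obj
    if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  }
  if (is.null(pixel_size)) pixel_size <- 1
  d <- dim(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4,
           endian = "little")
  writeBin(as.numeric(c(d * pixel_size, 90, 90, 90)), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(arr), max(arr), mean(arr))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(1L, 0L)), con, size = 4, endian = "little") # ispg, nsymbt
  writeBin(raw(100), con)                                  # extra
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little") # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)         # little-endian
  writeBin(as.numeric(sd(as.numeric(arr))), con, size = 4, endian = "little")
  writeBin(as.integer(0L), con, size = 4, endian = "little") # nlabl
  writeBin(raw(800), con)
  writeBin(as.numeric(arr), con, size = 4, endian = "little")
  invisible(path)
}

param_cols <- c("index", "phi", "theta", "psi", "x", "y")

#' Read a particle parameter table
#'
#' Whitespace-separated text with a header row naming at least
#' `index phi theta psi x y`; unknown columns are preserved.  Angles are
#' normalized to `[0, 360)` on read.  The shift convention is the
#' package-wide one: `(x, y)` moves the projected object by `(+x, +y)`
#' pixels in the image.
#'
#' @param path File path.
#' @return Data frame of per-particle parameters.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  df <- read.table(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  missing <- setdiff(param_cols, names(df))
  if (length(missing))
    stop_format(paste("missing required columns:",
                      paste(missing, collapse = ", ")))
  for (cn in c("phi", "theta", "psi")) df[[cn]] <- wrap360(df[[cn]])
  df
}

#' Write a particle parameter table
#'
#' Values are written with six decimals; the header records units and the
#' shift sign convention.
#'
#' @param params Data frame with at least `index phi theta psi x y`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  missing <- setdiff(param_cols, names(params))
  if (length(missing))
    stop_invalid(paste("missing required columns:",
                       paste(missing, collapse = ", ")))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    "# per-particle alignment parameters: angles in degrees (ZYZ),",
    "# shifts in pixels; (x, y) moves the projected object by (+x, +y)."),
    con)
  fmt <- params
  for (cn in names(fmt))
    if (is.numeric(fmt[[cn]]) && cn != "index" && cn != "defocus_group")
      fmt[[cn]] <- sprintf("%.6f", fmt[[cn]])
  write.table(fmt, con, quote = FALSE, row.names = FALSE)
  invisible(path)
}
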