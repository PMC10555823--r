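# Minimal MRC2014 image stack I/O (mode 2, 32-bit float, little-endian).
# Covers what the montage pipeline needs: single images, tilt stacks and
# small volumes with a voxel size, written from and read into base R arrays
# indexed [x, y] / [x, y, z].

#' Write an array as an MRC file
#'
#' @param x Numeric matrix (`[x, y]`) or 3D array (`[x, y, z]`).
#' @param path Output path.
#' @param pixel_size_A Voxel size stored in the header, Angstrom.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path, pixel_size_A = 1) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3, pixel_size_A > 0)
  d <- dim(x)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(d)                     # nx ny nz
  wi(2L)                    # mode 2: float32
  wi(c(0L, 0L, 0L))         # nxstart nystart nzstart
  wi(d)                     # mx my mz
  wf(d * pixel_size_A)      # cell dimensions (A)
  wf(c(90, 90, 90))         # cell angles
  wi(c(1L, 2L, 3L))         # axis order
  wf(c(min(x), max(x), mean(x)))
  wi(c(0L, 0L))             # ispg, nsymbt
  wi(integer(25))           # extra
  wf(c(0, 0, 0))            # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(x)))
  wi(0L)                    # nlabl
  writeBin(raw(800), con)   # labels
  writeBin(as.numeric(as.vector(x)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC file
#'
#' Supports modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16),
#' little-endian.
#'
#' @param path Path to an MRC file.
#' @return Numeric array `[x, y, z]` (a matrix is returned as `nz = 1`
#'   array) with attribute `pixel_size_A`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)          # nxstart..
  mx <- ri(3)
  cell <- rf(3)
  seek(con, 1024)
  n <- prod(d)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = rf(n),
    "6" = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                             endian = "little")),
    stop("unsupported MRC mode: ", mode)
  )
  arr <- array(data, dim = d)
  attr(arr, "pixel_size_A") <- if (mx[1] > 0) cell[1] / mx[1] else NA_real_
  arr
}
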