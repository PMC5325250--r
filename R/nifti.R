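#' Minimal NIfTI-1 volume I/O
#'
#' The offline toolchain this package targets ships no R NIfTI reader, so a
#' small single-file NIfTI-1 implementation is provided: little-endian `.nii`
#' (optionally gzip-compressed), one 348-byte header plus the 4-byte extension
#' flag, data types uint8/int16/int32/float32/float64, and a diagonal sform
#' built from the voxel spacing. This covers everything the pipeline reads and
#' writes; it is not a general-purpose NIfTI library (no slope/intercept
#' scaling other than identity on write, no qform quaternions, no NIfTI-2).
#'
#' @param x numeric or integer array, 3D or 4D.
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @param voxdim voxel spacing in mm (3 values); a 4th value, if given, is the
#'   frame interval in seconds for 4D series.
#' @param datatype one of `"float64"`, `"float32"`, `"int16"`, `"uint8"`.
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns a list
#'   with elements `data` (array), `voxdim`, and `datatype`.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' write_nifti(array(rnorm(60), c(3, 4, 5)), f, voxdim = c(2, 2, 5))
#' dim(read_nifti(f)$data)
#' @export
write_nifti <- function(x, path, voxdim = c(1, 1, 1), datatype = "float64") {
  stopifnot(is.array(x), length(dim(x)) %in% c(3L, 4L))
  dt <- match.arg(datatype, c("float64", "float32", "int16", "uint8"))
  code <- c(float64 = 64L, float32 = 16L, int16 = 4L, uint8 = 2L)[[dt]]
  bitpix <- c(float64 = 64L, float32 = 32L, int16 = 16L, uint8 = 8L)[[dt]]
  nd <- length(dim(x))
  dims <- rep(1L, 8); dims[1] <- nd; dims[1 + seq_len(nd)] <- dim(x)
  pixdim <- rep(0, 8)
  pixdim[2:4] <- voxdim[1:3]
  pixdim[5] <- if (length(voxdim) >= 4) voxdim[4] else 0

  # header + 4-byte extension flag = 352 bytes, data immediately after
  hdr <- raw(352)
  poke_i <- function(off, v, size) {
    b <- writeBin(as.integer(v), raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <<- b
  }
  poke_f <- function(off, v) {
    b <- writeBin(as.double(v), raw(), size = 4, endian = "little")
    hdr[(off + 1):(off + length(b))] <<- b
  }
  poke_i(0, 348L, 4)                      # sizeof_hdr
  hdr[40] <- charToRaw("r")               # regular (offset 39)
  poke_i(40, dims, 2)                     # dim[8]
  poke_i(70, code, 2)                     # datatype
  poke_i(72, bitpix, 2)                   # bitpix
  poke_f(76, pixdim)                      # pixdim[8]
  poke_f(108, 352)                        # vox_offset
  poke_f(112, 1)                          # scl_slope
  poke_f(116, 0)                          # scl_inter
  poke_i(254, 1L, 2)                      # sform_code = 1
  poke_f(280, c(voxdim[1], 0, 0, 0))      # srow_x
  poke_f(296, c(0, voxdim[2], 0, 0))      # srow_y
  poke_f(312, c(0, 0, voxdim[3], 0))      # srow_z
  hdr[345:347] <- charToRaw("n+1")        # magic, nul-terminated by raw(0)

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  if (dt %in% c("float64", "float32")) {
    writeBin(as.double(as.vector(x)), con,
             size = if (dt == "float64") 8 else 4, endian = "little")
  } else {
    writeBin(as.integer(as.vector(x)), con,
             size = if (dt == "int16") 2 else 1, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path)
  peek_i <- function(off, n, size, signed = TRUE) {
    readBin(hdr[(off + 1):(off + n * size)], "integer", n = n, size = size,
            endian = "little", signed = signed)
  }
  peek_f <- function(off, n) {
    readBin(hdr[(off + 1):(off + n * 4)], "double", n = n, size = 4,
            endian = "little")
  }
  if (peek_i(0, 1, 4) != 348L) stop("not a little-endian NIfTI-1 file: ", path)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path)
  dims <- peek_i(40, 8, 2)
  nd <- dims[1]
  if (!nd %in% c(2L, 3L, 4L)) stop("unsupported dimensionality: ", nd)
  shape <- dims[1 + seq_len(nd)]
  code <- peek_i(70, 1, 2)
  pixdim <- peek_f(76, 8)
  vox_offset <- peek_f(108, 1)
  slope <- peek_f(112, 1); inter <- peek_f(116, 1)
  n <- prod(shape)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  data <- switch(as.character(code),
    "2"  = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE,
                              endian = "little")),
    "4"  = as.numeric(readBin(con, "integer", n = n, size = 2, endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n = n, size = 4, endian = "little")),
    "16" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n = n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code: ", code))
  if (length(data) < n) stop("truncated NIfTI data in ", path)
  if (slope != 0 && !(slope == 1 && inter == 0)) data <- data * slope + inter
  dtname <- c("2" = "uint8", "4" = "int16", "8" = "int32",
              "16" = "float32", "64" = "float64")[[as.character(code)]]
  list(data = array(data, dim = shape),
       voxdim = c(pixdim[2:4], if (nd == 4L) pixdim[5]),
       datatype = dtname)
}
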