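# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# No NIfTI package exists in the supported dependency set, so the fixed
# 348-byte header is handled directly. Supported on read: datatypes uint8,
# int16, int32, float32, float64, either endianness; written data are
# float32 or int32, little-endian, with an sform affine.

nii_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D or 4D array as NIfTI-1
#'
#' @param x numeric or integer array, 3 or 4 dimensions.
#' @param path output path; `.gz` suffix selects gzip compression.
#' @param pixdim voxel sizes (mm) for the spatial dimensions, recycled into
#'   the header and the default affine.
#' @param datatype `"float32"` (default) or `"int32"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, pixdim = c(1, 1, 1),
                        datatype = c("float32", "int32")) {
  datatype <- match.arg(datatype)
  nd <- length(dim(x))
  if (!nd %in% c(3L, 4L)) stop("x must be a 3D or 4D array")
  dims <- rep(1L, 8); dims[1] <- nd; dims[1 + seq_len(nd)] <- dim(x)
  pd <- rep(1, 8); pd[2:4] <- rep(pixdim, length.out = 3)
  dt_code <- if (datatype == "float32") 16L else 8L
  bitpix <- 32L

  con <- nii_con(path, "wb")
  on.exit(close(con))
  w <- function(v, what, size) writeBin(v, con, size = size, endian = "little")
  w(348L, size = 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                              # filler through dim_info
  w(as.integer(dims), size = 2)                       # dim[8]
  w(c(0, 0, 0), size = 4)                             # intent_p1..3 (float)
  w(0L, size = 2)                                     # intent_code
  w(dt_code, size = 2); w(bitpix, size = 2); w(0L, size = 2)  # slice_start
  w(pd, size = 4)                                     # pixdim[8]
  w(352, size = 4)                                    # vox_offset
  w(c(1, 0), size = 4)                                # scl_slope, scl_inter
  w(0L, size = 2); writeBin(raw(2), con)              # slice_end/code/units
  w(c(0, 0, 0, 0), size = 4)                          # cal_max..toffset
  w(c(0L, 0L), size = 4)                              # glmax, glmin
  writeBin(raw(80 + 24), con)                         # descrip, aux_file
  w(c(0L, 1L), size = 2)                              # qform=0, sform=1
  w(c(0, 0, 0, 0, 0, 0), size = 4)                    # quatern, qoffset
  w(c(pd[2], 0, 0, 0), size = 4)                      # srow_x
  w(c(0, pd[3], 0, 0), size = 4)                      # srow_y
  w(c(0, 0, pd[4], 0), size = 4)                      # srow_z
  writeBin(raw(16), con)                              # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)       # magic
  writeBin(raw(4), con)                               # no extensions
  if (datatype == "float32") {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return Numeric (or integer for integer datatypes) array with attributes
#'   `pixdim` and `datatype`.
#' @export
read_nifti <- function(path) {
  con <- nii_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("not a NIfTI-1 file: header too short")
  rd <- function(off, what, n, size, endian) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = TRUE)
  }
  endian <- "little"
  if (rd(0, "integer", 1, 4, "little") != 348L) {
    if (rd(0, "integer", 1, 4, "big") == 348L) endian <- "big"
    else stop("not a NIfTI-1 file: bad sizeof_hdr")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file: bad magic")
  dims <- rd(40, "integer", 8, 2, endian)
  nd <- dims[1]
  if (nd < 1 || nd > 7) stop("unsupported NIfTI dimensionality: ", nd)
  shape <- dims[1 + seq_len(nd)]
  datatype <- rd(70, "integer", 1, 2, endian)
  pixdim <- rd(76, "numeric", 8, 4, endian)
  vox_offset <- rd(108, "numeric", 1, 4, endian)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(shape)
  x <- switch(as.character(datatype),
    "2"  = as.integer(readBin(con, "integer", n, size = 1, signed = FALSE,
                              endian = endian)),
    "4"  = readBin(con, "integer", n, size = 2, endian = endian),
    "8"  = readBin(con, "integer", n, size = 4, endian = endian),
    "16" = readBin(con, "numeric", n, size = 4, endian = endian),
    "64" = readBin(con, "numeric", n, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code: ", datatype))
  if (length(x) < n) stop("truncated NIfTI data section")
  out <- array(x, dim = shape)
  attr(out, "pixdim") <- pixdim[2:(1 + min(nd, 3))]
  attr(out, "datatype") <- datatype
  out
}
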