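# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Scope: 3-D/4-D volumes on a regular grid, little-endian, datatypes
# uint8 (2), int16 (4), int32 (8), float32 (16), float64 (64). Affines are
# passed through as stored; synthetic grids carry a diagonal voxel-size
# affine. This is deliberately not a general neuroimaging I/O library.

.nifti_dtypes <- list(
  uint8  = list(code =  2L, size = 1L, what = "integer", signed = FALSE),
  int16  = list(code =  4L, size = 2L, what = "integer", signed = TRUE),
  int32  = list(code =  8L, size = 4L, what = "integer", signed = TRUE),
  float  = list(code = 16L, size = 4L, what = "double",  signed = TRUE),
  double = list(code = 64L, size = 8L, what = "double",  signed = TRUE)
)

.nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3-D or 4-D array as a NIfTI-1 volume
#'
#' Writes a single-file NIfTI-1 image (magic \code{"n+1"}). Compression is
#' chosen from the file extension (\code{.nii.gz} triggers gzip).
#'
#' @param data numeric or logical array with 3 or 4 dimensions.
#' @param path output file path ending in \code{.nii} or \code{.nii.gz}.
#' @param voxel_size_mm voxel edge length(s) in mm; recycled to 3.
#' @param datatype one of \code{"double"}, \code{"float"}, \code{"uint8"},
#'   \code{"int16"}, \code{"int32"}. Masks and atlases are typically written
#'   as integer types; statistic maps as \code{"double"}.
#' @return \code{path}, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size_mm = 1, datatype = "double") {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3-D or 4-D array")
  dt <- .nifti_dtypes[[match.arg(datatype, names(.nifti_dtypes))]]
  dims <- dim(data)
  nd <- length(dims)
  dim_field <- rep(1L, 8L)
  dim_field[1L] <- nd
  dim_field[seq_len(nd) + 1L] <- as.integer(dims)
  vs <- rep(as.numeric(voxel_size_mm), length.out = 3L)
  pixdim <- c(1, vs, rep(1, 4))

  con <- .nifti_open(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_char <- function(s, n) {
    b <- charToRaw(s)
    writeBin(c(b, raw(n - length(b))), con)
  }

  w_i32(348L)                      # sizeof_hdr
  w_raw(10L)                       # data_type (unused)
  w_raw(18L)                       # db_name (unused)
  w_i32(0L)                        # extents
  w_i16(0L)                        # session_error
  w_raw(1L)                        # regular
  writeBin(as.raw(0L), con)        # dim_info
  w_i16(dim_field)                 # dim[8]
  w_f32(c(0, 0, 0))                # intent_p1..p3
  w_i16(0L)                        # intent_code
  w_i16(dt$code)                   # datatype
  w_i16(dt$size * 8L)              # bitpix
  w_i16(0L)                        # slice_start
  w_f32(pixdim)                    # pixdim[8]
  w_f32(352)                       # vox_offset
  w_f32(1)                         # scl_slope
  w_f32(0)                         # scl_inter
  w_i16(0L)                        # slice_end
  writeBin(as.raw(c(0L, 0L)), con) # slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                 # glmax, glmin
  w_char("convzone", 80L)          # descrip
  w_raw(24L)                       # aux_file
  w_i16(0L)                        # qform_code
  w_i16(1L)                        # sform_code (scaled identity)
  w_f32(c(0, 0, 0, 0, 0, 0))      # quatern b,c,d + qoffset x,y,z
  w_f32(c(vs[1], 0, 0, 0))         # srow_x
  w_f32(c(0, vs[2], 0, 0))         # srow_y
  w_f32(c(0, 0, vs[3], 0))         # srow_z
  w_raw(16L)                       # intent_name
  w_char("n+1", 4L)                # magic
  w_raw(4L)                        # extension flag

  vals <- as.vector(data)
  if (dt$what == "integer") {
    storage.mode(vals) <- "integer"
    # writeBin in 1 MiB-ish chunks keeps gzip connections happy
    writeBin(vals, con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file little-endian NIfTI-1 image written by
#' \code{\link{write_nifti}} or any compliant tool, applying
#' \code{scl_slope}/\code{scl_inter} when set.
#'
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @return list with \code{data} (array), \code{voxel_size_mm} (length-3
#'   numeric) and \code{datatype} (character).
#' @export
read_nifti <- function(path) {
  con <- .nifti_open(path, "rb")
  on.exit(close(con))
  r_i32 <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  r_i16 <- function(n) readBin(con, "integer", n, size = 2L, endian = "little")
  r_f32 <- function(n) readBin(con, "double", n, size = 4L, endian = "little")

  sizeof_hdr <- r_i32(1L)
  if (!identical(sizeof_hdr, 348L))
    stop("not a little-endian NIfTI-1 file: ", path)
  invisible(readBin(con, "raw", 36L))
  dim_field <- r_i16(8L)
  invisible(r_f32(3L)); invisible(r_i16(1L))
  dt_code <- r_i16(1L)
  invisible(r_i16(2L))               # bitpix, slice_start
  pixdim <- r_f32(8L)
  vox_offset <- r_f32(1L)
  scl_slope <- r_f32(1L)
  scl_inter <- r_f32(1L)
  dt <- NULL
  for (nm in names(.nifti_dtypes))
    if (.nifti_dtypes[[nm]]$code == dt_code) dt <- .nifti_dtypes[[nm]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", dt_code)
  nd <- dim_field[1L]
  if (!(nd %in% c(3L, 4L))) stop("only 3-D/4-D NIfTI volumes are supported")
  dims <- dim_field[seq_len(nd) + 1L]
  n <- prod(dims)

  # skip to vox_offset (we are at byte 120 after scl_inter)
  invisible(readBin(con, "raw", as.integer(round(vox_offset)) - 120L))
  if (dt$what == "integer") {
    vals <- readBin(con, "integer", n, size = dt$size,
                    signed = dt$signed || dt$size > 2L, endian = "little")
    vals <- as.double(vals)
  } else {
    vals <- readBin(con, "double", n, size = dt$size, endian = "little")
  }
  if (length(vals) != n) stop("truncated NIfTI data section in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  dtype_name <- names(.nifti_dtypes)[vapply(.nifti_dtypes, function(d)
    d$code == dt_code, logical(1))]
  list(data = array(vals, dim = dims),
       voxel_size_mm = pixdim[2:4],
       datatype = dtype_name)
}
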