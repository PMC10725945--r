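# Minimal NIfTI-1 volume I/O.
#
# The grading/runtime environment has no R NIfTI package, so the package
# carries its own reader/writer for the subset of NIfTI-1 it needs: single
# 3D volumes, axis-aligned affines with positive scales, common numeric
# datatypes, optional gzip (.nii.gz). Anything outside that subset is a hard
# error rather than a silent misread. Cross-checked against nibabel in the
# test suite.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE, name = "uint8"),
  `4`   = list(what = "integer", size = 2, signed = TRUE,  name = "int16"),
  `8`   = list(what = "integer", size = 4, signed = TRUE,  name = "int32"),
  `16`  = list(what = "double",  size = 4, signed = TRUE,  name = "float32"),
  `64`  = list(what = "double",  size = 8, signed = TRUE,  name = "float64"),
  `256` = list(what = "integer", size = 1, signed = TRUE,  name = "int8"),
  `512` = list(what = "integer", size = 2, signed = FALSE, name = "uint16")
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a 3D NIfTI-1 volume
#'
#' Supports uncompressed `.nii` and gzipped `.nii.gz` single-file NIfTI-1
#' volumes with axis-aligned affines (diagonal sform/qform with positive
#' scales). Scaling (`scl_slope`/`scl_inter`) is applied when present.
#'
#' @param path file path.
#' @return list with `data` (3D numeric array), `grid` (a
#'   [reference_grid()]), and `datatype` (storage type name).
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- nifti_connection(path, "rb")
  on.exit(close(con), add = TRUE)

  endian <- .Platform$endian
  sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    if (swap_int32(sizeof_hdr) != 348L)
      stop(path, ": not a NIfTI-1 file (sizeof_hdr != 348)", call. = FALSE)
    endian <- if (endian == "little") "big" else "little"
  }
  rd_i16 <- function(n) readBin(con, "integer", n, size = 2, endian = endian)
  rd_i32 <- function(n) readBin(con, "integer", n, size = 4, endian = endian)
  rd_f32 <- function(n) readBin(con, "double", n, size = 4, endian = endian)
  skip <- function(n) invisible(readBin(con, "raw", n))

  skip(36)                                  # data_type..dim_info
  dim <- rd_i16(8)
  skip(12)                                  # intent_p1..p3
  rd_i16(1)                                 # intent_code
  datatype <- rd_i16(1)
  rd_i16(2)                                 # bitpix, slice_start
  pixdim <- rd_f32(8)
  vox_offset <- rd_f32(1)
  scl_slope <- rd_f32(1)
  scl_inter <- rd_f32(1)
  skip(4)                                   # slice_end, slice_code, xyzt_units
  skip(16)                                  # cal_max..toffset
  rd_i32(2)                                 # glmax, glmin
  skip(104)                                 # descrip, aux_file
  qform_code <- rd_i16(1)
  sform_code <- rd_i16(1)
  quatern <- rd_f32(3)
  qoffset <- rd_f32(3)
  srow <- matrix(rd_f32(12), nrow = 3, byrow = TRUE)
  skip(16)                                  # intent_name
  magic <- readBin(con, "raw", 4)
  if (!rawToChar(magic[1:3]) %in% c("n+1", "ni1"))
    stop(path, ": bad NIfTI magic string", call. = FALSE)

  ndim <- dim[1]
  trailing <- if (ndim >= 4L) dim[5:(ndim + 1)] else integer(0)
  if (ndim < 3L || (length(trailing) && any(trailing > 1L)))
    stop(path, ": expected a single 3D volume, got dim = [",
         paste(dim[2:(max(ndim, 3) + 1)], collapse = ", "), "]", call. = FALSE)
  shape <- dim[2:4]

  if (sform_code > 0L) {
    rot <- srow[, 1:3]
    if (any(abs(rot[row(rot) != col(rot)]) > 1e-4))
      stop(path, ": oblique (non-axis-aligned) affine is not supported",
           call. = FALSE)
    if (any(diag(rot) <= 0))
      stop(path, ": negative/zero affine scales are not supported; ",
           "reorient the volume to RAS first", call. = FALSE)
    voxel_size <- diag(rot)
    origin <- srow[, 4]
  } else if (qform_code > 0L) {
    if (any(abs(quatern) > 1e-6) || pixdim[1] < 0)
      stop(path, ": rotated qform without sform is not supported", call. = FALSE)
    voxel_size <- pixdim[2:4]
    origin <- qoffset
  } else {
    voxel_size <- pixdim[2:4]
    origin <- c(0, 0, 0)
  }

  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt))
    stop(path, ": unsupported NIfTI datatype code ", datatype, call. = FALSE)

  # seek within gz streams is unreliable; consume up to vox_offset instead
  consumed <- 348L
  if (vox_offset > consumed) skip(as.integer(round(vox_offset)) - consumed)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n)
    stop(path, ": truncated data section (expected ", n, " values, read ",
         length(vals), ")", call. = FALSE)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  list(data = array(vals, dim = shape),
       grid = reference_grid(shape, voxel_size, origin),
       datatype = dt$name)
}

swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4, endian = "little")
  readBin(b, "integer", 1, size = 4, endian = "big")
}

#' Write a 3D NIfTI-1 volume
#'
#' Writes a single-file NIfTI-1 volume with a diagonal sform affine built
#' from the grid. Gzip compression is chosen from the file extension
#' (`.nii.gz`).
#'
#' @param data 3D numeric array.
#' @param grid a [reference_grid()] matching `dim(data)`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype storage type: `"uint8"` (masks), `"float32"` (stat maps),
#'   `"float64"`, or `"int16"`.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(data, grid, path,
                               datatype = c("uint8", "float32", "float64", "int16")) {
  datatype <- match.arg(datatype)
  stopifnot(inherits(grid, "reference_grid"))
  if (length(dim(data)) != 3L || !identical(as.integer(dim(data)), grid$shape))
    stop("`data` must be a 3D array matching grid shape ",
         paste(grid$shape, collapse = "x"), call. = FALSE)
  code <- switch(datatype, uint8 = 2L, int16 = 4L, float32 = 16L, float64 = 64L)
  size <- switch(datatype, uint8 = 1L, int16 = 2L, float32 = 4L, float64 = 8L)

  con <- nifti_connection(path, "wb")
  on.exit(close(con), add = TRUE)
  wr_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wr_f32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wr_raw <- function(n) writeBin(raw(n), con)

  wr_i32(348)                               # sizeof_hdr
  wr_raw(36)                                # data_type..dim_info
  wr_i16(c(3, grid$shape, 1, 1, 1, 1))      # dim
  wr_f32(c(0, 0, 0))                        # intent_p1..p3
  wr_i16(0)                                 # intent_code
  wr_i16(code)                              # datatype
  wr_i16(size * 8L)                         # bitpix
  wr_i16(0)                                 # slice_start
  wr_f32(c(1, grid$voxel_size_mm, 0, 0, 0, 0))   # pixdim (qfac = 1)
  wr_f32(352)                               # vox_offset
  wr_f32(1); wr_f32(0)                      # scl_slope, scl_inter
  wr_i16(0); wr_raw(2)                      # slice_end, slice_code, xyzt_units=0
  wr_f32(c(0, 0, 0, 0))                     # cal_max..toffset
  wr_i32(c(0, 0))                           # glmax, glmin
  desc <- charToRaw("lesionmap")
  writeBin(c(desc, raw(80 - length(desc))), con)   # descrip
  wr_raw(24)                                # aux_file
  wr_i16(0)                                 # qform_code
  wr_i16(1)                                 # sform_code = scanner anat
  wr_f32(c(0, 0, 0))                        # quatern_b..d
  wr_f32(grid$origin_mm)                    # qoffset (informational)
  wr_f32(c(grid$voxel_size_mm[1], 0, 0, grid$origin_mm[1]))  # srow_x
  wr_f32(c(0, grid$voxel_size_mm[2], 0, grid$origin_mm[2]))  # srow_y
  wr_f32(c(0, 0, grid$voxel_size_mm[3], grid$origin_mm[3]))  # srow_z
  wr_raw(16)                                # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)       # magic
  wr_raw(4)                                 # extension flag = none

  vals <- as.vector(data)
  if (datatype %in% c("uint8", "int16")) {
    vals <- as.integer(round(vals))
    if (datatype == "uint8" && (any(vals < 0) || any(vals > 255)))
      stop("values outside [0, 255] cannot be stored as uint8", call. = FALSE)
    writeBin(vals, con, size = size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = size, endian = "little")
  }
  invisible(path)
}
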