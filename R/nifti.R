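# Minimal NIfTI-1 I/O.
#
# The deployment environment provides no R NIfTI package, so the package
# carries a small single-file reader/writer for the subset it needs:
# 3D volumes, little-endian, datatypes uint8/int16/int32/float32/float64,
# diagonal affine with the origin at the array corner, optional gzip.
# Round-trips are verified against nibabel in the test suite.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                 float64 = 64L)
NIFTI_BITPIX <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)

pad_char <- function(s, n) {
  r <- raw(n)
  b <- charToRaw(s)
  if (length(b) > n) b <- b[seq_len(n)]
  r[seq_along(b)] <- b
  r
}

#' Write a 3D array as a NIfTI-1 file
#'
#' Writes a single-frame NIfTI-1 volume with an isotropic diagonal affine
#' (sform code 1) whose origin sits at the array corner. Files ending in
#' \code{.gz} are gzip-compressed.
#'
#' @param a 3D numeric or integer array.
#' @param path output path (.nii or .nii.gz).
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param datatype one of "uint8","int16","int32","float32","float64".
#' @return invisibly, the path.
#' @export
write_nifti <- function(a, path, voxel_size_mm,
                        datatype = if (is.integer(a)) "int32" else "float64") {
  stopifnot(is.array(a), length(dim(a)) == 3L)
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)
  bitpix <- NIFTI_BITPIX[[as.character(dt)]]
  d <- dim(a)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_raw <- function(x) writeBin(x, con)

  w_i32(348L)                                   # sizeof_hdr
  w_raw(raw(10 + 18))                           # data_type, db_name
  w_i32(0L); w_i16(0L); w_raw(raw(2))           # extents, session_error, regular, dim_info
  w_i16(c(3L, d, 1L, 1L, 1L, 1L))               # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)                  # intent_p*, intent_code
  w_i16(dt); w_i16(bitpix); w_i16(0L)           # datatype, bitpix, slice_start
  w_f32(c(1, rep(voxel_size_mm, 3), 1, 1, 1, 1))# pixdim[8]
  w_f32(352); w_f32(1); w_f32(0)                # vox_offset, scl_slope, scl_inter
  w_i16(0L); w_raw(raw(1))                      # slice_end, slice_code
  w_raw(as.raw(2L))                             # xyzt_units: mm
  w_f32(c(0, 0, 0, 0)); w_i32(c(0L, 0L))        # cal/slice_duration/toffset, glmax/glmin
  w_raw(pad_char("petlong", 80))                # descrip
  w_raw(raw(24))                                # aux_file
  w_i16(0L); w_i16(1L)                          # qform_code, sform_code
  w_f32(rep(0, 6))                              # quatern, qoffset
  w_f32(c(voxel_size_mm, 0, 0, 0))              # srow_x
  w_f32(c(0, voxel_size_mm, 0, 0))              # srow_y
  w_f32(c(0, 0, voxel_size_mm, 0))              # srow_z
  w_raw(raw(16))                                # intent_name
  w_raw(pad_char("n+1", 4))                     # magic
  w_raw(raw(4))                                 # extension flag

  v <- as.vector(a)
  if (dt %in% c(2L, 4L, 8L)) {
    writeBin(as.integer(v), con, size = bitpix / 8, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = bitpix / 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by this package (or compatible)
#'
#' Supports 3D little-endian volumes with datatypes
#' uint8/int16/int32/float32/float64 and applies scl scaling when set.
#'
#' @param path .nii or .nii.gz path.
#' @return list with \code{data} (3D array), \code{voxel_size_mm}.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  r_i32 <- function(off) readBin(hdr[off + 1:4], "integer", size = 4,
                                 endian = "little")
  r_i16 <- function(off, n = 1) readBin(hdr[off + seq_len(2 * n)], "integer",
                                        size = 2, n = n, endian = "little")
  r_f32 <- function(off, n = 1) readBin(hdr[off + seq_len(4 * n)], "numeric",
                                        size = 4, n = n, endian = "little")
  if (r_i32(0) != 348L)
    stop("not a little-endian NIfTI-1 file (sizeof_hdr != 348)")
  dims <- r_i16(40, 8)
  ndim <- dims[1]
  if (ndim < 3) stop("expected a 3D volume")
  d <- dims[2:4]
  if (ndim > 3 && any(dims[5:(ndim + 1)] > 1))
    stop("only single-frame 3D volumes are supported")
  dt <- r_i16(70)
  pixdim <- r_f32(76, 8)
  vox_offset <- r_f32(108)
  scl_slope <- r_f32(112); scl_inter <- r_f32(116)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  v <- switch(as.character(dt),
    `2`  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    `4`  = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    `8`  = as.numeric(readBin(con, "integer", n, size = 4, endian = "little")),
    `16` = readBin(con, "numeric", n, size = 4, endian = "little"),
    `64` = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code: ", dt))
  if (length(v) != n) stop("truncated NIfTI data section")
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  list(data = array(v, dim = d), voxel_size_mm = pixdim[2])
}

#' Write a LabelVolume as NIfTI plus JSON sidecar
#'
#' The integer segmentation goes to \code{<stem>.nii.gz}; the label
#' dictionary (and truth table, if supplied) to \code{<stem>.json}.
#'
#' @param lv LabelVolume.
#' @param stem output path without extension.
#' @param truth optional named list/vector of per-label true activities.
#' @return invisibly, the two paths.
#' @export
write_label_volume <- function(lv, stem, truth = NULL) {
  stopifnot(inherits(lv, "LabelVolume"))
  nii <- paste0(stem, ".nii.gz")
  js <- paste0(stem, ".json")
  write_nifti(lv$labels, nii, lv$voxel_size_mm, datatype = "int32")
  side <- list(label_map = as.list(lv$label_map),
               voxel_size_mm = lv$voxel_size_mm)
  if (!is.null(truth)) side$true_activity <- as.list(truth)
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(nii, js))
}

#' Read a LabelVolume written by \code{write_label_volume}
#'
#' @param stem path without extension.
#' @return list with \code{label_volume} and (if present) \code{true_activity}.
#' @export
read_label_volume <- function(stem) {
  nii <- read_nifti(paste0(stem, ".nii.gz"))
  side <- jsonlite::read_json(paste0(stem, ".json"))
  lm <- unlist(side$label_map)
  lv <- label_volume(array(as.integer(nii$data), dim = dim(nii$data)),
                     nii$voxel_size_mm, lm)
  out <- list(label_volume = lv)
  if (!is.null(side$true_activity))
    out$true_activity <- unlist(side$true_activity)
  out
}

#' Write an ActivityVolume as NIfTI
#' @param img ActivityVolume.
#' @param path .nii or .nii.gz output path.
#' @return invisibly, the path.
#' @export
write_activity_volume <- function(img, path) {
  stopifnot(inherits(img, "ActivityVolume"))
  write_nifti(img$values, path, img$voxel_size_mm, datatype = "float64")
}

#' Read an ActivityVolume from NIfTI
#' @param path .nii or .nii.gz path.
#' @return ActivityVolume.
#' @export
read_activity_volume <- function(path) {
  x <- read_nifti(path)
  activity_volume(x$data, x$voxel_size_mm)
}
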