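# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# Only the subset needed to round-trip the pipeline's volumes is supported:
# 3D images, datatypes uint8 / int16 / int32 / float32 / float64, spacing in
# pixdim with an sform diag affine. No R NIfTI reader is assumed installed.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE)
)

#' Write a 3D volume as NIfTI-1
#'
#' @param data 3D numeric (or 0/1 integer) array with dims `(nx, ny, nz)`.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param spacing per-axis voxel size in mm, length 3.
#' @param datatype `"float32"` (default) or `"uint8"` (masks).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1), datatype = "float32") {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L, all(spacing > 0))
  code <- switch(datatype, float32 = 16L, uint8 = 2L,
                 stopf("unsupported datatype '%s'", datatype))
  bitpix <- switch(datatype, float32 = 32L, uint8 = 8L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                            # sizeof_hdr
  writeBin(raw(36), con)                                   # unused
  writeBin(as.integer(c(3L, dim(data), 1L, 1L, 1L, 1L)), con, size = 2) # dim
  writeBin(raw(14), con)                                   # intent_p*, intent_code
  writeBin(as.integer(c(code, bitpix, 0L)), con, size = 2) # datatype, bitpix, slice_start
  writeBin(c(1, spacing, 1, 1, 1, 1), con, size = 4)       # pixdim (qfac first)
  writeBin(352, con, size = 4)                             # vox_offset
  writeBin(c(1, 0, 0), con, size = 4)                      # scl_slope, scl_inter, slice_end+codes
  writeBin(raw(24), con)                                   # cal_max..glmin
  writeBin(raw(104), con)                                  # descrip + aux_file
  writeBin(as.integer(c(0L, 1L)), con, size = 2)           # qform_code=0, sform_code=1
  writeBin(rep(0, 6), con, size = 4)                       # quatern
  writeBin(c(spacing[1], 0, 0, 0), con, size = 4)          # srow_x
  writeBin(c(0, spacing[2], 0, 0), con, size = 4)          # srow_y
  writeBin(c(0, 0, spacing[3], 0), con, size = 4)          # srow_z
  writeBin(raw(16), con)                                   # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)            # magic
  writeBin(raw(4), con)                                    # extension flag
  if (datatype == "uint8") {
    writeBin(as.integer(round(data)), con, size = 1)
  } else {
    writeBin(as.numeric(data), con, size = 4)
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()] (or compatible)
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return a [volume3d()] with the stored spacing.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348 || readBin(hdr[1:4], "integer", 1, 4) != 348L)
    stopf("'%s' is not a NIfTI-1 file (bad header size)", path)
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1") stopf("'%s' is not single-file NIfTI-1 (magic '%s')", path, magic)
  dims <- readBin(hdr[41:56], "integer", 8, 2)
  if (dims[1] < 3L) stopf("'%s': expected a 3D image", path)
  nd <- dims[2:4]
  dtype <- readBin(hdr[71:72], "integer", 1, 2)
  spec <- NIFTI_DTYPES[[as.character(dtype)]]
  if (is.null(spec)) stopf("'%s': unsupported NIfTI datatype code %d", path, dtype)
  pixdim <- readBin(hdr[77:108], "double", 8, 4)
  vox_offset <- readBin(hdr[109:112], "double", 1, 4)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(nd)
  vals <- readBin(con, spec$what, n, size = spec$size, signed = spec$signed)
  if (length(vals) != n) stopf("'%s': truncated voxel data", path)
  volume3d(array(as.numeric(vals), dim = nd), spacing = pixdim[2:4])
}
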