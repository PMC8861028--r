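# Minimal NIfTI-1 support: single-file .nii / .nii.gz, 3-D, little-endian on
# write, either endianness on read. Intensities are stored as signed 16-bit
# integers (datatype 4), which covers the AU range used here; spacing lives
# in pixdim and is mirrored into an identity-direction sform.

NIFTI_DT <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE)
)

write_nifti <- function(volume, path) {
  d <- dim(volume)
  h <- volume$spacing
  vals <- round(volume$intensities)
  if (any(vals < -32768 | vals > 32767)) {
    stop_tarsalct("intensities exceed the signed 16-bit range", "format")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wc <- function(s, len) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(len - length(raw_s))), con)
  }
  wi(348L, 4)                       # sizeof_hdr
  writeBin(raw(36), con)            # data_type, db_name, extents, session_error, regular, dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)   # dim[8]
  wf(c(0, 0, 0))                    # intent_p1..3
  wi(0L, 2)                         # intent_code
  wi(4L, 2)                         # datatype: int16
  wi(16L, 2)                        # bitpix
  wi(0L, 2)                         # slice_start
  wf(c(1, h, 0, 0, 0, 0))           # pixdim[8]
  wf(352)                           # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0L, 2)                         # slice_end
  writeBin(as.raw(c(0L, 2L)), con)  # slice_code, xyzt_units (mm)
  wf(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                  # glmax, glmin
  wc("tarsalct", 80)                # descrip
  writeBin(raw(24), con)            # aux_file
  wi(0L, 2)                         # qform_code
  wi(1L, 2)                         # sform_code
  wf(c(0, 0, 0))                    # quatern b, c, d
  wf(c(0, 0, 0))                    # qoffset x, y, z
  wf(c(h[1], 0, 0, 0))              # srow_x
  wf(c(0, h[2], 0, 0))              # srow_y
  wf(c(0, 0, h[3], 0))              # srow_z
  writeBin(raw(16), con)            # intent_name
  wc("n+1", 4)                      # magic
  writeBin(raw(4), con)             # extension flag
  writeBin(as.integer(vals), con, size = 2L, endian = "little")
  invisible(path)
}

read_nifti <- function(path) {
  con <- gzfile(path, "rb") # reads plain files too
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop_tarsalct("file too short for a NIfTI-1 header", "format")
  rd_i <- function(off, size, n = 1L, endian) {
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size, endian = endian)
  }
  rd_f <- function(off, n = 1L, endian) {
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L, endian = endian)
  }
  endian <- "little"
  if (rd_i(0L, 4L, endian = endian) != 348L) {
    endian <- "big"
    if (rd_i(0L, 4L, endian = endian) != 348L) {
      stop_tarsalct("not a NIfTI-1 file (bad sizeof_hdr)", "format")
    }
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop_tarsalct("not a NIfTI-1 file (bad magic)", "format")
  }
  dim8 <- rd_i(40L, 2L, 8L, endian)
  if (dim8[1] < 3L) stop_tarsalct("volume must be 3-D", "format")
  d <- dim8[2:4]
  if (any(dim8[5:8] > 1L)) stop_tarsalct("only single-frame 3-D volumes are supported", "format")
  datatype <- rd_i(70L, 2L, 1L, endian)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) {
    stop_tarsalct(sprintf("unsupported NIfTI datatype %d", datatype), "format")
  }
  pixdim <- rd_f(76L, 8L, endian)
  spacing <- abs(pixdim[2:4])
  if (any(spacing <= 0)) stop_tarsalct("NIfTI header carries no positive spacing", "metadata")
  vox_offset <- rd_f(108L, 1L, endian)
  scl_slope <- rd_f(112L, 1L, endian)
  scl_inter <- rd_f(116L, 1L, endian)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  n <- prod(d)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed, endian = endian)
  if (length(vals) < n) stop_tarsalct("truncated NIfTI data section", "format")
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  voxel_volume(array(as.numeric(vals), d), spacing = spacing)
}
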