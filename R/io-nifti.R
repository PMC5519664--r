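# Minimal NIfTI-1 reader/writer (single .nii files, little-endian written,
# either endianness read). No NIfTI package exists in the supported stack,
# so the 348-byte header is handled directly. Velocity fields are stored
# as dim = [nx, ny, nz, nt, 3] float64 with intent code 1007 (vector);
# scalar volumes and masks as 3-D volumes. Spacing is written in mm
# (xyzt_units = mm | sec), the affine in srow_*, venc in descrip.

NIFTI_DT <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                 `4` = list(what = "integer", size = 2, signed = TRUE),
                 `8` = list(what = "integer", size = 4, signed = TRUE),
                 `16` = list(what = "double", size = 4, signed = TRUE),
                 `64` = list(what = "double", size = 8, signed = TRUE),
                 `256` = list(what = "integer", size = 1, signed = TRUE),
                 `512` = list(what = "integer", size = 2, signed = FALSE))

write_nifti_raw <- function(path, data_dims, pixdim, origin, payload,
                            intent_code = 0L, descrip = "", toffset = 0) {
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, len) {
    raw_s <- charToRaw(as.character(s))
    if (length(raw_s) > len) raw_s <- raw_s[seq_len(len)]
    writeBin(c(raw_s, raw(len - length(raw_s))), con)
  }
  ndim <- length(data_dims)
  dim8 <- rep(1L, 8)
  dim8[1] <- ndim
  dim8[1 + seq_len(ndim)] <- data_dims
  pd8 <- rep(0, 8)
  pd8[1] <- 1                      # qfac
  pd8[2:4] <- pixdim[1:3]          # mm
  if (length(pixdim) >= 4) pd8[5] <- pixdim[4]  # s
  wi(348, 4)                       # sizeof_hdr
  wc("", 10); wc("", 18)           # data_type, db_name (unused)
  wi(0, 4); wi(0, 2); wc("", 1); wc("r", 1)  # extents, session_error, regular, dim_info
  wi(dim8, 2)
  wf(c(0, 0, 0))                   # intent_p1..p3
  wi(intent_code, 2)
  wi(64, 2)                        # datatype: float64
  wi(64, 2)                        # bitpix
  wi(0, 2)                         # slice_start
  writeBin(pd8, con, size = 4, endian = "little")
  wf(352)                          # vox_offset
  wf(1); wf(0)                     # scl_slope, scl_inter
  wi(0, 2); wc("", 1)              # slice_end, slice_code
  writeBin(as.raw(bitwOr(2L, 8L)), con)  # xyzt_units: mm | sec
  wf(0); wf(0)                     # cal_max, cal_min
  wf(0); wf(toffset)               # slice_duration, toffset
  wi(0, 4); wi(0, 4)               # glmax, glmin
  wc(descrip, 80); wc("", 24)      # descrip, aux_file
  wi(0, 2); wi(1, 2)               # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))          # quatern b,c,d + qoffset x,y,z
  wf(c(pixdim[1], 0, 0, origin[1]))
  wf(c(0, pixdim[2], 0, origin[2]))
  wf(c(0, 0, pixdim[3], origin[3]))
  wc("", 16)                       # intent_name
  wc("n+1", 4)                     # magic (writeBin-padded with NUL)
  writeBin(raw(4), con)            # extension flag
  writeBin(as.numeric(payload), con, size = 8, endian = "little")
  invisible(path)
}

read_nifti_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- "little"
  if (sz != 348L) {
    endian <- "big"
    seek(con, 0)
    sz <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (sz != 348L)
      stop_flow4d("not a NIfTI-1 file (bad sizeof_hdr)", "flow4d_format_error")
  }
  ri <- function(n, size) readBin(con, "integer", n, size = size, endian = endian)
  rf <- function(n, size = 4) readBin(con, "double", n, size = size, endian = endian)
  readBin(con, "raw", 36)                       # unused + dim_info
  dim8 <- ri(8, 2)
  rf(3)                                          # intent_p
  intent_code <- ri(1, 2)
  datatype <- ri(1, 2)
  ri(1, 2); ri(1, 2)                             # bitpix, slice_start
  pd8 <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  ri(1, 2); readBin(con, "raw", 1)               # slice_end, slice_code
  xyzt <- as.integer(readBin(con, "raw", 1))
  rf(3)                                          # cal_max, cal_min, slice_duration
  toffset <- rf(1)
  ri(2, 4)                                       # glmax glmin
  descrip <- readBin(con, "raw", 80)
  readBin(con, "raw", 24)
  ri(1, 2)                                       # qform_code
  sform_code <- ri(1, 2)
  rf(6)
  srow <- matrix(rf(12), nrow = 3, byrow = TRUE)
  readBin(con, "raw", 16)
  magic <- rawToChar(readBin(con, "raw", 4)[1:3])
  if (!magic %in% c("n+1", "ni1"))
    stop_flow4d("not a NIfTI-1 file (bad magic)", "flow4d_format_error")
  ndim <- dim8[1]
  dims <- dim8[1 + seq_len(ndim)]
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt))
    stop_flow4d(sprintf("unsupported NIfTI datatype %d", datatype),
                "flow4d_format_error")
  seek(con, vox_offset)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n)
    stop_flow4d("NIfTI payload truncated", "flow4d_format_error")
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  spacing <- pd8[2:4]
  # spatial unit conversion to mm: 1 = m, 2 = mm, 3 = um
  sp_unit <- bitwAnd(xyzt, 7L)
  spacing <- spacing * switch(as.character(sp_unit), `1` = 1000, `2` = 1,
                              `3` = 0.001, 1)
  if (any(spacing <= 0))
    stop_flow4d("NIfTI header has no positive voxel spacing",
                "flow4d_metadata_error")
  origin <- c(0, 0, 0)
  if (sform_code > 0) origin <- srow[, 4]
  descrip <- rawToChar(descrip[descrip != as.raw(0)])
  list(dims = dims, data = array(vals, dim = dims), spacing = spacing,
       origin = origin, dt = pd8[5], toffset = toffset,
       intent_code = intent_code, descrip = descrip)
}
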