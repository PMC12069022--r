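# Minimal NIfTI-1 / NIfTI-2 reader and NIfTI-1 writer.
#
# No NIfTI package is available in the target library, so the (simple,
# fixed-layout) binary headers are handled directly with readBin/writeBin.
# Reading supports both header versions, plain and gzip files, little and big
# endianness, the common scalar datatypes, scl_slope/scl_inter scaling, and
# sform/qform affines.  Writing emits little-endian NIfTI-1 with an sform:
# float64 data for volumes (lossless round-trip) and uint8 for masks.
# Affines survive a round-trip only to float32 precision (the NIfTI-1 srow
# fields are 32-bit), i.e. to ~1e-6 for coordinates of order 10 mm.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

#' Read a NIfTI image
#'
#' @param path path to a `.nii` or `.nii.gz` file (NIfTI-1 or NIfTI-2).
#' @return An [as_volume()] object.  The affine is taken from the sform if
#'   set, else from the qform, else a diagonal pixdim affine; the axial axis
#'   is the grid axis closest to the world inferior-superior direction.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path))
    lcseg_error("lcseg_io_error", sprintf("file not found: %s", path))
  con <- gzfile(path, "rb")
  on.exit(close(con))
  head4 <- readBin(con, "raw", 4L)
  if (length(head4) < 4L)
    lcseg_error("lcseg_io_error", sprintf("not a NIfTI file: %s", path))
  sz_le <- readBin(head4, "integer", 1L, 4L, endian = "little")
  endian <- "little"
  if (sz_le %in% c(348L, 540L)) {
    hdr_size <- sz_le
  } else {
    sz_be <- readBin(head4, "integer", 1L, 4L, endian = "big")
    if (!sz_be %in% c(348L, 540L))
      lcseg_error("lcseg_io_error", sprintf("not a NIfTI file: %s", path))
    hdr_size <- sz_be
    endian <- "big"
  }
  hdr <- c(head4, readBin(con, "raw", hdr_size - 4L))
  if (hdr_size == 348L) info <- parse_nifti1(hdr, endian)
  else info <- parse_nifti2(hdr, endian)

  ndim <- info$dim[1]
  shape <- info$dim[2:(1 + max(ndim, 1))]
  if (ndim > 3L && any(info$dim[5:(1 + ndim)] > 1L))
    lcseg_error("lcseg_format_error",
                sprintf("only 3-D scalar images are supported (dim = %s)",
                        paste(info$dim[2:(1 + ndim)], collapse = "x")))
  shape <- c(shape, 1L, 1L)[1:3]
  dt <- NIFTI_DT[[as.character(info$datatype)]]
  if (is.null(dt))
    lcseg_error("lcseg_format_error",
                sprintf("unsupported NIfTI datatype code %d", info$datatype))
  skip <- info$vox_offset - hdr_size
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (length(vals) < n)
    lcseg_error("lcseg_io_error", sprintf("truncated NIfTI data in %s", path))
  vals <- as.double(vals)
  if (!is.na(info$scl_slope) && info$scl_slope != 0 &&
      !(info$scl_slope == 1 && info$scl_inter == 0))
    vals <- vals * info$scl_slope + info$scl_inter
  as_volume(array(vals, shape), voxel_size = abs(info$pixdim[2:4]),
            affine = info$affine)
}

parse_nifti1 <- function(hdr, endian) {
  i16 <- function(off, n = 1L) readBin(hdr[(off + 1):(off + 2 * n)], "integer",
                                       n, 2L, endian = endian)
  f32 <- function(off, n = 1L) readBin(hdr[(off + 1):(off + 4 * n)], "double",
                                       n, 4L, endian = endian)
  dim <- i16(40, 8)
  pixdim <- f32(76, 8)
  sform_code <- i16(254)
  qform_code <- i16(252)
  affine <- NULL
  if (sform_code > 0) {
    affine <- rbind(f32(280, 4), f32(296, 4), f32(312, 4), c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    affine <- quaternion_affine(f32(256, 3), f32(268, 3), pixdim)
  }
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- abs(pixdim[2:4])
  }
  list(dim = dim, datatype = i16(70), pixdim = pixdim,
       vox_offset = as.integer(f32(108)), scl_slope = f32(112),
       scl_inter = f32(116), affine = affine)
}

parse_nifti2 <- function(hdr, endian) {
  i64 <- function(off, n = 1L) {
    # readBin has no int64; read as two int32 halves
    lo_off <- if (endian == "little") 0L else 4L
    hi_off <- 4L - lo_off
    sapply(seq_len(n) - 1L, function(k) {
      lo <- readBin(hdr[(off + 8 * k + lo_off + 1):(off + 8 * k + lo_off + 4)],
                    "integer", 1L, 4L, endian = endian)
      hi <- readBin(hdr[(off + 8 * k + hi_off + 1):(off + 8 * k + hi_off + 4)],
                    "integer", 1L, 4L, endian = endian)
      if (lo < 0) lo <- lo + 2^32
      hi * 2^32 + lo
    })
  }
  i16 <- function(off) readBin(hdr[(off + 1):(off + 2)], "integer", 1L, 2L,
                               endian = endian)
  i32 <- function(off) readBin(hdr[(off + 1):(off + 4)], "integer", 1L, 4L,
                               endian = endian)
  f64 <- function(off, n = 1L) readBin(hdr[(off + 1):(off + 8 * n)], "double",
                                       n, 8L, endian = endian)
  dim <- i64(16, 8)
  pixdim <- f64(104, 8)
  sform_code <- i32(348)
  qform_code <- i32(344)
  affine <- NULL
  if (sform_code > 0) {
    affine <- rbind(f64(400, 4), f64(432, 4), f64(464, 4), c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    affine <- quaternion_affine(f64(352, 3), f64(376, 3), pixdim)
  }
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- abs(pixdim[2:4])
  }
  list(dim = dim, datatype = i16(12), pixdim = pixdim,
       vox_offset = i64(168), scl_slope = f64(176), scl_inter = f64(184),
       affine = affine)
}

quaternion_affine <- function(bcd, offset, pixdim) {
  b <- bcd[1]; c <- bcd[2]; d <- bcd[3]
  a2 <- 1 - b^2 - c^2 - d^2
  a <- if (a2 < 0) 0 else sqrt(a2)
  R <- matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d),   2 * (b * d - a * c),
    2 * (b * c - a * d),   a^2 + c^2 - b^2 - d^2, 2 * (c * d + a * b),
    2 * (b * d + a * c),   2 * (c * d - a * b),   a^2 + d^2 - b^2 - c^2
  ), 3, 3)
  qfac <- if (pixdim[1] < 0) -1 else 1
  S <- diag(c(abs(pixdim[2]), abs(pixdim[3]), qfac * abs(pixdim[4])))
  rbind(cbind(R %*% S, offset), c(0, 0, 0, 1))
}

#' Write a volume or mask as NIfTI-1
#'
#' Volumes are written as float64 (bit-exact round-trip); masks as uint8.
#' The affine is stored in the sform (float32 fields).  Gzip compression is
#' selected by a `.gz` suffix.
#'
#' @param x an `lc_volume` or `lc_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  if (!inherits(x, c("lc_volume", "lc_mask")))
    lcseg_error("lcseg_argument_error", "x must be an lc_volume or lc_mask")
  is_mask <- inherits(x, "lc_mask")
  con <- tryCatch(
    if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb"),
    error = function(e) lcseg_error("lcseg_io_error", conditionMessage(e)),
    warning = function(w) lcseg_error("lcseg_io_error", conditionMessage(w)))
  on.exit(close(con))
  shape <- dim(x$data)
  wi16 <- function(v) writeBin(as.integer(v), con, 2L, endian = "little")
  wi32 <- function(v) writeBin(as.integer(v), con, 4L, endian = "little")
  wf32 <- function(v) writeBin(as.double(v), con, 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi32(348)                       # sizeof_hdr
  wraw(36)                        # data_type..dim_info
  wi16(c(3, shape, 1, 1, 1, 1))   # dim
  wf32(c(0, 0, 0))                # intent_p1..3
  wi16(0)                         # intent_code
  wi16(if (is_mask) 2 else 64)    # datatype: uint8 / float64
  wi16(if (is_mask) 8 else 64)    # bitpix
  wi16(0)                         # slice_start
  wf32(c(1, x$voxel_size, 1, 1, 1, 1))  # pixdim (qfac = 1)
  wf32(352)                       # vox_offset
  wf32(1); wf32(0)                # scl_slope, scl_inter
  wi16(0); wraw(1)                # slice_end, slice_code
  writeBin(as.raw(2L), con)       # xyzt_units: mm
  wf32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  wi32(c(0, 0))                   # glmax, glmin
  wraw(80 + 24)                   # descrip, aux_file
  wi16(0); wi16(2)                # qform_code, sform_code (aligned)
  wf32(c(0, 0, 0))                # quatern b, c, d
  wf32(c(0, 0, 0))                # qoffset
  wf32(x$affine[1, ]); wf32(x$affine[2, ]); wf32(x$affine[3, ])
  wraw(16)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)
  wraw(4)                         # extension flag
  if (is_mask) writeBin(as.raw(as.integer(x$data)), con)
  else writeBin(as.double(x$data), con, 8L, endian = "little")
  invisible(path)
}
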