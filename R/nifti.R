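# NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only the header fields a desk-scale quantification tool needs are handled:
# dims, datatype, pixdim, scl_slope/scl_inter, and the sform/qform affine.
# NIfTI stores world coordinates in RAS; the package convention is LPS, so the
# first two affine rows are negated at this boundary. gzip is detected from
# the magic bytes, not the file name, so .nii files that are secretly
# compressed still read.

NIFTI_TYPES <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2, signed = FALSE), # uint16
  `256` = list(what = "integer", size = 1, signed = TRUE)   # int8
)

open_maybe_gz <- function(path, mode = "rb") {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", 2)
  close(con)
  if (length(magic) == 2 && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b))
    gzfile(path, mode)
  else
    file(path, mode)
}

read_nifti <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con), add = TRUE)
  endian <- "little"
  hdr_raw <- readBin(con, "raw", 348)
  if (length(hdr_raw) < 348)
    stop("not a NIfTI-1 file (truncated header): ", path, call. = FALSE)
  rd <- function(what, n, size, off) {
    readBin(hdr_raw[(off + 1):length(hdr_raw)], what, n = n, size = size,
            endian = endian)
  }
  sizeof_hdr <- rd("integer", 1, 4, 0)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- rd("integer", 1, 4, 0)
    if (sizeof_hdr != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path, call. = FALSE)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path, call. = FALSE)
  if (magic == "ni1")
    stop("two-file NIfTI (.hdr/.img) is not supported: ", path, call. = FALSE)

  dims <- rd("integer", 8, 2, 40)
  ndim <- dims[1]
  nd <- dims[2:8]
  extra <- if (ndim > 3) nd[4:ndim] else integer(0)
  if (ndim < 3 || (length(extra) && any(extra > 1)))
    stop("expected a 3D image, got ", ndim, "D: ", path, call. = FALSE)
  dim3 <- nd[1:3]

  datatype <- rd("integer", 1, 2, 70)
  tinfo <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(tinfo))
    stop("unsupported NIfTI datatype code ", datatype, ": ", path,
         call. = FALSE)
  pixdim <- rd("double", 8, 4, 76)
  vox_offset <- rd("double", 1, 4, 108)
  scl_slope <- rd("double", 1, 4, 112)
  scl_inter <- rd("double", 1, 4, 116)
  qform_code <- rd("integer", 1, 2, 252)
  sform_code <- rd("integer", 1, 2, 254)
  quat <- rd("double", 6, 4, 256)       # quatern_b,c,d + qoffset x,y,z
  srow <- matrix(rd("double", 12, 4, 280), nrow = 3, byrow = TRUE)

  if (sform_code > 0) {
    A <- srow                            # 3x4 RAS affine
  } else if (qform_code > 0) {
    b <- quat[1]; c <- quat[2]; d <- quat[3]
    a2 <- 1 - b * b - c * c - d * d
    a <- if (a2 < 0) 0 else sqrt(a2)
    R <- matrix(c(
      a * a + b * b - c * c - d * d, 2 * (b * c - a * d), 2 * (b * d + a * c),
      2 * (b * c + a * d), a * a + c * c - b * b - d * d, 2 * (c * d - a * b),
      2 * (b * d - a * c), 2 * (c * d + a * b), a * a + d * d - b * b - c * c),
      3, 3, byrow = TRUE)
    qfac <- if (pixdim[1] %in% c(-1, 1)) pixdim[1] else 1
    S <- diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
    A <- cbind(R %*% S, quat[4:6])
  } else {
    A <- cbind(diag(pixdim[2:4]), c(0, 0, 0))
  }
  # RAS -> LPS: negate the x and y world rows
  A[1, ] <- -A[1, ]
  A[2, ] <- -A[2, ]
  spacing <- sqrt(colSums(A[, 1:3]^2))
  if (any(spacing <= 0))
    stop("degenerate voxel spacing in header: ", path, call. = FALSE)
  direction <- sweep(A[, 1:3], 2, spacing, "/")
  origin <- A[, 4]

  nvox <- prod(dim3)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  vals <- readBin(con, tinfo$what, n = nvox, size = tinfo$size,
                  signed = tinfo$signed, endian = endian)
  if (length(vals) < nvox)
    stop("truncated NIfTI voxel data: ", path, call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  image_volume(array(vals, dim3), spacing = spacing, origin = origin,
               direction = direction)
}

nifti_datatype_for <- function(data) {
  if (is.integer(data) || isTRUE(all(data == round(data)))) {
    rng <- range(data)
    if (rng[1] >= 0 && rng[2] <= 255) return(list(code = 2L, size = 1L,
                                                  what = "integer"))
    if (rng[1] >= -32768 && rng[2] <= 32767) return(list(code = 4L, size = 2L,
                                                         what = "integer"))
    if (rng[1] >= -2^31 && rng[2] < 2^31) return(list(code = 8L, size = 4L,
                                                      what = "integer"))
  }
  list(code = 64L, size = 8L, what = "double")
}

write_nifti <- function(vol, path) {
  stopifnot_volume(vol)
  dt <- nifti_datatype_for(vol$data)
  # LPS -> RAS affine
  A <- cbind(vol$direction %*% diag(vol$spacing), vol$origin)
  A[1, ] <- -A[1, ]
  A[2, ] <- -A[2, ]

  hdr <- raw(348)
  put <- function(hdr, value, what, size, off) {
    b <- writeBin(value, raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 348L, "integer", 4, 0)
  hdr <- put(hdr, as.integer(c(3, dim(vol$data), 1, 1, 1, 1)), "integer", 2, 40)
  hdr <- put(hdr, dt$code, "integer", 2, 70)
  bitpix <- as.integer(dt$size * 8)
  hdr <- put(hdr, bitpix, "integer", 2, 72)
  hdr <- put(hdr, c(1, vol$spacing, 1, 1, 1, 1), "double", 4, 76)
  hdr <- put(hdr, 352, "double", 4, 108)        # vox_offset
  hdr <- put(hdr, c(1, 0), "double", 4, 112)    # scl_slope, scl_inter
  hdr <- put(hdr, c(0L, 1L), "integer", 2, 252) # qform_code=0, sform_code=1
  hdr <- put(hdr, as.numeric(t(A)), "double", 4, 280)
  magic <- c(charToRaw("n+1"), as.raw(0))
  hdr[345:348] <- magic

  gz <- grepl("\\.gz$", path)
  con <- tryCatch(
    if (gz) gzfile(path, "wb") else file(path, "wb"),
    error = function(e) stop("cannot open for writing: ", path, call. = FALSE),
    warning = function(w) stop("cannot open for writing: ", path,
                               call. = FALSE))
  on.exit(close(con), add = TRUE)
  writeBin(hdr, con)
  writeBin(raw(4), con)                          # extension flag
  vals <- as.vector(vol$data)
  if (dt$what == "integer") vals <- as.integer(round(vals))
  writeBin(vals, con, size = dt$size, endian = "little")
  invisible(path)
}
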