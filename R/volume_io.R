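#' Read a 3D volume from NIfTI-1 or NRRD
#'
#' Dispatches on file extension (`.nii`, `.nii.gz`, `.nrrd`, `.nhdr`).
#' World metadata is returned in the package's internal convention:
#' LPS millimetres, voxel centers, 0-based indices.
#'
#' @param path path to an existing NIfTI or NRRD file.
#' @return An [image_volume].
#' @export
read_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("'path' must be a single file path", call. = FALSE)
  if (!file.exists(path))
    stop("file does not exist: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    read_nifti(path)
  } else if (grepl("\\.(nrrd|nhdr)$", lower)) {
    read_nrrd(path)
  } else {
    # sniff: NRRD is self-identifying, NIfTI by sizeof_hdr/magic
    head4 <- readBin(path, "raw", 8)
    if (length(head4) >= 4 && rawToChar(head4[1:4]) == "NRRD")
      read_nrrd(path)
    else
      read_nifti(path)
  }
}

#' Write a 3D volume to NIfTI-1 or NRRD
#'
#' Format chosen from the extension. Integer data (labels, masks) are stored
#' bit-exactly in the narrowest integer type that fits; everything else is
#' written as float64.
#'
#' @param vol an [image_volume].
#' @param path destination ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot_volume(vol)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    write_nifti(vol, path)
  } else if (grepl("\\.(nrrd|nhdr)$", lower)) {
    write_nrrd(vol, path)
  } else {
    stop("unsupported output format (use .nii, .nii.gz or .nrrd): ", path,
         call. = FALSE)
  }
  invisible(path)
}

# Sample a volume at continuous 0-based voxel indices (n x 3). Points outside
# the grid return `fill`. Linear = trilinear; nearest = round-half-up.
sample_at_index <- function(vol, idx, interp = c("linear", "nearest"),
                            fill = 0) {
  interp <- match.arg(interp)
  d <- dim(vol$data)
  n <- nrow(idx)
  out <- rep(fill, n)
  if (interp == "nearest") {
    ii <- round(idx)
    ok <- ii[, 1] >= 0 & ii[, 1] <= d[1] - 1 &
          ii[, 2] >= 0 & ii[, 2] <= d[2] - 1 &
          ii[, 3] >= 0 & ii[, 3] <= d[3] - 1
    lin <- 1 + ii[ok, 1] + d[1] * (ii[ok, 2] + d[2] * ii[ok, 3])
    out[ok] <- vol$data[lin]
    return(out)
  }
  ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
        idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
        idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  p <- idx[ok, , drop = FALSE]
  f0 <- floor(p)
  fr <- p - f0
  # clamp the +1 corner so points exactly on the far face stay in range
  c0 <- f0
  c1 <- pmin(f0 + 1, matrix(rep(d - 1, each = nrow(p)), ncol = 3))
  gv <- function(a, b, cc) {
    lin <- 1 + a + d[1] * (b + d[2] * cc)
    vol$data[lin]
  }
  wx <- fr[, 1]; wy <- fr[, 2]; wz <- fr[, 3]
  val <-
    gv(c0[, 1], c0[, 2], c0[, 3]) * (1 - wx) * (1 - wy) * (1 - wz) +
    gv(c1[, 1], c0[, 2], c0[, 3]) * wx * (1 - wy) * (1 - wz) +
    gv(c0[, 1], c1[, 2], c0[, 3]) * (1 - wx) * wy * (1 - wz) +
    gv(c1[, 1], c1[, 2], c0[, 3]) * wx * wy * (1 - wz) +
    gv(c0[, 1], c0[, 2], c1[, 3]) * (1 - wx) * (1 - wy) * wz +
    gv(c1[, 1], c0[, 2], c1[, 3]) * wx * (1 - wy) * wz +
    gv(c0[, 1], c1[, 2], c1[, 3]) * (1 - wx) * wy * wz +
    gv(c1[, 1], c1[, 2], c1[, 3]) * wx * wy * wz
  out[ok] <- val
  out
}

#' Resample a volume to an isotropic grid
#'
#' The output grid shares the input origin and direction; along each axis it
#' covers the input physical extent with `ceiling(extent / voxel_mm)` voxels,
#' so the extent is preserved to within one voxel. Use `nearest` for label
#' volumes (never invents labels), `linear` for scalar images.
#'
#' @param vol an [image_volume].
#' @param voxel_mm target isotropic voxel size in mm (> 0). Default 1.
#' @param interp `"nearest"` or `"linear"`.
#' @return An [image_volume] with spacing `c(voxel_mm, voxel_mm, voxel_mm)`.
#' @export
resample_isotropic <- function(vol, voxel_mm = 1,
                               interp = c("nearest", "linear")) {
  stopifnot_volume(vol)
  interp <- match.arg(interp)
  if (!is.numeric(voxel_mm) || length(voxel_mm) != 1 || !is.finite(voxel_mm) ||
      voxel_mm <= 0)
    stop("'voxel_mm' must be a positive scalar", call. = FALSE)
  d <- dim(vol$data)
  extent <- d * vol$spacing
  nd <- pmax(1L, as.integer(ceiling(extent / voxel_mm)))
  # output voxel centers in input continuous index space (same axes);
  # clamped to the grid so border voxels replicate rather than zero-fill --
  # the output covers the full physical extent, whose outermost sliver lies
  # beyond the last input voxel center
  ax <- lapply(1:3, function(a)
    pmin((seq_len(nd[a]) - 1) * voxel_mm / vol$spacing[a], d[a] - 1))
  idx <- cbind(rep(ax[[1]], times = nd[2] * nd[3]),
               rep(rep(ax[[2]], each = nd[1]), times = nd[3]),
               rep(ax[[3]], each = nd[1] * nd[2]))
  vals <- sample_at_index(vol, idx, interp = interp, fill = 0)
  if (interp == "nearest" &&
      (is.integer(vol$data) || all(vol$data == round(vol$data))))
    vals <- as.integer(vals)
  image_volume(array(vals, nd), spacing = rep(voxel_mm, 3),
               origin = vol$origin, direction = vol$direction)
}
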