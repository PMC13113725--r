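#' 3D image volume with physical-space metadata
#'
#' The universal voxel container of the package: a 3D array of scalars or
#' integer labels together with voxel spacing (mm), the world position of the
#' center of voxel `[1,1,1]`, and a 3x3 direction matrix whose columns are the
#' world directions of the array axes. World coordinates are LPS millimetres
#' throughout the package; format-native conventions (e.g. NIfTI's RAS) are
#' converted at the reader boundary. Voxel indices are 0-based in world-space
#' formulas and a voxel's world position is its center.
#'
#' @param data 3D numeric/integer/logical array.
#' @param spacing numeric length-3, mm per axis, all > 0.
#' @param origin numeric length-3, mm; world position of the first voxel
#'   center. Default `c(0, 0, 0)`.
#' @param direction 3x3 orthonormal matrix (columns = axis directions).
#'   Default identity.
#' @return An object of class `image_volume`.
#' @examples
#' v <- image_volume(array(0L, c(4, 4, 4)), spacing = c(0.65, 0.65, 1))
#' dim(v$data)
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0),
                         direction = diag(3)) {
  if (is.logical(data)) storage.mode(data) <- "integer"
  if (length(dim(data)) != 3L)
    stop("image_volume: 'data' must be a 3D array, got ",
         length(dim(data)), " dimensions", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_volume: 'spacing' must be 3 positive mm values", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("image_volume: 'origin' must be 3 finite mm values", call. = FALSE)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6 ||
      abs(abs(det(direction)) - 1) > 1e-6)
    stop("image_volume: 'direction' must be orthonormal", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<image_volume> ", paste(d, collapse = " x "),
      " | spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm | origin (", paste(signif(x$origin, 4), collapse = ", "), ")\n",
      sep = "")
  rng <- range(x$data)
  cat("  values in [", rng[1], ", ", rng[2], "]\n", sep = "")
  invisible(x)
}

is_image_volume <- function(x) inherits(x, "image_volume")

stopifnot_volume <- function(x, what = "volume") {
  if (!is_image_volume(x))
    stop(what, " must be an image_volume", call. = FALSE)
  invisible(x)
}

# world position (mm, LPS) of 0-based continuous voxel indices (n x 3 matrix)
index_to_world <- function(vol, idx0) {
  idx0 <- rbind(idx0)
  sweep(idx0 %*% t(vol$direction * rep(vol$spacing, each = 3)), 2,
        vol$origin, "+")
}

# 0-based continuous voxel indices of world points (n x 3 matrix, mm LPS)
world_to_index <- function(vol, pts) {
  pts <- rbind(pts)
  rel <- sweep(pts, 2, vol$origin)
  idx <- rel %*% vol$direction          # t(D) %*% rel, rowwise
  sweep(idx, 2, vol$spacing, "/")
}

# centers of the voxel grid along one axis (0-based index vector)
grid_axis <- function(vol, axis) seq_len(dim(vol$data)[axis]) - 1

# binary foreground as logical vector plus dims; accepts 0/1 or logical data
as_binary_mask <- function(vol) {
  v <- vol$data
  u <- unique(as.vector(v))
  if (!all(u %in% c(0, 1)))
    stop("mask must be binary (values 0/1), found values: ",
         paste(utils::head(sort(u), 5), collapse = ", "), call. = FALSE)
  array(v != 0, dim(v))
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol
}

# morphological closing (dilate then erode) by a sphere of physical radius
# r_mm, both steps via the spacing-aware distance transform
close_mask <- function(mask_arr, spacing, r_mm) {
  if (r_mm <= 0) return(mask_arr)
  d2 <- edt_sq(mask_arr, spacing)
  dil <- array(d2 <= r_mm^2, dim(mask_arr))
  e2 <- edt_sq(!dil, spacing)
  dil & array(e2 > r_mm^2, dim(mask_arr))
}

# spacing-aware squared EDT to the nearest TRUE voxel center (mm^2)
edt_sq <- function(mask_arr, spacing) {
  cpp_edt_sq(as.logical(mask_arr), dim(mask_arr), as.numeric(spacing))
}

# distance (mm) from every foreground voxel to the nearest background;
# voxels outside the array count as background
distance_to_background <- function(mask_arr, spacing) {
  bg <- !mask_arr
  d2 <- edt_sq(bg, spacing)
  # clamp to boundary of the array: distance to the nearest face plane
  dm <- dim(mask_arr)
  i <- slice.index(mask_arr, 1) - 1
  j <- slice.index(mask_arr, 2) - 1
  k <- slice.index(mask_arr, 3) - 1
  face <- pmin((i + 1) * spacing[1], (dm[1] - i) * spacing[1],
               (j + 1) * spacing[2], (dm[2] - j) * spacing[2],
               (k + 1) * spacing[3], (dm[3] - k) * spacing[3])
  pmin(sqrt(array(d2, dm)), face)
}
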