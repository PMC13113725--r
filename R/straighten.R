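#' Rotation-minimizing frames along a centerline
#'
#' Tangents come from central differences; the initial normal is the world
#' axis least aligned with the first tangent, orthogonalized against it;
#' subsequent frames are transported with the double-reflection
#' rotation-minimizing method, which avoids both the zero-curvature
#' degeneracy and the torsion-driven twist of Frenet frames.
#'
#' @param cl a centerline (>= 2 points).
#' @return `list(tangent, normal, binormal)`, each an n x 3 matrix of unit
#'   vectors; class `frame_field`.
#' @export
compute_frames <- function(cl) {
  pts <- cl$points
  n <- nrow(pts)
  if (n < 2) stop("need at least 2 centerline points", call. = FALSE)
  if (any(sqrt(rowSums(diff(pts)^2)) < 1e-9))
    stop("duplicate consecutive centerline points", call. = FALSE)

  # central differences over a +-2 sample baseline where available: exact
  # for straight lines and circular arcs, and twice as resistant to
  # sub-voxel jitter of individual samples as +-1 differences
  tang <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    lo <- max(1, i - 2)
    hi <- min(n, i + 2)
    tang[i, ] <- pts[hi, ] - pts[lo, ]
  }
  tang <- tang / sqrt(rowSums(tang^2))

  # initial normal: world axis least aligned with t1, Gram-Schmidt
  a <- which.min(abs(tang[1, ]))
  e <- c(0, 0, 0); e[a] <- 1
  n0 <- e - sum(e * tang[1, ]) * tang[1, ]
  n0 <- n0 / sqrt(sum(n0^2))

  normal <- matrix(0, n, 3)
  normal[1, ] <- n0
  for (i in seq_len(n - 1)) {
    # double reflection (Wang et al. 2008)
    v1 <- pts[i + 1, ] - pts[i, ]
    c1 <- sum(v1 * v1)
    rL <- normal[i, ] - (2 / c1) * sum(v1 * normal[i, ]) * v1
    tL <- tang[i, ] - (2 / c1) * sum(v1 * tang[i, ]) * v1
    v2 <- tang[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    ni <- if (c2 < 1e-12) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    ni <- ni - sum(ni * tang[i + 1, ]) * tang[i + 1, ]
    normal[i + 1, ] <- ni / sqrt(sum(ni^2))
  }
  binormal <- cbind(
    tang[, 2] * normal[, 3] - tang[, 3] * normal[, 2],
    tang[, 3] * normal[, 1] - tang[, 1] * normal[, 3],
    tang[, 1] * normal[, 2] - tang[, 2] * normal[, 1])
  structure(list(tangent = tang, normal = normal, binormal = binormal),
            class = "frame_field")
}

#' Curved planar reformation (vessel straightening)
#'
#' Resamples the volume on planes orthogonal to the centerline: slice `k` of
#' the output is a `plane_extent_mm` x `plane_extent_mm` grid at 1 mm pitch,
#' centered on centerline point `k` and spanned by that point's (normal,
#' binormal) frame. The third output axis is therefore arc length, and the
#' output voxel size is exactly 1 mm isotropic — the straightened, uniformly
#' resampled representation the quantification stage measures on. Samples
#' falling outside the source volume become 0.
#'
#' The first and last `truncate_slices` slices are flagged endpoint-truncated
#' (their planes cut the open tube ends) and are excluded from downstream
#' summary statistics.
#'
#' @param vol source [image_volume] (scalar or label).
#' @param cl centerline; internally resampled to 1 mm steps if needed.
#' @param frames optional [compute_frames()] result for the 1 mm centerline.
#' @param plane_extent_mm in-plane field of view, mm (> 0). Default 80
#'   (comfortably over twice the largest aortic diameter).
#' @param interp `"nearest"` (default, labels) or `"linear"`.
#' @param truncate_slices slices flagged at each end, or `NULL` (default) for
#'   an adaptive window of one local lumen radius: the zone in which planes
#'   near an open tube end cut partial or oblique lumens extends about one
#'   inscribed radius inward, so a fixed small window under-flags wide
#'   vessels. Never fewer than 3 slices.
#' @return A `straightened_volume`: `volume` ([image_volume], spacing 1 mm),
#'   `arclength` per slice, `truncated` flags, `plane_extent_mm`,
#'   `source_centerline`.
#' @export
curved_planar_reformat <- function(vol, cl, frames = NULL,
                                   plane_extent_mm = 80,
                                   interp = c("nearest", "linear"),
                                   truncate_slices = NULL) {
  stopifnot_volume(vol)
  interp <- match.arg(interp)
  if (plane_extent_mm <= 0)
    stop("'plane_extent_mm' must be > 0", call. = FALSE)
  if (abs(cl$step_mm - 1) > 1e-9) {
    cl <- new_centerline(resample_path(cl$points, 1), 1)
    frames <- NULL
  }
  if (is.null(frames)) frames <- compute_frames(cl)
  n <- nrow(cl$points)
  half <- floor(plane_extent_mm / 2)
  uu <- seq(-half, half, by = 1)
  m <- length(uu)
  grid_u <- rep(uu, times = m)
  grid_v <- rep(uu, each = m)

  out <- array(0, c(m, m, n))
  for (k in seq_len(n)) {
    pk <- cl$points[k, ]
    P <- outer(grid_u, frames$normal[k, ]) + outer(grid_v, frames$binormal[k, ])
    P <- sweep(P, 2, pk, "+")
    idx <- world_to_index(vol, P)
    out[, , k] <- sample_at_index(vol, idx, interp = interp, fill = 0)
  }
  if (interp == "nearest" && all(vol$data == round(vol$data)))
    storage.mode(out) <- "integer"
  trunc <- rep(FALSE, n)
  if (is.null(truncate_slices)) {
    # lumen radius near each end, from the largest cross-section among
    # slices 2-15 (slice 1 may be a partial cut); the window is capped so a
    # focal dilation just beyond the end zone is not mistaken for the end
    # radius and truncated away
    probe <- 2:min(n, 15)
    rad_of <- function(ks) {
      a <- max(vapply(ks, function(k) sum(out[, , k] != 0), 0))
      sqrt(a / pi)
    }
    tk_lo <- max(3, min(16, ceiling(rad_of(probe))))
    tk_hi <- max(3, min(16, ceiling(rad_of(n + 1 - probe))))
  } else {
    tk_lo <- tk_hi <- truncate_slices
  }
  tk_lo <- min(tk_lo, floor((n - 1) / 2))
  tk_hi <- min(tk_hi, floor((n - 1) / 2))
  if (tk_lo > 0) trunc[seq_len(tk_lo)] <- TRUE
  if (tk_hi > 0) trunc[n + 1 - seq_len(tk_hi)] <- TRUE
  sv <- image_volume(out, spacing = c(1, 1, 1),
                     origin = c(-half, -half, 0))
  structure(list(volume = sv, arclength = cl$arclength,
                 truncated = trunc, plane_extent_mm = plane_extent_mm,
                 source_centerline = cl, interp = interp),
            class = "straightened_volume")
}

#' @export
print.straightened_volume <- function(x, ...) {
  cat("<straightened_volume> ", dim(x$volume$data)[3], " slices x ",
      paste(dim(x$volume$data)[1:2], collapse = " x "),
      " mm plane, interp=", x$interp, "\n", sep = "")
  invisible(x)
}

#' Write a straightened volume as NIfTI plus a JSON sidecar
#'
#' @param sv a straightened_volume.
#' @param path NIfTI destination; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_straightened <- function(sv, path) {
  write_volume(sv$volume, path)
  side <- sub("\\.nii(\\.gz)?$|\\.nrrd$", ".json", path)
  jsonlite::write_json(
    list(plane_extent_mm = sv$plane_extent_mm, interp = sv$interp,
         arclength = sv$arclength,
         centerline = unname(as.data.frame(sv$source_centerline$points))),
    side, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
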