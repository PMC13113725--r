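#' @name evalmetrics
#' @title Spacing-aware segmentation comparison metrics
#' @description
#' Overlap metrics (Dice, IoU) and surface-distance metrics (95% Hausdorff,
#' average symmetric surface distance) between two binary volumes on the same
#' grid. Surfaces are boundary voxel centers under 6-connectivity (voxels
#' outside the array count as background); distances are physical mm, taken
#' from the spacing-aware Euclidean distance transform; HD95 is the
#' 95th percentile (linear interpolation) of the POOLED bidirectional
#' nearest-surface distance set, with the max-of-directed-percentiles
#' alternative available via `pooled = FALSE`.
NULL

check_pair <- function(a, b) {
  stopifnot_volume(a, "first mask")
  stopifnot_volume(b, "second mask")
  if (!same_grid(a, b))
    stop("masks are on different grids (shape or spacing mismatch)",
         call. = FALSE)
  list(a = as_binary_mask(a), b = as_binary_mask(b))
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks compare as 1.
#' @param a,b binary [image_volume]s on the same grid.
#' @return unitless overlap in `[0, 1]`.
#' @export
dice <- function(a, b) {
  m <- check_pair(a, b)
  na <- sum(m$a); nb <- sum(m$b)
  if (na + nb == 0) return(1)
  2 * sum(m$a & m$b) / (na + nb)
}

#' Intersection over union (Jaccard)
#'
#' `|A n B| / (A u B)`; two empty masks compare as 1.
#' @inheritParams dice
#' @return unitless overlap in `[0, 1]`.
#' @export
iou <- function(a, b) {
  m <- check_pair(a, b)
  un <- sum(m$a | m$b)
  if (un == 0) return(1)
  sum(m$a & m$b) / un
}

# boundary voxels under 6-connectivity, outside-of-array = background
boundary_voxels <- function(arr) {
  d <- dim(arr)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  interior <-
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  arr & !interior
}

# pooled bidirectional nearest-surface distances (mm)
surface_distances <- function(a, b) {
  m <- check_pair(a, b)
  if (!any(m$a) || !any(m$b))
    stop("surface distances are undefined for an empty mask", call. = FALSE)
  sa <- boundary_voxels(m$a)
  sb <- boundary_voxels(m$b)
  spacing <- a$spacing
  d_to_b <- sqrt(edt_sq(sb, spacing))
  d_to_a <- sqrt(edt_sq(sa, spacing))
  list(a2b = d_to_b[which(sa)], b2a = d_to_a[which(sb)])
}

#' 95% Hausdorff distance
#'
#' @inheritParams dice
#' @param pooled if `TRUE` (default) the percentile is taken over the pooled
#'   bidirectional distance set; if `FALSE`, the max of the two directed 95th
#'   percentiles.
#' @return distance in mm.
#' @export
hausdorff95 <- function(a, b, pooled = TRUE) {
  sd <- surface_distances(a, b)
  if (pooled)
    as.numeric(stats::quantile(c(sd$a2b, sd$b2a), 0.95, type = 7))
  else
    max(stats::quantile(sd$a2b, 0.95, type = 7),
        stats::quantile(sd$b2a, 0.95, type = 7))
}

#' Average symmetric surface distance
#'
#' Mean of the pooled bidirectional nearest-surface distances.
#' @inheritParams dice
#' @return distance in mm.
#' @export
assd <- function(a, b) {
  sd <- surface_distances(a, b)
  mean(c(sd$a2b, sd$b2a))
}

#' All four segmentation metrics at once
#'
#' @inheritParams dice
#' @return `list(dice, iou, hd95_mm, assd_mm)`.
#' @export
seg_compare <- function(a, b) {
  sd <- surface_distances(a, b)
  pooled <- c(sd$a2b, sd$b2a)
  list(dice = dice(a, b), iou = iou(a, b),
       hd95_mm = as.numeric(stats::quantile(pooled, 0.95, type = 7)),
       assd_mm = mean(pooled))
}
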