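#' @name centerline-module
#' @title Vessel endpoint detection and centerline extraction
#' @description
#' The centerline is found in three stages, mirroring the automated
#' quantification workflow this package implements:
#' 1. [detect_endpoints()] reduces the mask to a unit-width curve skeleton by
#'    topology-preserving thinning and reports its leaf voxels as candidate
#'    endpoints, ordered by descending world z (most superior first), then
#'    scan order.
#' 2. [select_inlet_outlet()] applies the first/farthest rule: the inlet is
#'    the first candidate, the outlet the candidate at maximal Euclidean
#'    distance from it (earlier candidate wins ties).
#' 3. [extract_centerline()] runs a least-cost traversal on the 26-connected
#'    foreground voxel graph with edge cost
#'    `step_length * 1 / (DT(target) + eps)`, where `DT` is the spacing-aware
#'    distance to background, pulling the path onto the medial axis; the path
#'    is then smoothed (moving average, 5 points) and resampled to uniform
#'    arc-length steps.
NULL

new_centerline <- function(points, step_mm) {
  gaps <- sqrt(rowSums(diff(points)^2))
  structure(list(points = points,
                 arclength = c(0, cumsum(gaps)),
                 step_mm = step_mm),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat("<centerline> ", nrow(x$points), " points, length ",
      round(max(x$arclength), 1), " mm, step ", x$step_mm, " mm\n", sep = "")
  invisible(x)
}

#' Detect candidate vessel endpoints
#'
#' Skeletonizes the mask (sequential topology-preserving thinning, peeling in
#' order of increasing distance-to-background so the curve hugs the medial
#' axis) and returns the skeleton's leaf voxels (<= 1 skeleton neighbor in
#' 26-connectivity) as world-space candidates. Ordering: descending world z,
#' then ascending scan order — so the "first" candidate is the most superior
#' point, anatomically the aortic-root side in thoracic scans.
#'
#' @param mask binary [image_volume] with exactly one 26-connected foreground
#'   component.
#' @return matrix of candidate points (mm), one row each, most superior first.
#' @export
detect_endpoints <- function(mask) {
  stopifnot_volume(mask)
  arr <- as_binary_mask(mask)
  if (!any(arr)) stop("empty mask: no foreground voxels", call. = FALSE)
  lab <- cpp_label3d(as.logical(arr), dim(arr), 26L)
  ncomp <- max(lab)
  if (ncomp != 1L)
    stop("mask has ", ncomp, " connected components; expected exactly 1",
         call. = FALSE)
  # Thick-slice voxelization leaves staircase terraces whose diagonal
  # contacts create spurious topological handles; homotopic thinning would
  # faithfully keep them as skeleton loops. A morphological closing at the
  # scale of one voxel diagonal seals them before topology analysis;
  # measurements elsewhere always use the unclosed mask.
  arr_topo <- close_mask(arr, mask$spacing, sqrt(sum(mask$spacing^2)))
  dt <- distance_to_background(arr_topo, mask$spacing)
  skel <- array(cpp_skeletonize(as.logical(arr_topo), dim(arr_topo),
                                as.numeric(dt)),
                dim(arr_topo))
  skel <- prune_spurs(skel, dt, mask$spacing)
  arr <- arr_topo
  g <- skeleton_graph(skel)
  leaves <- g$nodes[g$degree <= 1L]
  if (!length(leaves)) leaves <- g$nodes[1]
  pts <- t(vapply(leaves, function(lf)
    extend_leaf_to_boundary(lf, g, skel, arr, mask, dt), numeric(3)))
  ord <- order(-pts[, 3], seq_len(nrow(pts)))
  pts[ord, , drop = FALSE]
}

# Adjacency of the skeleton voxels, reduced to a BFS spanning forest. The
# voxel 26-adjacency graph of a digital curve carries chord edges (corner
# triangles) that masquerade as junctions and cycles; the spanning tree keeps
# the curve structure and drops the chords, so leaves and branch walks are
# well defined.
skeleton_graph <- function(skel) {
  d <- dim(skel)
  nodes <- which(skel)
  co <- cbind((nodes - 1) %% d[1],
              ((nodes - 1) %/% d[1]) %% d[2],
              (nodes - 1) %/% (d[1] * d[2]))
  id <- integer(prod(d))
  id[nodes] <- seq_along(nodes)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  adj <- vector("list", length(nodes))
  for (t in seq_len(nrow(offs))) {
    nc <- co + matrix(offs[t, ], nrow(co), 3, byrow = TRUE)
    ok <- nc[, 1] >= 0 & nc[, 1] < d[1] & nc[, 2] >= 0 & nc[, 2] < d[2] &
          nc[, 3] >= 0 & nc[, 3] < d[3]
    lin <- 1 + nc[ok, 1] + d[1] * (nc[ok, 2] + d[2] * nc[ok, 3])
    hit <- id[lin] > 0
    src <- which(ok)[hit]
    for (s in seq_along(src))
      adj[[src[s]]] <- c(adj[[src[s]]], id[lin[hit][s]])
  }
  # BFS spanning forest; face/edge neighbors are visited before corner
  # neighbors within each adjacency list because offsets are scan-ordered
  n <- length(nodes)
  tree <- vector("list", n)
  visited <- logical(n)
  for (root in seq_len(n)) {
    if (visited[root]) next
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (!visited[nb]) {
          visited[nb] <- TRUE
          tree[[cur]] <- c(tree[[cur]], nb)
          tree[[nb]] <- c(tree[[nb]], cur)
          queue <- c(queue, nb)
        }
      }
    }
  }
  list(nodes = nodes, coords = co, adj = tree,
       degree = lengths(tree), dims = d)
}

# Delete covered leaf branches: a branch (leaf up to its junction) whose
# every voxel lies inside the inscribed sphere of some skeleton voxel
# OUTSIDE the branch runs within the vessel it sprouted from -- a thinning
# artifact of blunt ends and thick-slice staircase terraces, not a real
# vessel end. Real ends and side-branch stubs protrude beyond the inscribed
# spheres of the remaining skeleton and survive. Smallest-protrusion
# branches go first; repeats until stable.
prune_spurs <- function(skel, dt, spacing, margin_mm = 0.5) {
  repeat {
    g <- skeleton_graph(skel)
    w_mm <- g$coords * rep(spacing, each = nrow(g$coords))
    dts <- dt[g$nodes]
    worst <- NULL
    worst_prot <- Inf
    for (li in which(g$degree <= 1L)) {
      branch <- walk_branch(g, li)
      if (!branch$at_junction) next
      rest <- setdiff(seq_along(g$nodes), branch$path)
      if (!length(rest)) next
      bw <- w_mm[branch$path, , drop = FALSE]
      rw <- w_mm[rest, , drop = FALSE]
      # protrusion of v = distance beyond the best covering inscribed sphere
      prot <- vapply(seq_len(nrow(bw)), function(t) {
        dd <- sqrt(colSums((t(rw) - bw[t, ])^2))
        min(dd - dts[rest])
      }, 0)
      p <- max(prot)
      if (p <= margin_mm && p < worst_prot) {
        worst <- branch$path
        worst_prot <- p
      }
    }
    if (is.null(worst)) return(skel)
    skel[g$nodes[worst]] <- FALSE
  }
}

# follow the skeleton from a leaf until a junction (degree >= 3) or another
# leaf; returns the node ids of the branch (junction excluded) and, when the
# walk stopped at a junction, the junction's node id
walk_branch <- function(g, leaf, max_steps = 1e5) {
  path <- leaf
  prev <- -1L
  cur <- leaf
  for (step in seq_len(max_steps)) {
    nxt <- setdiff(g$adj[[cur]], c(prev, path))
    if (!length(nxt)) return(list(path = path, at_junction = FALSE))
    if (g$degree[cur] >= 3L && cur != leaf)
      return(list(path = path[-length(path)], at_junction = TRUE,
                  junction = cur))
    prev <- cur
    cur <- nxt[1]
    path <- c(path, cur)
  }
  list(path = path, at_junction = FALSE)
}

# The curve skeleton of a blunt-ended tube legitimately stops about one
# radius short of the end face (where the maximal inscribed sphere touches
# the cap). March from the leaf along the branch's end tangent until leaving
# the mask; the last interior position is the endpoint candidate, which for
# a tube is the end-face center.
extend_leaf_to_boundary <- function(leaf_node, g, skel, arr, mask, dt) {
  li <- which(g$nodes == leaf_node)
  branch <- walk_branch(g, li)
  take <- head(branch$path, 16)
  co <- g$coords[take, , drop = FALSE]
  w <- index_to_world(mask, co)
  p0 <- w[1, ]
  if (nrow(w) < 3) return(p0)
  # end tangent by principal direction of the branch segment: robust against
  # thick-slice staircase wiggle, which defeats a two-point difference
  cw <- sweep(w, 2, colMeans(w))
  dirv <- svd(cw, nu = 0, nv = 1)$v[, 1]
  if (sum(dirv * (p0 - w[nrow(w), ])) < 0) dirv <- -dirv
  track_to_end(p0, dirv, arr, mask,
               rloc = dt[leaf_node] + 2 * max(mask$spacing),
               limit_mm = 1.5 * dt[leaf_node] + 4 * max(mask$spacing))
}

# Tube-tracking march: advance along the running direction, re-centering on
# the centroid of the mask within the orthogonal disc at each step, until the
# disc leaves the mask. The march self-corrects an imperfect starting
# tangent, so the end point lands on the end-face center even when the
# skeleton leaf retracted into a wide bulge.
track_to_end <- function(p0, dirv, arr, mask, rloc, limit_mm, step = 1) {
  d <- dim(arr)
  rloc <- min(max(rloc, 2 * max(mask$spacing)), 35)
  gg <- expand.grid(u = seq(-rloc, rloc, by = 1),
                    v = seq(-rloc, rloc, by = 1))
  gg <- gg[gg$u^2 + gg$v^2 <= rloc^2, ]
  plane_centroid <- function(center, dirv) {
    a <- which.min(abs(dirv))
    e <- c(0, 0, 0); e[a] <- 1
    u <- e - sum(e * dirv) * dirv
    u <- u / sqrt(sum(u^2))
    v <- c(dirv[2] * u[3] - dirv[3] * u[2],
           dirv[3] * u[1] - dirv[1] * u[3],
           dirv[1] * u[2] - dirv[2] * u[1])
    P <- sweep(outer(gg$u, u) + outer(gg$v, v), 2, center, "+")
    idx <- round(world_to_index(mask, P))
    ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
          idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
          idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
    if (!any(ok)) return(NULL)
    lin <- 1 + idx[ok, 1] + d[1] * (idx[ok, 2] + d[2] * idx[ok, 3])
    fg <- arr[lin]
    # a handful of hits is rounding spill from the last voxel layer past an
    # end face, not a cross-section
    if (sum(fg) < 5) return(NULL)
    list(cen = colMeans(P[ok, , drop = FALSE][fg, , drop = FALSE]),
         count = sum(fg))
  }
  inside <- function(p) {
    i <- round(world_to_index(mask, p))
    all(i >= 0) && all(i <= d - 1) &&
      arr[1 + i[1] + d[1] * (i[2] + d[2] * i[3])]
  }
  cur <- p0
  trail <- matrix(p0, 1, 3)
  counts <- numeric(0)
  for (t in seq_len(ceiling(limit_mm / step))) {
    nxt <- cur + step * dirv
    # the end-face center is precisely where the tracked axis point leaves
    # the mask: creep past it with halved steps, then stop
    if (!inside(nxt)) {
      h <- step / 2
      for (it in 1:12) {
        if (h <= 0.2 * min(mask$spacing)) break
        if (inside(cur + h * dirv)) cur <- cur + h * dirv else h <- h / 2
      }
      # undo the drift a lagged plane orientation accumulates near the end:
      # recenter on a cross-section far enough inside the face that the
      # tilted disc cannot clip past it, then project back out along dirv
      back <- max(2 * step, 0.25 * rloc)
      pc_end <- plane_centroid(cur - back * dirv, dirv)
      if (!is.null(pc_end) &&
          sqrt(sum((pc_end$cen - cur + back * dirv)^2)) < 6)
        cur <- pc_end$cen + back * dirv
      break
    }
    pc <- plane_centroid(nxt, dirv)
    # end detection: the plane leaves the mask, the centroid jumps far more
    # than the step (the disc is grazing past an end face), or the
    # cross-section collapses abruptly -- genuine taper is gradual, an end
    # face crashes the count within a step or two
    stop_now <- is.null(pc) ||
      sqrt(sum((pc$cen - nxt)^2)) > 3 * step ||
      (length(counts) >= 2 &&
         pc$count < 0.6 * counts[length(counts) - 1])
    if (stop_now) {
      # approach the end face with halved steps before giving up
      h <- step / 2
      ref <- if (length(counts) >= 2) counts[length(counts) - 1] else Inf
      for (it in 1:12) {
        if (h <= 0.2 * min(mask$spacing)) break
        pc2 <- plane_centroid(cur + h * dirv, dirv)
        if (!is.null(pc2) &&
            sqrt(sum((pc2$cen - cur - h * dirv)^2)) <= h &&
            pc2$count >= 0.6 * ref)
          cur <- pc2$cen
        else
          h <- h / 2
      }
      back <- max(2 * step, 0.25 * rloc)
      pc_end <- plane_centroid(cur - back * dirv, dirv)
      if (!is.null(pc_end) &&
          sqrt(sum((pc_end$cen - cur + back * dirv)^2)) < 6)
        cur <- pc_end$cen + back * dirv
      break
    }
    cur <- pc$cen
    counts <- c(counts, pc$count)
    trail <- rbind(trail, cur)
    # steer from a trailing baseline: per-step centroid jitter is the same
    # order as the step length, so a one-step direction update would wander
    if (nrow(trail) >= 6) {
      base <- cur - trail[nrow(trail) - 5, ]
      nn <- sqrt(sum(base^2))
      if (nn > 1e-9) {
        dirv <- 0.5 * dirv + 0.5 * base / nn
        dirv <- dirv / sqrt(sum(dirv^2))
      }
    }
  }
  cur
}

#' Select inlet and outlet from endpoint candidates
#'
#' The rule used by the automated workflow when more than two candidates are
#' detected: keep the first candidate (inlet) and the candidate farthest from
#' it in Euclidean distance (outlet). Distance ties are broken by list order.
#'
#' @param candidates matrix of candidate points (mm), >= 2 rows, in the order
#'   produced by [detect_endpoints()].
#' @return `list(inlet =, outlet =)`, each a length-3 mm coordinate.
#' @export
select_inlet_outlet <- function(candidates) {
  candidates <- rbind(candidates)
  if (nrow(candidates) < 2)
    stop("need at least 2 endpoint candidates, got ", nrow(candidates),
         call. = FALSE)
  inlet <- candidates[1, ]
  d <- sqrt(rowSums(sweep(candidates, 2, inlet)^2))
  outlet <- candidates[which.max(d), ]   # which.max keeps the earliest tie
  list(inlet = inlet, outlet = outlet)
}

#' Extract a centerline between two points of a vessel mask
#'
#' Least-cost path on the 26-connected foreground voxel graph; each step to a
#' neighbor costs its physical length times `1 / (DT + eps)` at the target,
#' with `DT` the spacing-aware Euclidean distance to background, so the
#' cheapest route runs along the medial axis. The voxel path is smoothed with
#' a 5-point moving average and resampled to uniform `step_mm` arc spacing.
#'
#' @param mask binary [image_volume].
#' @param inlet,outlet world points (mm) inside the mask.
#' @param step_mm resampling interval, mm (> 0). Default 1.
#' @param eps_mm regularizer of the inverse-distance cost. Default 0.1.
#' @param smooth_window moving-average window on the voxel path. Default 5.
#' @return A `centerline` object (`points`, `arclength`, `step_mm`).
#' @export
extract_centerline <- function(mask, inlet, outlet, step_mm = 1,
                               eps_mm = 0.1, smooth_window = 5) {
  stopifnot_volume(mask)
  if (step_mm <= 0) stop("'step_mm' must be > 0", call. = FALSE)
  arr <- as_binary_mask(mask)
  dmask <- dim(arr)
  to_lin <- function(p) {
    i <- round(world_to_index(mask, p))
    i <- pmin(pmax(i, 0), matrix(dmask - 1, 1))
    1 + i[1] + dmask[1] * (i[2] + dmask[2] * i[3])
  }
  src <- to_lin(inlet)
  dst <- to_lin(outlet)
  if (!arr[src] || !arr[dst]) {
    # snap to the nearest foreground voxel (endpoints sit on voxel centers
    # of the skeleton so this is only a guard for user-supplied points)
    fg <- which(arr)
    snap <- function(lin) {
      i0 <- cbind((fg - 1) %% dmask[1],
                  ((fg - 1) %/% dmask[1]) %% dmask[2],
                  (fg - 1) %/% (dmask[1] * dmask[2]))
      p0 <- cbind((lin - 1) %% dmask[1],
                  ((lin - 1) %/% dmask[1]) %% dmask[2],
                  (lin - 1) %/% (dmask[1] * dmask[2]))
      dd <- colSums((t(i0) - as.numeric(p0))^2 * mask$spacing^2)
      fg[which.min(dd)]
    }
    if (!arr[src]) src <- snap(src)
    if (!arr[dst]) dst <- snap(dst)
  }
  if (src == dst)
    stop("inlet and outlet resolve to the same voxel; degenerate path",
         call. = FALSE)
  dt <- distance_to_background(arr, mask$spacing)
  w <- 1 / (as.numeric(dt) + eps_mm)
  path <- cpp_dijkstra(as.logical(arr), dmask, mask$spacing, w,
                       src - 1, dst - 1)
  if (!length(path))
    stop("inlet and outlet are not connected in the foreground",
         call. = FALSE)
  idx0 <- cbind(path %% dmask[1],
                (path %/% dmask[1]) %% dmask[2],
                path %/% (dmask[1] * dmask[2]))
  pts <- index_to_world(mask, idx0)
  pts <- moving_average_path(pts, smooth_window)
  pts <- resample_path(pts, step_mm)
  # sub-voxel refinement: pull each sample onto the centroid of its
  # orthogonal cross-section, undoing the slight inward bias a discrete
  # least-cost path has on curved segments
  pts <- recenter_path(pts, arr, mask, array(dt, dmask))
  pts <- moving_average_path(pts, smooth_window)
  pts <- resample_path(pts, step_mm)
  new_centerline(pts, step_mm)
}

# centroid of the mask cross-section through `center` orthogonal to `dirv`,
# sampled on a 1 mm disc grid of radius rloc; NULL when the plane has (all
# but rounding spill) left the mask
plane_centroid_at <- function(center, dirv, rloc, arr, mask) {
  d <- dim(arr)
  uu <- seq(-rloc, rloc, by = 1)
  gg <- expand.grid(u = uu, v = uu)
  gg <- gg[gg$u^2 + gg$v^2 <= rloc^2, ]
  a <- which.min(abs(dirv))
  e <- c(0, 0, 0); e[a] <- 1
  u <- e - sum(e * dirv) * dirv
  u <- u / sqrt(sum(u^2))
  v <- c(dirv[2] * u[3] - dirv[3] * u[2],
         dirv[3] * u[1] - dirv[1] * u[3],
         dirv[1] * u[2] - dirv[2] * u[1])
  P <- sweep(outer(gg$u, u) + outer(gg$v, v), 2, center, "+")
  idx <- round(world_to_index(mask, P))
  ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
        idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
        idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  if (!any(ok)) return(NULL)
  lin <- 1 + idx[ok, 1] + d[1] * (idx[ok, 2] + d[2] * idx[ok, 3])
  fg <- arr[lin]
  if (sum(fg) < 5) return(NULL)
  colMeans(P[ok, , drop = FALSE][fg, , drop = FALSE])
}

recenter_path <- function(pts, arr, mask, dt_arr) {
  n <- nrow(pts)
  if (n < 3) return(pts)
  d <- dim(arr)
  tang <- matrix(0, n, 3)
  tang[1, ] <- pts[2, ] - pts[1, ]
  tang[n, ] <- pts[n, ] - pts[n - 1, ]
  if (n > 2) tang[2:(n - 1), ] <- pts[3:n, ] - pts[1:(n - 2), ]
  tang <- tang / sqrt(rowSums(tang^2))
  out <- pts
  for (i in seq_len(n)) {
    ii <- pmin(pmax(round(world_to_index(mask, pts[i, ])), 0),
               matrix(d - 1, 1))
    rloc <- dt_arr[1 + ii[1] + d[1] * (ii[2] + d[2] * ii[3])]
    rloc <- min(max(rloc + 2 * max(mask$spacing), 3), 35)
    cen <- plane_centroid_at(pts[i, ], tang[i, ], rloc, arr, mask)
    # keep the original sample where the plane clips an end face
    if (!is.null(cen) && sqrt(sum((cen - pts[i, ])^2)) < 3)
      out[i, ] <- cen
  }
  out
}

# centered moving average with SYMMETRICALLY shrinking windows at the ends:
# an asymmetric clipped window would drag the path ends inward on every pass
moving_average_path <- function(pts, window) {
  n <- nrow(pts)
  if (n < 3 || window < 2) return(pts)
  half <- window %/% 2
  hs <- pmin(half, seq_len(n) - 1, n - seq_len(n))
  out <- pts
  for (a in 1:3) {
    cs <- cumsum(c(0, pts[, a]))
    lo <- seq_len(n) - hs
    hi <- seq_len(n) + hs
    out[, a] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  out
}

# resample a polyline to uniform arc-length steps (linear interpolation);
# the final point is always kept so total length is preserved
resample_path <- function(pts, step_mm) {
  gaps <- sqrt(rowSums(diff(pts)^2))
  keep <- c(TRUE, gaps > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 2) return(pts)
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  total <- s[length(s)]
  ts <- seq(0, total, by = step_mm)
  if (total - ts[length(ts)] > 1e-6) ts <- c(ts, total)
  out <- sapply(1:3, function(a) approx(s, pts[, a], xout = ts)$y)
  matrix(out, ncol = 3)
}

#' Serialize a centerline to JSON or CSV
#'
#' @param cl a centerline.
#' @param path output path; `.json` writes points + arclength + step,
#'   `.csv` writes a 3-column mm coordinate table.
#' @return `path`, invisibly.
#' @export
write_centerline <- function(cl, path) {
  if (grepl("\\.json$", tolower(path))) {
    jsonlite::write_json(list(points = unname(as.data.frame(cl$points)),
                              arclength = cl$arclength,
                              step_mm = cl$step_mm),
                         path, digits = NA, auto_unbox = TRUE)
  } else {
    df <- as.data.frame(cl$points)
    names(df) <- c("x_mm", "y_mm", "z_mm")
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
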