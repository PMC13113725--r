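#' Specify a voxelized vascular phantom
#'
#' Phantoms are tubes around an analytically known centerline, voxelized by a
#' center-inclusion test against the exact geometry, so every downstream stage
#' can be validated against closed-form truth. Three shapes are provided:
#'
#' * `straight_tube` — a cylinder of `length_mm` along `axis`;
#' * `curved_tube` — an `arc_deg` arc of a torus with ring radius
#'   `ring_radius_mm`;
#' * `candy_cane` — ascending limb (`asc_mm`, vertical), half-torus arch
#'   (`ring_radius_mm`), descending limb (`desc_mm`): a simplified thoracic
#'   aorta with known arc length everywhere.
#'
#' An optional Gaussian `bulge` (`list(s0, amplitude, width)`, mm; `width` is
#' the Gaussian sigma) models a focal dilation of the lumen radius at arc
#' length `s0`. Optional `branch_stubs` (`list(list(s, radius, length), ...)`)
#' attach outward-pointing side tubes on the main curve as stand-ins for the
#' brachiocephalic trunk and left subclavian artery; their arc lengths are the
#' phantom's landmark positions.
#'
#' @param shape one of `"straight_tube"`, `"curved_tube"`, `"candy_cane"`.
#' @param tube_radius_mm lumen radius in mm (> 0).
#' @param length_mm straight tube length (mm).
#' @param axis straight tube direction (unit-normalized internally).
#' @param ring_radius_mm torus ring radius (mm) for curved/candy-cane shapes.
#' @param arc_deg arc of the curved tube in degrees (default 90).
#' @param asc_mm,desc_mm candy-cane limb lengths (mm).
#' @param wall_mm vessel wall thickness (mm, >= 0); rendered only when a mask
#'   is voxelized with `include_wall = TRUE` (the "non-contrast" condition).
#' @param bulge optional `list(s0, amplitude, width)` in mm.
#' @param branch_stubs optional list of `list(s, radius, length)` in mm.
#' @param spacing voxel spacing, mm. Default `c(0.65, 0.65, 1)`, the in-plane
#'   pixel spacing and thin-slice thickness of the emulated CT protocols.
#' @param seed integer; only consumed by optional label noise.
#' @param noise_flip_prob probability of flipping a boundary voxel (default 0,
#'   i.e. noise-free).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c("candy_cane", "straight_tube",
                                   "curved_tube"),
                         tube_radius_mm = 15,
                         length_mm = 100, axis = c(0, 0, 1),
                         ring_radius_mm = 50, arc_deg = 90,
                         asc_mm = 60, desc_mm = 90,
                         wall_mm = 0, bulge = NULL, branch_stubs = NULL,
                         spacing = c(0.65, 0.65, 1), seed = 1L,
                         noise_flip_prob = 0) {
  shape <- match.arg(shape)
  if (!is.numeric(tube_radius_mm) || tube_radius_mm <= 0)
    stop("tube_radius_mm must be > 0", call. = FALSE)
  if (wall_mm < 0) stop("wall_mm must be >= 0", call. = FALSE)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (!is.null(bulge)) {
    bulge <- as.list(bulge)
    stopifnot(all(c("s0", "amplitude", "width") %in% names(bulge)))
    if (bulge$amplitude < 0) stop("bulge amplitude must be >= 0",
                                  call. = FALSE)
    if (bulge$width <= 0) stop("bulge width must be > 0", call. = FALSE)
  }
  structure(list(shape = shape, tube_radius_mm = tube_radius_mm,
                 length_mm = length_mm, axis = axis / sqrt(sum(axis^2)),
                 ring_radius_mm = ring_radius_mm, arc_deg = arc_deg,
                 asc_mm = asc_mm, desc_mm = desc_mm, wall_mm = wall_mm,
                 bulge = bulge, branch_stubs = branch_stubs,
                 spacing = as.numeric(spacing), seed = as.integer(seed),
                 noise_flip_prob = noise_flip_prob),
            class = "phantom_spec")
}

# lumen radius of the main tube at arc length s (vectorized)
phantom_radius_at <- function(spec, s) {
  r <- rep(spec$tube_radius_mm, length(s))
  if (!is.null(spec$bulge))
    r <- r + spec$bulge$amplitude *
      exp(-(s - spec$bulge$s0)^2 / (2 * spec$bulge$width^2))
  r
}

# ---- analytic pieces -------------------------------------------------------
# A piece is a straight segment or a circular arc with a global arc-length
# offset. dist/s to each piece have closed forms; the lumen is the union of
# per-piece tubes.

piece_straight <- function(p0, u, len, s_start, radius = NULL) {
  list(kind = "straight", p0 = p0, u = u / sqrt(sum(u^2)), len = len,
       s_start = s_start, radius = radius)
}

piece_arc <- function(center, e1, e2, R, theta_max, s_start, radius = NULL) {
  list(kind = "arc", center = center, e1 = e1, e2 = e2, R = R,
       theta_max = theta_max, s_start = s_start, radius = radius)
}

piece_point_at <- function(piece, s_local) {
  if (piece$kind == "straight") {
    sweep(outer(s_local, piece$u), 2, piece$p0, "+")
  } else {
    th <- s_local / piece$R
    piece$center[col(outer(th, 1:3))] +
      piece$R * (outer(cos(th), piece$e1) + outer(sin(th), piece$e2))
  }
}

piece_length <- function(piece) {
  if (piece$kind == "straight") piece$len else piece$R * piece$theta_max
}

# radial distance from points P (n x 3) to the piece curve, plus local arc
# parameter. The distance is Inf outside the piece's parameter range, which
# gives voxelized tubes FLAT end caps (a clamped distance would round them
# into spherocylinders and shift the true endpoints outward).
piece_dist <- function(piece, P) {
  if (piece$kind == "straight") {
    rel <- sweep(P, 2, piece$p0)
    t <- as.vector(rel %*% piece$u)
    foot <- outer(t, piece$u)
    d <- sqrt(rowSums((rel - foot)^2))
    d[t < 0 | t > piece$len] <- Inf
    list(d = d, s = pmin(pmax(t, 0), piece$len))
  } else {
    rel <- sweep(P, 2, piece$center)
    a <- as.vector(rel %*% piece$e1)
    b <- as.vector(rel %*% piece$e2)
    nrm <- piece$e1[c(2, 3, 1)] * piece$e2[c(3, 1, 2)] -
           piece$e1[c(3, 1, 2)] * piece$e2[c(2, 3, 1)]
    h <- as.vector(rel %*% nrm)
    phi <- atan2(b, a)
    inplane <- sqrt(a^2 + b^2)
    d <- sqrt((inplane - piece$R)^2 + h^2)
    d[!(phi >= 0 & phi <= piece$theta_max)] <- Inf
    list(d = d, s = pmin(pmax(phi, 0), piece$theta_max) * piece$R)
  }
}

# main-curve pieces (in flow order) + stub pieces, with landmark arc lengths
phantom_pieces <- function(spec) {
  main <- list()
  landmarks <- numeric(0)
  if (spec$shape == "straight_tube") {
    main[[1]] <- piece_straight(c(0, 0, 0), spec$axis, spec$length_mm, 0)
  } else if (spec$shape == "curved_tube") {
    th <- spec$arc_deg * pi / 180
    main[[1]] <- piece_arc(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1),
                           spec$ring_radius_mm, th, 0)
  } else {                              # candy_cane
    R <- spec$ring_radius_mm
    h <- spec$asc_mm
    main[[1]] <- piece_straight(c(R, 0, 0), c(0, 0, 1), h, 0)
    main[[2]] <- piece_arc(c(0, 0, h), c(1, 0, 0), c(0, 0, 1), R, pi, h)
    main[[3]] <- piece_straight(c(-R, 0, h), c(0, 0, -1), spec$desc_mm,
                                h + pi * R)
  }
  total <- sum(vapply(main, piece_length, 0))
  stubs <- list()
  if (!is.null(spec$branch_stubs)) {
    for (st in spec$branch_stubs) {
      s <- st$s
      att <- phantom_point_at(main, s)
      dir <- phantom_outward_at(main, s)
      stubs[[length(stubs) + 1]] <-
        piece_straight(att, dir, st$length, 0, radius = st$radius)
      landmarks <- c(landmarks, s)
    }
  }
  list(main = main, stubs = stubs, total = total,
       landmarks = sort(landmarks))
}

# point on the main curve at global arc length s
phantom_point_at <- function(main, s) {
  for (p in main) {
    len <- piece_length(p)
    if (s <= p$s_start + len + 1e-9 && s >= p$s_start - 1e-9)
      return(as.vector(piece_point_at(p, s - p$s_start)))
  }
  stop("arc length ", s, " outside the centerline", call. = FALSE)
}

# outward direction for a stub attached at arc length s: radial for arcs,
# +z for straight pieces (arbitrary but deterministic)
phantom_outward_at <- function(main, s) {
  for (p in main) {
    len <- piece_length(p)
    if (s <= p$s_start + len + 1e-9 && s >= p$s_start - 1e-9) {
      if (p$kind == "arc") {
        th <- (s - p$s_start) / p$R
        return(cos(th) * p$e1 + sin(th) * p$e2)
      }
      return(c(0, 0, 1))
    }
  }
  stop("arc length ", s, " outside the centerline", call. = FALSE)
}

# ---- voxelization ----------------------------------------------------------

phantom_bbox <- function(spec, geo) {
  ss <- seq(0, geo$total, by = 0.5)
  pts <- do.call(rbind, lapply(geo$main, function(p) {
    sl <- ss[ss >= p$s_start - 1e-9 & ss <= p$s_start + piece_length(p) + 1e-9]
    piece_point_at(p, sl - p$s_start)
  }))
  if (length(geo$stubs)) {
    pts <- rbind(pts, do.call(rbind, lapply(geo$stubs, function(p)
      piece_point_at(p, seq(0, p$len, by = 0.5)))))
  }
  rmax <- max(phantom_radius_at(spec, ss),
              vapply(geo$stubs, function(p) p$radius, 0, USE.NAMES = FALSE),
              spec$tube_radius_mm)
  pad <- rmax + spec$wall_mm + 3
  list(lo = apply(pts, 2, min) - pad, hi = apply(pts, 2, max) + pad)
}

voxelize_spec <- function(spec, include_wall = FALSE) {
  geo <- phantom_pieces(spec)
  minrad <- min(phantom_radius_at(spec, seq(0, geo$total, by = 0.5)),
                vapply(geo$stubs, function(p) p$radius, 0,
                       USE.NAMES = FALSE) %||% Inf)
  if (minrad < 2 * max(spec$spacing))
    stop("resolution error: tube radius ", signif(minrad, 3),
         " mm is below 2 voxels at spacing ",
         paste(spec$spacing, collapse = "x"), " mm", call. = FALSE)

  bb <- phantom_bbox(spec, geo)
  nd <- pmax(2L, as.integer(ceiling((bb$hi - bb$lo) / spec$spacing)) + 1L)
  ax <- lapply(1:3, function(a) bb$lo[a] + (seq_len(nd[a]) - 1) *
                 spec$spacing[a])
  P <- cbind(rep(ax[[1]], times = nd[2] * nd[3]),
             rep(rep(ax[[2]], each = nd[1]), times = nd[3]),
             rep(ax[[3]], each = nd[1] * nd[2]))
  extra <- if (include_wall) spec$wall_mm else 0
  inside <- rep(FALSE, nrow(P))
  near <- rep(FALSE, nrow(P))
  for (p in geo$main) {
    ds <- piece_dist(p, P)
    inside <- inside | (ds$d <= phantom_radius_at(spec, p$s_start + ds$s) +
                          extra)
    near <- near | (ds$d <= phantom_radius_at(spec, p$s_start + ds$s) +
                      extra + 8)
  }
  for (p in geo$stubs) {
    ds <- piece_dist(p, P)
    inside <- inside | (ds$d <= p$radius + extra)
  }
  if (include_wall && extra > 0) {
    # a true Euclidean dilation extends the free tube ends axially by the
    # wall thickness (with rounded rims); the ball envelope at the end
    # points covers exactly that region
    end_s <- c(0, geo$total)
    for (t in 1:2) {
      ec <- phantom_point_at(geo$main, end_s[t])
      er <- phantom_radius_at(spec, end_s[t]) + extra
      dd2 <- (P[, 1] - ec[1])^2 + (P[, 2] - ec[2])^2 + (P[, 3] - ec[3])^2
      inside <- inside | (dd2 <= er^2)
    }
    for (p in geo$stubs) {
      tip <- p$p0 + p$u * p$len
      er <- p$radius + extra
      dd2 <- (P[, 1] - tip[1])^2 + (P[, 2] - tip[2])^2 + (P[, 3] - tip[3])^2
      inside <- inside | (dd2 <= er^2)
    }
  }
  if (include_wall && extra > 0 && !is.null(spec$bulge)) {
    # Where the lumen radius varies steeply (bulge flanks) the wall must be
    # a true Euclidean dilation of the lumen, i.e. the envelope of balls
    # B(c(s), r(s) + wall): the radial test alone under-fills the overhang
    # and would let a thin-slice resampling of the lumen poke through it.
    bw <- spec$bulge$width
    svals <- seq(max(0, spec$bulge$s0 - 4 * bw),
                 min(geo$total, spec$bulge$s0 + 4 * bw), by = 0.5)
    centers <- t(vapply(svals, function(s) phantom_point_at(geo$main, s),
                        numeric(3)))
    radii <- phantom_radius_at(spec, svals) + extra
    cand <- which(near & !inside)
    chunk <- 20000L
    for (lo in seq(1, length(cand), by = chunk)) {
      ix <- cand[lo:min(lo + chunk - 1L, length(cand))]
      Q <- P[ix, , drop = FALSE]
      hit <- rep(FALSE, nrow(Q))
      for (t in seq_along(svals)) {
        dd2 <- (Q[, 1] - centers[t, 1])^2 + (Q[, 2] - centers[t, 2])^2 +
               (Q[, 3] - centers[t, 3])^2
        hit <- hit | (dd2 <= radii[t]^2)
      }
      inside[ix[hit]] <- TRUE
    }
  }
  mask <- array(as.integer(inside), nd)
  if (spec$noise_flip_prob > 0) {
    mask <- with_preserved_seed(spec$seed, flip_boundary(mask, spec$spacing,
                                                         spec$noise_flip_prob))
  }
  vol <- image_volume(mask, spacing = spec$spacing, origin = bb$lo)
  list(vol = vol, geo = geo)
}

`%||%` <- function(a, b) if (length(a)) a else b

flip_boundary <- function(mask, spacing, prob) {
  arr <- mask != 0
  d <- distance_to_background(arr, spacing)
  boundary <- arr & d <= 1.5 * max(spacing)
  idx <- which(boundary)
  flip <- idx[runif(length(idx)) < prob]
  mask[flip] <- 1L - mask[flip]
  mask
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

# ---- public API ------------------------------------------------------------

#' Voxelize a phantom and return its exact ground truth
#'
#' The lumen mask sets a voxel to 1 iff its center lies within the (bulge
#' modulated) lumen radius of the analytic centerline; the returned truth is
#' exact analytic geometry, so voxelization error is the only discrepancy any
#' downstream measurement can have.
#'
#' @param spec a [phantom_spec].
#' @param thresholds named per-segment dilation thresholds in mm, used to set
#'   the truth's `dilated` flags. Default `c(ascending = 40, arch = 35,
#'   descending = 30)`.
#' @param include_wall if `TRUE`, voxelize lumen + `wall_mm` (the non-contrast
#'   condition) instead of the bare lumen.
#' @return `list(mask = image_volume, truth = list(...))`; truth carries
#'   `centerline_points` (mm, 0.5 mm sampling), `arclength`, `radius_profile`
#'   (data.frame `s`, `radius`), `landmark_arclengths`, per-segment true max
#'   diameters and `dilated` flags, `total_length_mm`, and the generating
#'   `spec`.
#' @export
make_phantom <- function(spec, thresholds = c(ascending = 40, arch = 35,
                                              descending = 30),
                         include_wall = FALSE) {
  if (!inherits(spec, "phantom_spec"))
    stop("'spec' must be a phantom_spec", call. = FALSE)
  vx <- voxelize_spec(spec, include_wall = include_wall)
  geo <- vx$geo
  ss <- seq(0, geo$total, by = 0.5)
  pts <- t(vapply(ss, function(s) phantom_point_at(geo$main, s), numeric(3)))
  radii <- phantom_radius_at(spec, ss)

  lm <- geo$landmarks
  segs <- truth_segments(spec, geo, ss)
  segmax <- vapply(segs, function(ix)
    if (length(ix)) 2 * max(radii[ix]) else NA_real_, 0)
  dil <- mapply(function(mx, th) isTRUE(mx > th), segmax[names(thresholds)],
                thresholds)
  truth <- list(
    centerline_points = pts,
    arclength = ss,
    radius_profile = data.frame(s = ss, radius = radii),
    landmark_arclengths = lm,
    total_length_mm = geo$total,
    max_diameter_mm = c(whole = 2 * max(radii), segmax),
    dilated = c(as.list(dil), list(any = any(unlist(dil)))),
    spec = spec)
  list(mask = vx$vol, truth = truth)
}

# index sets of the truth sampling per segment; landmark-based for candy canes
# with stubs or explicit landmarks, otherwise everything is "whole" only
truth_segments <- function(spec, geo, ss) {
  lm <- geo$landmarks
  if (length(lm) < 2 && spec$shape == "candy_cane") {
    # no stubs: nominal landmark positions on the arch (35% / 65% of the arc)
    R <- spec$ring_radius_mm
    lm <- spec$asc_mm + pi * R * c(0.35, 0.65)
  }
  if (length(lm) >= 2) {
    list(ascending = which(ss < lm[1]),
         arch = which(ss >= lm[1] & ss <= lm[2]),
         descending = which(ss > lm[2]))
  } else {
    list(ascending = which(ss <= max(ss)),
         arch = integer(0), descending = integer(0))
  }
}

#' Grow a vessel wall around a lumen mask
#'
#' Morphological dilation by a sphere of physical radius `wall_mm`
#' (spacing-aware; implemented by thresholding the Euclidean distance
#' transform of the background). The output is always a superset of the
#' input; `wall_mm = 0` is the identity.
#'
#' @param lumen_mask binary [image_volume].
#' @param wall_mm wall thickness in mm (>= 0).
#' @return binary [image_volume] of lumen plus wall.
#' @export
add_wall <- function(lumen_mask, wall_mm) {
  stopifnot_volume(lumen_mask)
  if (!is.numeric(wall_mm) || length(wall_mm) != 1 || wall_mm < 0)
    stop("'wall_mm' must be a single value >= 0", call. = FALSE)
  arr <- as_binary_mask(lumen_mask)
  if (wall_mm == 0) return(lumen_mask)
  d2 <- array(edt_sq(arr, lumen_mask$spacing), dim(arr))
  out <- arr | (d2 <= wall_mm^2)
  image_volume(array(as.integer(out), dim(arr)), spacing = lumen_mask$spacing,
               origin = lumen_mask$origin, direction = lumen_mask$direction)
}

#' Generate a paired contrast / non-contrast phantom cohort
#'
#' Emulates the paired same-session design used to validate the workflow:
#' each case is a random candy-cane phantom; the "contrast" arm is the bare
#' lumen voxelized at 1 mm slice thickness, the "non-contrast" arm is lumen +
#' `wall_mm` voxelized at 3 mm slice thickness (both 0.65 mm in-plane),
#' mirroring how non-contrast segmentations include the aortic wall. Exactly
#' `round(n * dilated_fraction)` cases carry an ascending-aorta bulge lifting
#' the true max lumen diameter at least 5 mm above the ascending threshold,
#' so dilated and non-dilated cases are separable by construction.
#'
#' @param n cohort size (>= 1).
#' @param seed integer; the same seed reproduces the cohort byte-identically.
#' @param dilated_fraction proportion of dilated cases in `[0, 1]`.
#' @param thresholds per-segment dilation thresholds (mm).
#' @param wall_mm wall thickness of the non-contrast arm (mm). Default 2.
#' @param radius_range base lumen radius range (mm) sampled uniformly.
#'   Default `c(9.5, 12.5)`, keeping undilated segments at least 5 mm below
#'   every threshold.
#' @return list of `n` cases, each
#'   `list(contrast_mask, noncontrast_mask, truth)`.
#' @export
make_paired_cohort <- function(n, seed = 1L, dilated_fraction = 0.5,
                               thresholds = c(ascending = 40, arch = 35,
                                              descending = 30),
                               wall_mm = 2, radius_range = c(9.5, 12.5)) {
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (dilated_fraction < 0 || dilated_fraction > 1)
    stop("'dilated_fraction' must be in [0, 1]", call. = FALSE)
  specs <- with_preserved_seed(seed, {
    k <- round(n * dilated_fraction)
    dilate_case <- seq_len(n) %in% sample(n)[seq_len(k)]
    lapply(seq_len(n), function(i) {
      r <- runif(1, radius_range[1], radius_range[2])
      asc <- runif(1, 50, 65)
      ring <- runif(1, max(38, 3 * r), max(38, 3 * r) + 15)
      desc <- asc + runif(1, 25, 45)   # descending longer => inferior outlet
      bulge <- NULL
      if (dilate_case[i]) {
        target <- thresholds[["ascending"]] + 5 + runif(1, 0, 3)
        bulge <- list(s0 = asc / 2, amplitude = target / 2 - r, width = 12)
      }
      phantom_spec("candy_cane", tube_radius_mm = r, asc_mm = asc,
                   desc_mm = desc, ring_radius_mm = ring, wall_mm = wall_mm,
                   bulge = bulge, seed = seed + i)
    })
  })
  lapply(specs, function(sp) {
    spc <- sp; spc$spacing <- c(0.65, 0.65, 1)
    spn <- sp; spn$spacing <- c(0.65, 0.65, 3)
    contrast <- make_phantom(spc, thresholds = thresholds)
    noncontrast <- make_phantom(spn, thresholds = thresholds,
                                include_wall = TRUE)
    list(contrast_mask = contrast$mask, noncontrast_mask = noncontrast$mask,
         truth = contrast$truth)
  })
}
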