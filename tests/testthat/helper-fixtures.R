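# Shared fixtures. Heavier voxel objects are built once per test run and
# cached here; everything is generated in code -- no binary fixtures on disk.

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

# canonical straight tube: radius 15 mm, length 100 mm, 1 mm isotropic
tube15 <- function() cached("tube15", {
  make_phantom(phantom_spec("straight_tube", tube_radius_mm = 15,
                            length_mm = 100, spacing = c(1, 1, 1)))
})

# quarter-torus tube: ring 50 mm, lumen radius 10 mm
qtorus <- function() cached("qtorus", {
  make_phantom(phantom_spec("curved_tube", tube_radius_mm = 10,
                            ring_radius_mm = 50, arc_deg = 90,
                            spacing = c(1, 1, 1)))
})

# candy cane with landmark stubs at CT-like spacing
cane_stubs <- function() cached("cane_stubs", {
  lm <- 60 + pi * 45 * c(0.35, 0.65)
  make_phantom(phantom_spec(
    "candy_cane", tube_radius_mm = 12, asc_mm = 60, desc_mm = 90,
    ring_radius_mm = 45,
    branch_stubs = list(list(s = lm[1], radius = 7, length = 22),
                        list(s = lm[2], radius = 7, length = 22)),
    spacing = c(0.65, 0.65, 1)))
})

# small random 2D blob mask (union of a few discs) for diameter oracles
random_blob <- function(n = 24) {
  cx <- runif(3, 5, n - 5)
  cy <- runif(3, 5, n - 5)
  r <- runif(3, 2, 6)
  xs <- matrix(rep(seq_len(n), n), n)
  ys <- t(xs)
  m <- matrix(FALSE, n, n)
  for (t in 1:3) m <- m | ((xs - cx[t])^2 + (ys - cy[t])^2 <= r[t]^2)
  m
}

# brute-force max boundary-pixel distance (the rotating-calipers oracle)
brute_max_diameter <- function(mask, pixel_mm = 1) {
  cc <- aortaquant:::largest_component_2d(mask)
  if (!any(cc)) return(0)
  pts <- aortaquant:::boundary_pixels_2d(cc) * pixel_mm
  if (nrow(pts) < 2) return(0)
  max(stats::dist(pts))
}

# small random 3D mask pair on a common grid for surface-distance oracles
random_mask3d <- function(dim3 = c(10, 10, 10), p = 0.2) {
  a <- array(runif(prod(dim3)) < p, dim3)
  # ensure nonempty
  if (!any(a)) a[ceiling(dim3[1] / 2), ceiling(dim3[2] / 2),
                 ceiling(dim3[3] / 2)] <- TRUE
  a
}

# brute-force pooled surface distances between two binary arrays
brute_surface_distances <- function(a, b, spacing) {
  bnd <- function(m) {
    w <- which(aortaquant:::boundary_voxels(m))
    d <- dim(m)
    cbind((w - 1) %% d[1], ((w - 1) %/% d[1]) %% d[2],
          (w - 1) %/% (d[1] * d[2]))
  }
  pa <- sweep(bnd(a), 2, spacing, "*")
  pb <- sweep(bnd(b), 2, spacing, "*")
  cross <- function(p, q) {
    apply(p, 1, function(v) min(sqrt(colSums((t(q) - v)^2))))
  }
  c(cross(pa, pb), cross(pb, pa))
}

vol_from <- function(arr, spacing = c(1, 1, 1)) {
  image_volume(array(as.integer(arr), dim(arr)), spacing = spacing)
}
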