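#' Cross-sectional area of a binary slice
#'
#' Foreground pixel count of the largest 4-connected component times the
#' pixel area. Restricting to the largest component protects the measurement
#' from branch-stub or neighboring-structure fragments cut by the same plane.
#'
#' @param slice_mask 2D binary matrix.
#' @param pixel_mm in-plane pixel spacing, mm (isotropic).
#' @return area in mm^2; 0 for an empty slice.
#' @export
slice_area <- function(slice_mask, pixel_mm = 1) {
  cc <- largest_component_2d(slice_mask)
  sum(cc) * pixel_mm^2
}

largest_component_2d <- function(slice_mask) {
  m <- slice_mask != 0
  if (!any(m)) return(m)
  lab <- cpp_label2d(as.logical(m), nrow(m), ncol(m))
  tab <- tabulate(lab[lab > 0])
  matrix(lab == which.max(tab), nrow(m), ncol(m))
}

# boundary pixels (4-neighbor background or image edge) of a binary matrix,
# returned as 0-based (i, j) pixel coordinates
boundary_pixels_2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  nb <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
        pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  idx <- which(core & !nb)
  cbind((idx - 1) %% nr, (idx - 1) %/% nr)
}

#' Maximal (Feret) diameter of a binary slice
#'
#' Maximal pairwise Euclidean distance between boundary-pixel centers of the
#' largest 4-connected component, computed with a convex hull plus rotating
#' calipers (the antipodal-pair sweep), so it is exact and fast even for
#' large cross-sections. A single-pixel component has diameter 0 — the
#' pixel-center convention carries an up-to-one-pixel negative bias relative
#' to outer-edge distances, which measurement tolerances absorb.
#'
#' @param slice_mask 2D binary matrix.
#' @param pixel_mm in-plane pixel spacing, mm.
#' @return diameter in mm; 0 for an empty or single-pixel slice.
#' @export
slice_max_diameter <- function(slice_mask, pixel_mm = 1) {
  cc <- largest_component_2d(slice_mask)
  if (!any(cc)) return(0)
  pts <- boundary_pixels_2d(cc) * pixel_mm
  max_pairwise_calipers(pts)
}

# rotating-calipers diameter of a 2D point set
max_pairwise_calipers <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])   # counter-clockwise hull
  hp <- pts[h, , drop = FALSE]
  m <- nrow(hp)
  if (m == 1) return(0)
  if (m == 2) return(sqrt(sum((hp[1, ] - hp[2, ])^2)))
  # chull() returns clockwise order; reverse for CCW
  hp <- hp[rev(seq_len(m)), , drop = FALSE]
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  area2 <- sum(vapply(2:(m - 1), function(t) cross(hp[1, ], hp[t, ],
                                                   hp[t + 1, ]), 0))
  if (abs(area2) < 1e-12) {
    # degenerate (collinear) hull: the caliper sweep is undefined, the
    # diameter is just the farthest pair among the hull vertices
    dd <- as.matrix(stats::dist(hp))
    return(max(dd))
  }
  best <- 0
  k <- 2L
  nxt <- function(i) if (i == m) 1L else i + 1L
  budget <- 2L * m          # k advances at most twice around in total
  for (i in seq_len(m)) {
    j <- nxt(i)
    repeat {
      best <- max(best,
                  sum((hp[i, ] - hp[k, ])^2),
                  sum((hp[j, ] - hp[k, ])^2),
                  sum((hp[i, ] - hp[nxt(k), ])^2),
                  sum((hp[j, ] - hp[nxt(k), ])^2))
      # advance the caliper while the support distance (triangle area over
      # edge i-j) does not decrease; ">=" so ties on symmetric hulls do not
      # stop the sweep early, with a global budget to prevent cycling
      cur <- abs(cross(hp[i, ], hp[j, ], hp[k, ]))
      nx <- abs(cross(hp[i, ], hp[j, ], hp[nxt(k), ]))
      if (nx >= cur && budget > 0L) {
        k <- nxt(k)
        budget <- budget - 1L
      } else break
    }
  }
  sqrt(best)
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing built directly from the normal
#' equations (no filter routine is delegated to): for each interior position
#' a degree-`order` polynomial is fit to the centered window and evaluated at
#' its center, which reduces to a fixed convolution kernel. The
#' `window %/% 2` positions at each edge are filled by evaluating the
#' polynomial fitted to the terminal window (interpolating edge mode), which
#' avoids the endpoint bias of truncation modes. Any sequence that is
#' globally a polynomial of degree <= `order` is reproduced exactly,
#' including the edges.
#'
#' @param values numeric sequence.
#' @param window odd window length. Default 11.
#' @param order polynomial degree < window. Default 2.
#' @return smoothed sequence, same length. If `length(values) < window` the
#'   input is returned unchanged with a warning.
#' @export
smooth_profile <- function(values, window = 11, order = 2) {
  if (window %% 2 != 1) stop("'window' must be odd", call. = FALSE)
  if (order >= window) stop("'order' must be < window", call. = FALSE)
  n <- length(values)
  if (n < window) {
    warning("sequence shorter than window (", n, " < ", window,
            "); returned unchanged")
    return(values)
  }
  half <- window %/% 2
  kern <- savgol_kernel(window, order)
  out <- numeric(n)
  for (i in (half + 1):(n - half))
    out[i] <- sum(kern * values[(i - half):(i + half)])
  # interpolating edges: fit the terminal windows, evaluate the polynomial
  x <- seq_len(window) - 1
  X <- outer(x, 0:order, `^`)
  XtXi <- solve(crossprod(X))
  bfirst <- XtXi %*% crossprod(X, values[1:window])
  blast <- XtXi %*% crossprod(X, values[(n - window + 1):n])
  for (i in 1:half)
    out[i] <- sum(bfirst * (i - 1)^(0:order))
  for (i in (n - half + 1):n)
    out[i] <- sum(blast * (i - (n - window + 1))^(0:order))
  out
}

#' Savitzky-Golay convolution kernel from the normal equations
#'
#' Solves the window's polynomial least-squares normal equations for the
#' weights that evaluate the fit at the window center. For `window = 5,
#' order = 2` this recovers the classical kernel `(-3, 12, 17, 12, -3)/35`.
#'
#' @param window odd window length.
#' @param order polynomial degree < window.
#' @return numeric kernel of length `window`.
#' @export
savgol_kernel <- function(window, order = 2) {
  if (window %% 2 != 1) stop("'window' must be odd", call. = FALSE)
  if (order >= window) stop("'order' must be < window", call. = FALSE)
  half <- window %/% 2
  x <- (-half):half
  X <- outer(x, 0:order, `^`)
  # center value of the fit = e1' (X'X)^-1 X' y
  as.vector(solve(crossprod(X), t(X))[1, ])
}

#' Per-slice diameter and area profile of a straightened vessel
#'
#' Applies [slice_max_diameter()] and [slice_area()] to every cross-section
#' of a straightened (curved-planar-reformatted) binary volume and smooths
#' both sequences with the Savitzky-Golay filter.
#'
#' @param sv a `straightened_volume` with binary labels.
#' @param window,order Savitzky-Golay parameters. Defaults 11 and 2.
#' @return A `cross_section_profile` data.frame-like list with `arclength`,
#'   `diameter_raw`, `diameter_smooth`, `area_raw`, `area_smooth`,
#'   `truncated`.
#' @export
profile_from_straightened <- function(sv, window = 11, order = 2) {
  if (!inherits(sv, "straightened_volume"))
    stop("'sv' must be a straightened_volume", call. = FALSE)
  arr <- sv$volume$data
  nsl <- dim(arr)[3]
  dia <- numeric(nsl)
  are <- numeric(nsl)
  for (k in seq_len(nsl)) {
    sl <- arr[, , k] != 0
    if (!any(sl)) next
    cc <- largest_component_2d(sl)
    are[k] <- sum(cc)                      # 1 mm pixels
    pts <- boundary_pixels_2d(cc)
    dia[k] <- max_pairwise_calipers(pts)
  }
  if (all(are == 0))
    stop("straightened volume has no foreground in any slice", call. = FALSE)
  prof <- list(arclength = sv$arclength[seq_len(nsl)],
               diameter_raw = dia,
               diameter_smooth = smooth_profile_quiet(dia, window, order),
               area_raw = are,
               area_smooth = smooth_profile_quiet(are, window, order),
               truncated = sv$truncated[seq_len(nsl)])
  structure(prof, class = "cross_section_profile")
}

smooth_profile_quiet <- function(v, window, order) {
  if (length(v) < window) return(v)
  smooth_profile(v, window, order)
}

#' @export
print.cross_section_profile <- function(x, ...) {
  cat("<cross_section_profile> ", length(x$arclength), " slices, ",
      sum(x$truncated), " endpoint-truncated\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cross_section_profile <- function(x, ...) {
  data.frame(arclength_mm = x$arclength, diameter_raw = x$diameter_raw,
             diameter_smooth = x$diameter_smooth, area_raw = x$area_raw,
             area_smooth = x$area_smooth, truncated = x$truncated)
}

#' Define the aortic segment boundaries
#'
#' Segments follow the landmark convention used for regional validation:
#' ascending aorta `[0, s_bct)`, aortic arch `[s_bct, s_lsa]`, descending
#' aorta `(s_lsa, end]`, with `s_bct` and `s_lsa` the arc lengths of the
#' brachiocephalic trunk and left subclavian artery origins.
#'
#' @param s_bct,s_lsa landmark arc lengths in mm, `0 < s_bct < s_lsa`.
#' @return a `segment_spec`.
#' @export
segment_spec <- function(s_bct, s_lsa) {
  if (!is.numeric(s_bct) || !is.numeric(s_lsa) || s_bct <= 0 ||
      s_bct >= s_lsa)
    stop("need 0 < s_bct < s_lsa", call. = FALSE)
  structure(list(s_bct = s_bct, s_lsa = s_lsa), class = "segment_spec")
}

#' Assign profile slices to aortic segments
#'
#' @param profile a `cross_section_profile`.
#' @param seg a [segment_spec()].
#' @return named list of integer index vectors (`ascending`, `arch`,
#'   `descending`) partitioning the non-truncated slices.
#' @export
subdivide_segments <- function(profile, seg) {
  if (!inherits(seg, "segment_spec"))
    seg <- segment_spec(seg$s_bct, seg$s_lsa)
  if (seg$s_lsa >= max(profile$arclength))
    stop("s_lsa (", seg$s_lsa, ") must be below the total arc length (",
         round(max(profile$arclength), 1), ")", call. = FALSE)
  ok <- !profile$truncated
  s <- profile$arclength
  list(ascending = which(ok & s < seg$s_bct),
       arch = which(ok & s >= seg$s_bct & s <= seg$s_lsa),
       descending = which(ok & s > seg$s_lsa))
}

#' Per-segment summary of a cross-section profile
#'
#' Max/mean/median of the smoothed diameter and area channels over the
#' non-truncated slices of each segment and of the whole vessel. Smoothed
#' channels feed the summaries; raw channels stay available in the profile
#' for audit.
#'
#' @param profile a `cross_section_profile`.
#' @param seg a [segment_spec()].
#' @return a `quant_report`: per segment (`whole`, `ascending`, `arch`,
#'   `descending`) a list of `diameter_max/mean/median` (mm) and
#'   `area_max/mean/median` (mm^2).
#' @export
summarize_segments <- function(profile, seg) {
  idx <- subdivide_segments(profile, seg)
  idx <- c(list(whole = which(!profile$truncated)), idx)
  out <- lapply(names(idx), function(nm) {
    ii <- idx[[nm]]
    if (!length(ii))
      stop("segment '", nm, "' has no non-truncated slices", call. = FALSE)
    d <- profile$diameter_smooth[ii]
    a <- profile$area_smooth[ii]
    list(diameter_max = max(d), diameter_mean = mean(d),
         diameter_median = stats::median(d),
         area_max = max(a), area_mean = mean(a),
         area_median = stats::median(a), n_slices = length(ii))
  })
  names(out) <- names(idx)
  structure(out, class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat("<quant_report>\n")
  for (nm in names(x)) {
    if (nm == "dilated" || nm == "thresholds") next
    s <- x[[nm]]
    cat(sprintf("  %-10s D max/mean/med = %5.1f /%5.1f /%5.1f mm   A max = %7.1f mm2\n",
                nm, s$diameter_max, s$diameter_mean, s$diameter_median,
                s$area_max))
  }
  if (!is.null(x$dilated)) {
    fl <- names(Filter(isTRUE, x$dilated))
    cat("  dilated: ", if (length(fl)) paste(fl, collapse = ", ") else "none",
        "\n", sep = "")
  }
  invisible(x)
}

#' Flag dilated segments
#'
#' A segment is flagged when its max diameter strictly exceeds its threshold
#' (a measurement exactly at threshold is not flagged). Defaults are the
#' clinical cutoffs 40 mm (ascending aorta), 35 mm (arch), 30 mm
#' (descending aorta).
#'
#' @param report a `quant_report`.
#' @param thresholds named numeric, mm per segment.
#' @return named logical flags, plus `any`.
#' @export
detect_dilation <- function(report, thresholds = c(ascending = 40, arch = 35,
                                                   descending = 30)) {
  segs <- intersect(names(report), c("ascending", "arch", "descending"))
  missing_th <- setdiff(segs, names(thresholds))
  if (length(missing_th))
    stop("no threshold configured for segment(s): ",
         paste(missing_th, collapse = ", "), call. = FALSE)
  flags <- lapply(segs, function(nm)
    report[[nm]]$diameter_max > thresholds[[nm]])
  names(flags) <- segs
  c(flags, list(any = any(unlist(flags))))
}

#' Regression calibration between a measurement method and a reference
#'
#' Ordinary least squares of `reference = intercept + slope * measured`,
#' the correction used to map one arm's measurements onto reference values
#' estimated from an annotated subset.
#'
#' @param measured,reference paired numeric vectors, n >= 3.
#' @return `list(intercept, slope, apply)`; `apply(x)` maps new measurements
#'   through the fit.
#' @export
calibrate_measurements <- function(measured, reference) {
  if (length(measured) != length(reference) || length(measured) < 3)
    stop("need >= 3 paired measurements", call. = FALSE)
  vx <- stats::var(measured)
  if (!is.finite(vx) || vx < 1e-12)
    stop("degenerate predictor: measured values are (nearly) constant",
         call. = FALSE)
  slope <- stats::cov(measured, reference) / vx
  intercept <- mean(reference) - slope * mean(measured)
  list(intercept = intercept, slope = slope,
       apply = function(x) intercept + slope * x)
}
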