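# Cross-section measurement, smoothing, segmentation and calibration.

test_that("slice_area counts the largest 4-connected component", {
  expect_equal(slice_area(matrix(FALSE, 8, 8)), 0)
  sq <- matrix(FALSE, 12, 12)
  sq[2:11, 2:11] <- TRUE
  expect_equal(slice_area(sq, 1), 100)
  # a detached fragment must not contribute
  frag <- sq
  frag[1, 1] <- TRUE
  expect_equal(slice_area(frag, 1), 100)
  # rasterized disc r = 10 mm within 2% of pi r^2
  n <- 25
  xs <- matrix(rep(seq_len(n) - 13, n), n)
  disc <- xs^2 + t(xs)^2 <= 10^2
  expect_lt(abs(slice_area(disc, 1) - pi * 100) / (pi * 100), 0.02)
})

test_that("slice_max_diameter matches conventions on degenerate shapes", {
  expect_equal(slice_max_diameter(matrix(FALSE, 5, 5)), 0)
  single <- matrix(FALSE, 5, 5)
  single[3, 3] <- TRUE
  expect_equal(slice_max_diameter(single), 0)
  row <- matrix(FALSE, 3, 13)
  row[2, 2:12] <- TRUE                  # 11 collinear pixel centers
  expect_equal(slice_max_diameter(row, 1), 10)
  expect_equal(slice_max_diameter(row, 0.5), 5)
})

test_that("rotating calipers equals the brute-force pairwise oracle", {
  set.seed(101)
  for (rep in 1:200) {
    m <- random_blob()
    expect_identical(slice_max_diameter(m, 1), brute_max_diameter(m, 1))
  }
})

test_that("convex slices satisfy the area/diameter inequality", {
  set.seed(7)
  n <- 31
  xs <- matrix(rep(seq_len(n) - 16, n), n)
  for (r in c(4, 7, 11)) {
    disc <- xs^2 + t(xs)^2 <= r^2
    d <- slice_max_diameter(disc)
    a <- slice_area(disc)
    expect_gte(d + 1e-9, 2 * sqrt(a / pi) - 1)  # pixel-center bias <= 1 px
  }
})

test_that("Savitzky-Golay reproduces low-degree polynomials exactly", {
  expect_equal(smooth_profile(rep(30, 50), 11, 2), rep(30, 50))
  v <- (0:40)^2
  expect_equal(smooth_profile(v, 11, 2), v, tolerance = 1e-9)
  vlin <- 3 * (0:30) + 2
  expect_equal(smooth_profile(vlin, 11, 2), vlin, tolerance = 1e-9)
})

test_that("Savitzky-Golay kernel solver recovers the classical window-5 kernel", {
  expect_equal(savgol_kernel(5, 2), c(-3, 12, 17, 12, -3) / 35,
               tolerance = 1e-12)
  # kernels are normalized and symmetric for any odd window
  for (w in c(7, 11, 15)) {
    k <- savgol_kernel(w, 2)
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_equal(k, rev(k), tolerance = 1e-12)
  }
})

test_that("smoothing argument validation and short-input passthrough", {
  expect_error(smooth_profile(1:20, window = 10), "odd")
  expect_error(smooth_profile(1:20, window = 5, order = 5), "order")
  expect_warning(out <- smooth_profile(1:5, window = 11), "unchanged")
  expect_equal(out, 1:5)
})

test_that("segment subdivision follows the half-open landmark convention", {
  prof <- structure(list(
    arclength = 0:300, diameter_raw = rep(30, 301),
    diameter_smooth = rep(30, 301), area_raw = rep(700, 301),
    area_smooth = rep(700, 301), truncated = rep(FALSE, 301)),
    class = "cross_section_profile")
  idx <- subdivide_segments(prof, segment_spec(100, 150))
  expect_equal(prof$arclength[idx$ascending], 0:99)
  expect_equal(prof$arclength[idx$arch], 100:150)
  expect_equal(prof$arclength[idx$descending], 151:300)
  # partition of the non-truncated slices
  all_idx <- sort(unname(unlist(idx)))
  expect_equal(all_idx, seq_along(prof$arclength))
  expect_error(segment_spec(150, 150), "s_bct")
  expect_error(segment_spec(200, 100), "s_bct")
})

test_that("summaries use smoothed channels and satisfy structure invariants", {
  set.seed(5)
  raw <- 30 + rnorm(301, sd = 0.5)
  prof <- structure(list(
    arclength = 0:300, diameter_raw = raw,
    diameter_smooth = smooth_profile(raw),
    area_raw = pi * (raw / 2)^2, area_smooth = smooth_profile(pi * (raw / 2)^2),
    truncated = c(rep(TRUE, 3), rep(FALSE, 295), rep(TRUE, 3))),
    class = "cross_section_profile")
  rep_ <- summarize_segments(prof, segment_spec(100, 150))
  expect_equal(rep_$whole$diameter_max,
               max(rep_$ascending$diameter_max, rep_$arch$diameter_max,
                   rep_$descending$diameter_max))
  for (nm in c("whole", "ascending", "arch", "descending")) {
    expect_gte(rep_[[nm]]$diameter_max, rep_[[nm]]$diameter_mean)
    expect_gte(rep_[[nm]]$diameter_mean, 0)
  }
  expect_equal(rep_$whole$diameter_mean, mean(prof$diameter_smooth[4:298]))
})

test_that("dilation flags use strict inequality at the threshold", {
  mkrep <- function(asc, arch, desc) {
    structure(list(
      whole = list(diameter_max = max(asc, arch, desc)),
      ascending = list(diameter_max = asc),
      arch = list(diameter_max = arch),
      descending = list(diameter_max = desc)), class = "quant_report")
  }
  f <- detect_dilation(mkrep(41, 34, 29))
  expect_true(f$ascending); expect_false(f$arch); expect_false(f$descending)
  expect_true(f$any)
  f2 <- detect_dilation(mkrep(39.9, 34, 29))
  expect_false(f2$any)
  f3 <- detect_dilation(mkrep(40, 35, 30))       # exactly at threshold
  expect_false(f3$ascending); expect_false(f3$any)
  expect_error(detect_dilation(mkrep(40, 35, 30), c(ascending = 40)),
               "threshold")
})

test_that("regression calibration equals the closed-form OLS solution", {
  expect_equal(calibrate_measurements(c(10, 20, 30), c(10, 20, 30))[1:2],
               list(intercept = 0, slope = 1))
  cal <- calibrate_measurements(c(10, 20, 30), c(12, 22, 32))
  expect_equal(cal$intercept, 2)
  expect_equal(cal$slope, 1)
  expect_equal(cal$apply(100), 102)
  set.seed(11)
  x <- runif(50, 20, 50)
  y <- 1.7 * x - 3 + rnorm(50)
  cal2 <- calibrate_measurements(x, y)
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(cal2$intercept, beta[1], tolerance = 1e-9)
  expect_equal(cal2$slope, beta[2], tolerance = 1e-9)
  expect_error(calibrate_measurements(rep(5, 10), 1:10), "degenerate")
})
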