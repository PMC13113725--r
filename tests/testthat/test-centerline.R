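# Endpoint detection, inlet/outlet selection, centerline extraction.

test_that("straight tube endpoints sit at the end-face centers", {
  ph <- tube15()
  cand <- detect_endpoints(ph$mask)
  expect_equal(nrow(cand), 2)
  # ordered by descending z; within 3 voxels (3 mm) of the analytic centers
  expect_lt(sqrt(sum((cand[1, ] - c(0, 0, 100))^2)), 3)
  expect_lt(sqrt(sum((cand[2, ] - c(0, 0, 0))^2)), 3)
})

test_that("branch stubs contribute endpoint candidates", {
  ph <- cane_stubs()
  cand <- detect_endpoints(ph$mask)
  expect_gte(nrow(cand), 4)
  # the two main ends are among the candidates
  ends <- rbind(c(45, 0, 0), c(-45, 0, -30))
  for (t in 1:2) {
    dmin <- min(sqrt(rowSums(sweep(cand, 2, ends[t, ])^2)))
    expect_lt(dmin, 4)
  }
})

test_that("degenerate masks are rejected with informative errors", {
  empty <- vol_from(array(FALSE, c(6, 6, 6)))
  expect_error(detect_endpoints(empty), "empty")
  two <- array(FALSE, c(12, 12, 12))
  two[2:4, 2:4, 2:4] <- TRUE
  two[8:10, 8:10, 8:10] <- TRUE
  expect_error(detect_endpoints(vol_from(two)), "2 connected components")
})

test_that("inlet/outlet selection implements first + farthest with tie order", {
  cands <- rbind(c(0, 0, 100), c(0, 0, 50), c(0, 0, 0))
  io <- select_inlet_outlet(cands)
  expect_equal(io$inlet, c(0, 0, 100))
  expect_equal(io$outlet, c(0, 0, 0))
  two <- rbind(c(1, 2, 3), c(4, 5, 6))
  io2 <- select_inlet_outlet(two)
  expect_equal(io2$inlet, c(1, 2, 3))
  expect_equal(io2$outlet, c(4, 5, 6))
  # distance tie: (3,4,0) and (5,0,0) are both 5 from the origin
  tie <- rbind(c(0, 0, 0), c(3, 4, 0), c(5, 0, 0))
  expect_equal(select_inlet_outlet(tie)$outlet, c(3, 4, 0))
  expect_error(select_inlet_outlet(rbind(c(0, 0, 0))), "2 endpoint")
})

test_that("straight-tube centerline recovers the axis and its length", {
  ph <- tube15()
  io <- select_inlet_outlet(detect_endpoints(ph$mask))
  cl <- extract_centerline(ph$mask, io$inlet, io$outlet)
  expect_true(all(abs(cl$points[, 1]) <= 1))      # within 1 voxel of axis
  expect_true(all(abs(cl$points[, 2]) <= 1))
  expect_lt(abs(max(cl$arclength) - 100) / 100, 0.03)
  # arc length strictly increasing, uniform spacing (gap CV < 5%)
  expect_true(all(diff(cl$arclength) > 0))
  gaps <- diff(cl$arclength)
  core <- gaps[-length(gaps)]                      # final gap may be partial
  expect_lt(sd(core) / mean(core), 0.05)
})

test_that("curved-tube centerline arc length matches the analytic arc", {
  ph <- qtorus()
  io <- select_inlet_outlet(detect_endpoints(ph$mask))
  cl <- extract_centerline(ph$mask, io$inlet, io$outlet)
  expect_lt(abs(max(cl$arclength) - pi / 2 * 50) / (pi / 2 * 50), 0.03)
})

test_that("centrality: the path runs along the medial axis", {
  ph <- tube15()
  io <- select_inlet_outlet(detect_endpoints(ph$mask))
  cl <- extract_centerline(ph$mask, io$inlet, io$outlet)
  arr <- ph$mask$data != 0
  dt <- aortaquant:::distance_to_background(arr, ph$mask$spacing)
  idx <- round(aortaquant:::world_to_index(ph$mask, cl$points))
  lin <- 1 + idx[, 1] + dim(arr)[1] * (idx[, 2] + dim(arr)[2] * idx[, 3])
  vals <- dt[lin]
  interior <- vals[cl$arclength > 15 & cl$arclength < 85]
  expect_gte(mean(interior), 0.8 * 15)
})

test_that("reversal symmetry and degenerate input handling", {
  ph <- tube15()
  io <- select_inlet_outlet(detect_endpoints(ph$mask))
  a <- extract_centerline(ph$mask, io$inlet, io$outlet)
  b <- extract_centerline(ph$mask, io$outlet, io$inlet)
  # compare at matched arc-length positions from opposite ends
  rev_b <- b$points[nrow(b$points):1, ]
  n <- min(nrow(a$points), nrow(rev_b))
  dev <- sqrt(rowSums((a$points[1:n, ] - rev_b[1:n, ])^2))
  expect_lt(max(dev), 1.5)                         # within ~1 voxel
  expect_error(extract_centerline(ph$mask, io$inlet, io$inlet), "degenerate")
  expect_error(extract_centerline(ph$mask, io$inlet, io$outlet, step_mm = 0),
               "step_mm")
})

test_that("disconnected inlet/outlet is reported", {
  two <- array(FALSE, c(20, 8, 8))
  two[2:6, 3:6, 3:6] <- TRUE
  two[14:18, 3:6, 3:6] <- TRUE
  v <- vol_from(two)
  expect_error(extract_centerline(v, c(3, 4, 4), c(16, 4, 4)),
               "not connected")
})

test_that("centerline serialization round trips", {
  ph <- tube15()
  io <- select_inlet_outlet(detect_endpoints(ph$mask))
  cl <- extract_centerline(ph$mask, io$inlet, io$outlet)
  fj <- withr::local_tempfile(fileext = ".json")
  write_centerline(cl, fj)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$step_mm, 1)
  expect_equal(length(back$arclength), nrow(cl$points))
  fc <- withr::local_tempfile(fileext = ".csv")
  write_centerline(cl, fc)
  df <- read.csv(fc)
  expect_equal(nrow(df), nrow(cl$points))
  expect_equal(df$z_mm, cl$points[, 3])
})
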