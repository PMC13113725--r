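# Phantom generator: voxelization accuracy against analytic geometry, walls,
# cohort construction.

test_that("straight tube slice areas match the analytic disc", {
  ph <- tube15()
  arr <- ph$mask$data
  expect_equal(ph$truth$radius_profile$radius,
               rep(15, nrow(ph$truth$radius_profile)))
  nz <- dim(arr)[3]
  z0 <- ph$mask$origin[3] + (seq_len(nz) - 1)     # 1 mm spacing
  interior <- which(z0 > 5 & z0 < 95)
  areas <- vapply(interior, function(k) sum(arr[, , k]), 0)
  expect_true(all(abs(areas - pi * 225) / (pi * 225) < 0.02))
})

test_that("curved tube truth arc length matches the analytic arc", {
  ph <- qtorus()
  expect_lt(abs(ph$truth$total_length_mm - pi / 2 * 50) / (pi / 2 * 50),
            0.001)
  # voxelization error on interior cross-sections (property at r = 10 >= 5 vox)
  s <- ph$truth$arclength
  expect_true(all(diff(s) > 0))
})

test_that("unresolvable geometry is refused", {
  expect_error(make_phantom(phantom_spec("straight_tube",
                                         tube_radius_mm = 0.5,
                                         spacing = c(1, 1, 1))),
               "resolution")
  expect_error(phantom_spec("straight_tube", tube_radius_mm = -2), "> 0")
  expect_error(phantom_spec("candy_cane",
                            bulge = list(s0 = 10, amplitude = -1, width = 5)),
               "amplitude")
})

test_that("bulge construction is monotone in amplitude", {
  prev <- 0
  for (amp in c(0, 2, 5, 9)) {
    sp <- phantom_spec("candy_cane", tube_radius_mm = 10, asc_mm = 50,
                       desc_mm = 80, ring_radius_mm = 40,
                       bulge = if (amp > 0)
                         list(s0 = 25, amplitude = amp, width = 10),
                       spacing = c(1.3, 1.3, 2))
    ph <- make_phantom(sp)
    mx <- ph$truth$max_diameter_mm[["whole"]]
    expect_gte(mx, prev)
    prev <- mx
  }
})

test_that("add_wall dilates by the physical wall thickness", {
  ph <- tube15()
  expect_identical(add_wall(ph$mask, 0)$data, ph$mask$data)
  walled <- add_wall(ph$mask, 2)
  expect_true(all(walled$data >= ph$mask$data))   # superset
  # outer diameter on a mid slice ~ 34 mm within 2 voxels
  k <- round(dim(walled$data)[3] / 2)
  d <- slice_max_diameter(walled$data[, , k] != 0, 1)
  expect_lt(abs(d - 34), 2)
  expect_error(add_wall(ph$mask, -1), ">= 0")
})

test_that("landmark arc lengths coincide with stub attachment points", {
  ph <- cane_stubs()
  lm <- ph$truth$landmark_arclengths
  expect_equal(lm, 60 + pi * 45 * c(0.35, 0.65), tolerance = 1e-9)
  expect_true(all(diff(lm) > 0))
  expect_true(all(lm > 0 & lm < ph$truth$total_length_mm))
})

test_that("paired cohort: counts, determinism, wall superset", {
  co <- make_paired_cohort(6, seed = 42, dilated_fraction = 0.5)
  expect_length(co, 6)
  dil <- vapply(co, function(cs) isTRUE(cs$truth$dilated$ascending), TRUE)
  expect_equal(sum(dil), 3)
  # same seed -> byte-identical masks
  co2 <- make_paired_cohort(6, seed = 42, dilated_fraction = 0.5)
  expect_identical(co[[2]]$contrast_mask$data, co2[[2]]$contrast_mask$data)
  expect_identical(co[[5]]$noncontrast_mask$data,
                   co2[[5]]$noncontrast_mask$data)
  # different seed -> different cohort
  co3 <- make_paired_cohort(6, seed = 43, dilated_fraction = 0.5)
  expect_false(identical(co[[1]]$contrast_mask$data,
                         co3[[1]]$contrast_mask$data))
  # spacing conventions of the two arms
  expect_equal(co[[1]]$contrast_mask$spacing, c(0.65, 0.65, 1))
  expect_equal(co[[1]]$noncontrast_mask$spacing, c(0.65, 0.65, 3))
  # non-contrast arm contains the contrast arm after resampling to 1 mm
  # (grids share the origin; compare on the common subgrid)
  for (cs in co[1:2]) {
    rc <- resample_isotropic(cs$contrast_mask, 1, "nearest")
    rn <- resample_isotropic(cs$noncontrast_mask, 1, "nearest")
    dd <- pmin(dim(rc$data), dim(rn$data))
    a <- rc$data[seq_len(dd[1]), seq_len(dd[2]), seq_len(dd[3])]
    b <- rn$data[seq_len(dd[1]), seq_len(dd[2]), seq_len(dd[3])]
    expect_equal(sum(a == 1 & b == 0), 0)
  }
})

test_that("dilated cases clear their threshold by the construction margin", {
  co <- make_paired_cohort(6, seed = 9, dilated_fraction = 0.5)
  for (cs in co) {
    tmax <- cs$truth$max_diameter_mm[["ascending"]]
    if (isTRUE(cs$truth$dilated$ascending)) {
      expect_gte(tmax, 45)
    } else {
      expect_lte(tmax, 35)
      expect_false(cs$truth$dilated$arch)
      expect_false(cs$truth$dilated$descending)
    }
  }
})
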