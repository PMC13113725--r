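# Overlap and surface-distance metrics, checked against voxel counting and
# brute-force all-pairs distance oracles.

nested_cubes <- function() {
  a <- array(FALSE, c(8, 8, 8)); a[3:6, 3:6, 3:6] <- TRUE   # 4^3
  b <- array(FALSE, c(8, 8, 8)); b[4:5, 4:5, 4:5] <- TRUE   # 2^3 inside
  list(a = vol_from(a), b = vol_from(b))
}

test_that("dice and iou match voxel counting", {
  cu <- nested_cubes()
  expect_equal(dice(cu$a, cu$a), 1)
  expect_equal(iou(cu$a, cu$a), 1)
  expect_equal(dice(cu$a, cu$b), 2 * 8 / (8 + 64))
  expect_equal(iou(cu$a, cu$b), 8 / 64)
  disj <- array(FALSE, c(8, 8, 8)); disj[1, 1, 1] <- TRUE
  expect_equal(dice(cu$a, vol_from(disj)), 0)
  empty <- vol_from(array(FALSE, c(8, 8, 8)))
  expect_equal(dice(empty, empty), 1)
  expect_equal(iou(empty, empty), 1)
  small <- vol_from(array(0L, c(4, 4, 4)))
  expect_error(dice(cu$a, small), "grid")
})

test_that("iou = dice / (2 - dice) on random pairs", {
  set.seed(31)
  for (rep in 1:20) {
    a <- vol_from(random_mask3d())
    b <- vol_from(random_mask3d())
    d <- dice(a, b)
    expect_equal(iou(a, b), d / (2 - d), tolerance = 1e-12)
  }
})

test_that("surface distances on constructed cases", {
  p1 <- array(FALSE, c(9, 9, 9)); p1[5, 5, 2] <- TRUE
  p2 <- array(FALSE, c(9, 9, 9)); p2[5, 5, 5] <- TRUE
  expect_equal(hausdorff95(vol_from(p1), vol_from(p2)), 3)
  expect_equal(assd(vol_from(p1), vol_from(p2)), 3)
  # two parallel 1-voxel plates 4 mm apart: every nearest distance is 4
  q1 <- array(FALSE, c(6, 6, 9)); q1[, , 2] <- TRUE
  q2 <- array(FALSE, c(6, 6, 9)); q2[, , 6] <- TRUE
  expect_equal(assd(vol_from(q1), vol_from(q2)), 4)
  cu <- nested_cubes()
  expect_equal(hausdorff95(cu$a, cu$a), 0)
  expect_equal(assd(cu$a, cu$a), 0)
  empty <- vol_from(array(FALSE, c(9, 9, 9)))
  expect_error(assd(vol_from(p1), empty), "empty")
})

test_that("hd95/assd equal brute-force oracles on random masks incl. anisotropy", {
  set.seed(77)
  for (rep in 1:12) {
    spacing <- if (rep %% 2) c(1, 1, 1) else c(0.65, 0.65, 3)
    a <- random_mask3d(c(10, 11, 9), p = 0.15)
    b <- random_mask3d(c(10, 11, 9), p = 0.15)
    va <- vol_from(a, spacing); vb <- vol_from(b, spacing)
    pooled <- brute_surface_distances(a, b, spacing)
    expect_equal(hausdorff95(va, vb),
                 as.numeric(quantile(pooled, 0.95, type = 7)),
                 tolerance = 1e-9)
    expect_equal(assd(va, vb), mean(pooled), tolerance = 1e-9)
  }
})

test_that("metrics are symmetric and translation-equivariant", {
  set.seed(55)
  a0 <- random_mask3d(c(10, 10, 10), 0.15)
  b0 <- random_mask3d(c(10, 10, 10), 0.15)
  a <- array(FALSE, c(14, 14, 14)); a[2:11, 2:11, 2:11] <- a0
  b <- array(FALSE, c(14, 14, 14)); b[2:11, 2:11, 2:11] <- b0
  as_ <- array(FALSE, c(14, 14, 14)); as_[4:13, 4:13, 4:13] <- a0
  bs_ <- array(FALSE, c(14, 14, 14)); bs_[4:13, 4:13, 4:13] <- b0
  va <- vol_from(a); vb <- vol_from(b)
  expect_equal(dice(va, vb), dice(vb, va))
  expect_equal(hausdorff95(va, vb), hausdorff95(vb, va))
  expect_equal(assd(va, vb), assd(vb, va))
  expect_equal(dice(va, vb), dice(vol_from(as_), vol_from(bs_)))
  expect_equal(hausdorff95(va, vb),
               hausdorff95(vol_from(as_), vol_from(bs_)), tolerance = 1e-9)
})

test_that("dice decreases monotonically under progressive erosion", {
  ball <- array(FALSE, c(15, 15, 15))
  xs <- (1:15) - 8
  for (i in 1:15) for (j in 1:15) for (k in 1:15)
    ball[i, j, k] <- xs[i]^2 + xs[j]^2 + xs[k]^2 <= 36
  ref <- vol_from(ball)
  prev <- 1
  for (shrink in c(5, 4, 3)) {
    er <- array(FALSE, c(15, 15, 15))
    for (i in 1:15) for (j in 1:15) for (k in 1:15)
      er[i, j, k] <- xs[i]^2 + xs[j]^2 + xs[k]^2 <= shrink^2
    d <- dice(ref, vol_from(er))
    expect_lt(d, prev)
    prev <- d
  }
})

test_that("seg_compare bundles all four metrics consistently", {
  cu <- nested_cubes()
  m <- seg_compare(cu$a, cu$b)
  expect_equal(m$dice, dice(cu$a, cu$b))
  expect_equal(m$iou, iou(cu$a, cu$b))
  expect_equal(m$hd95_mm, hausdorff95(cu$a, cu$b))
  expect_equal(m$assd_mm, assd(cu$a, cu$b))
  expect_true(m$iou <= m$dice && m$dice <= 1)
  expect_gte(m$hd95_mm, 0)
})
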