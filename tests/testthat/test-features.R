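# Feature extraction: contrast ratios, splits, length, volume, bilateral.

make_feature_fixture <- function() {
  # 6x6x12 grid, reference block of 100s, LC block {110, 120}
  arr <- array(100, c(6, 6, 12))
  arr[2, 2, 3] <- 110
  arr[2, 2, 4] <- 120
  vol <- as_volume(arr, 0.5)
  lc <- array(0L, dim(arr)); lc[2, 2, 3] <- 1L; lc[2, 2, 4] <- 1L
  ref <- array(0L, dim(arr)); ref[5, 5, 3:8] <- 1L
  list(vol = vol, lc = as_mask(lc, like = vol), ref = as_mask(ref, like = vol))
}

test_that("contrast_ratio reproduces the printed formula", {
  fx <- make_feature_fixture()
  expect_equal(contrast_ratio(fx$lc, fx$vol, fx$ref, "max"), 0.2)
  expect_equal(contrast_ratio(fx$lc, fx$vol, fx$ref, "median"), 0.15)
  # LC equal to reference: ratio 0
  same <- fx
  same$vol$data[2, 2, 3:4] <- 100
  expect_equal(contrast_ratio(same$lc, same$vol, same$ref, "max"), 0)
  # errors: empty masks, zero reference median
  empty <- as_mask(array(0L, dim(fx$vol$data)), like = fx$vol)
  expect_error(contrast_ratio(empty, fx$vol, fx$ref, "max"),
               class = "lcseg_feature_error")
  expect_error(contrast_ratio(fx$lc, fx$vol, empty, "max"),
               class = "lcseg_feature_error")
  zref <- fx
  zref$vol$data[5, 5, 3:8] <- 0
  expect_error(contrast_ratio(zref$lc, zref$vol, zref$ref, "max"),
               class = "lcseg_division_error")
})

test_that("contrast_ratio equals a brute-force oracle on random grids", {
  set.seed(8)
  for (rep in 1:20) {
    n <- 6
    vol <- as_volume(array(runif(n^3, 50, 150), c(n, n, n)), 1)
    lc <- random_mask(n, 0.2)
    ref <- random_mask(n, 0.2)
    if (sum(lc$data) == 0 || sum(ref$data) == 0) next
    # sort-based median oracle
    med <- function(v) {
      v <- sort(v); m <- length(v)
      if (m %% 2) v[(m + 1) / 2] else (v[m / 2] + v[m / 2 + 1]) / 2
    }
    rv <- vol$data[ref$data == 1L]
    lv <- vol$data[lc$data == 1L]
    expect_equal(contrast_ratio(lc, vol, ref, "max"),
                 (max(lv) - med(rv)) / med(rv))
    expect_equal(contrast_ratio(lc, vol, ref, "median"),
                 (med(lv) - med(rv)) / med(rv))
    # scaling invariance / shift non-invariance
    vol2 <- vol; vol2$data <- vol$data * 3.7
    expect_equal(contrast_ratio(lc, vol2, ref, "max"),
                 contrast_ratio(lc, vol, ref, "max"), tolerance = 1e-12)
    vol3 <- vol; vol3$data <- vol$data + 50
    expect_false(isTRUE(all.equal(contrast_ratio(lc, vol3, ref, "max"),
                                  contrast_ratio(lc, vol, ref, "max"))))
  }
})

test_that("split_rostrocaudal follows the stated rounding rule", {
  mk_rod <- function(nz) rod_mask(shape = c(5, 5, nz + 4), nz = nz)
  # S = 9, n = 3: exact thirds
  s3 <- split_rostrocaudal(mk_rod(9), 3)
  expect_identical(vapply(s3, function(m) sum(m$data), integer(1)), c(3L, 3L, 3L))
  # S = 10, n = 3: round(10/3) = 3, round(20/3) = 7 -> sizes 3, 4, 3
  s3b <- split_rostrocaudal(mk_rod(10), 3)
  expect_identical(vapply(s3b, function(m) sum(m$data), integer(1)),
                   c(3L, 4L, 3L))
  # partition property + near-equal sizes for many S, n
  for (nz in 3:17) for (n in 2:3) {
    if (nz < n) next
    rod <- mk_rod(nz)
    secs <- split_rostrocaudal(rod, n)
    u <- Reduce(`+`, lapply(secs, function(m) m$data))
    expect_identical(u, rod$data)           # union = mask, disjoint (0/1 sum)
    sizes <- vapply(secs, function(m) sum(m$data), integer(1))
    expect_lte(max(sizes) - min(sizes), 1L)
  }
  expect_error(split_rostrocaudal(mk_rod(2), 3), class = "lcseg_feature_error")
})

test_that("sections are ordered caudal to rostral even on flipped grids", {
  rod <- rod_mask(shape = c(5, 5, 16), nz = 12)
  s <- split_rostrocaudal(rod, 2)
  # default affine: low slice index = inferior = caudal
  expect_lt(max(lcseg:::mask_axial_slices(s[[1]])),
            min(lcseg:::mask_axial_slices(s[[2]])))
  # flip the axial axis in the affine: low index now superior -> reversed
  Af <- rod$affine
  Af[3, 3] <- -1
  rodf <- as_mask(rod$data, voxel_size = rod$voxel_size, affine = Af)
  sf <- split_rostrocaudal(rodf, 2)
  expect_gt(max(lcseg:::mask_axial_slices(sf[[1]])),
            min(lcseg:::mask_axial_slices(sf[[2]])))
})

test_that("length and volume follow the counting definitions", {
  rod <- rod_mask(shape = c(5, 5, 26), nz = 20, voxel = 0.375)
  expect_equal(lc_length_mm(rod), 7.5)
  empty <- as_mask(array(0L, c(4, 4, 4)), voxel_size = 0.375)
  expect_equal(lc_length_mm(empty), 0)
  expect_equal(lc_volume_mm3(empty), 0)
  # gap: occupied slices counted, not extent
  g <- array(0L, c(5, 5, 26))
  g[3, 3, c(3:11, 14:22)] <- 1L
  gap <- as_mask(g, voxel_size = 0.375)
  expect_equal(lc_length_mm(gap), 18 * 0.375)
  # 100 voxels at 0.375 isotropic
  h <- array(0L, c(10, 10, 10))
  h[sample.int(1000, 100)] <- 1L
  expect_equal(lc_volume_mm3(as_mask(h, voxel_size = 0.375)), 5.2734375)
  # brute-force counting oracle on a random mask
  set.seed(3)
  m <- random_mask(8, 0.4, voxel = 0.7)
  expect_equal(lc_volume_mm3(m), sum(m$data) * 0.7^3)
  cnt <- 0
  for (k in 1:8) if (any(m$data[, , k] == 1L)) cnt <- cnt + 1
  expect_equal(lc_length_mm(m), cnt * 0.7)
})

test_that("extract_features: symmetry, bilateral mean, partial flag", {
  # perfectly mirrored scene
  arr <- array(100, c(12, 8, 12))
  lcL <- array(0L, dim(arr)); lcR <- array(0L, dim(arr))
  refL <- array(0L, dim(arr)); refR <- array(0L, dim(arr))
  arr[3, 4, 4:9] <- c(110, 115, 120, 120, 115, 110)
  arr[10, 4, 4:9] <- c(110, 115, 120, 120, 115, 110)
  lcL[3, 4, 4:9] <- 1L; lcR[10, 4, 4:9] <- 1L
  refL[2, 7, 5:8] <- 1L; refR[11, 7, 5:8] <- 1L
  vol <- as_volume(arr, 0.5)
  lc <- hemi_pair(as_mask(lcL, like = vol), as_mask(lcR, like = vol))
  ref <- hemi_pair(as_mask(refL, like = vol), as_mask(refR, like = vol))
  f <- extract_features(vol, lc, ref)
  expect_equal(f$left, f$right)
  expect_equal(f$left, f$bilateral)
  expect_false(f$partial)
  expect_equal(f$bilateral$cr_max, 0.2)
  # cr_max >= cr_median; cr_max = max over section CRs
  expect_gte(f$bilateral$cr_max, f$bilateral$cr_median)
  expect_equal(max(f$left$sub3_cr_max), f$left$cr_max)
  expect_equal(max(f$left$sub2_cr_max), f$left$cr_max)
  # asymmetric: bilateral is the unweighted mean
  arr2 <- arr
  arr2[10, 4, 6:7] <- 130
  vol2 <- as_volume(arr2, 0.5)
  f2 <- extract_features(vol2, lc, ref)
  expect_equal(f2$bilateral$cr_max, (0.2 + 0.3) / 2)
  # empty hemisphere: NA side, partial bilateral from the other side
  lc_e <- hemi_pair(as_mask(array(0L, dim(arr)), like = vol), lc$right)
  fe <- extract_features(vol, lc_e, ref)
  expect_true(fe$partial)
  expect_true(is.na(fe$left$cr_max))
  expect_equal(fe$bilateral$cr_max, fe$right$cr_max)
  # data frame flattening
  df <- as.data.frame(f)
  expect_identical(df$scope, c("left", "right", "bilateral"))
  expect_identical(ncol(df), 16L)
})

test_that("a planted rostral contrast gradient is detected by sub3 CRs", {
  arr <- array(100, c(12, 8, 14))
  lcL <- array(0L, dim(arr)); lcR <- array(0L, dim(arr))
  refL <- array(0L, dim(arr)); refR <- array(0L, dim(arr))
  grad <- seq(110, 130, length.out = 9)   # rising toward superior = rostral
  arr[3, 4, 3:11] <- grad
  arr[10, 4, 3:11] <- grad
  lcL[3, 4, 3:11] <- 1L; lcR[10, 4, 3:11] <- 1L
  refL[2, 7, 5:8] <- 1L; refR[11, 7, 5:8] <- 1L
  vol <- as_volume(arr, 0.5)
  f <- extract_features(vol, hemi_pair(as_mask(lcL, like = vol),
                                       as_mask(lcR, like = vol)),
                        hemi_pair(as_mask(refL, like = vol),
                                  as_mask(refR, like = vol)))
  expect_gt(f$bilateral$sub3_cr_max[["rostral"]],
            f$bilateral$sub3_cr_max[["caudal"]])
})
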