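# LC coordinate frame, offset learning, reference placement.

test_that("principal_axis: axis-aligned rod, rotated rod, degenerate cases", {
  rod <- rod_mask()
  expect_equal(principal_axis(rod), c(0, 0, 1), tolerance = 1e-12)
  # rotate the same voxel cloud 30 degrees about x and compare against an
  # independent eigen-decomposition of the rotated coordinates
  R <- lcseg:::rot_x(30)
  A <- diag(4)
  A[1:3, 1:3] <- R
  got <- principal_axis(rod, affine = A)
  xyz <- lcseg:::voxel_to_world(A, lcseg:::mask_voxels(rod))
  eg <- eigen(stats::cov(xyz), symmetric = TRUE)
  want <- eg$vectors[, 1]
  if (want[3] < 0) want <- -want
  expect_equal(got, want, tolerance = 1e-6)
  expect_equal(got, as.vector(R %*% c(0, 0, 1)), tolerance = 1e-6)
  # 2 voxels: degenerate
  two <- as_mask(array(c(1L, 1L, rep(0L, 25)), c(3, 3, 3)), voxel_size = 1)
  expect_error(principal_axis(two), class = "lcseg_geometry_error")
})

test_that("compute_frame reproduces the parallel-rod closed form", {
  # rods at x = +-4 mm: v1 = z, v2 = (c_l - c_r) x v1 / |.| = y, v3 = -x
  a <- array(0L, c(17, 9, 25))
  a[3, 5, 3:22] <- 1L   # left rod (low grid x)
  b <- array(0L, c(17, 9, 25))
  b[13, 5, 3:22] <- 1L  # right rod
  A <- lcseg:::centered_affine(c(17, 9, 25), c(0.8, 1, 1))
  left <- suppressWarnings(as_mask(a, voxel_size = c(0.8, 1, 1), affine = A))
  right <- suppressWarnings(as_mask(b, voxel_size = c(0.8, 1, 1), affine = A))
  fr <- compute_frame(hemi_pair(left, right))
  expect_equal(fr$v1, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fr$v2, c(0, 1, 0), tolerance = 1e-9)
  expect_equal(fr$v3, c(-1, 0, 0), tolerance = 1e-9)
  expect_frame_orthonormal(fr)
  # swapping hemispheres flips v2 and v3, keeps v1
  fr2 <- compute_frame(hemi_pair(right, left))
  expect_equal(fr2$v1, fr$v1)
  expect_equal(fr2$v2, -fr$v2)
  expect_equal(fr2$v3, -fr$v3)
})

test_that("frame is orthonormal/right-handed across random phantoms", {
  spec <- fast_spec(rotation_deg = 25)
  for (seed in 1:40) {
    s <- generate_phantom(spec, seed = seed, masks_only = TRUE)
    expect_frame_orthonormal(compute_frame(s$lc_truth))
  }
})

test_that("frame is rotation-equivariant within rasterization limits", {
  spec0 <- fast_spec(rotation_deg = 0)
  s0 <- generate_phantom(spec0, seed = 4, masks_only = TRUE)
  fr0 <- compute_frame(s0$lc_truth)
  spec <- fast_spec(rotation_deg = 30)
  for (seed in c(8, 15, 23)) {
    s <- generate_phantom(spec, seed = seed, masks_only = TRUE)
    R <- lcseg:::rot_xyz(s$applied_rotation_deg)
    fr <- compute_frame(s$lc_truth)
    for (v in c("v1", "v2", "v3"))
      expect_lt(max(abs(fr[[v]] - as.vector(R %*% fr0[[v]]))), 1e-3 * 30)
    # 1e-3-per-component equivariance holds for the rotation applied to the
    # same scene's own frame: check origin too
    expect_lt(max(abs(fr$origin - as.vector(R %*% fr0$origin))), 0.5)
  }
})

test_that("world/frame round-trips and basis examples", {
  s <- generate_phantom(fast_spec(rotation_deg = 18), seed = 2, masks_only = TRUE)
  fr <- compute_frame(s$lc_truth)
  expect_equal(world_to_frame(fr, fr$origin), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(world_to_frame(fr, fr$origin + fr$v1), c(1, 0, 0),
               tolerance = 1e-9)
  set.seed(1)
  pts <- matrix(rnorm(30, sd = 5), 10, 3)
  expect_equal(frame_to_world(fr, world_to_frame(fr, pts)), pts,
               tolerance = 1e-9)
})

test_that("learn_offset averages per-sample frame offsets", {
  spec <- fast_spec(rotation_deg = 10)
  samples <- lapply(1:4, function(i)
    generate_phantom(spec, seed = i, masks_only = TRUE))
  model <- learn_offset(samples)
  expect_identical(model$n_training, 4L)
  expect_equal(model$mean_left, colMeans(model$per_sample$left))
  # single sample: mean equals that sample's offset
  m1 <- learn_offset(samples[1])
  expect_equal(m1$mean_left, model$per_sample$left[1, ])
  # planted offsets recovered
  expect_lt(max(abs(model$mean_left - spec$ref_offset_frame$left)), 0.3)
  expect_lt(max(abs(model$mean_right - spec$ref_offset_frame$right)), 0.3)
})

test_that("place_reference_region matches a brute-force rotated-box test", {
  s <- generate_phantom(fast_spec(rotation_deg = 22), seed = 13,
                        masks_only = TRUE)
  fr <- compute_frame(s$lc_truth)
  model <- learn_offset(list(s))
  shape_mm <- c(4, 3, 3)
  pair <- place_reference_region(fr, model, shape_mm, grid = s$volume)
  # independent membership check per voxel: point-in-rotated-box
  shape <- dim(s$volume$data)
  idx0 <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                                k = 0:(shape[3] - 1)))
  w <- lcseg:::voxel_to_world(s$volume$affine, idx0)
  B <- cbind(fr$v1, fr$v2, fr$v3)
  for (side in c("left", "right")) {
    ctr <- if (side == "left") model$mean_left else model$mean_right
    rel <- sweep(w, 2, fr$origin) %*% B
    rel <- sweep(rel, 2, ctr - shape_mm / 2)
    inside <- rel[, 1] >= 0 & rel[, 1] < shape_mm[1] &
      rel[, 2] >= 0 & rel[, 2] < shape_mm[2] &
      rel[, 3] >= 0 & rel[, 3] < shape_mm[3]
    expect_identical(as.vector(pair[[side]]$data), as.integer(inside))
  }
  # identity-frame sanity: 3-voxel cube at the grid center has 27 voxels
  g <- as_volume(array(0, c(9, 9, 9)), 1)
  idfr <- structure(list(origin = c(0, 0, 0), v1 = c(1, 0, 0),
                         v2 = c(0, 1, 0), v3 = c(0, 0, 1)),
                    class = "lc_frame")
  m0 <- structure(list(mean_left = c(0, 0, 0), mean_right = c(0, 0, 3),
                       n_training = 1L, per_sample = NULL),
                  class = "lc_offsetmodel")
  pr <- place_reference_region(idfr, m0, c(3, 3, 3), grid = g)
  expect_identical(sum(pr$left$data), 27L)
  # fully outside grid: placement error
  m_out <- structure(list(mean_left = c(100, 0, 0), mean_right = c(0, 0, 3),
                          n_training = 1L, per_sample = NULL),
                     class = "lc_offsetmodel")
  expect_error(place_reference_region(idfr, m_out, c(3, 3, 3), grid = g),
               class = "lcseg_placement_error")
})

test_that("placed regions never overlap the LC on default geometry", {
  spec <- fast_spec(rotation_deg = 15)
  samples <- lapply(1:6, function(i)
    generate_phantom(spec, seed = 30 + i, masks_only = TRUE))
  model <- learn_offset(samples)
  for (s in samples) {
    fr <- compute_frame(s$lc_truth)
    pair <- place_reference_region(fr, model, spec$ref_region_shape_mm,
                                   grid = s$volume)
    lc_union <- s$lc_truth$left$data | s$lc_truth$right$data
    expect_false(any((pair$left$data | pair$right$data) & lc_union))
  }
})
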