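# Networks and ensembling: voting, localization arithmetic, training
# contracts.  Training tests run on tiny 16^3 inputs so they take seconds.

tiny_config <- function(...) {
  net_config(depth = 2, base_channels = 4, patch_size_vox = c(16, 16, 16),
             loc_downsample = 2, max_epochs = 5, patience = 2,
             batch_size = 1, lr = 3e-3, ...)
}

# prepared (x, y) sample: bright ball at a random position in a 16^3 grid
tiny_sample <- function(seed) {
  lcseg:::with_seed(seed, {
    n <- 16
    ctr <- runif(3, 5, 11)
    g <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
    d2 <- (g$i - ctr[1])^2 + (g$j - ctr[2])^2 + (g$k - ctr[3])^2
    y <- array(as.integer(d2 <= 9), c(n, n, n))
    x <- array(rnorm(n^3, 0, 0.1), c(n, n, n)) + y * 2
    list(x = lcseg:::zscore_arr(x), y = y)
  })
}

test_that("majority_vote: identity, threshold arithmetic, counting oracle", {
  set.seed(1)
  m <- random_mask(6)
  expect_identical(majority_vote(rep(list(m), 5))$data, m$data)
  # votes (1,1,1,0,0) -> 1; (1,1,0,0,0) -> 0 at a chosen voxel
  z <- as_mask(array(0L, c(6, 6, 6)), voxel_size = 1)
  o <- as_mask(array(c(1L, rep(0L, 215)), c(6, 6, 6)), voxel_size = 1)
  expect_identical(majority_vote(list(o, o, o, z, z))$data[1], 1L)
  expect_identical(majority_vote(list(o, o, z, z, z))$data[1], 0L)
  # brute-force per-voxel oracle on random 10^3 masks + permutation invariance
  masks <- lapply(1:5, function(i) random_mask(10))
  got <- majority_vote(masks)
  brute <- array(0L, c(10, 10, 10))
  for (v in seq_along(brute)) {
    cnt <- sum(vapply(masks, function(m) m$data[v], integer(1)))
    brute[v] <- as.integer(cnt >= 3)
  }
  expect_identical(got$data, brute)
  expect_identical(majority_vote(masks[c(3, 1, 5, 2, 4)])$data, got$data)
  expect_error(majority_vote(masks[1:4]), class = "lcseg_argument_error")
  expect_error(majority_vote(c(masks[1:4], list(random_mask(9)))),
               class = "lcseg_argument_error")
})

test_that("locate_lc_centers reflects ensemble averaging arithmetic", {
  n <- 12
  blob <- function(at) {
    a <- array(0, c(n, n, n))
    a[at[1] + (-1:1), at[2] + (-1:1), at[3] + (-1:1)] <- 1
    a
  }
  A <- blob(c(3, 6, 6)); B <- blob(c(9, 6, 6))
  # all 5 members agree: centers are the blob centroids
  avg <- (A + B)
  got <- locate_lc_centers(avg)
  expect_identical(nrow(got$centers), 2L)
  expect_equal(got$centers[order(got$centers[, 1]), ],
               rbind(c(2, 5, 5), c(8, 5, 5)), ignore_attr = TRUE)
  # 3 of 5 members vote for A: average 0.6 > 0.5 survives; 2 of 5 does not
  avg2 <- (3 * A + 2 * B) / 5
  got2 <- locate_lc_centers(avg2)
  expect_identical(nrow(got2$centers), 1L)
  expect_equal(got2$centers[1, ], c(2, 5, 5), ignore_attr = TRUE)
  expect_identical(nrow(locate_lc_centers(array(0, c(n, n, n)))$centers), 0L)
})

test_that("train_member learns, early-stops, and is seed-reproducible", {
  cfg <- tiny_config()
  train <- lapply(1:6, tiny_sample)
  val <- lapply(7:8, tiny_sample)
  m <- train_member("segmentation", train, val, cfg, seed = 1)
  expect_s3_class(m, "lc_member")
  # learning sanity: best val loss beats the first epoch's
  expect_lt(m$best_val, m$log$val_loss[1])
  # early-stopping contract: stopped no later than best_epoch + patience
  expect_lte(nrow(m$log), m$best_epoch + cfg$patience)
  # reproducibility: identical run, identical trajectory and parameters
  m2 <- train_member("segmentation", train, val, cfg, seed = 1)
  expect_identical(m$log, m2$log)
  expect_identical(m$best_epoch, m2$best_epoch)
  expect_identical(m$params, m2$params)
  # trained member beats chance on a held-out ball
  held <- tiny_sample(99)
  p <- lcseg:::unet_predict(m$params, held$x, cfg$depth)
  pred <- (p >= 0.5) * 1L
  d <- 2 * sum(pred & held$y) / (sum(pred) + sum(held$y))
  expect_gt(d, 0.5)
})

test_that("training halts early on a plateau and flags non-finite loss", {
  # lr = 0 freezes the parameters: the validation loss can never improve,
  # so training must stop after exactly 1 + patience epochs
  cfg <- net_config(depth = 2, base_channels = 2, patch_size_vox = 8,
                    loc_downsample = 2, max_epochs = 50, patience = 2,
                    batch_size = 1, lr = 0)
  s <- tiny_sample(5)
  s$x <- s$x[1:8, 1:8, 1:8]
  s$y <- s$y[1:8, 1:8, 1:8]
  m <- train_member("segmentation", list(s), list(s), cfg, seed = 2)
  expect_identical(nrow(m$log), 1L + cfg$patience)
  expect_identical(m$best_epoch, 1L)
  # a non-finite activation surfaces as a typed training error
  cfg2 <- net_config(depth = 2, base_channels = 2, patch_size_vox = 8,
                     loc_downsample = 2, max_epochs = 8, patience = 2,
                     batch_size = 1, lr = 1e-3)
  s2 <- tiny_sample(1)
  s2$x <- s2$x[1:8, 1:8, 1:8]
  s2$y <- s2$y[1:8, 1:8, 1:8]
  s2$x[1] <- NaN
  expect_error(
    train_member("segmentation", list(s2), list(s2), cfg2, seed = 1),
    class = "lcseg_training_error")
})

test_that("train_ensemble builds 5 members per stage with honest splits", {
  spec <- phantom_spec(grid_shape = c(16, 16, 16), voxel_size_mm = 1.2,
                       lc_length_mm = 6, lc_diameter_mm = 2.4,
                       inter_lc_distance_mm = 6, lc_curvature_mm = 0.2,
                       noise_sd = 0.02, bias_amplitude = 0, rotation_deg = 5,
                       ref_offset_frame = list(left = c(0, -4, 1.2),
                                               right = c(0, -4, -1.2)),
                       ref_region_shape_mm = c(3, 2.5, 2.5))
  ds <- generate_dataset(6, spec, seed = 11)
  cfg <- net_config(depth = 2, base_channels = 2, patch_size_vox = 16,
                    loc_downsample = 2, max_epochs = 2, patience = 1,
                    batch_size = 2, lr = 3e-3)
  model <- train_ensemble(ds, cfg, seed = 4)
  expect_length(model$loc_members, 5L)
  expect_length(model$seg_members, 5L)
  for (i in 1:5)
    expect_length(intersect(model$splits[[i]]$train, model$splits[[i]]$val), 0)
  # serialization round-trip reproduces identical predictions
  path <- tempfile(fileext = ".lcseg")
  save_model(model, path)
  back <- load_model(path)
  x <- lcseg:::zscore_arr(ds[[1]]$volume$data)
  p1 <- lcseg:::unet_predict(model$seg_members[[1]]$params, x, cfg$depth)
  p2 <- lcseg:::unet_predict(back$seg_members[[1]]$params, x, cfg$depth)
  expect_identical(p1, p2)
  expect_true(file.exists(paste0(path, ".json")))
  unlink(c(path, paste0(path, ".json")))
  expect_error(train_ensemble(ds[1:3], cfg), class = "lcseg_argument_error")
})

test_that("network gradients match finite differences on a tiny net", {
  set.seed(31)
  params <- lcseg:::unet_init(1, 2)
  x <- array(rnorm(6^3), c(6, 6, 6))
  y <- array(rbinom(216, 1, 0.3), c(6, 6, 6))
  g <- lcseg:::cpp_unet_grad(params, as.double(x), dim(x), as.double(y), 1L)
  for (nm in c("enc0_c1_W", "bott_c2_W", "dec0_c1_W", "out_W", "out_b")) {
    eps <- 2e-3
    up <- params; up[[nm]][1] <- up[[nm]][1] + eps
    dn <- params; dn[[nm]][1] <- dn[[nm]][1] - eps
    l1 <- lcseg:::cpp_unet_grad(up, as.double(x), dim(x), as.double(y), 1L)$loss
    l0 <- lcseg:::cpp_unet_grad(dn, as.double(x), dim(x), as.double(y), 1L)$loss
    fd <- (l1 - l0) / (2 * eps)
    # float32 forward passes limit finite-difference precision
    expect_lt(abs(g$grads[[nm]][1] - fd), 1e-3 + 0.01 * abs(fd))
  }
})
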