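# Tiny 3D U-Net training: configuration, initialization, Adam, early
# stopping, and the five-member ensemble builder.
#
# Both cascade stages use the same architecture; they differ only in their
# input representation.  The localization stage sees the whole volume
# block-averaged by `loc_downsample` (z-scored) and learns a dilated LC
# probability map (dilation radius 2 working-grid voxels stabilizes the
# tiny target).  The segmentation stage sees a z-scored patch around the
# LC pair and learns the hard LC labels.  The loss is soft-Dice plus
# binary cross-entropy, the de-facto choice under the extreme class
# imbalance of a ~100-voxel structure in a 64^3 patch.

#' Network/training configuration
#'
#' @param depth number of pooling steps; patch edges must be divisible by
#'   `2^depth`.
#' @param base_channels channels of the first encoder level (doubled per
#'   level).
#' @param patch_size_vox segmentation-stage patch edges, working-grid
#'   voxels.
#' @param loc_downsample integer block-averaging factor for the
#'   localization stage.
#' @param loss_name loss identifier (only `"dice_bce"` is implemented).
#' @param pos_weight weight of foreground voxels in the BCE term.  The LC
#'   occupies well under 1% of a patch; a moderate fixed weight keeps the
#'   background term from swamping the foreground without the gross
#'   over-segmentation a raw class-ratio weight causes.
#' @param lr Adam learning rate.
#' @param max_epochs,patience training length and early-stopping patience
#'   (epochs without validation improvement).
#' @param batch_size gradient-accumulation batch size.
#' @param seed training seed.
#' @return List of class `lc_netconfig`.
#' @export
net_config <- function(depth = 2, base_channels = 8,
                       patch_size_vox = c(64, 64, 64), loc_downsample = 4,
                       loss_name = "dice_bce", pos_weight = 10, lr = 1e-2,
                       max_epochs = 12, patience = 3, batch_size = 1,
                       seed = 1) {
  patch_size_vox <- rep_len(as.integer(patch_size_vox), 3L)
  if (any(patch_size_vox %% (2^depth) != 0))
    lcseg_error("lcseg_argument_error",
                "patch_size_vox must be divisible by 2^depth")
  if (patience >= max_epochs)
    lcseg_error("lcseg_argument_error", "patience must be < max_epochs")
  if (loss_name != "dice_bce")
    lcseg_error("lcseg_argument_error", "only loss_name = 'dice_bce' is implemented")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 patch_size_vox = patch_size_vox,
                 loc_downsample = as.integer(loc_downsample),
                 loss_name = loss_name, pos_weight = pos_weight, lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), seed = seed),
            class = "lc_netconfig")
}

# He-initialized parameter list; draws from the current RNG stream
unet_init <- function(depth, base_channels, in_channels = 1L) {
  params <- list()
  add <- function(name, cin, cout) {
    params[[paste0(name, "_W")]] <<- array(
      rnorm(27 * cin * cout, 0, sqrt(2 / (27 * cin))), c(3, 3, 3, cin, cout))
    params[[paste0(name, "_b")]] <<- rep(0, cout)
    params[[paste0(name, "_g")]] <<- rep(1, cout)   # instance-norm scale
    params[[paste0(name, "_n")]] <<- rep(0, cout)   # instance-norm shift
  }
  ch <- base_channels * 2^(0:depth)
  cin <- in_channels
  for (l in seq_len(depth) - 1L) {
    add(sprintf("enc%d_c1", l), cin, ch[l + 1])
    add(sprintf("enc%d_c2", l), ch[l + 1], ch[l + 1])
    cin <- ch[l + 1]
  }
  add("bott_c1", cin, ch[depth + 1])
  add("bott_c2", ch[depth + 1], ch[depth + 1])
  up_ch <- ch[depth + 1]
  for (l in rev(seq_len(depth) - 1L)) {
    add(sprintf("dec%d_c1", l), up_ch + ch[l + 1], ch[l + 1])
    add(sprintf("dec%d_c2", l), ch[l + 1], ch[l + 1])
    up_ch <- ch[l + 1]
  }
  params[["out_W"]] <- rnorm(ch[1], 0, sqrt(1 / ch[1]))
  params[["out_b"]] <- 0
  params
}

# forward pass on a raw array
unet_predict <- function(params, x, depth) {
  cpp_unet_predict(params, as.double(x), as.integer(dim(x)), as.integer(depth))
}

# soft-Dice + positive-weighted BCE on a probability array (validation
# twin of the C++ training loss)
dice_bce_loss <- function(p, y, pos_weight = 10) {
  eps <- 1
  num <- 2 * sum(p * y) + eps
  den <- sum(p) + sum(y) + eps
  n <- length(y)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  bce <- -sum(pos_weight * y * log(pc) + (1 - y) * log(1 - pc)) / n
  (1 - num / den) + bce
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- sample preparation -----------------------------------------------------

# z-score an array (population SD; training-time twin of normalize_patch)
zscore_arr <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (!is.finite(s) || s == 0)
    lcseg_error("lcseg_normalization_error", "constant input cannot be z-scored")
  (x - mu) / s
}

# localization-stage sample: block-averaged z-scored volume, dilated target
prepare_loc_sample <- function(sample, config) {
  vol <- sample$volume
  f <- config$loc_downsample
  shape <- dim(vol$data)
  if (any(shape %% f != 0))
    lcseg_error("lcseg_argument_error", "grid not divisible by loc_downsample")
  x <- cpp_downsample_mean(as.double(vol$data), as.integer(shape), f)
  union <- (sample$lc_truth$left$data | sample$lc_truth$right$data) * 1L
  dil <- cpp_dilate3(as.integer(union), as.integer(shape), 2L)
  y <- cpp_downsample_max(dil, as.integer(shape), f)
  list(x = zscore_arr(x), y = y)
}

# segmentation-stage sample: normalized patch at the (jittered) true LC
# pair midpoint, with the hard LC union labels as target
prepare_seg_sample <- function(sample, config, jitter_vox = 0L) {
  vol <- sample$volume
  c_l <- colMeans(mask_voxels(sample$lc_truth$left))
  c_r <- colMeans(mask_voxels(sample$lc_truth$right))
  center <- round((c_l + c_r) / 2)
  if (jitter_vox > 0)
    center <- center + sample.int(2 * jitter_vox + 1, 3, replace = TRUE) -
      jitter_vox - 1
  center <- pmin(pmax(center, 0), dim(vol$data) - 1)
  px <- extract_patch(vol, center, config$patch_size_vox)
  union <- as_mask((sample$lc_truth$left$data | sample$lc_truth$right$data) * 1L,
                   like = vol)
  py <- crop_to_patch(union$data, px$offset)
  list(x = normalize_patch(px$patch)$data, y = py)
}

prepare_stage_samples <- function(samples, stage, config) {
  lapply(samples, function(s) {
    if (!inherits(s, "lc_phantom")) return(s)  # already prepared list(x, y)
    if (stage == "localization") prepare_loc_sample(s, config)
    else prepare_seg_sample(s, config, jitter_vox = 2L)
  })
}

# ---- training ---------------------------------------------------------------

#' Train one ensemble member
#'
#' Runs Adam on the soft-Dice + BCE loss with gradient accumulation over
#' `batch_size` samples, tracks the best validation loss, and stops after
#' `patience` epochs without improvement.  Single-threaded runs with a
#' fixed seed are bit-reproducible.
#'
#' @param stage `"localization"` or `"segmentation"`.
#' @param train,val nonempty lists of phantom samples (or prepared
#'   `list(x, y)` pairs with matching array shapes).
#' @param config an [net_config()].
#' @param seed training seed (default `config$seed`).
#' @return List of class `lc_member` with `params` (best-validation
#'   state), `log` (per-epoch data frame), `best_epoch` and `stage`.
#' @export
train_member <- function(stage = c("localization", "segmentation"),
                         train, val, config, seed = config$seed) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "lc_netconfig"))
  if (length(train) == 0L || length(val) == 0L)
    lcseg_error("lcseg_argument_error", "train and val must be nonempty")
  tr <- prepare_stage_samples(train, stage, config)
  va <- prepare_stage_samples(val, stage, config)
  with_seed(seed, {
    params <- unet_init(config$depth, config$base_channels)
    ad <- adam_init(params)
    best <- params
    best_val <- Inf
    best_epoch <- 0L
    wait <- 0L
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(length(tr))
      losses <- numeric(0)
      batch <- list()
      flush <- function(batch) {
        if (length(batch) == 0L) return(NULL)
        gsum <- NULL
        for (g in batch)
          gsum <- if (is.null(gsum)) g else Map(`+`, gsum, g)
        gmean <- lapply(gsum, function(g) g / length(batch))
        st <- adam_step(params, gmean, ad, config$lr)
        params <<- st$params
        ad <<- st$state
        NULL
      }
      for (i in ord) {
        s <- tr[[i]]
        res <- cpp_unet_grad(params, as.double(s$x), as.integer(dim(s$x)),
                             as.double(s$y), config$depth,
                             pos_weight = config$pos_weight)
        if (!is.finite(res$loss))
          lcseg_error("lcseg_training_error",
                      sprintf("non-finite loss at epoch %d", epoch))
        losses <- c(losses, res$loss)
        batch[[length(batch) + 1L]] <- res$grads
        if (length(batch) >= config$batch_size) {
          flush(batch)
          batch <- list()
        }
      }
      flush(batch)
      val_loss <- mean(vapply(va, function(s) {
        p <- unet_predict(params, s$x, config$depth)
        dice_bce_loss(p, s$y, config$pos_weight)
      }, numeric(1)))
      if (!is.finite(val_loss))
        lcseg_error("lcseg_training_error",
                    sprintf("non-finite validation loss at epoch %d", epoch))
      log <- rbind(log, data.frame(epoch = epoch, train_loss = mean(losses),
                                   val_loss = val_loss))
      if (val_loss < best_val - 1e-6) {
        best <- params
        best_val <- val_loss
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(list(params = best, log = log, best_epoch = best_epoch,
                   best_val = best_val, stage = stage),
              class = "lc_member")
  })
}

#' Train the full five-member two-stage ensemble
#'
#' Splits the dataset with [make_final_split()] (k = 5) and trains one
#' localization and one segmentation member per split; member `i`
#' validates on subset `i` and trains on the rest.
#'
#' @param dataset list of at least 5 phantom samples.
#' @param config an [net_config()].
#' @param seed master seed (drives the split and per-member seeds).
#' @return List of class `lc_ensemble` with `loc_members`, `seg_members`
#'   (5 `lc_member` each), `config`, `train_norm_stats`, `version`.
#' @export
train_ensemble <- function(dataset, config, seed = config$seed) {
  if (length(dataset) < 5L)
    lcseg_error("lcseg_argument_error", "need at least 5 training samples")
  splits <- make_final_split(length(dataset), 5L, seed)
  members <- function(stage) lapply(seq_len(5L), function(i) {
    sp <- splits[[i]]
    train_member(stage, dataset[sp$train], dataset[sp$val], config,
                 seed = derive_seed(seed, i, salt = match(stage, c(
                   "localization", "segmentation"))))
  })
  structure(list(loc_members = members("localization"),
                 seg_members = members("segmentation"),
                 config = config, splits = splits,
                 train_norm_stats = list(scheme = "zscore_per_input"),
                 version = "lcseg-0.1.0"),
            class = "lc_ensemble")
}

#' @export
print.lc_ensemble <- function(x, ...) {
  cat(sprintf("<lc_ensemble> %d loc + %d seg members, depth %d, base %d, v%s\n",
              length(x$loc_members), length(x$seg_members),
              x$config$depth, x$config$base_channels, x$version))
  invisible(x)
}

#' Save / load a trained ensemble
#'
#' The model archive is a single RDS file; a JSON sidecar
#' (`<path>.json`) records the configuration and version for inspection.
#' A serialization round-trip reproduces identical predictions.
#'
#' @param model an `lc_ensemble`.
#' @param path archive path (e.g. `model.lcseg`).
#' @return `path` (save) or the restored `lc_ensemble` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "lc_ensemble"))
  saveRDS(model, path)
  sidecar <- list(version = model$version,
                  config = unclass(model$config),
                  n_loc_members = length(model$loc_members),
                  n_seg_members = length(model$seg_members))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "lc_ensemble"))
    lcseg_error("lcseg_io_error", "file does not contain an lc_ensemble")
  model
}
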