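# Ensemble inference: probability averaging for localization, per-voxel
# majority vote for segmentation.

#' Per-voxel majority vote over five binary masks
#'
#' Output voxel is 1 iff at least 3 of the 5 masks are 1 there; with five
#' voters no tie is possible.  Permutation-invariant and idempotent on
#' identical inputs.
#'
#' @param masks list of exactly 5 `lc_mask` objects on identical grids.
#' @return The voted `lc_mask`.
#' @export
majority_vote <- function(masks) {
  if (length(masks) != 5L)
    lcseg_error("lcseg_argument_error", "majority_vote needs exactly 5 masks")
  ref <- masks[[1]]
  for (m in masks) {
    if (!inherits(m, "lc_mask"))
      lcseg_error("lcseg_argument_error", "all inputs must be lc_mask")
    if (!same_grid(m, ref))
      lcseg_error("lcseg_argument_error", "masks must share a grid")
  }
  votes <- Reduce(`+`, lapply(masks, function(m) m$data))
  as_mask(array(as.integer(votes >= 3L), dim(ref$data)),
          voxel_size = ref$voxel_size, affine = ref$affine,
          axis_convention = ref$axis_convention)
}

#' Extract candidate centers from an averaged localization probability map
#'
#' Thresholds the map at 0.5, labels 6-connected components, and returns
#' their centroids (0-based voxel coordinates on the map's grid) ordered
#' by decreasing component size.
#'
#' @param prob 3-D probability array (member average).
#' @param threshold probability threshold, default 0.5 (inclusive).
#' @return List with `centers` (k x 3 matrix) and `sizes`.
#' @export
locate_lc_centers <- function(prob, threshold = 0.5) {
  bin <- array(as.integer(prob >= threshold), dim(prob))
  lab <- cpp_label3(bin, as.integer(dim(prob)))
  k <- max(lab)
  if (k == 0L) return(list(centers = matrix(numeric(0), 0, 3), sizes = integer(0)))
  centers <- t(vapply(seq_len(k), function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    colMeans(idx) - 1
  }, numeric(3)))
  sizes <- vapply(seq_len(k), function(l) sum(lab == l), integer(1))
  list(centers = centers, sizes = sizes)
}

#' Localize the two LCs with the ensemble
#'
#' The five localization members predict on the block-averaged volume;
#' their probability maps are voxel-wise averaged, thresholded at 0.5, and
#' the two largest connected components give the left/right patch centers,
#' rescaled to the full-resolution grid and assigned left/right by their
#' world left-right coordinate (from the affine, never the grid index).
#' If only one component is found it is split at its left-right world
#' midpoint (fallback, flagged); no component raises a localization error.
#'
#' @param model an `lc_ensemble`.
#' @param volume the working-resolution `lc_volume`.
#' @return List with `left`, `right` (0-based full-resolution voxel
#'   coordinates), `fallback_used`, and `avg_prob` (downsampled grid).
#' @export
localize <- function(model, volume) {
  stopifnot(inherits(model, "lc_ensemble"), inherits(volume, "lc_volume"))
  cfg <- model$config
  f <- cfg$loc_downsample
  shape <- dim(volume$data)
  if (any(shape %% f != 0))
    lcseg_error("lcseg_argument_error", "grid not divisible by loc_downsample")
  x <- zscore_arr(cpp_downsample_mean(as.double(volume$data),
                                      as.integer(shape), f))
  probs <- lapply(model$loc_members, function(m)
    unet_predict(m$params, x, cfg$depth))
  avg <- Reduce(`+`, probs) / length(probs)
  loc <- locate_lc_centers(avg, 0.5)
  fallback <- FALSE
  if (nrow(loc$centers) == 0L)
    lcseg_error("lcseg_localization_error",
                "no component above threshold in the averaged probability map")
  to_full <- function(c_ds) (c_ds + 0.5) * f - 0.5
  if (nrow(loc$centers) >= 2L) {
    cand <- loc$centers[1:2, , drop = FALSE]
  } else {
    # single component: split at its left-right world midpoint
    fallback <- TRUE
    bin <- array(as.integer(avg >= 0.5), dim(avg))
    lab <- cpp_label3(bin, as.integer(dim(avg)))
    idx <- which(lab == 1L, arr.ind = TRUE) - 1
    A_ds <- volume$affine
    A_ds[1:3, 1:3] <- A_ds[1:3, 1:3] * f
    A_ds[1:3, 4] <- A_ds[1:3, 4] + volume$affine[1:3, 1:3] %*% rep((f - 1) / 2, 3)
    w <- voxel_to_world(A_ds, idx)
    mid <- mean(range(w[, 1]))
    grp <- w[, 1] <= mid
    if (all(grp) || !any(grp))
      lcseg_error("lcseg_localization_error",
                  "single-component fallback could not split the blob")
    cand <- rbind(colMeans(idx[grp, , drop = FALSE]),
                  colMeans(idx[!grp, , drop = FALSE]))
  }
  full <- t(apply(cand, 1, to_full))
  wx <- voxel_to_world(volume$affine, full)[, 1]
  left_i <- which.min(wx)   # RAS: left = smaller x
  list(left = full[left_i, ], right = full[3 - left_i, ],
       fallback_used = fallback, avg_prob = avg)
}

#' Segment a normalized patch with the ensemble
#'
#' Each segmentation member predicts a probability map over the patch,
#' thresholded at 0.5 into a hard mask; the five masks are combined with
#' [majority_vote()].
#'
#' @param model an `lc_ensemble`.
#' @param patch a normalized patch `lc_volume` of shape
#'   `config$patch_size_vox`.
#' @return The voted `lc_mask` on the patch grid.
#' @export
segment_patch <- function(model, patch) {
  stopifnot(inherits(model, "lc_ensemble"), inherits(patch, "lc_volume"))
  cfg <- model$config
  if (!all(dim(patch$data) == cfg$patch_size_vox))
    lcseg_error("lcseg_argument_error",
                sprintf("patch shape %s does not match config %s",
                        paste(dim(patch$data), collapse = "x"),
                        paste(cfg$patch_size_vox, collapse = "x")))
  masks <- lapply(model$seg_members, function(m) {
    p <- unet_predict(m$params, patch$data, cfg$depth)
    as_mask(array(as.integer(p >= 0.5), dim(p)), like = patch)
  })
  majority_vote(masks)
}
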