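# End-to-end inference: localization -> patch extraction -> patch
# re-normalization -> ensemble segmentation -> full-volume reconstruction
# -> hemisphere splitting.
#
# One axis-aligned patch covers both hemispheres (centered at the midpoint
# of the two localization centers); left/right is always decided in world
# space through the affine.

#' Extract an axis-aligned patch around a voxel center
#'
#' The crop is clamped at the grid borders and zero-padded so the patch
#' always has the requested size; the returned offset record allows exact
#' re-insertion.
#'
#' @param volume an `lc_volume`.
#' @param center 0-based voxel coordinates (rounded to integers).
#' @param size patch edges in voxels (each `<=` the grid shape).
#' @return List with `patch` (`lc_volume`) and `offset` (re-insertion
#'   record with `start`, `size`, `src`, `dst`, `full_shape`).
#' @export
extract_patch <- function(volume, center, size) {
  stopifnot(inherits(volume, "lc_volume"))
  shape <- dim(volume$data)
  size <- rep_len(as.integer(size), 3L)
  if (any(size > shape))
    lcseg_error("lcseg_argument_error", "patch size exceeds the grid")
  center <- round(center)
  if (any(center < 0) || any(center >= shape))
    lcseg_error("lcseg_argument_error", "patch center outside the grid")
  start <- as.integer(center - size %/% 2)            # 0-based
  src_lo <- pmax(start, 0L)
  src_hi <- pmin(start + size - 1L, shape - 1L)
  dst_lo <- src_lo - start
  dst_hi <- src_hi - start
  out <- array(0, size)
  out[(dst_lo[1] + 1):(dst_hi[1] + 1), (dst_lo[2] + 1):(dst_hi[2] + 1),
      (dst_lo[3] + 1):(dst_hi[3] + 1)] <-
    volume$data[(src_lo[1] + 1):(src_hi[1] + 1), (src_lo[2] + 1):(src_hi[2] + 1),
                (src_lo[3] + 1):(src_hi[3] + 1)]
  A <- volume$affine
  A[1:3, 4] <- A[1:3, 4] + A[1:3, 1:3] %*% start
  patch <- as_volume(out, voxel_size = volume$voxel_size, affine = A,
                     axis_convention = volume$axis_convention)
  offset <- list(start = start, size = size, src_lo = src_lo, src_hi = src_hi,
                 dst_lo = dst_lo, dst_hi = dst_hi, full_shape = shape)
  list(patch = patch, offset = offset)
}

# crop a full-grid array to a recorded patch window (zero-padded)
crop_to_patch <- function(full_arr, offset) {
  out <- array(0, offset$size)
  o <- offset
  out[(o$dst_lo[1] + 1):(o$dst_hi[1] + 1), (o$dst_lo[2] + 1):(o$dst_hi[2] + 1),
      (o$dst_lo[3] + 1):(o$dst_hi[3] + 1)] <-
    full_arr[(o$src_lo[1] + 1):(o$src_hi[1] + 1),
             (o$src_lo[2] + 1):(o$src_hi[2] + 1),
             (o$src_lo[3] + 1):(o$src_hi[3] + 1)]
  out
}

#' Re-insert a patch mask into the full grid
#'
#' Exact inverse of the crop on the patch support; voxel counts are
#' conserved for masks whose support lies within the grid.
#'
#' @param patch_mask an `lc_mask` on the patch grid.
#' @param offset the offset record from [extract_patch()].
#' @param like an `lc_volume`/`lc_mask` supplying full-grid metadata.
#' @return Full-grid `lc_mask`.
#' @export
reinsert_patch <- function(patch_mask, offset, like) {
  o <- offset
  full <- array(0L, o$full_shape)
  full[(o$src_lo[1] + 1):(o$src_hi[1] + 1), (o$src_lo[2] + 1):(o$src_hi[2] + 1),
       (o$src_lo[3] + 1):(o$src_hi[3] + 1)] <-
    patch_mask$data[(o$dst_lo[1] + 1):(o$dst_hi[1] + 1),
                    (o$dst_lo[2] + 1):(o$dst_hi[2] + 1),
                    (o$dst_lo[3] + 1):(o$dst_hi[3] + 1)]
  as_mask(full, like = like)
}

#' Z-score normalize a patch
#'
#' Subtracts the patch mean and divides by the patch standard deviation,
#' reducing the variance of the intensity range before segmentation; the
#' output is invariant under any affine intensity rescaling of the input.
#'
#' @param patch an `lc_volume` with more than one distinct intensity.
#' @return The normalized `lc_volume` (mean 0, SD 1).
#' @export
normalize_patch <- function(patch) {
  stopifnot(inherits(patch, "lc_volume"))
  mu <- mean(patch$data)
  s <- sqrt(mean((patch$data - mu)^2))   # population SD: {0,2} -> {-1,+1}
  if (!is.finite(s) || s == 0)
    lcseg_error("lcseg_normalization_error",
                "constant patch cannot be normalized (degenerate crop)")
  as_volume((patch$data - mu) / s, voxel_size = patch$voxel_size,
            affine = patch$affine, axis_convention = patch$axis_convention)
}

#' Split a mask into left/right hemisphere components
#'
#' Connected components are assigned by the sign of their centroid's
#' left-right world coordinate relative to the combined centroid;
#' components with voxels strictly on both sides are divided at the
#' plane.  The union of the two outputs equals the input (minus components
#' below `min_component`, if set).
#'
#' @param mask a nonempty `lc_mask`.
#' @param affine voxel-to-world affine; defaults to the mask's.
#' @param min_component drop components smaller than this many voxels
#'   before assignment (0 keeps everything).
#' @return An `lc_hemipair`.
#' @export
split_hemispheres <- function(mask, affine = mask$affine, min_component = 0L) {
  if (mask_count(mask) == 0L)
    lcseg_error("lcseg_argument_error", "cannot split an empty mask")
  lab <- cpp_label3(mask$data, as.integer(dim(mask$data)))
  k <- max(lab)
  keep <- seq_len(k)
  if (min_component > 0L) {
    sizes <- vapply(keep, function(l) sum(lab == l), integer(1))
    keep <- keep[sizes >= min_component]
  }
  left <- array(0L, dim(mask$data))
  right <- array(0L, dim(mask$data))
  if (length(keep)) {
    all_idx <- which(array(lab %in% keep, dim(lab)), arr.ind = TRUE)
    all_w <- voxel_to_world(affine, all_idx - 1)
    x0 <- mean(all_w[, 1])
    for (l in keep) {
      idx <- which(lab == l, arr.ind = TRUE)
      wx <- voxel_to_world(affine, idx - 1)[, 1]
      if (all(wx <= x0)) left[idx] <- 1L
      else if (all(wx >= x0)) right[idx] <- 1L
      else {                       # crossing component: divide at the plane
        left[idx[wx <= x0, , drop = FALSE]] <- 1L
        right[idx[wx > x0, , drop = FALSE]] <- 1L
      }
    }
  }
  mk <- function(a) as_mask(a, voxel_size = mask$voxel_size, affine = affine,
                            axis_convention = mask$axis_convention)
  hemi_pair(mk(left), mk(right))
}

#' Run the full segmentation pipeline on a volume
#'
#' Composes [localize()], [extract_patch()] at the midpoint of the two
#' centers, [normalize_patch()], [segment_patch()], re-insertion into the
#' full grid, removal of sub-3-voxel speckle, and [split_hemispheres()].
#' Degenerate inputs (failed localization, empty segmentation) produce a
#' result with raised `qc` flags instead of an error.
#'
#' @param model a trained `lc_ensemble`.
#' @param volume the working-resolution `lc_volume`.
#' @return List of class `lc_segresult` with `masks` (`lc_hemipair`),
#'   `patch_provenance` (`center`, `size`), and `qc` flags
#'   (`localization_failed`, `localization_fallback`, `empty_left`,
#'   `empty_right`).
#' @export
run_inference <- function(model, volume) {
  stopifnot(inherits(model, "lc_ensemble"), inherits(volume, "lc_volume"))
  qc <- list(localization_failed = FALSE, localization_fallback = FALSE,
             empty_left = FALSE, empty_right = FALSE)
  empty_pair <- hemi_pair(empty_mask_like(volume), empty_mask_like(volume))
  loc <- tryCatch(localize(model, volume),
                  lcseg_localization_error = function(e) e)
  if (inherits(loc, "condition")) {
    qc$localization_failed <- TRUE
    qc$empty_left <- qc$empty_right <- TRUE
    return(structure(list(masks = empty_pair, patch_provenance = NULL, qc = qc),
                     class = "lc_segresult"))
  }
  qc$localization_fallback <- loc$fallback_used
  center <- round((loc$left + loc$right) / 2)
  center <- pmin(pmax(center, 0), dim(volume$data) - 1)
  px <- extract_patch(volume, center, model$config$patch_size_vox)
  npatch <- normalize_patch(px$patch)
  patch_mask <- segment_patch(model, npatch)
  full <- reinsert_patch(patch_mask, px$offset, volume)
  if (mask_count(full) == 0L) {
    qc$empty_left <- qc$empty_right <- TRUE
    masks <- empty_pair
  } else {
    masks <- split_hemispheres(full, volume$affine, min_component = 3L)
    qc$empty_left <- mask_count(masks$left) == 0L
    qc$empty_right <- mask_count(masks$right) == 0L
  }
  structure(list(masks = masks,
                 patch_provenance = list(center = center,
                                         size = model$config$patch_size_vox),
                 qc = qc),
            class = "lc_segresult")
}

#' @export
print.lc_segresult <- function(x, ...) {
  cat(sprintf("<lc_segresult> left %d / right %d voxels; qc: %s\n",
              mask_count(x$masks$left), mask_count(x$masks$right),
              paste(names(Filter(isTRUE, x$qc)), collapse = ", ") %||% ""))
  invisible(x)
}
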