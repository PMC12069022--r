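# LC-oriented orthonormal coordinate frame and automatic reference-region
# placement.
#
# The frame is built from the two LC masks alone: v1 averages the left and
# right first principal axes (rostrocaudal direction), v2 is the cross
# product of the left-right center-of-mass difference with v1, v3 completes
# the right-handed basis, and the origin is the midpoint of the two centers
# of mass.  Reference regions are then placed at a per-hemisphere mean
# offset, learned in frame coordinates on training data, which makes the
# placement equivariant under rigid head rotation and independent of any
# pons segmentation.

#' First principal axis of a mask's voxel cloud
#'
#' First eigenvector of the covariance of the mask voxels' world
#' coordinates, with its sign fixed so the superior (world z) component is
#' non-negative.
#'
#' @param mask an `lc_mask` with at least 3 voxels spanning more than a point.
#' @param affine voxel-to-world affine; defaults to the mask's own.
#' @return Unit 3-vector (world mm).
#' @export
principal_axis <- function(mask, affine = mask$affine) {
  xyz <- voxel_to_world(affine, mask_voxels(mask))
  if (nrow(xyz) < 3L)
    lcseg_error("lcseg_geometry_error",
                sprintf("principal axis needs >= 3 voxels, got %d", nrow(xyz)))
  cv <- stats::cov(xyz)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[1] < 1e-9)
    lcseg_error("lcseg_geometry_error", "mask voxels are coincident (zero spread)")
  v <- eg$vectors[, 1]
  v <- v / vnorm(v)
  if (v[3] < 0) v <- -v
  else if (v[3] == 0) {
    nz <- which(v != 0)[1]
    if (v[nz] < 0) v <- -v
  }
  v
}

#' LC-oriented orthonormal coordinate frame
#'
#' With `l1`, `r1` the per-hemisphere principal axes and `c_l`, `c_r` the
#' centers of mass: `v1 = normalize((l1 + r1) / 2)`,
#' `v2 = normalize((c_l - c_r) x v1)`, `v3 = v1 x v2`, origin
#' `(c_l + c_r) / 2`.  The mean of unit vectors is not itself unit length
#' and the cross product is not either, so both v1 and v2 are explicitly
#' re-normalized to make the basis orthonormal.
#'
#' @param pair an `lc_hemipair` of LC masks (both nonempty).
#' @param affine voxel-to-world affine; defaults to the left mask's.
#' @return A list of class `lc_frame` with `origin`, `v1`, `v2`, `v3`.
#' @export
compute_frame <- function(pair, affine = pair$left$affine) {
  stopifnot(inherits(pair, "lc_hemipair"))
  l1 <- principal_axis(pair$left, affine)
  r1 <- principal_axis(pair$right, affine)
  c_l <- colMeans(voxel_to_world(affine, mask_voxels(pair$left)))
  c_r <- colMeans(voxel_to_world(affine, mask_voxels(pair$right)))
  v1 <- (l1 + r1) / 2
  if (vnorm(v1) < 1e-6)
    lcseg_error("lcseg_geometry_error", "left/right principal axes are anti-parallel")
  v1 <- v1 / vnorm(v1)
  d <- c_l - c_r
  if (vnorm(d) < 1e-6)
    lcseg_error("lcseg_geometry_error", "left/right centers of mass coincide")
  v2 <- cross3(d, v1)
  if (vnorm(v2) < 1e-9)
    lcseg_error("lcseg_geometry_error", "center-of-mass axis is parallel to v1")
  v2 <- v2 / vnorm(v2)
  v3 <- cross3(v1, v2)
  structure(list(origin = (c_l + c_r) / 2, v1 = v1, v2 = v2, v3 = v3,
                 c_l = c_l, c_r = c_r),
            class = "lc_frame")
}

#' @export
print.lc_frame <- function(x, ...) {
  cat("<lc_frame>\n origin:", signif(x$origin, 4), "\n v1:", signif(x$v1, 4),
      "\n v2:", signif(x$v2, 4), "\n v3:", signif(x$v3, 4), "\n")
  invisible(x)
}

#' Change of basis between world and frame coordinates
#'
#' Frame coordinates are ordered (v1, v2, v3), in mm.  The maps are exact
#' inverses of each other.
#'
#' @param frame an `lc_frame`.
#' @param xyz points: a 3-vector or n x 3 matrix.
#' @return Points in the other coordinate system, same shape as the input.
#' @export
world_to_frame <- function(frame, xyz) {
  B <- cbind(frame$v1, frame$v2, frame$v3)
  one <- is.null(dim(xyz))
  xyz <- matrix(xyz, ncol = 3)
  out <- sweep(xyz, 2, frame$origin) %*% B
  if (one) drop(out) else out
}

#' @rdname world_to_frame
#' @export
frame_to_world <- function(frame, xyz) {
  B <- cbind(frame$v1, frame$v2, frame$v3)
  one <- is.null(dim(xyz))
  xyz <- matrix(xyz, ncol = 3)
  out <- sweep(xyz %*% t(B), 2, -frame$origin)
  if (one) drop(out) else out
}

#' Learn mean reference-region offsets in the LC frame
#'
#' For every training subject the frame is computed from the LC pair and the
#' same-side reference-region centroid is expressed in frame coordinates;
#' the model keeps the per-hemisphere arithmetic means (and all per-sample
#' offsets, for dispersion reporting).  Offsets are averaged per hemisphere
#' separately, not mirrored.
#'
#' @param training a list whose elements are either phantom samples
#'   ([generate_phantom()]) or lists with fields `lc` (`lc_hemipair`),
#'   `ref` (`lc_hemipair`), and optionally `affine`.
#' @return A list of class `lc_offsetmodel` with `mean_left`, `mean_right`,
#'   `n_training`, and `per_sample` offsets (n x 3 matrices, frame order
#'   v1, v2, v3, mm).
#' @export
learn_offset <- function(training) {
  if (length(training) < 1L)
    lcseg_error("lcseg_argument_error", "need at least one training sample")
  offs_l <- list()
  offs_r <- list()
  for (s in training) {
    if (inherits(s, "lc_phantom"))
      s <- list(lc = s$lc_truth, ref = s$ref_truth, affine = s$volume$affine)
    affine <- s$affine %||% s$lc$left$affine
    ok <- tryCatch({
      fr <- compute_frame(s$lc, affine)
      offs_l[[length(offs_l) + 1L]] <-
        world_to_frame(fr, mask_centroid_world(s$ref$left))
      offs_r[[length(offs_r) + 1L]] <-
        world_to_frame(fr, mask_centroid_world(s$ref$right))
      TRUE
    }, lcseg_geometry_error = function(e) {
      warning(sprintf("skipping degenerate training sample: %s",
                      conditionMessage(e)))
      FALSE
    })
  }
  if (length(offs_l) == 0L)
    lcseg_error("lcseg_geometry_error", "all training samples were degenerate")
  per_l <- do.call(rbind, offs_l)
  per_r <- do.call(rbind, offs_r)
  structure(list(mean_left = colMeans(per_l), mean_right = colMeans(per_r),
                 n_training = nrow(per_l),
                 per_sample = list(left = per_l, right = per_r)),
            class = "lc_offsetmodel")
}

#' Place reference regions from a frame and learned offsets
#'
#' Rasterizes, per hemisphere, a box with edges `shape_mm` aligned to the
#' frame axes and centered at the learned mean offset.  A voxel belongs to
#' the region iff its center's frame coordinates lie within the half-open
#' box; the region is implicitly clipped to the grid.
#'
#' @param frame an `lc_frame` (typically from the subject's predicted LC).
#' @param model an `lc_offsetmodel` from [learn_offset()].
#' @param shape_mm box edge lengths in mm, frame order (v1, v2, v3).
#' @param grid an `lc_volume` or `lc_mask` supplying the target grid.
#' @return An `lc_hemipair` of reference-region masks.
#' @export
place_reference_region <- function(frame, model, shape_mm = c(5, 3, 3), grid) {
  stopifnot(inherits(frame, "lc_frame"), inherits(model, "lc_offsetmodel"))
  left <- rasterize_frame_box(frame, model$mean_left, shape_mm, grid)
  right <- rasterize_frame_box(frame, model$mean_right, shape_mm, grid)
  if (mask_count(left) == 0L || mask_count(right) == 0L)
    lcseg_error("lcseg_placement_error",
                "reference region falls entirely outside the grid")
  hemi_pair(left, right)
}

# membership test shared by placement and the phantom generator
rasterize_frame_box <- function(frame, center_frame, shape_mm, grid) {
  shape <- dim(grid$data)
  idx0 <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                                k = 0:(shape[3] - 1)))
  f <- world_to_frame(frame, voxel_to_world(grid$affine, idx0))
  lo <- center_frame - shape_mm / 2
  inside <- f[, 1] >= lo[1] & f[, 1] < lo[1] + shape_mm[1] &
    f[, 2] >= lo[2] & f[, 2] < lo[2] + shape_mm[2] &
    f[, 3] >= lo[3] & f[, 3] < lo[3] + shape_mm[3]
  as_mask(array(as.integer(inside), shape), voxel_size = grid$voxel_size,
          affine = grid$affine, axis_convention = grid$axis_convention)
}
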