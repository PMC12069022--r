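# Core volumetric containers: intensity volumes, binary masks, hemisphere
# pairs.  World coordinates follow the RAS convention (+x right, +y anterior,
# +z superior); voxel indices are 0-based throughout.

#' Construct an intensity volume
#'
#' A volume couples a 3-D numeric array with its voxel size (mm), a 4x4
#' voxel-to-world affine, and the "axial stacking" axis: the grid axis whose
#' world direction is closest to the inferior-superior axis.  An axial slice
#' is a plane of constant (0-based) index along that axis.
#'
#' @param data 3-D numeric array of intensities (finite values).
#' @param voxel_size length-1 or length-3 positive numeric, mm per axis.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).  Default
#'   places the world origin at the grid center with axes along the grid.
#' @param axis_convention integer in 1:3, the inferior-superior grid axis.
#'   Derived from the affine when `NULL`.
#' @return An object of class `lc_volume`.
#' @export
as_volume <- function(data, voxel_size, affine = NULL, axis_convention = NULL) {
  if (length(dim(data)) != 3L)
    lcseg_error("lcseg_format_error", "volume data must be a 3-D array")
  if (!all(is.finite(data)))
    lcseg_error("lcseg_format_error", "volume intensities must all be finite")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0))
    lcseg_error("lcseg_argument_error", "voxel sizes must be strictly positive")
  if (is.null(affine)) affine <- centered_affine(dim(data), voxel_size)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    lcseg_error("lcseg_format_error", "affine must be an invertible 4x4 matrix")
  if (is.null(axis_convention)) axis_convention <- infer_axial_axis(affine)
  axis_convention <- as.integer(axis_convention)
  if (!axis_convention %in% 1:3)
    lcseg_error("lcseg_argument_error", "axis_convention must name one grid axis (1:3)")
  if (length(unique(signif(voxel_size, 10))) > 1L)
    warning("non-isotropic voxel sizes; mm conversions use per-axis sizes")
  structure(list(data = data, voxel_size = voxel_size, affine = affine,
                 axis_convention = axis_convention),
            class = "lc_volume")
}

# affine with axes along the grid and the world origin at the grid center
centered_affine <- function(shape, voxel_size) {
  A <- diag(4)
  diag(A)[1:3] <- voxel_size
  A[1:3, 4] <- -(shape - 1) / 2 * voxel_size
  A
}

# grid axis whose world direction has the largest |superior| component
infer_axial_axis <- function(affine) {
  R <- affine[1:3, 1:3]
  cols <- apply(R, 2, function(v) abs(v[3]) / vnorm(v))
  which.max(cols)
}

#' Construct a binary mask on a volume grid
#'
#' @param data 3-D array coercible to 0/1, or an `lc_volume` whose
#'   intensities are all 0/1.
#' @param like optional `lc_volume` or `lc_mask` supplying grid metadata.
#' @param voxel_size,affine,axis_convention grid metadata when `like` is
#'   not given.
#' @return An object of class `lc_mask`.
#' @export
as_mask <- function(data, like = NULL, voxel_size = NULL, affine = NULL,
                    axis_convention = NULL) {
  if (inherits(data, "lc_volume")) {
    like <- like %||% data
    data <- data$data
  }
  if (!is.null(like)) {
    voxel_size <- like$voxel_size
    affine <- like$affine
    axis_convention <- like$axis_convention
    if (!all(dim(data) == dim(like$data)))
      lcseg_error("lcseg_argument_error", "mask shape must equal the volume shape")
  }
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    lcseg_error("lcseg_format_error", "mask values must be exactly 0 or 1")
  storage.mode(data) <- "integer"
  vol <- as_volume(array(0, dim(data)), voxel_size %||% 1, affine, axis_convention)
  structure(list(data = data, voxel_size = vol$voxel_size, affine = vol$affine,
                 axis_convention = vol$axis_convention),
            class = "lc_mask")
}

#' Pair of left/right hemisphere masks
#'
#' @param left,right `lc_mask` objects on the same grid.  They must be
#'   voxel-disjoint; a valid segmentation result has both nonempty, but empty
#'   sides are representable (and flagged downstream).
#' @return An object of class `lc_hemipair`.
#' @export
hemi_pair <- function(left, right) {
  stopifnot(inherits(left, "lc_mask"), inherits(right, "lc_mask"))
  if (!all(dim(left$data) == dim(right$data)))
    lcseg_error("lcseg_argument_error", "left/right masks must share a grid")
  if (any(left$data & right$data))
    lcseg_error("lcseg_argument_error", "left and right masks must be disjoint")
  structure(list(left = left, right = right), class = "lc_hemipair")
}

mask_count <- function(mask) sum(mask$data)

# 0-based voxel indices (n x 3) of the mask's nonzero voxels
mask_voxels <- function(mask) {
  idx <- which(mask$data != 0L, arr.ind = TRUE)
  idx - 1
}

# world coordinates (n x 3) for 0-based voxel indices
voxel_to_world <- function(affine, idx0) {
  idx0 <- matrix(idx0, ncol = 3)
  h <- cbind(idx0, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

world_to_voxel <- function(affine, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  h <- cbind(xyz, 1) %*% t(solve(affine))
  h[, 1:3, drop = FALSE]
}

# world centroid (mm) of a nonempty mask
mask_centroid_world <- function(mask) {
  if (mask_count(mask) == 0L)
    lcseg_error("lcseg_argument_error", "centroid of an empty mask is undefined")
  colMeans(voxel_to_world(mask$affine, mask_voxels(mask)))
}

same_grid <- function(a, b) {
  all(dim(a$data) == dim(b$data))
}

empty_mask_like <- function(obj) {
  as_mask(array(0L, dim(obj$data)), voxel_size = obj$voxel_size,
          affine = obj$affine, axis_convention = obj$axis_convention)
}

#' @export
print.lc_volume <- function(x, ...) {
  cat(sprintf("<lc_volume> %s voxels @ %s mm, axial axis %d\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              x$axis_convention))
  invisible(x)
}

#' @export
print.lc_mask <- function(x, ...) {
  cat(sprintf("<lc_mask> %s voxels @ %s mm, %d set\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              mask_count(x)))
  invisible(x)
}

#' @export
print.lc_hemipair <- function(x, ...) {
  cat(sprintf("<lc_hemipair> left %d / right %d voxels\n",
              mask_count(x$left), mask_count(x$right)))
  invisible(x)
}
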