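# Synthetic FLASH-like brainstem phantoms with ground-truth LC and
# reference-region masks.
#
# The scene is defined analytically in an unrotated anatomical frame
# (+x right, +y anterior, +z superior, origin mid-pons): a smooth
# pons-like ellipsoid of baseline intensity, and two near-cylindrical
# hyperintense tubes (the left/right LC, ~2 mm diameter) running
# rostrocaudally with a gentle outward lateral bow.  Rigid head rotation is
# applied by evaluating the analytic geometry at back-rotated voxel centers,
# so ground-truth masks are rasterized directly on the rotated grid and
# never interpolated.  The LC intensity is a plateau softened by a
# one-voxel Gaussian (partial-volume blur of the intensity, not of the
# mask), rescaled so that before noise
# (max LC intensity - median reference intensity) / median reference
# intensity equals the requested contrast ratio exactly.  A smooth
# multiplicative bias field (3 random low-order cosine modes, applied in
# scanner/grid coordinates) and additive Gaussian noise follow.

#' Phantom specification
#'
#' Defaults describe the emulated acquisitions at working resolution:
#' 64^3 voxels at 0.375 mm (a 24 mm field of view around the pons), 2 mm LC
#' diameter, 7.5 mm LC signal length, 8 mm between the two LCs, peak
#' contrast ratio 0.2, 2% Gaussian noise, 10% residual bias field, and head
#' rotations up to +-10 degrees per axis.  Reference boxes (default
#' 3 x 3 mm cross-section, 5 mm along v1) are planted at frame offsets
#' (0, -6, +2) mm for the left and (0, -6, -2) mm for the right hemisphere
#' (a single 3-vector is accepted and mirrored along v3 for the right).
#'
#' @param grid_shape voxels per axis.
#' @param voxel_size_mm isotropic voxel size, mm.
#' @param lc_diameter_mm,lc_length_mm,lc_curvature_mm,inter_lc_distance_mm
#'   tube geometry: diameter, rostrocaudal length, lateral bow amplitude,
#'   and left-right center distance (all mm).
#' @param true_cr target peak contrast ratio (dimensionless, > 0).
#' @param background_level mean pons intensity (arbitrary units).
#' @param noise_sd additive Gaussian sigma as a fraction of
#'   `background_level`.
#' @param bias_amplitude peak-to-trough multiplicative bias fraction, in
#'   `[0, 1)`.
#' @param rotation_deg maximal random rigid rotation per axis, degrees
#'   (`[0, 45]`).
#' @param ref_offset_frame planted reference-box center offsets in LC-frame
#'   coordinates (mm): a list with `left` and `right` 3-vectors, or one
#'   3-vector mirrored for the right hemisphere.
#' @param ref_region_shape_mm reference box edges, frame order (v1, v2, v3).
#' @param seed default RNG seed used by [generate_phantom()].
#' @return A list of class `lc_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), voxel_size_mm = 0.375,
                         lc_diameter_mm = 2, lc_length_mm = 7.5,
                         lc_curvature_mm = 0.5, inter_lc_distance_mm = 8,
                         true_cr = 0.2, background_level = 100,
                         noise_sd = 0.02, bias_amplitude = 0.1,
                         rotation_deg = 10,
                         ref_offset_frame = list(left = c(0, -6, 2),
                                                 right = c(0, -6, -2)),
                         ref_region_shape_mm = c(5, 3, 3), seed = 1L) {
  if (!is.list(ref_offset_frame))
    ref_offset_frame <- list(left = ref_offset_frame,
                             right = ref_offset_frame * c(1, 1, -1))
  spec <- list(grid_shape = rep_len(as.integer(grid_shape), 3L),
               voxel_size_mm = voxel_size_mm,
               lc_diameter_mm = lc_diameter_mm, lc_length_mm = lc_length_mm,
               lc_curvature_mm = lc_curvature_mm,
               inter_lc_distance_mm = inter_lc_distance_mm,
               true_cr = true_cr, background_level = background_level,
               noise_sd = noise_sd, bias_amplitude = bias_amplitude,
               rotation_deg = rotation_deg,
               ref_offset_frame = ref_offset_frame,
               ref_region_shape_mm = rep_len(ref_region_shape_mm, 3L),
               seed = seed)
  validate_phantom_spec(spec)
  structure(spec, class = "lc_phantom_spec")
}

validate_phantom_spec <- function(s) {
  pos <- c("voxel_size_mm", "lc_diameter_mm", "lc_length_mm",
           "inter_lc_distance_mm", "true_cr", "background_level")
  for (f in pos) if (!is.numeric(s[[f]]) || s[[f]] <= 0)
    lcseg_error("lcseg_argument_error", sprintf("%s must be > 0", f))
  if (s$lc_curvature_mm < 0)
    lcseg_error("lcseg_argument_error", "lc_curvature_mm must be >= 0")
  if (s$noise_sd < 0)
    lcseg_error("lcseg_argument_error", "noise_sd must be >= 0")
  if (s$bias_amplitude < 0 || s$bias_amplitude >= 1)
    lcseg_error("lcseg_argument_error", "bias_amplitude must be in [0, 1)")
  if (s$rotation_deg < 0 || s$rotation_deg > 45)
    lcseg_error("lcseg_argument_error", "rotation_deg must be in [0, 45]")
  invisible(s)
}

#' Generate one phantom
#'
#' @param spec a [phantom_spec()].
#' @param seed RNG seed; the same (spec, seed) is bit-reproducible.
#' @param masks_only if `TRUE`, skip intensity synthesis (fast path for
#'   geometry-only experiments); the returned volume is all zero.
#' @param with_ref if `FALSE`, also skip reference-region rasterization
#'   (`ref_truth` is `NULL`); only meaningful with `masks_only = TRUE`.
#' @return A list of class `lc_phantom` with `volume`, `lc_truth`,
#'   `ref_truth` (both `lc_hemipair`), `spec` and `applied_rotation_deg`.
#' @export
generate_phantom <- function(spec, seed = spec$seed, masks_only = FALSE,
                             with_ref = TRUE) {
  stopifnot(inherits(spec, "lc_phantom_spec"))
  with_seed(seed, generate_phantom_impl(spec, masks_only, with_ref))
}

generate_phantom_impl <- function(spec, masks_only, with_ref = TRUE) {
  shape <- spec$grid_shape
  vx <- rep_len(spec$voxel_size_mm, 3L)
  affine <- centered_affine(shape, vx)
  half_fov <- shape * vx / 2

  # analytic extent check: bounding sphere of the tubes must fit under any
  # rotation (rotation is about the world origin = grid center)
  reach <- sqrt((spec$inter_lc_distance_mm / 2 + spec$lc_curvature_mm +
                   spec$lc_diameter_mm / 2)^2 +
                  (spec$lc_diameter_mm / 2)^2 + (spec$lc_length_mm / 2)^2)
  if (reach > min(half_fov) - 2 * max(vx))
    lcseg_error("lcseg_geometry_error",
                sprintf("LC tubes (reach %.1f mm) exceed the %.1f mm half-FOV",
                        reach, min(half_fov)))

  angles <- runif(3, -spec$rotation_deg, spec$rotation_deg)
  R <- rot_xyz(angles)

  idx0 <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                                k = 0:(shape[3] - 1)))
  P <- voxel_to_world(affine, idx0)       # rotated-scene (scanner) coords
  Q <- P %*% R                            # back-rotated anatomical coords

  r <- spec$lc_diameter_mm / 2
  L <- spec$lc_length_mm
  zok <- Q[, 3] >= -L / 2 & Q[, 3] < L / 2
  tt <- Q[, 3] / L + 0.5
  bow <- spec$lc_curvature_mm * sin(pi * pmin(pmax(tt, 0), 1))
  cx <- spec$inter_lc_distance_mm / 2 + bow
  in_left <- zok & ((Q[, 1] + cx)^2 + Q[, 2]^2 <= r^2)
  in_right <- zok & ((Q[, 1] - cx)^2 + Q[, 2]^2 <= r^2)

  mk <- function(v) as_mask(array(as.integer(v), shape), voxel_size = vx,
                            affine = affine, axis_convention = 3L)
  lc <- hemi_pair(mk(in_left), mk(in_right))
  if (mask_count(lc$left) == 0L || mask_count(lc$right) == 0L)
    lcseg_error("lcseg_geometry_error", "an LC tube rasterized to zero voxels")

  if (masks_only && !with_ref) {
    vol <- as_volume(array(0, shape), vx, affine, 3L)
    return(structure(list(volume = vol, lc_truth = lc, ref_truth = NULL,
                          spec = spec, applied_rotation_deg = angles),
                     class = "lc_phantom"))
  }

  frame <- compute_frame(lc, affine)
  ref_left <- rasterize_frame_box(frame, spec$ref_offset_frame$left,
                                  spec$ref_region_shape_mm, lc$left)
  ref_right <- rasterize_frame_box(frame, spec$ref_offset_frame$right,
                                   spec$ref_region_shape_mm, lc$right)
  if (mask_count(ref_left) == 0L || mask_count(ref_right) == 0L)
    lcseg_error("lcseg_geometry_error", "a reference region left the grid")
  ref <- hemi_pair(ref_left, ref_right)
  if (any((ref_left$data | ref_right$data) & (lc$left$data | lc$right$data)))
    lcseg_error("lcseg_geometry_error", "reference regions overlap the LC")

  if (masks_only) {
    vol <- as_volume(array(0, shape), vx, affine, 3L)
    return(structure(list(volume = vol, lc_truth = lc, ref_truth = ref,
                          spec = spec, applied_rotation_deg = angles),
                     class = "lc_phantom"))
  }

  # pons-like background: plateau inside an ellipsoid, smooth 10% rim
  semi <- pmin(c(10, 10.5, 11), 0.9 * min(half_fov))
  rho <- sqrt((Q[, 1] / semi[1])^2 + (Q[, 2] / semi[2])^2 + (Q[, 3] / semi[3])^2)
  u <- pmin(pmax((1 - rho) / 0.1, 0), 1)
  edge <- u * u * (3 - 2 * u)
  out_level <- 0.35 * spec$background_level
  img <- out_level + (spec$background_level - out_level) * edge

  # LC plateau softened by a one-voxel Gaussian, peak-calibrated to true_cr
  ind <- array(as.double(in_left | in_right), shape)
  soft <- cpp_smooth3(ind, shape, 1.0)
  lc_vox <- in_left | in_right
  peak <- max(soft[lc_vox])
  img <- img + as.vector(soft) * (spec$true_cr * spec$background_level / peak)

  img <- array(img, shape)
  if (spec$bias_amplitude > 0) {
    uu <- lapply(1:3, function(a) (idx0[, a] + 0.5) / shape[a])
    f <- 0
    for (m in 1:3) {
      kvec <- runif(3, 0.3, 1.2)
      phase <- runif(1)
      f <- f + cos(2 * pi * (uu[[1]] * kvec[1] + uu[[2]] * kvec[2] +
                               uu[[3]] * kvec[3] + phase))
    }
    f <- f / max(abs(f))
    img <- img * array(1 + spec$bias_amplitude / 2 * f, shape)
  }
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(prod(shape), 0,
                             spec$noise_sd * spec$background_level), shape)

  vol <- as_volume(img, vx, affine, 3L)
  structure(list(volume = vol, lc_truth = lc, ref_truth = ref, spec = spec,
                 applied_rotation_deg = angles),
            class = "lc_phantom")
}

#' @export
print.lc_phantom <- function(x, ...) {
  cat(sprintf("<lc_phantom> %s grid, rotation (%.1f, %.1f, %.1f) deg, LC %d+%d voxels\n",
              paste(dim(x$volume$data), collapse = "x"),
              x$applied_rotation_deg[1], x$applied_rotation_deg[2],
              x$applied_rotation_deg[3],
              mask_count(x$lc_truth$left), mask_count(x$lc_truth$right)))
  invisible(x)
}

#' Generate a phantom cohort
#'
#' Per-sample seeds are derived deterministically from the master seed, so
#' sample `i` is identical across runs regardless of `n`.  Geometric
#' parameters may be jittered with per-sample multiplicative factors
#' `1 + U(-j, j)` to create inter-subject variance (a relative half-width
#' `j` yields a coefficient of variation of about `j / sqrt(3)`).
#'
#' @param n number of samples.
#' @param spec base [phantom_spec()].
#' @param seed master seed.
#' @param jitter named list of relative half-widths, e.g.
#'   `list(lc_length_mm = 0.1)`.
#' @return List of `lc_phantom` samples.
#' @export
generate_dataset <- function(n, spec, seed = spec$seed, jitter = list()) {
  stopifnot(inherits(spec, "lc_phantom_spec"))
  if (n < 1) lcseg_error("lcseg_argument_error", "n must be >= 1")
  jitterable <- c("lc_diameter_mm", "lc_length_mm", "lc_curvature_mm",
                  "inter_lc_distance_mm", "true_cr", "background_level")
  bad <- setdiff(names(jitter), jitterable)
  if (length(bad))
    lcseg_error("lcseg_argument_error",
                sprintf("cannot jitter: %s", paste(bad, collapse = ", ")))
  lapply(seq_len(n), function(i) {
    sub_seed <- derive_seed(seed, i)
    spec_i <- spec
    if (length(jitter)) {
      factors <- with_seed(derive_seed(seed, i, salt = 7L), {
        vapply(names(jitter), function(nm)
          1 + runif(1, -jitter[[nm]], jitter[[nm]]), numeric(1))
      })
      for (nm in names(jitter)) spec_i[[nm]] <- spec_i[[nm]] * factors[[nm]]
      validate_phantom_spec(spec_i)
    }
    generate_phantom(spec_i, seed = sub_seed)
  })
}
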