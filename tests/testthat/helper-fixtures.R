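# Shared fixtures built in code.

# small fast phantom spec for geometry-heavy tests (0.6 mm grid keeps the
# tubes a few voxels wide while staying cheap)
fast_spec <- function(...) {
  args <- list(grid_shape = c(40, 40, 40), voxel_size_mm = 0.6,
               lc_length_mm = 7.2, noise_sd = 0, bias_amplitude = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

# random binary mask on an n^3 grid with identity-scaled metadata
random_mask <- function(n = 10, p = 0.3, voxel = 1) {
  as_mask(array(as.integer(stats::runif(n^3) < p), c(n, n, n)),
          voxel_size = voxel)
}

# axis-aligned rod mask: nz voxels along the third axis
rod_mask <- function(shape = c(9, 9, 25), nz = 20, at = c(5, 5), voxel = 1) {
  a <- array(0L, shape)
  a[at[1], at[2], seq_len(nz) + 2] <- 1L
  as_mask(a, voxel_size = voxel)
}

expect_frame_orthonormal <- function(fr, tol = 1e-9) {
  B <- cbind(fr$v1, fr$v2, fr$v3)
  expect_lt(max(abs(crossprod(B) - diag(3))), tol)
  expect_gt(det(B), 0)
}
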