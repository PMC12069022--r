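# Shared small helpers: error conditions, 3-vector algebra, rounding.

lcseg_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "lcseg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(x) sqrt(sum(x^2))

# round half away from zero (R's round() is banker's rounding)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# rotation matrices about world axes, angles in degrees
rot_x <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
rot_xyz <- function(angles_deg) {
  rot_z(angles_deg[3]) %*% rot_y(angles_deg[2]) %*% rot_x(angles_deg[1])
}

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a per-item 31-bit seed from a master seed
derive_seed <- function(seed, i, salt = 0L) {
  (((as.double(seed) %% 1000003) * 2011 + as.double(i) * 7919 +
      as.double(salt) * 104729) %% 2147483647) + 1
}
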