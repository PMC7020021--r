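# Shared phantom objects, built once per test run.
.cheek_cache <- new.env(parent = emptyenv())

shared_phantom <- function() {
  if (is.null(.cheek_cache$ph)) .cheek_cache$ph <- make_phantom()
  .cheek_cache$ph
}

shared_ctx <- function() {
  if (is.null(.cheek_cache$ctx)) {
    .cheek_cache$ctx <- prepare_patient(shared_phantom())
  }
  .cheek_cache$ctx
}

# Minimal landmark set for frame tests (non-facial geometry).
frame_landmarks <- function(po_l = c(-60, 0, 0), po_r = c(60, 0, 0),
                            or_l = c(-30, 70, 2), or_r = c(30, 70, -2),
                            s = c(0, 20, 0), n = c(0, 80, 10),
                            ba = c(0, -20, -30)) {
  landmark_set(list(Po_L = po_l, Po_R = po_r, Or_L = or_l, Or_R = or_r,
                    S = s, N = n, Ba = ba),
               require_all = FALSE)
}

# Deterministic random rigid transform (modest rotation + translation).
random_rigid <- function(seed, max_angle = 20, max_shift = 15) {
  set.seed(seed)
  axis <- rnorm(3)
  angle <- runif(1, -max_angle, max_angle)
  shift <- runif(3, -max_shift, max_shift)
  rigid_transform(rotation_about_axis(axis, angle), shift)
}

# A flat anterior-facing sheet y = const over [x_lo, x_hi] x [z_lo, z_hi].
flat_sheet <- function(x_lo = -60, x_hi = 60, z_lo = -45, z_hi = 25,
                       y = 45, step = 1) {
  xs <- seq(x_lo, x_hi, by = step)
  zs <- seq(z_lo, z_hi, by = step)
  nx <- length(xs)
  nz <- length(zs)
  V <- cbind(rep(xs, times = nz), y, rep(zs, each = nx))
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = nz - 1L)
  j <- rep(seq_len(nz - 1L), each = nx - 1L)
  F <- rbind(
    cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j)),
    cbind(idx(i + 1L, j), idx(i, j + 1L), idx(i + 1L, j + 1L))
  )
  surface_mesh(V, F)
}

# Sheet with a Gaussian prominence (for curved-surface volumetrics tests).
bump_sheet <- function(amp = 3, sigma = 8, cx = 25, cz = -12, ...) {
  m <- flat_sheet(...)
  m$vertices[, 2] <- m$vertices[, 2] +
    amp * exp(-((m$vertices[, 1] - cx)^2 + (m$vertices[, 3] - cz)^2) /
                (2 * sigma^2))
  m
}

translate_mesh <- function(mesh, dy) {
  mesh$vertices[, 2] <- mesh$vertices[, 2] + dy
  mesh
}
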