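# Parametric craniofacial phantom: smooth bone/soft midface surfaces with a
# full landmark set, a surgical transform (maxillary advancement + clockwise
# pitch), a linear soft-tissue response, and cohort generation.

#' Phantom geometry specification
#'
#' Defines the parametric midface used by [make_phantom()]: a gently curved
#' anterior-facing sheet (a quadratic height field y(x, z)) carrying one
#' Gaussian cheek prominence per side, with the soft-tissue surface offset
#' anteriorly from the bone by a uniform thickness. The default dimensions
#' approximate an adult midface; the cheek prominence is kept shallow so
#' that the region-of-interest surface area stays close to its projected
#' area and volumetric-subtraction movement estimates are unbiased.
#'
#' @param half_width lateral half-extent of the sheet in mm.
#' @param z_min,z_max vertical extent in mm (0 is the Frankfort horizontal
#'   level; negative is inferior).
#' @param base_depth anterior depth of the sheet at its crown in mm.
#' @param bump_amplitude cheek prominence height in mm.
#' @param bump_sigma cheek prominence Gaussian width in mm.
#' @param thickness soft-tissue thickness (bone-to-skin offset) in mm.
#' @param resolution mesh grid spacing in mm; must be at most
#'   `bump_sigma / 5` so the prominence is resolved.
#' @param cheek_projection pre-operative cheek-mass position in mm (apex of
#'   the cheek profile relative to the cornea point).
#' @param seed retained for interface symmetry; the phantom geometry is
#'   deterministic.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(half_width = 55, z_min = -70, z_max = 30,
                         base_depth = 46, bump_amplitude = 1.5,
                         bump_sigma = 12, thickness = 8, resolution = 2,
                         cheek_projection = 2, seed = NULL) {
  spec <- list(
    half_width = half_width, z_min = z_min, z_max = z_max,
    base_depth = base_depth, bump_amplitude = bump_amplitude,
    bump_sigma = bump_sigma, thickness = thickness,
    resolution = resolution, cheek_projection = cheek_projection,
    seed = seed,
    # derived layout constants (mm): landmark x/z positions
    x_al = 12, x_ex = 38, z_sn = -25, z_al = -22, z_ex = -2,
    bump_z = -12
  )
  spec$bump_x <- (spec$x_al + spec$x_ex) / 2
  if (any(c(half_width, z_max - z_min, base_depth, bump_sigma,
            thickness, resolution) <= 0)) {
    stop("phantom dimensions must be positive")
  }
  if (resolution > bump_sigma / 5) {
    stop("resolution too coarse for the cheek prominence")
  }
  structure(spec, class = "phantom_spec")
}

# Analytic bone height field y(x, z) in mm.
phantom_bone_height <- function(spec, x, z) {
  base <- spec$base_depth - 0.0015 * x^2 - 0.001 * (z - 5)^2
  bump <- spec$bump_amplitude * (
    exp(-((x - spec$bump_x)^2 + (z - spec$bump_z)^2) / (2 * spec$bump_sigma^2)) +
    exp(-((x + spec$bump_x)^2 + (z - spec$bump_z)^2) / (2 * spec$bump_sigma^2))
  )
  base + bump
}

phantom_soft_height <- function(spec, x, z) {
  phantom_bone_height(spec, x, z) + spec$thickness
}

# Triangulate a height field over a regular grid, anterior-facing normals.
heightfield_mesh <- function(xs, zs, y) {
  nx <- length(xs)
  nz <- length(zs)
  V <- cbind(
    rep(xs, times = nz),
    as.numeric(y),
    rep(zs, each = nx)
  )
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = nz - 1L)
  j <- rep(seq_len(nz - 1L), each = nx - 1L)
  v00 <- idx(i, j)
  v10 <- idx(i + 1L, j)
  v01 <- idx(i, j + 1L)
  v11 <- idx(i + 1L, j + 1L)
  # winding chosen so normals point along +y for a flat sheet
  F <- rbind(
    cbind(v00, v01, v10),
    cbind(v10, v01, v11)
  )
  surface_mesh(V, F)
}

#' Build a craniofacial phantom
#'
#' Generates the pre-operative bone and soft-tissue surface meshes and the
#' complete landmark set. Landmarks are placed parametrically and
#' consistently: the porions and orbitale points define the Frankfort
#' horizontal at z = 0, sella and nasion define the midsagittal plane at
#' x = 0, exocanthion/alare/subnasale bound the cheek ROIs, the cornea
#' points sit on the mid-pupillary planes through the cheek prominences,
#' and the dentition (U1, U6) gives a pre-operative occlusal-plane
#' inclination of 8 degrees.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom`: `bone`, `soft` ([surface_mesh()]s),
#'   `landmarks` ([landmark_set()]), `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  xs <- seq(-spec$half_width, spec$half_width, by = spec$resolution)
  zs <- seq(spec$z_min, spec$z_max, by = spec$resolution)
  gx <- matrix(xs, length(xs), length(zs))
  gz <- matrix(zs, length(xs), length(zs), byrow = TRUE)
  bone <- heightfield_mesh(xs, zs, phantom_bone_height(spec, gx, gz))
  soft <- heightfield_mesh(xs, zs, phantom_soft_height(spec, gx, gz))

  yb <- function(x, z) phantom_bone_height(spec, x, z)
  ys <- function(x, z) phantom_soft_height(spec, x, z)

  # cheek profile apex on the mid-pupillary plane within the search window
  apex <- optimize(function(z) ys(spec$bump_x, z),
                   lower = spec$z_sn + 0.5, upper = -0.5, maximum = TRUE)
  c_y <- apex$objective - spec$cheek_projection
  c_z <- -3

  op_drop <- 30 * tan(8 * pi / 180)  # pre-op occlusal inclination 8 deg
  lm <- landmark_set(list(
    Po_L = c(-spec$half_width, -15, 0),
    Po_R = c(spec$half_width, -15, 0),
    Or_L = c(-28, yb(-28, 0), 0),
    Or_R = c(28, yb(28, 0), 0),
    N = c(0, yb(0, 10), 10),
    S = c(0, 10, 5),
    Ba = c(0, -15, -35),
    Ex_L = c(-spec$x_ex, ys(-spec$x_ex, spec$z_ex), spec$z_ex),
    Ex_R = c(spec$x_ex, ys(spec$x_ex, spec$z_ex), spec$z_ex),
    Al_L = c(-spec$x_al, ys(-spec$x_al, spec$z_al), spec$z_al),
    Al_R = c(spec$x_al, ys(spec$x_al, spec$z_al), spec$z_al),
    Sn = c(0, ys(0, spec$z_sn), spec$z_sn),
    C_L = c(-spec$bump_x, c_y, c_z),
    C_R = c(spec$bump_x, c_y, c_z),
    U1 = c(0, 40, -32),
    U6_L = c(-22, 10, -32 + op_drop),
    U6_R = c(22, 10, -32 + op_drop)
  ))

  structure(list(bone = bone, soft = soft, landmarks = lm, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> bone %d tris, soft %d tris, resolution %.2f mm%s\n",
    n_faces(x$bone), n_faces(x$soft), x$spec$resolution,
    if (is.null(x$params)) "" else
      sprintf(" (post-op: d = %.2f mm, rotation = %.2f deg)",
              x$params$advancement, x$params$rotation)
  ))
  invisible(x)
}

#' Surgical movement parameters for the phantom
#'
#' @param advancement maxillary advancement d in mm (>= 0, along the
#'   anterior axis).
#' @param rotation clockwise pitch in degrees about the lateral axis
#'   through U1 (posterior impaction positive).
#' @param a1 soft-tissue response to advancement (mm per mm).
#' @param a2 soft-tissue response to rotation (mm per degree).
#' @param noise_sd SD in mm of the per-side coherent response noise.
#' @param seed optional seed for the noise draw; `NULL` uses the current
#'   RNG state.
#' @return object of class `surgery_params`.
#' @export
surgery_params <- function(advancement, rotation = 0, a1 = 0.627,
                           a2 = 0.070, noise_sd = 0, seed = NULL) {
  if (advancement < 0) stop("advancement must be non-negative")
  structure(list(
    advancement = advancement, rotation = rotation,
    a1 = a1, a2 = a2, noise_sd = noise_sd, seed = seed
  ), class = "surgery_params")
}

# Raised-cosine window: 1 inside [lo, hi], decaying to 0 over `margin`
# outside, so the response plateau covers the whole ROI.
taper_window <- function(v, lo, hi, margin) {
  out <- numeric(length(v))
  inside <- v >= lo & v <= hi
  out[inside] <- 1
  below <- v < lo & v > lo - margin
  out[below] <- 0.5 * (1 + cos(pi * (lo - v[below]) / margin))
  above <- v > hi & v < hi + margin
  out[above] <- 0.5 * (1 + cos(pi * (v[above] - hi) / margin))
  out
}

#' Apply a simulated Le Fort I movement to a phantom
#'
#' The maxillary segment of the bone surface (inferior to the Frankfort
#' horizontal, anterior to the coronal plane through sella) is moved
#' rigidly: a clockwise pitch about the lateral axis through U1 composed
#' with an anterior translation by the advancement. Dental landmarks move
#' with the bone. Soft-tissue vertices respond along the anterior axis by
#' `a1 * advancement + a2 * rotation` plus a coherent per-side noise term,
#' at full amplitude across each cheek ROI and tapering smoothly to zero
#' over a 6 mm band outside it; all other regions (forehead, orbits) are
#' left unchanged.
#'
#' @param phantom a pre-operative [make_phantom()] result.
#' @param params a [surgery_params()].
#' @return a post-operative `phantom` with the movement applied and
#'   `params` attached.
#' @export
apply_surgery <- function(phantom, params) {
  stopifnot(inherits(phantom, "phantom"), inherits(params, "surgery_params"))
  lm <- phantom$landmarks
  frame <- build_reference_frame(lm)
  planes <- construct_planes(frame, lm)
  x_axis <- frame$axes["x", ]
  y_axis <- frame$axes["y", ]
  u1 <- landmark(lm, "U1")

  Rx <- rotation_about_axis(x_axis, -params$rotation)
  move_rigid <- function(P) {
    rel <- sweep(P, 2, u1)
    out <- rel %*% t(Rx)
    out <- sweep(out, 2, u1 + params$advancement * y_axis, "+")
    out
  }

  # maxillary segment: inferior to FH, anterior to CO
  bone <- phantom$bone
  sd_fh <- signed_distance(planes$FH, bone$vertices)
  sd_co <- signed_distance(planes$CO, bone$vertices)
  maxilla <- sd_fh <= 1e-9 & sd_co > 0
  bone$vertices[maxilla, ] <- move_rigid(bone$vertices[maxilla, , drop = FALSE])

  # dental landmarks follow the bone segment
  lm_post <- unclass(lm)
  for (nm in c("U1", "U6_L", "U6_R")) {
    lm_post[nm, ] <- move_rigid(matrix(lm[nm, ], 1, 3))
  }
  lm_post <- landmark_set(lm_post)

  # soft-tissue response
  if (!is.null(params$seed)) set.seed(params$seed)
  eps <- rnorm(2, 0, params$noise_sd)  # L, R
  names(eps) <- c("L", "R")
  soft <- phantom$soft
  sc <- frame_coords(frame, soft$vertices)
  z_fh <- frame_coords(frame, landmark(lm, "Po_L"))[3]
  z_sn <- frame_coords(frame, landmark(lm, "Sn"))[3]
  margin <- 6
  base_disp <- params$a1 * params$advancement + params$a2 * params$rotation
  disp <- numeric(nrow(sc))
  for (side in c("L", "R")) {
    xa <- frame_coords(frame, landmark(lm, paste0("Al_", side)))[1]
    xe <- frame_coords(frame, landmark(lm, paste0("Ex_", side)))[1]
    xr <- sort(c(xa, xe))
    w <- taper_window(sc[, 1], xr[1], xr[2], margin) *
      taper_window(sc[, 3], z_sn, z_fh, margin)
    disp <- disp + (base_disp + eps[side]) * w
  }
  soft$vertices <- soft$vertices + outer(disp, y_axis)

  structure(list(
    bone = bone, soft = soft, landmarks = lm_post,
    spec = phantom$spec, params = params
  ), class = "phantom")
}

# ---- cohort generation ------------------------------------------------------

#' Cohort simulation specification
#'
#' Defines the generative conditions for a simulated surgical cohort: the
#' number of patients (two cheek sides each), the distribution of
#' advancements across the four reporting strata, the rotation
#' distribution, the linear soft-tissue response, and the response noise.
#' Defaults reproduce the published cohort structure: 96 sides split
#' 14/34/34/14 across the 1-2, 2-3, 3-4 and >4 mm strata, rotation normal
#' with mean 3.341 and SD 2.346 degrees truncated at 0, and response
#' coefficients 0.627 mm/mm and 0.070 mm/degree. When `noise_sd` is `NULL`
#' it is calibrated analytically with [calibrate_noise_sd()] so the
#' population coefficient of determination equals `r2_target`.
#'
#' @param n_patients number of patients (each contributes both sides).
#' @param proportions length-4 stratum proportions over sides (sum 1);
#'   `proportions * n_patients` must be whole patients.
#' @param rotation_mean,rotation_sd rotation distribution in degrees
#'   (truncated at 0).
#' @param a1,a2 response coefficients (mm/mm, mm/degree).
#' @param noise_sd per-side response noise SD in mm, or `NULL` to
#'   calibrate from `r2_target`.
#' @param r2_target population R-squared used for calibration.
#' @param seed integer seed; required for reproducibility.
#' @param phantom a [phantom_spec()] used in mesh mode.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 48,
                        proportions = c(14, 34, 34, 14) / 96,
                        rotation_mean = 3.341, rotation_sd = 2.346,
                        a1 = 0.627, a2 = 0.070,
                        noise_sd = NULL, r2_target = 0.788,
                        seed = 1, phantom = phantom_spec()) {
  if (length(proportions) != 4L || abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must be 4 values summing to 1")
  }
  counts <- proportions * n_patients
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop("infeasible stratum proportions for ", n_patients, " patients")
  }
  spec <- list(
    n_patients = n_patients, proportions = proportions,
    patient_counts = as.integer(round(counts)),
    rotation_mean = rotation_mean, rotation_sd = rotation_sd,
    a1 = a1, a2 = a2, noise_sd = noise_sd, r2_target = r2_target,
    seed = seed, phantom = phantom
  )
  if (is.null(spec$noise_sd)) {
    spec$noise_sd <- calibrate_noise_sd(spec)
  }
  structure(spec, class = "cohort_spec")
}

# Advancement bins for the four strata; the open-ended stratum is sampled
# uniformly up to 5.5 mm.
advancement_bins <- function() {
  list(c(1, 2), c(2, 3), c(3, 4), c(4, 5.5))
}

#' Calibrate the response noise to a target R-squared
#'
#' Computes, analytically from the generative distributions, the variance
#' of the deterministic response `a1 X1 + a2 X2` (advancement uniform
#' within strata at the specified proportions; rotation normal truncated at
#' zero) and returns the noise SD for which the population squared
#' correlation between response and noisy outcome equals the target:
#' `sd^2 = Var(a1 X1 + a2 X2) * (1 - R2) / R2`.
#'
#' @param spec a [cohort_spec()] (the `noise_sd` field is ignored).
#' @return noise SD in mm.
#' @export
calibrate_noise_sd <- function(spec) {
  bins <- advancement_bins()
  p <- spec$proportions
  m <- vapply(bins, mean, numeric(1))
  w <- vapply(bins, function(b) diff(b)^2 / 12, numeric(1))
  var_x1 <- sum(p * (w + m^2)) - sum(p * m)^2

  mu <- spec$rotation_mean
  sg <- spec$rotation_sd
  alpha <- -mu / sg
  lambda <- dnorm(alpha) / (1 - pnorm(alpha))
  var_x2 <- sg^2 * (1 + alpha * lambda - lambda^2)

  var_mu <- spec$a1^2 * var_x1 + spec$a2^2 * var_x2
  r2 <- spec$r2_target
  sqrt(var_mu * (1 - r2) / r2)
}

# Inverse-CDF draw from a normal truncated below at 0 (deterministic RNG use).
rtruncnorm0 <- function(n, mean, sd) {
  p0 <- pnorm(0, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

# Published per-stratum cheek-mass position summaries used as generative
# defaults in fast mode.
stratum_position_params <- function() {
  data.frame(
    stratum = advancement_strata(),
    mean = c(1.307, 1.491, 1.906, 2.375),
    sd = c(0.621, 0.607, 0.531, 0.723)
  )
}

#' Generate a simulated surgical cohort
#'
#' In `"fast"` mode the per-side outcomes are drawn directly from the
#' response model (no meshes): Y = a1 X1 + a2 X2 + noise, with the two
#' sides of a patient sharing (X1, X2) and differing only in noise, and
#' per-stratum cheek-mass positions drawn from the published summaries. In
#' `"mesh"` mode each patient is a full phantom put through the geometric
#' pipeline (surgery, registration, ROI volumetrics, cheek metric), so Y
#' and X1 are measured, not assigned.
#'
#' @param spec a [cohort_spec()].
#' @param mode `"fast"` or `"mesh"`.
#' @param config a [run_config()] for mesh mode.
#' @return a [cohort_table()]; mesh mode attaches the per-patient results
#'   as attribute `"patients"`.
#' @export
generate_cohort <- function(spec = cohort_spec(), mode = c("fast", "mesh"),
                            config = run_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  bins <- advancement_bins()
  strata <- advancement_strata()
  stratum_idx <- rep(seq_len(4L), spec$patient_counts)
  n <- spec$n_patients
  d <- numeric(n)
  for (i in seq_len(n)) {
    b <- bins[[stratum_idx[i]]]
    d[i] <- runif(1, b[1], b[2])
  }
  theta <- rtruncnorm0(n, spec$rotation_mean, spec$rotation_sd)

  if (mode == "fast") {
    eps <- matrix(rnorm(2 * n, 0, spec$noise_sd), n, 2)
    pos_par <- stratum_position_params()
    pos <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      pp <- pos_par[stratum_idx[i], ]
      pos[i, ] <- rnorm(2, pp$mean, pp$sd)
    }
    df <- data.frame(
      patient = rep(seq_len(n), each = 2L),
      side = rep(c("L", "R"), times = n),
      soft_movement = rep(spec$a1 * d + spec$a2 * theta, each = 2L) +
        as.numeric(t(eps)),
      bone_advancement = rep(d, each = 2L),
      rotation = rep(theta, each = 2L),
      cheek_position = as.numeric(t(pos)),
      stratum = rep(strata[stratum_idx], each = 2L)
    )
    return(cohort_table(df))
  }

  # mesh mode: one shared pre-operative phantom, per-patient surgery
  pre <- make_phantom(spec$phantom)
  ctx <- prepare_patient(pre, config)
  rows <- list()
  patients <- list()
  for (i in seq_len(n)) {
    post <- apply_surgery(pre, surgery_params(
      advancement = d[i], rotation = theta[i],
      a1 = spec$a1, a2 = spec$a2, noise_sd = spec$noise_sd
    ))
    res <- run_patient(pre, post, config, pre_ctx = ctx)
    if (!identical(res$status, "ok")) {
      patients[[i]] <- res
      next
    }
    mm <- res$measurements
    for (side in c("L", "R")) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient = i, side = side,
        soft_movement = mm$movement[mm$side == side & mm$tissue == "soft"],
        bone_advancement = mm$movement[mm$side == side & mm$tissue == "bone"],
        rotation = res$rotation_change,
        cheek_position = res$cheek$position[res$cheek$side == side],
        stratum = strata[stratum_idx[i]]
      )
    }
    patients[[i]] <- res
  }
  out <- cohort_table(do.call(rbind, rows))
  attr(out, "patients") <- patients
  out
}
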