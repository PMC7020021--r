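test_that("frame axes from symmetric landmarks match the analytic construction", {
  lm <- frame_landmarks()
  fr <- build_reference_frame(lm)
  # mid-orbitale z cancels, so FH is the z = 0 plane exactly
  expect_equal(unname(fr$axes["z", ]), c(0, 0, 1), tolerance = 1e-12)
  # S -> N projected onto FH gives the anterior axis
  expect_equal(unname(fr$axes["y", ]), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(unname(fr$axes["x", ]), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$origin, c(0, 20, 0))

  # orthonormal, right-handed
  expect_equal(max(abs(tcrossprod(fr$axes) - diag(3))), 0, tolerance = 1e-9)
  expect_equal(det(fr$axes), 1, tolerance = 1e-9)
  # nasion anterior of sella in frame coordinates
  expect_gt(frame_coords(fr, landmark(lm, "N"))[2], 0)
})

test_that("frame construction is rigid-motion equivariant", {
  lm <- shared_phantom()$landmarks
  fr0 <- build_reference_frame(lm)
  c0 <- frame_coords(fr0, unclass(lm))
  for (seed in 1:5) {
    tr <- random_rigid(seed)
    lm2 <- apply_transform(lm, tr)
    fr2 <- build_reference_frame(lm2)
    c2 <- frame_coords(fr2, unclass(lm2))
    expect_lt(max(abs(c2 - c0)), 1e-8)
  }
})

test_that("frame construction errors on missing or degenerate landmarks", {
  lm <- frame_landmarks()
  lm_missing <- landmark_set(unclass(lm)[rownames(lm) != "S", ],
                             require_all = FALSE)
  expect_error(build_reference_frame(lm_missing), "incomplete landmark set")
  lm_flat <- frame_landmarks(po_l = c(-60, 0, 0), po_r = c(60, 0, 0),
                             or_l = c(-30, 0, 0), or_r = c(30, 0, 0))
  expect_error(build_reference_frame(lm_flat), "degenerate frame")
})

test_that("every plane contains its defining landmarks and the axial planes are orthogonal", {
  ph <- shared_phantom()
  lm <- ph$landmarks
  fr <- build_reference_frame(lm)
  pl <- construct_planes(fr, lm)

  on_plane <- function(plane, name) {
    expect_lt(abs(signed_distance(plane, landmark(lm, name))), 1e-6)
  }
  on_plane(pl$FH, "Po_L"); on_plane(pl$FH, "Po_R")
  expect_lt(abs(signed_distance(
    pl$FH, (landmark(lm, "Or_L") + landmark(lm, "Or_R")) / 2)), 1e-6)
  on_plane(pl$MSP, "S"); on_plane(pl$MSP, "N")
  on_plane(pl$CO, "S")
  on_plane(pl$OP, "U1")
  expect_lt(abs(signed_distance(
    pl$OP, (landmark(lm, "U6_L") + landmark(lm, "U6_R")) / 2)), 1e-6)
  for (side in c("L", "R")) {
    on_plane(pl[[paste0("MPP_", side)]], paste0("C_", side))
    on_plane(pl[[paste0("CPP_", side)]], paste0("C_", side))
    on_plane(pl[[paste0("LCP_", side)]], paste0("Ex_", side))
    on_plane(pl[[paste0("MCP_", side)]], paste0("Al_", side))
  }
  on_plane(pl$ICP, "Sn")

  # FH, MSP, CO pairwise perpendicular; all normals unit
  expect_lt(abs(sum(pl$FH$normal * pl$MSP$normal)), 1e-6)
  expect_lt(abs(sum(pl$FH$normal * pl$CO$normal)), 1e-6)
  expect_lt(abs(sum(pl$MSP$normal * pl$CO$normal)), 1e-6)
  for (p in pl) expect_equal(sum(p$normal^2), 1, tolerance = 1e-9)
})

test_that("ICP and MCP planes are parallel/perpendicular to FH as defined", {
  ph <- shared_phantom()
  fr <- build_reference_frame(ph$landmarks)
  pl <- construct_planes(fr, ph$landmarks)
  expect_equal(abs(sum(pl$ICP$normal * pl$FH$normal)), 1, tolerance = 1e-9)
  expect_lt(abs(sum(pl$MCP_R$normal * pl$FH$normal)), 1e-9)
  # parasagittal: MCP normal is the lateral axis
  expect_equal(abs(sum(pl$MCP_R$normal * fr$axes["x", ])), 1, tolerance = 1e-9)
})

test_that("maxillary rotation angle matches analytic slope constructions", {
  lm0 <- frame_landmarks()
  base <- unclass(lm0)
  with_dentition <- function(u1, u6_l, u6_r) {
    landmark_set(rbind(base, U1 = u1, U6_L = u6_l, U6_R = u6_r),
                 require_all = FALSE)
  }
  fr <- build_reference_frame(lm0)

  # occlusal plane parallel to FH
  lm <- with_dentition(c(0, 70, -25), c(-30, 40, -25), c(30, 40, -25))
  expect_equal(maxillary_rotation_angle(fr, lm), 0, tolerance = 1e-9)

  # trace with slope tan(10 deg) over a 30 mm anteroposterior run
  drop <- 30 * tan(10 * pi / 180)
  lm10 <- with_dentition(c(0, 70, -25), c(-30, 40, -25 + drop),
                         c(30, 40, -25 + drop))
  expect_equal(maxillary_rotation_angle(fr, lm10), 10, tolerance = 1e-9)

  # invariant under uniform anteroposterior translation of the dentition
  lm10b <- with_dentition(c(0, 75, -25), c(-30, 45, -25 + drop),
                          c(30, 45, -25 + drop))
  expect_equal(maxillary_rotation_angle(fr, lm10b), 10, tolerance = 1e-9)

  # degenerate occlusal plane
  lm_bad <- with_dentition(c(0, 40, -25), c(-30, 40, -25), c(30, 40, -25))
  expect_error(maxillary_rotation_angle(fr, lm_bad), "degenerate occlusal plane")
})

test_that("rotation angle is invariant under rigid motion", {
  ph <- shared_phantom()
  fr <- build_reference_frame(ph$landmarks)
  a0 <- maxillary_rotation_angle(fr, ph$landmarks)
  expect_equal(a0, 8, tolerance = 1e-6)  # phantom dentition inclination
  for (seed in 6:8) {
    tr <- random_rigid(seed)
    lm2 <- apply_transform(ph$landmarks, tr)
    fr2 <- build_reference_frame(lm2)
    expect_equal(maxillary_rotation_angle(fr2, lm2), a0, tolerance = 1e-8)
  }
})

test_that("signed distance matches the projection oracle", {
  pl <- plane(c(0, 0, 1), offset = 0)
  expect_equal(signed_distance(pl, c(1, 2, 3)), 3)
  expect_equal(signed_distance(pl, c(5, -2, 0)), 0)

  set.seed(31)
  for (i in 1:10) {
    a <- rnorm(3, sd = 10); b <- rnorm(3, sd = 10); cc <- rnorm(3, sd = 10)
    n <- pracma_cross(b - a, cc - a)
    if (sqrt(sum(n^2)) < 1e-6) next
    pl <- plane(n, point = a)
    p <- rnorm(3, sd = 10)
    # oracle: residual of projecting p - a onto the plane's spanning vectors
    M <- cbind(b - a, cc - a)
    resid <- (p - a) - M %*% solve(crossprod(M), crossprod(M, p - a))
    d_oracle <- sqrt(sum(resid^2)) * sign(sum((p - a) * pl$normal))
    expect_equal(signed_distance(pl, p), d_oracle, tolerance = 1e-12)
  }
})
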