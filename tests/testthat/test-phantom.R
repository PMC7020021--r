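test_that("the phantom is symmetric and deterministic", {
  ph <- shared_phantom()
  fr <- build_reference_frame(ph$landmarks)
  pl <- construct_planes(fr, ph$landmarks)
  aL <- clip_mesh_to_roi(ph$bone, pl, "L")$area
  aR <- clip_mesh_to_roi(ph$bone, pl, "R")$area
  expect_equal(aL, aR, tolerance = aR * 0.005)

  ph2 <- make_phantom()
  expect_identical(ph2$bone$vertices, ph$bone$vertices)
  expect_identical(ph2$soft$vertices, ph$soft$vertices)
  expect_identical(unclass(ph2$landmarks), unclass(ph$landmarks))
})

test_that("phantom landmarks satisfy the plane incidence suite", {
  ph <- shared_phantom()
  fr <- build_reference_frame(ph$landmarks)
  pl <- construct_planes(fr, ph$landmarks)
  lm <- ph$landmarks
  pairs <- list(
    c("FH", "Po_L"), c("FH", "Po_R"), c("MSP", "S"), c("MSP", "N"),
    c("CO", "S"), c("OP", "U1"), c("MPP_L", "C_L"), c("MPP_R", "C_R"),
    c("CPP_L", "C_L"), c("CPP_R", "C_R"), c("LCP_L", "Ex_L"),
    c("LCP_R", "Ex_R"), c("MCP_L", "Al_L"), c("MCP_R", "Al_R"),
    c("ICP", "Sn")
  )
  for (p in pairs) {
    expect_lt(abs(signed_distance(pl[[p[1]]], landmark(lm, p[2]))), 1e-6)
  }
  # left/right pairs straddle the midsagittal plane
  for (nm in c("Po", "Or", "Ex", "Al", "C", "U6")) {
    dl <- signed_distance(pl$MSP, landmark(lm, paste0(nm, "_L")))
    dr <- signed_distance(pl$MSP, landmark(lm, paste0(nm, "_R")))
    expect_lt(dl * dr, 0)
  }
})

test_that("too coarse a mesh resolution is rejected", {
  expect_error(phantom_spec(resolution = 4), "resolution too coarse")
})

test_that("pure advancement passes through the pipeline end to end", {
  ph <- shared_phantom()
  ctx <- shared_ctx()
  for (d in c(1, 3, 5)) {
    post <- apply_surgery(ph, surgery_params(d, 0, a1 = 1))
    res <- run_patient(ph, post, pre_ctx = ctx)
    expect_identical(res$status, "ok")
    mm <- res$measurements
    for (tissue in c("bone", "soft")) {
      for (side in c("L", "R")) {
        mv <- mm$movement[mm$tissue == tissue & mm$side == side]
        expect_lt(abs(mv - d), 0.05)
      }
    }
  }
})

test_that("pure rotation changes the occlusal angle and leaves the mask region fixed", {
  ph <- shared_phantom()
  ctx <- shared_ctx()
  post <- apply_surgery(ph, surgery_params(0, 5))
  res <- run_patient(ph, post, pre_ctx = ctx)
  expect_equal(res$rotation_change, 5, tolerance = 0.1)
  expect_lt(res$qc$rms, 1e-6)  # forehead and orbit untouched

  # near the rotation axis the bone hardly moves; at ROI height it does
  fr <- ctx$frame
  vz <- frame_coords(fr, post$bone$vertices)[, 3]
  vz0 <- frame_coords(fr, ph$bone$vertices)[, 3]
  shift <- sqrt(rowSums((post$bone$vertices - ph$bone$vertices)^2))
  near_axis <- which(abs(vz0 - frame_coords(fr, landmark(ph$landmarks, "U1"))[3]) < 3)
  expect_lt(max(shift[near_axis]), 0.5)
})

test_that("forehead and orbital vertices are identical pre and post surgery", {
  ph <- shared_phantom()
  post <- apply_surgery(ph, surgery_params(4, 6, noise_sd = 0.3, seed = 2))
  fr <- build_reference_frame(ph$landmarks)
  above <- frame_coords(fr, ph$bone$vertices)[, 3] > 1
  expect_identical(post$bone$vertices[above, ], ph$bone$vertices[above, ])
})

test_that("noiseless mesh-mode and fast-mode cohorts agree on the response", {
  spec <- cohort_spec(n_patients = 4, proportions = c(1, 1, 1, 1) / 4,
                      noise_sd = 0, seed = 77)
  fast <- generate_cohort(spec, mode = "fast")
  mesh <- generate_cohort(spec, mode = "mesh")
  expect_equal(nrow(mesh), 8)
  # same generative draws: the measured response agrees with the assigned
  # one (measured bone movement additionally carries the rotation's
  # contribution at ROI height, so only Y is compared record-wise)
  expect_lt(max(abs(mesh$soft_movement - fast$soft_movement)), 0.1)
})

test_that("a noiseless cohort recovers the generating coefficients exactly", {
  spec <- cohort_spec(noise_sd = 0, seed = 9)
  tab <- generate_cohort(spec, mode = "fast")
  m <- fit_prediction_model(tab)
  expect_equal(unname(m$coefficients["b1"]), 0.627, tolerance = 1e-9)
  expect_equal(unname(m$coefficients["b2"]), 0.070, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
})

test_that("noise calibration hits the target R-squared in expectation", {
  spec <- cohort_spec(seed = 1)
  expect_gt(spec$noise_sd, 0)
  r2 <- vapply(1:20, function(s) {
    fit_prediction_model(generate_cohort(cohort_spec(seed = s),
                                         mode = "fast"))$r_squared
  }, numeric(1))
  expect_equal(mean(r2), 0.788, tolerance = 0.03)
})

test_that("cohort generation is reproducible and validates proportions", {
  a <- generate_cohort(cohort_spec(seed = 123), mode = "fast")
  b <- generate_cohort(cohort_spec(seed = 123), mode = "fast")
  expect_identical(a, b)
  expect_error(cohort_spec(n_patients = 10, proportions = c(14, 34, 34, 14) / 96),
               "infeasible")
})
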