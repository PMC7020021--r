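# ROI clipping and volumetric subtraction, checked against analytic flat
# cases, brute-force half-space classification, and a voxel-counting oracle.

phantom_planes <- function() {
  ph <- shared_phantom()
  fr <- build_reference_frame(ph$landmarks)
  construct_planes(fr, ph$landmarks)
}

test_that("a flat sheet clips to exactly the ROI box area", {
  pl <- phantom_planes()
  sheet <- flat_sheet()  # spans well beyond the ROI
  patch <- clip_mesh_to_roi(sheet, pl, "R")
  # ROI box: x in [Al, Ex] = [12, 38], z in [Sn, FH] = [-25, 0]
  expect_equal(patch$area, 26 * 25, tolerance = 1e-6)
  # patch area equals the sum of its triangle areas by construction
  expect_equal(patch$area, sum(triangle_areas(patch$mesh)), tolerance = 1e-9)
})

test_that("clipped patches satisfy all four half-space constraints", {
  ph <- shared_phantom()
  pl <- phantom_planes()
  for (side in c("L", "R")) {
    patch <- clip_mesh_to_roi(ph$bone, pl, side)
    V <- patch$mesh$vertices
    F <- patch$mesh$faces
    centroids <- (V[F[, 1], ] + V[F[, 2], ] + V[F[, 3], ]) / 3
    for (b in patch$bounds) {
      expect_lt(max(signed_distance(b$plane, centroids) * b$sense), 1e-6)
    }
    # brute-force check: every retained vertex is inside all four bounds
    for (b in patch$bounds) {
      expect_true(all(signed_distance(b$plane, V) * b$sense <= 1e-6))
    }
    # anterior-facing only
    fr <- patch$frame
    expect_true(all(triangle_normals(patch$mesh) %*% fr$axes["y", ] > 0))
  }
})

test_that("a clipped vertex set matches per-vertex classification of the source mesh", {
  ph <- shared_phantom()
  pl <- phantom_planes()
  patch <- clip_mesh_to_roi(ph$bone, pl, "R")
  V0 <- ph$bone$vertices
  inside <- rep(TRUE, nrow(V0))
  for (b in patch$bounds) {
    inside <- inside & (signed_distance(b$plane, V0) * b$sense <= 1e-6)
  }
  # all strictly-inside source vertices must appear in the patch
  key_patch <- paste(round(patch$mesh$vertices[, 1], 6),
                     round(patch$mesh$vertices[, 2], 6),
                     round(patch$mesh$vertices[, 3], 6))
  key_src <- paste(round(V0[, 1], 6), round(V0[, 2], 6), round(V0[, 3], 6))
  expect_true(all(key_src[inside] %in% key_patch))
})

test_that("an ROI that misses the mesh errors", {
  pl <- phantom_planes()
  far <- flat_sheet(x_lo = 200, x_hi = 220, z_lo = 0, z_hi = 20)
  expect_error(clip_mesh_to_roi(far, pl, "R"), "ROI does not intersect mesh")
})

test_that("flat-patch volumetric subtraction recovers the applied translation exactly", {
  pl <- phantom_planes()
  sheet <- flat_sheet()
  patch <- clip_mesh_to_roi(sheet, pl, "R")
  vc <- volumetric_change(patch, translate_mesh(sheet, 3), grid_mm = 0.4)
  expect_equal(vc$delta_volume, 26 * 25 * 3, tolerance = 1e-6)
  expect_equal(vc$movement, 3, tolerance = 1e-9)

  # identity: post == pre gives zero volume
  vc0 <- volumetric_change(patch, sheet, grid_mm = 0.4)
  expect_equal(vc0$delta_volume, 0, tolerance = 1e-9)

  # flat-patch identity across grid sizes (within 0.5 %)
  for (g in c(0.5, 0.25)) {
    vcg <- volumetric_change(patch, translate_mesh(sheet, 1.7), grid_mm = g)
    expect_equal(vcg$movement, 1.7, tolerance = 1.7 * 0.005)
  }
})

test_that("height-field and voxel-oracle volumes agree on a curved patch", {
  pl <- phantom_planes()
  bump <- bump_sheet(amp = 3, sigma = 8)
  patch <- clip_mesh_to_roi(bump, pl, "R")
  post <- translate_mesh(bump, 2)
  vc <- volumetric_change(patch, post, grid_mm = 0.4)

  post_patch <- cheekmorph:::clip_to_patch_bounds(post, patch)
  dv_vox <- oracle_voxel_delta_volume(patch$mesh, post_patch, h = 0.2)
  expect_equal(vc$delta_volume, dv_vox, tolerance = abs(dv_vox) * 0.02)

  # |movement| <= |d| for a pure translation of a curved surface
  expect_lte(abs(vc$movement), 2)
})

test_that("pipeline movement for a curved patch never exceeds the applied translation", {
  ph <- shared_phantom()
  pl <- phantom_planes()
  patch <- clip_mesh_to_roi(ph$bone, pl, "L")
  vc <- volumetric_change(patch, translate_mesh(ph$bone, 2.4), grid_mm = 0.4)
  expect_lte(vc$movement, 2.4)
  expect_gt(vc$movement, 2.4 * 0.98)
})

test_that("insufficient post-operative coverage is an error", {
  pl <- phantom_planes()
  sheet <- flat_sheet()
  patch <- clip_mesh_to_roi(sheet, pl, "R")
  half <- flat_sheet(x_lo = -60, x_hi = 25, z_lo = -45, z_hi = 25)
  expect_error(volumetric_change(patch, half, grid_mm = 0.4),
               "surface coverage insufficient")
})

test_that("average sagittal movement is volume over area", {
  expect_equal(average_sagittal_movement(10, 5), 2)
  expect_equal(average_sagittal_movement(0, 123.4), 0)
  expect_error(average_sagittal_movement(10, 0), "positive")
  expect_error(average_sagittal_movement(10, -3), "positive")
})

test_that("rotation change is a plain signed difference", {
  expect_equal(rotation_change(8.3, 11.1), 2.8)
  expect_equal(rotation_change(5.5, 5.5), 0)
  expect_equal(rotation_change(11.1, 8.3), -2.8)
})

test_that("advancement strata use half-open left-closed bins", {
  expect_equal(stratify_advancement(c(1, 1.99, 2, 2.5, 3, 3.999, 4, 4.01, 9)),
               c("1-2 mm", "1-2 mm", "2-3 mm", "2-3 mm", "3-4 mm", "3-4 mm",
                 ">4 mm", ">4 mm", ">4 mm"))
  expect_equal(stratify_advancement(0.5), "below-range")
  expect_error(stratify_advancement(-0.1), "non-negative")
})

test_that("a generated cohort reproduces the published stratum counts", {
  tab <- generate_cohort(cohort_spec(seed = 5), mode = "fast")
  counts <- table(factor(tab$stratum, levels = advancement_strata()))
  expect_equal(unname(as.integer(counts)), c(14, 34, 34, 14))
})
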