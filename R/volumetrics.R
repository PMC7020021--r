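# Plane-bounded ROI clipping and volumetric subtraction.

# Clip a mesh to the half-space signed_distance(plane, p) * sense <= 0.
# Triangles crossing the boundary are split at the plane.
clip_halfspace <- function(mesh, plane, sense = 1) {
  V <- mesh$vertices
  F <- mesh$faces
  if (nrow(F) == 0L) return(mesh)
  d <- signed_distance(plane, V) * sense
  eps <- 1e-9
  din <- d <= eps
  tri_in <- matrix(din[F], ncol = 3)
  n_in <- rowSums(tri_in)
  keep <- which(n_in == 3L)
  crossing <- which(n_in == 1L | n_in == 2L)

  new_faces <- F[keep, , drop = FALSE]
  extraV <- list()
  extraF <- list()
  nv <- nrow(V)
  for (t in crossing) {
    vi <- F[t, ]
    inside <- tri_in[t, ]
    # rotate so the odd vertex is first
    if (sum(inside) == 1L) {
      k <- which(inside)
    } else {
      k <- which(!inside)
    }
    ord <- ((k - 1L + 0:2) %% 3L) + 1L
    vi <- vi[ord]
    dd <- d[vi]
    a <- V[vi[1], ]; b <- V[vi[2], ]; cc <- V[vi[3], ]
    tab <- dd[1] / (dd[1] - dd[2])
    tac <- dd[1] / (dd[1] - dd[3])
    pab <- a + tab * (b - a)
    pac <- a + tac * (cc - a)
    extraV[[length(extraV) + 1L]] <- rbind(pab, pac)
    iab <- nv + 2L * length(extraV) - 1L
    iac <- iab + 1L
    if (sum(inside) == 1L) {
      # only the first (rotated) vertex is inside: keep the tip triangle
      extraF[[length(extraF) + 1L]] <- c(vi[1], iab, iac)
    } else {
      # first vertex outside: keep the quad split into two triangles
      extraF[[length(extraF) + 1L]] <- c(iab, vi[2], vi[3])
      extraF[[length(extraF) + 1L]] <- c(iab, vi[3], iac)
    }
  }
  if (length(extraV) > 0L) {
    V <- rbind(V, do.call(rbind, extraV))
    new_faces <- rbind(new_faces, do.call(rbind, extraF))
  }
  if (nrow(new_faces) == 0L) {
    return(surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  }
  # drop unused vertices
  used <- sort(unique(as.integer(new_faces)))
  remap <- integer(nrow(V))
  remap[used] <- seq_along(used)
  surface_mesh(V[used, , drop = FALSE],
               matrix(remap[new_faces], ncol = 3))
}

#' Clip a mesh to the anteromedial cheek region of interest
#'
#' The ROI for a side is bounded laterally by the lateral cheek plane
#' (through exocanthion), medially by the medial cheek plane (through
#' alare), inferiorly by the inferior cheek plane (through subnasale) and
#' superiorly by the Frankfort horizontal plane. Triangles crossing a
#' boundary are split at the plane, and only anterior-facing triangles
#' (normal with a positive anteroposterior component) are retained.
#'
#' @param mesh a [surface_mesh()] (bone or soft tissue, pre- or post-op, in
#'   the pre-operative space).
#' @param planes a `plane_set` built from the pre-operative landmarks.
#' @param side `"L"` or `"R"`.
#' @return object of class `roi_patch`: `mesh` (the clipped patch), `side`,
#'   `area` (mm^2, sum of retained triangle areas), `frame`, and `bounds`
#'   (the four oriented half-space planes, reusable on another mesh).
#' @export
clip_mesh_to_roi <- function(mesh, planes, side = c("R", "L")) {
  side <- match.arg(side)
  frame <- attr(planes, "frame")
  lm <- attr(planes, "landmarks")
  lat <- planes[[paste0("LCP_", side)]]
  med <- planes[[paste0("MCP_", side)]]
  inf <- planes$ICP
  sup <- planes$FH

  # interior reference point: centre of the ROI box in frame coordinates
  al <- frame_coords(frame, landmark(lm, paste0("Al_", side)))
  ex <- frame_coords(frame, landmark(lm, paste0("Ex_", side)))
  sn <- frame_coords(frame, landmark(lm, "Sn"))
  po <- frame_coords(frame, landmark(lm, "Po_L"))
  ref <- world_coords(frame, c(
    (al[1] + ex[1]) / 2,
    (al[2] + ex[2]) / 2,
    (sn[3] + po[3]) / 2
  ))

  out <- mesh
  bounds <- list()
  for (pl in list(lat, med, inf, sup)) {
    sense <- if (signed_distance(pl, ref) > 0) -1 else 1
    out <- clip_halfspace(out, pl, sense)
    bounds[[length(bounds) + 1L]] <- list(plane = pl, sense = sense)
    if (n_faces(out) == 0L) stop("ROI does not intersect mesh")
  }
  # anterior-facing triangles only
  nrm <- triangle_normals(out)
  anterior <- as.numeric(nrm %*% frame$axes["y", ]) > 0
  out$faces <- out$faces[anterior, , drop = FALSE]
  if (n_faces(out) == 0L) stop("ROI does not intersect mesh")
  out <- weld_vertices(out)

  structure(list(
    mesh = out,
    side = side,
    area = mesh_area(out),
    frame = frame,
    bounds = bounds
  ), class = "roi_patch")
}

#' @export
print.roi_patch <- function(x, ...) {
  cat(sprintf("<roi_patch> side %s, %d triangles, area %.1f mm^2\n",
              x$side, n_faces(x$mesh), x$area))
  invisible(x)
}

# Apply the stored oriented half-spaces of a patch to another mesh and keep
# the anterior-facing portion.
clip_to_patch_bounds <- function(mesh, patch) {
  out <- mesh
  for (b in patch$bounds) {
    out <- clip_halfspace(out, b$plane, b$sense)
    if (n_faces(out) == 0L) return(out)
  }
  nrm <- triangle_normals(out)
  anterior <- as.numeric(nrm %*% patch$frame$axes["y", ]) > 0
  out$faces <- out$faces[anterior, , drop = FALSE]
  out
}

#' Volumetric change between pre- and post-operative surfaces in an ROI
#'
#' Signed volume enclosed between the pre-operative ROI patch and the
#' registered post-operative surface, computed by sampling both surfaces as
#' anterior height fields y(x, z) on a regular grid over the patch's
#' lateral-vertical footprint (rays along the anterior axis, outermost hit)
#' and integrating the height difference times the cell area. Anterior
#' displacement of the post-operative surface gives a positive volume.
#'
#' @param pre_patch an `roi_patch` from [clip_mesh_to_roi()] on the
#'   pre-operative mesh.
#' @param post_mesh the post-operative [surface_mesh()], already registered
#'   into pre-operative space.
#' @param grid_mm sampling grid spacing in mm (default 0.4, the CBCT voxel
#'   size the models derive from).
#' @param max_miss maximum tolerated fraction of footprint cells where the
#'   post-operative surface is not hit (default 0.01).
#' @return a list of class `volumetric_change`: `delta_volume` (mm^3,
#'   signed, anterior-positive), `pre_area` (mm^2), `movement` (mm,
#'   `delta_volume / pre_area`), `n_cells`, `miss_fraction`.
#' @export
volumetric_change <- function(pre_patch, post_mesh, grid_mm = 0.4,
                              max_miss = 0.01) {
  stopifnot(inherits(pre_patch, "roi_patch"), grid_mm > 0)
  frame <- pre_patch$frame
  post_patch <- clip_to_patch_bounds(post_mesh, pre_patch)
  if (n_faces(post_patch) == 0L) stop("surface coverage insufficient")

  preV <- frame_coords(frame, pre_patch$mesh$vertices)
  postV <- frame_coords(frame, post_patch$vertices)
  pre_f <- surface_mesh(preV, pre_patch$mesh$faces)
  post_f <- surface_mesh(postV, post_patch$faces)

  xr <- range(preV[, 1])
  zr <- range(preV[, 3])
  # tile the footprint exactly: adjust the cell size per axis so an integer
  # number of cells spans the extent (keeps flat-patch integration unbiased)
  nx <- max(1L, round(diff(xr) / grid_mm))
  nz <- max(1L, round(diff(zr) / grid_mm))
  cx <- diff(xr) / nx
  cz <- diff(zr) / nz
  xs <- xr[1] + (seq_len(nx) - 0.5) * cx
  zs <- zr[1] + (seq_len(nz) - 0.5) * cz
  gg <- as.matrix(expand.grid(x = xs, z = zs))
  cell_area <- cx * cz

  y_pre <- cpp_raycast_y(gg, pre_f$vertices, pre_f$faces)
  hit_pre <- !is.na(y_pre)
  if (!any(hit_pre)) stop("ROI does not intersect mesh")
  y_post <- cpp_raycast_y(gg[hit_pre, , drop = FALSE],
                          post_f$vertices, post_f$faces)
  miss <- mean(is.na(y_post))
  if (miss > max_miss) stop("surface coverage insufficient")
  both <- !is.na(y_post)
  dv <- sum(y_post[both] - y_pre[hit_pre][both]) * cell_area

  structure(list(
    delta_volume = dv,
    pre_area = pre_patch$area,
    movement = dv / pre_patch$area,
    n_cells = sum(hit_pre),
    miss_fraction = miss
  ), class = "volumetric_change")
}

#' @export
print.volumetric_change <- function(x, ...) {
  cat(sprintf(
    "<volumetric_change> dV %.1f mm^3 over %.1f mm^2 -> movement %.3f mm\n",
    x$delta_volume, x$pre_area, x$movement
  ))
  invisible(x)
}

#' Average sagittal movement of a region
#'
#' Volumetric change divided by the pre-operative surface area of the
#' region.
#'
#' @param delta_volume signed volumetric change in mm^3.
#' @param pre_area pre-operative surface area in mm^2 (> 0).
#' @return average movement in mm.
#' @export
average_sagittal_movement <- function(delta_volume, pre_area) {
  if (!is.finite(pre_area) || pre_area <= 0) {
    stop("pre_area must be positive")
  }
  delta_volume / pre_area
}

#' Surgical change of the maxillary rotational angle
#'
#' Post-operative minus pre-operative maxillary rotational angle; positive
#' values are clockwise rotations (posterior impaction steepening the
#' occlusal plane relative to the Frankfort horizontal).
#'
#' @param pre_angle,post_angle angles in degrees, from
#'   [maxillary_rotation_angle()].
#' @return change in degrees.
#' @export
rotation_change <- function(pre_angle, post_angle) {
  post_angle - pre_angle
}

#' Stratify maxillary advancement into the four reporting levels
#'
#' Half-open bins \[1,2), \[2,3), \[3,4) and \[4, Inf) mm; advancements
#' below 1 mm are flagged `"below-range"`.
#'
#' @param movement_mm non-negative advancement value(s) in mm.
#' @return character vector of stratum labels (`"1-2 mm"`, `"2-3 mm"`,
#'   `"3-4 mm"`, `">4 mm"`, `"below-range"`).
#' @export
stratify_advancement <- function(movement_mm) {
  if (any(movement_mm < 0, na.rm = TRUE)) {
    stop("advancement must be non-negative")
  }
  labs <- c("below-range", "1-2 mm", "2-3 mm", "3-4 mm", ">4 mm")
  idx <- findInterval(movement_mm, c(1, 2, 3, 4)) + 1L
  labs[idx]
}

#' Stratum labels in reporting order
#' @return character vector of the four advancement strata.
#' @export
advancement_strata <- function() c("1-2 mm", "2-3 mm", "3-4 mm", ">4 mm")
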