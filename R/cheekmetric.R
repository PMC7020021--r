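#' Cheek-mass point and its position relative to the cornea perpendicular
#' plane
#'
#' Intersects the soft-tissue surface with the mid-pupillary plane of the
#' chosen side to obtain a sagittal profile polyline, restricts it to the
#' vertical window between the subnasale level and the orbitale level
#' (the infraorbital region), and returns the most anterior profile point
#' (the cheek-mass point, Ck) together with its signed anteroposterior
#' distance to the cornea perpendicular plane. Positive values mean the
#' cheek apex lies ahead of the cornea; negative values (a deficient,
#' flat-to-concave cheek) are admitted.
#'
#' @param soft soft-tissue [surface_mesh()].
#' @param frame a `reference_frame`.
#' @param lm the matching `landmark_set` (needs C, Sn, Or for the side).
#' @param side `"L"` or `"R"`.
#' @return object of class `cheek_mass_result`: `side`, `ck_point` (world
#'   mm), `position` (mm, anterior-positive).
#' @export
cheek_mass_position <- function(soft, frame, lm, side = c("R", "L")) {
  side <- match.arg(side)
  c_pt <- landmark(lm, paste0("C_", side))
  or_pt <- landmark(lm, paste0("Or_", side))
  sn <- landmark(lm, "Sn")

  x_axis <- frame$axes["x", ]
  mpp <- plane(x_axis, point = c_pt, name = paste0("MPP_", side))

  V <- soft$vertices
  F <- soft$faces
  d <- signed_distance(mpp, V)
  dmat <- matrix(d[F], ncol = 3)
  crosses <- (row_min(dmat) < 0) & (row_max(dmat) > 0)
  on_plane <- abs(d) < 1e-9  # vertices lying exactly on the profile plane
  if (!any(crosses) && !any(on_plane)) stop("cheek profile not found")

  pts <- rbind(
    if (any(crosses)) profile_points(V, F[crosses, , drop = FALSE], d),
    V[on_plane, , drop = FALSE]
  )
  pc <- frame_coords(frame, pts)
  z_lo <- frame_coords(frame, sn)[3]
  z_hi <- frame_coords(frame, or_pt)[3]
  win <- pc[, 3] > z_lo & pc[, 3] < z_hi
  if (!any(win)) stop("cheek profile not found")
  pc <- pc[win, , drop = FALSE]
  best <- which.max(pc[, 2])
  ck_frame <- pc[best, ]
  ck_world <- world_coords(frame, ck_frame)

  c_frame <- frame_coords(frame, c_pt)
  position <- ck_frame[2] - c_frame[2]  # signed distance to CPP(side)

  structure(list(
    side = side,
    ck_point = as.numeric(ck_world),
    position = as.numeric(position)
  ), class = "cheek_mass_result")
}

#' @export
print.cheek_mass_result <- function(x, ...) {
  cat(sprintf(
    "<cheek_mass_result> side %s, position %+.3f mm vs cornea perpendicular plane\n",
    x$side, x$position
  ))
  invisible(x)
}

# Intersection points of triangle edges with the plane (d = per-vertex
# signed distances). Returns a matrix of points.
profile_points <- function(V, F, d) {
  out <- list()
  edges <- rbind(c(1, 2), c(2, 3), c(3, 1))
  for (e in seq_len(3)) {
    i <- F[, edges[e, 1]]
    j <- F[, edges[e, 2]]
    di <- d[i]
    dj <- d[j]
    cross_e <- (di < 0 & dj > 0) | (di > 0 & dj < 0)
    if (!any(cross_e)) next
    ii <- i[cross_e]
    jj <- j[cross_e]
    tt <- di[cross_e] / (di[cross_e] - dj[cross_e])
    out[[e]] <- V[ii, , drop = FALSE] +
      tt * (V[jj, , drop = FALSE] - V[ii, , drop = FALSE])
  }
  do.call(rbind, out)
}

row_min <- function(m) do.call(pmin, as.data.frame(m))
row_max <- function(m) do.call(pmax, as.data.frame(m))
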