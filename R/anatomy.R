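#' @useDynLib cheekmorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef cor dnorm fitted ks.test lm optimize pnorm pt
#'   qnorm residuals rnorm runif sd t.test var
NULL

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate frame: zero-length direction")
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Build the craniofacial reference frame from landmarks
#'
#' The Frankfort horizontal (FH) plane is fitted through the two porions and
#' the midpoint of the two orbitale points; its normal, oriented so that
#' nasion lies superior to basion, is the vertical (z) axis. The
#' anteroposterior (y) axis is the sella-to-nasion direction projected onto
#' FH (so the midsagittal plane is perpendicular to FH and contains S and
#' N), oriented anteriorly. The lateral (x) axis completes a right-handed
#' frame (x = y x z), positive toward the patient's right. Origin is sella.
#'
#' @param lm a `landmark_set` containing at least Po_L, Po_R, Or_L, Or_R,
#'   S, N, Ba.
#' @return object of class `reference_frame` with elements `origin` (sella)
#'   and `axes` (3 x 3 matrix with rows x, y, z).
#' @export
build_reference_frame <- function(lm) {
  po_l <- landmark(lm, "Po_L")
  po_r <- landmark(lm, "Po_R")
  or_m <- (landmark(lm, "Or_L") + landmark(lm, "Or_R")) / 2
  s <- landmark(lm, "S")
  n <- landmark(lm, "N")
  ba <- landmark(lm, "Ba")

  v1 <- po_r - po_l
  v2 <- or_m - po_l
  nrm <- cross3(v1, v2)
  if (sqrt(sum(nrm^2)) < 1e-8 * sqrt(sum(v1^2)) * sqrt(sum(v2^2))) {
    stop("degenerate frame: FH defining points are collinear")
  }
  z <- normalize3(nrm)
  if (sum(z * (n - ba)) < 0) z <- -z  # nasion superior to basion

  u <- n - s
  y0 <- u - sum(u * z) * z
  if (sqrt(sum(y0^2)) < 1e-9) {
    stop("degenerate frame: S and N coincide in the FH projection")
  }
  y <- normalize3(y0)  # anterior
  x <- cross3(y, z)    # patient's right; right-handed (x, y, z)

  axes <- rbind(x = x, y = y, z = z)
  structure(list(origin = s, axes = axes), class = "reference_frame")
}

#' @export
print.reference_frame <- function(x, ...) {
  cat("<reference_frame> origin (sella):",
      sprintf("(%.2f, %.2f, %.2f) mm\n", x$origin[1], x$origin[2], x$origin[3]))
  print(round(x$axes, 4))
  invisible(x)
}

#' Coordinates of points in a reference frame
#'
#' @param frame a `reference_frame`.
#' @param points n x 3 matrix or length-3 vector in world (scanner) mm.
#' @return coordinates in the frame (x lateral-right, y anterior,
#'   z superior), same shape as input.
#' @export
frame_coords <- function(frame, points) {
  one <- is.null(dim(points))
  p <- if (one) matrix(points, ncol = 3) else as.matrix(points)
  out <- sweep(p, 2, frame$origin) %*% t(frame$axes)
  colnames(out) <- c("x", "y", "z")
  if (one) drop(out) else out
}

#' World coordinates from frame coordinates
#' @param frame a `reference_frame`.
#' @param coords n x 3 matrix or length-3 vector in frame coordinates.
#' @return world coordinates, same shape.
#' @export
world_coords <- function(frame, coords) {
  one <- is.null(dim(coords))
  p <- if (one) matrix(coords, ncol = 3) else as.matrix(coords)
  out <- sweep(p %*% frame$axes, 2, frame$origin, "+")
  if (one) drop(out) else out
}

# ---- planes -----------------------------------------------------------------

#' Oriented plane
#'
#' A plane is stored as a unit normal and scalar offset; a point p lies on
#' the plane when `dot(normal, p) == offset`.
#'
#' @param normal length-3 normal vector (normalised internally).
#' @param point a point on the plane (used to set the offset), or `NULL` if
#'   `offset` is given directly.
#' @param offset scalar offset in mm (ignored when `point` is given).
#' @param name optional tag (e.g. "FH", "MSP", "ICP").
#' @return object of class `plane`.
#' @export
plane <- function(normal, point = NULL, offset = NULL, name = NULL) {
  normal <- normalize3(as.numeric(normal))
  if (!is.null(point)) offset <- sum(normal * as.numeric(point))
  if (is.null(offset)) stop("plane needs a point or an offset")
  structure(list(normal = normal, offset = as.numeric(offset), name = name),
            class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf(
    "<plane%s> normal (%.4f, %.4f, %.4f), offset %.3f mm\n",
    if (is.null(x$name)) "" else paste0(" ", x$name),
    x$normal[1], x$normal[2], x$normal[3], x$offset
  ))
  invisible(x)
}

#' Signed distance from a plane
#'
#' Positive on the side the normal points to.
#'
#' @param plane a `plane`.
#' @param p length-3 point or n x 3 matrix.
#' @return signed distance(s) in mm.
#' @export
signed_distance <- function(plane, p) {
  if (is.null(dim(p))) {
    sum(plane$normal * as.numeric(p)) - plane$offset
  } else {
    as.numeric(as.matrix(p) %*% plane$normal) - plane$offset
  }
}

#' Construct the craniofacial reference planes
#'
#' Builds, in world coordinates, the full set of reference planes: FH
#' (through the porions and mid-orbitale), MSP (perpendicular to FH through
#' S and N), CO (coronal through S), OP (occlusal, through U1 and the U6
#' midpoint, containing the lateral axis), and the sided planes MPP and CPP
#' (parasagittal/coronal through the cornea point), LCP (parasagittal
#' through exocanthion), MCP (parasagittal through alare), and ICP (parallel
#' to FH through subnasale).
#'
#' @param frame a `reference_frame` from [build_reference_frame()].
#' @param lm the `landmark_set` the frame was built from.
#' @return object of class `plane_set`: a named list of `plane`s
#'   (`FH`, `MSP`, `CO`, `OP`, `MPP_L`, `MPP_R`, `CPP_L`, `CPP_R`,
#'   `LCP_L`, `LCP_R`, `MCP_L`, `MCP_R`, `ICP`) with the frame and
#'   landmarks attached.
#' @export
construct_planes <- function(frame, lm) {
  x <- frame$axes["x", ]
  y <- frame$axes["y", ]
  z <- frame$axes["z", ]

  u1 <- landmark(lm, "U1")
  u6m <- (landmark(lm, "U6_L") + landmark(lm, "U6_R")) / 2
  d_op <- u1 - u6m
  n_op <- cross3(x, d_op)
  if (sqrt(sum(n_op^2)) < 1e-9) stop("degenerate occlusal plane")

  planes <- list(
    FH  = plane(z, point = landmark(lm, "Po_L"), name = "FH"),
    MSP = plane(x, point = landmark(lm, "S"), name = "MSP"),
    CO  = plane(y, point = landmark(lm, "S"), name = "CO"),
    OP  = plane(n_op, point = u1, name = "OP"),
    MPP_L = plane(x, point = landmark(lm, "C_L"), name = "MPP_L"),
    MPP_R = plane(x, point = landmark(lm, "C_R"), name = "MPP_R"),
    CPP_L = plane(y, point = landmark(lm, "C_L"), name = "CPP_L"),
    CPP_R = plane(y, point = landmark(lm, "C_R"), name = "CPP_R"),
    LCP_L = plane(x, point = landmark(lm, "Ex_L"), name = "LCP_L"),
    LCP_R = plane(x, point = landmark(lm, "Ex_R"), name = "LCP_R"),
    MCP_L = plane(x, point = landmark(lm, "Al_L"), name = "MCP_L"),
    MCP_R = plane(x, point = landmark(lm, "Al_R"), name = "MCP_R"),
    ICP = plane(z, point = landmark(lm, "Sn"), name = "ICP")
  )
  structure(planes, frame = frame, landmarks = lm, class = "plane_set")
}

#' @export
print.plane_set <- function(x, ...) {
  cat(sprintf("<plane_set> %d planes: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Maxillary rotational angle (FH vs occlusal plane)
#'
#' The dihedral angle between the Frankfort horizontal and the occlusal
#' plane, measured as the inclination of the occlusal-plane trace in the
#' midsagittal projection. Reported as a magnitude in \[0, 90\] degrees; the
#' direction of a surgical change is carried by the sign of the post-minus-
#' pre difference (see [rotation_change()]).
#'
#' @param frame a `reference_frame`.
#' @param lm a `landmark_set` with U1, U6_L, U6_R.
#' @return angle in degrees.
#' @export
maxillary_rotation_angle <- function(frame, lm) {
  u1 <- landmark(lm, "U1")
  u6m <- (landmark(lm, "U6_L") + landmark(lm, "U6_R")) / 2
  d <- frame_coords(frame, u1) - frame_coords(frame, u6m)
  if (sqrt(d[2]^2 + d[3]^2) < 1e-9) stop("degenerate occlusal plane")
  unname(atan2(abs(d[3]), abs(d[2])) * 180 / pi)
}
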