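#' Triangulated surface mesh
#'
#' Container for a triangulated surface (facial bone or soft-tissue model)
#' with vertex coordinates in millimetres. Faces index vertices (1-based)
#' and are assumed consistently oriented with outward (anterior-facing for
#' the face) normals.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @return An object of class `surface_mesh` with elements `vertices` and
#'   `faces`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0L) {
    rng <- range(faces)
    if (rng[1] < 1L || rng[2] > nrow(vertices)) {
      stop("face indices out of range")
    }
  }
  if (anyNA(vertices) || any(!is.finite(vertices))) {
    stop("vertices must be finite")
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "<surface_mesh> %d vertices, %d triangles, area %.1f mm^2\n",
    nrow(x$vertices), nrow(x$faces), mesh_area(x)
  ))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

#' Per-triangle areas of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @return numeric vector of triangle areas in mm^2.
#' @export
triangle_areas <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  if (nrow(F) == 0L) return(numeric(0))
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

#' Per-triangle unit normals (right-hand rule on vertex order)
#' @param mesh a `surface_mesh`.
#' @return m x 3 matrix of unit normals.
#' @export
triangle_normals <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  n <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# ---- rigid transforms -------------------------------------------------------

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation vector in mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf(
    "<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
    ang, x$translation[1], x$translation[2], x$translation[3]
  ))
  invisible(x)
}

#' Apply a rigid transform to points, meshes or landmark sets
#'
#' @param x an n x 3 matrix of points, a `surface_mesh`, or a `landmark_set`.
#' @param transform a `rigid_transform`.
#' @return the transformed object of the same type.
#' @export
apply_transform <- function(x, transform) {
  UseMethod("apply_transform")
}

#' @export
apply_transform.default <- function(x, transform) {
  p <- x
  one <- is.null(dim(p))
  if (one) p <- matrix(p, ncol = 3)
  out <- p %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, "+")
  if (one) out <- drop(out)
  out
}

#' @export
apply_transform.surface_mesh <- function(x, transform) {
  x$vertices <- apply_transform.default(x$vertices, transform)
  x
}

#' Compose two rigid transforms (first `a`, then `b`)
#' @param a,b `rigid_transform` objects.
#' @return the composed `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(
    rotation = b$rotation %*% a$rotation,
    translation = as.numeric(b$rotation %*% a$translation) + b$translation
  )
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(rotation = Rt, translation = as.numeric(-Rt %*% transform$translation))
}

#' Rotation about an arbitrary axis (Rodrigues)
#'
#' @param axis length-3 direction vector (need not be unit).
#' @param angle_deg rotation angle in degrees (right-hand rule about `axis`).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
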