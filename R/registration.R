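#' Least-squares rigid alignment of paired points (Kabsch)
#'
#' Finds the rotation and translation minimising the sum of squared
#' distances between `transform(P)` and `Q`.
#'
#' @param P,Q n x 3 matrices of corresponding points.
#' @return a [rigid_transform()].
#' @export
kabsch_transform <- function(P, Q) {
  P <- as.matrix(P)
  Q <- as.matrix(Q)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L, ncol(Q) == 3L, nrow(P) >= 3L)
  pc <- colMeans(P)
  qc <- colMeans(Q)
  H <- crossprod(sweep(P, 2, pc), sweep(Q, 2, qc))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(rotation = R, translation = as.numeric(qc - R %*% pc))
}

#' Landmark-based rough alignment for superimposition
#'
#' Procrustes (Kabsch) fit of the non-operated landmarks - porion,
#' orbitale, nasion and exocanthion - used to initialise the best-fit
#' surface registration deterministically.
#'
#' @param lm_moving,lm_fixed `landmark_set`s for the moving (post-op) and
#'   fixed (pre-op) models.
#' @param names landmarks used for the fit.
#' @return a [rigid_transform()] mapping moving into fixed space.
#' @export
landmark_init <- function(lm_moving, lm_fixed,
                          names = c("Po_L", "Po_R", "Or_L", "Or_R",
                                    "N", "Ex_L", "Ex_R")) {
  P <- t(vapply(names, function(nm) landmark(lm_moving, nm), numeric(3)))
  Q <- t(vapply(names, function(nm) landmark(lm_fixed, nm), numeric(3)))
  kabsch_transform(P, Q)
}

#' Registration mask over non-operated regions
#'
#' Selects the vertices used for best-fit superimposition and its RMS
#' check: vertices at or superior to the Frankfort horizontal plane, plus
#' vertices within `margin` mm of nasion or either exocanthion that are not
#' inferior to FH. Restricting the landmark balls to at/above FH keeps the
#' mask clear of the mobilised maxillary segment.
#'
#' @param mesh a [surface_mesh()].
#' @param planes a `plane_set` for the same model (supplies FH and its
#'   superior orientation).
#' @param lm the model's `landmark_set`.
#' @param margin radius in mm around N/Ex (default 15).
#' @return logical vector over mesh vertices.
#' @export
registration_mask <- function(mesh, planes, lm, margin = 15) {
  frame <- attr(planes, "frame")
  sd_fh <- signed_distance(planes$FH, mesh$vertices)
  # FH normal is the frame z axis, superior-positive by construction;
  # strictly superior keeps the mask clear of the mobilised segment, whose
  # superior boundary is the FH plane itself
  above <- sd_fh > 1e-6
  near <- rep(FALSE, nrow(mesh$vertices))
  for (nm in c("N", "Ex_L", "Ex_R")) {
    p <- landmark(lm, nm)
    d2 <- rowSums(sweep(mesh$vertices, 2, p)^2)
    near <- near | (d2 <= margin^2)
  }
  above | (near & sd_fh > 1e-6)
}

#' Rigid best-fit (ICP) superimposition over a masked region
#'
#' Iterative closest point with point-to-nearest-surface-point
#' correspondences, restricted to the masked vertices of the moving mesh.
#' The alignment is initialised with `init` (typically [landmark_init()])
#' so the whole procedure is deterministic. Iterations stop when the RMS
#' improvement falls below `tol_mm` or after `max_iter` iterations.
#'
#' @param moving,fixed `surface_mesh` objects (post-op and pre-op models).
#' @param mask logical vector or integer indices over `moving`'s vertices
#'   selecting the non-operated fitting region.
#' @param init optional initial [rigid_transform()].
#' @param max_iter iteration cap (default 100).
#' @param tol_mm RMS improvement threshold in mm (default 1e-4).
#' @param sample maximum number of mask vertices used (evenly thinned,
#'   deterministic; default 1000).
#' @return object of class `registration_result`: `transform`,
#'   `rms_deviation` (mm, over the mask after alignment),
#'   `n_correspondences`, `iterations`, `converged`.
#' @export
rigid_icp <- function(moving, fixed, mask, init = NULL,
                      max_iter = 100, tol_mm = 1e-4, sample = 1000) {
  if (n_faces(moving) == 0L || n_faces(fixed) == 0L) {
    stop("registration requires non-empty meshes")
  }
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(idx) == 0L) stop("empty registration mask")
  if (length(idx) < 100L) {
    warning("registration mask selects fewer than 100 vertices")
  }
  if (length(idx) > sample) {
    idx <- idx[round(seq(1, length(idx), length.out = sample))]
  }
  P <- moving$vertices[idx, , drop = FALSE]
  trans <- if (is.null(init)) rigid_transform() else init

  rms_prev <- Inf
  converged <- FALSE
  iter <- 0L
  rms <- NA_real_
  while (iter < max_iter) {
    iter <- iter + 1L
    Pt <- apply_transform(P, trans)
    cp <- cpp_closest_points(Pt, fixed$vertices, fixed$faces)
    rms <- sqrt(mean(cp$distance^2))
    if (is.finite(rms_prev) && (rms_prev - rms) < tol_mm) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
    trans <- kabsch_transform(P, cp$point)
  }
  # final RMS under the returned transform
  Pt <- apply_transform(P, trans)
  cp <- cpp_closest_points(Pt, fixed$vertices, fixed$faces)
  rms <- sqrt(mean(cp$distance^2))

  structure(list(
    transform = trans,
    rms_deviation = rms,
    n_correspondences = length(idx),
    iterations = iter,
    converged = converged
  ), class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> RMS %.4f mm over %d points, %d iterations%s\n",
    x$rms_deviation, x$n_correspondences, x$iterations,
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' RMS deviation between two surfaces over a region
#'
#' Root-mean-square of the distances from the masked vertices of `a` to the
#' nearest point on the surface of `b`.
#'
#' @param a,b `surface_mesh` objects.
#' @param mask logical vector or indices over `a`'s vertices; `NULL` uses
#'   all vertices.
#' @return RMS deviation in mm.
#' @export
rms_deviation <- function(a, b, mask = NULL) {
  idx <- if (is.null(mask)) seq_len(n_vertices(a))
         else if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(idx) == 0L) stop("empty region for RMS deviation")
  cp <- cpp_closest_points(a$vertices[idx, , drop = FALSE],
                           b$vertices, b$faces)
  sqrt(mean(cp$distance^2))
}

#' Registration quality gate
#'
#' A superimposition is certified when its RMS deviation does not exceed
#' the threshold (0.5 mm by default, boundary inclusive).
#'
#' @param result a `registration_result`, or a bare RMS value in mm.
#' @param threshold certification threshold in mm (default 0.5).
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
qc_registration <- function(result, threshold = 0.5) {
  rms <- if (inherits(result, "registration_result")) result$rms_deviation
         else as.numeric(result)
  isTRUE(rms <= threshold)
}
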