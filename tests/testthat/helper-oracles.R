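# Independent oracles, implemented separately from the package's own code
# paths.

# Closest point on one triangle via plane projection + edge clamping.
oracle_closest_on_triangle <- function(p, a, b, c) {
  n <- pracma_cross(b - a, c - a)
  n <- n / sqrt(sum(n^2))
  q <- p - sum((p - a) * n) * n
  # barycentric test of the projection
  e1 <- b - a
  e2 <- c - a
  M <- cbind(e1, e2)
  uv <- solve(crossprod(M), crossprod(M, q - a))
  if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1) return(q)
  seg <- function(p, u, v) {
    t <- sum((p - u) * (v - u)) / sum((v - u)^2)
    t <- min(1, max(0, t))
    u + t * (v - u)
  }
  cand <- rbind(seg(p, a, b), seg(p, b, c), seg(p, c, a))
  cand[which.min(rowSums(sweep(cand, 2, p)^2)), ]
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Exhaustive nearest-point search over all triangles of a mesh.
oracle_closest_on_mesh <- function(p, mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  best <- Inf
  bestq <- NULL
  for (t in seq_len(nrow(F))) {
    q <- oracle_closest_on_triangle(p, V[F[t, 1], ], V[F[t, 2], ], V[F[t, 3], ])
    d <- sum((p - q)^2)
    if (d < best) {
      best <- d
      bestq <- q
    }
  }
  list(distance = sqrt(best), point = bestq)
}

# Rasterise a mesh as an anterior height field over given cell centres
# (pure R; brute-force over triangles).
oracle_raster_height <- function(mesh, xs, zs) {
  V <- mesh$vertices
  F <- mesh$faces
  H <- matrix(NA_real_, length(xs), length(zs))
  for (t in seq_len(nrow(F))) {
    tri <- V[F[t, ], , drop = FALSE]
    ix <- which(xs >= min(tri[, 1]) - 1e-9 & xs <= max(tri[, 1]) + 1e-9)
    iz <- which(zs >= min(tri[, 3]) - 1e-9 & zs <= max(tri[, 3]) + 1e-9)
    if (!length(ix) || !length(iz)) next
    det <- (tri[2, 1] - tri[1, 1]) * (tri[3, 3] - tri[1, 3]) -
           (tri[3, 1] - tri[1, 1]) * (tri[2, 3] - tri[1, 3])
    if (abs(det) < 1e-12) next
    for (i in ix) {
      for (j in iz) {
        px <- xs[i] - tri[1, 1]
        pz <- zs[j] - tri[1, 3]
        l1 <- (px * (tri[3, 3] - tri[1, 3]) - pz * (tri[3, 1] - tri[1, 1])) / det
        l2 <- (pz * (tri[2, 1] - tri[1, 1]) - px * (tri[2, 3] - tri[1, 3])) / det
        if (l1 >= -1e-9 && l2 >= -1e-9 && l1 + l2 <= 1 + 1e-9) {
          y <- (1 - l1 - l2) * tri[1, 2] + l1 * tri[2, 2] + l2 * tri[3, 2]
          if (is.na(H[i, j]) || y > H[i, j]) H[i, j] <- y
        }
      }
    }
  }
  H
}

# Voxel-counting oracle for the volume between two surfaces over the
# footprint of `pre_mesh`: counts voxel centres lying between the surfaces
# in each column (boolean difference of the two solids).
oracle_voxel_delta_volume <- function(pre_mesh, post_mesh, h = 0.2) {
  xr <- range(pre_mesh$vertices[, 1])
  zr <- range(pre_mesh$vertices[, 3])
  nx <- max(1L, round(diff(xr) / h))
  nz <- max(1L, round(diff(zr) / h))
  xs <- xr[1] + (seq_len(nx) - 0.5) * diff(xr) / nx
  zs <- zr[1] + (seq_len(nz) - 0.5) * diff(zr) / nz
  cell <- (diff(xr) / nx) * (diff(zr) / nz)
  Hpre <- oracle_raster_height(pre_mesh, xs, zs)
  Hpost <- oracle_raster_height(post_mesh, xs, zs)
  ok <- !is.na(Hpre) & !is.na(Hpost)
  # signed voxel layers between the surfaces
  k_pre <- floor(Hpre[ok] / h)
  k_post <- floor(Hpost[ok] / h)
  sum(k_post - k_pre) * h * cell
}

# Welch two-sample t-test from summary statistics, textbook formulas.
oracle_welch <- function(m1, s1, n1, m2, s2, n2) {
  se2 <- s1^2 / n1 + s2^2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# ICC(2,1) mean squares via stats::aov on the long-format table.
oracle_icc_aov <- function(ratings) {
  df <- data.frame(
    y = as.numeric(ratings),
    target = factor(rep(seq_len(nrow(ratings)), ncol(ratings))),
    rater = factor(rep(seq_len(ncol(ratings)), each = nrow(ratings)))
  )
  ms <- summary(stats::aov(y ~ target + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(ratings); k <- ncol(ratings)
  list(
    msr = msr, msc = msc, mse = mse,
    icc = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  )
}
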