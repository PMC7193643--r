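# analytic meshes and transforms used as independent geometric oracles

# subdivided icosahedron on a sphere of radius r (optionally per-axis radii)
icosphere <- function(level = 3, radius = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lv in seq_len(level)) {
    mid <- new.env(parent = emptyenv())
    nv <- nrow(v)
    getmid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      id <- get0(k, mid)
      if (!is.null(id)) return(id)
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      nv <<- nv + 1L
      assign(k, nv, mid)
      nv
    }
    f2 <- matrix(0L, 4 * nrow(f), 3)
    for (j in seq_len(nrow(f))) {
      a <- f[j, 1]; b <- f[j, 2]; c <- f[j, 3]
      ab <- getmid(a, b); bc <- getmid(b, c); ca <- getmid(c, a)
      f2[4 * j - 3:0, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                 c(c, ca, bc), c(ab, bc, ca))
    }
    f <- f2
  }
  v <- v / sqrt(rowSums(v^2))
  if (length(radius) == 1) radius <- rep(radius, 3)
  surface_mesh(sweep(v, 2, radius, "*"), f)
}

# rectangular z = z0 plane mesh spanning [0, nx*h] x [0, ny*h]
plane_mesh <- function(z0, nx = 10, ny = 10, h = 1) {
  g <- expand.grid(x = 0:nx * h, y = 0:ny * h)
  v <- cbind(g$x, g$y, z0)
  id <- function(i, j) i + 1L + (nx + 1L) * j
  f <- matrix(0L, 0, 3)
  for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    f <- rbind(f,
               c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
               c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  surface_mesh(v, f)
}

# random proper rotation with angle <= max_deg, translation <= max_mm
random_rigid <- function(max_mm = 5, max_deg = 10) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0.2, 1) * max_deg * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  tr <- rnorm(3); tr <- tr / sqrt(sum(tr^2)) * runif(1, 0.2, 1) * max_mm
  rigid_transform(R, tr)
}

rotation_angle_deg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

# deviation of a transform from the identity over a set of points
transform_deviation <- function(tf, points) {
  max(sqrt(rowSums((transform_points(tf, points) - points)^2)))
}
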