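#' Rigid transform
#'
#' A proper rigid motion `x -> R x + t` with `R` a 3x3 rotation
#' (orthonormal, determinant +1) and `t` a translation in mm.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop_ts("rotation must be 3x3 and translation length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop_ts("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat("<rigid_transform> rotation ", signif(ang, 4), " deg, translation (",
      paste(signif(x$translation, 4), collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

#' @rdname rigid_transform
#' @param a,b Transforms; `compose_transforms(a, b)` applies `b` first.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_transform
#' @param tf A `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation),
                  -as.numeric(t(tf$rotation) %*% tf$translation))
}

#' @rdname rigid_transform
#' @export
transform_points <- function(tf, points) {
  points <- as.matrix(points)
  sweep(points %*% t(tf$rotation), 2, tf$translation, "+")
}

#' Apply a rigid transform to a mesh
#'
#' Vertices are mapped rigidly; faces and scalars are unchanged.
#'
#' @param mesh A [surface_mesh()].
#' @param tf A [rigid_transform()].
#' @return The transformed [surface_mesh()].
#' @export
apply_transform <- function(mesh, tf) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(tf, "rigid_transform"))
  surface_mesh(transform_points(tf, mesh$vertices), mesh$faces, mesh$scalars)
}

rotation_about <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3),
         y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3),
         z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3))
}

# rotation from a small-angle axis vector (Rodrigues)
rotation_from_omega <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-300) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' ICP settings
#'
#' Defaults mirror the registration configuration used throughout the
#' package's analysis: 100% estimated mesh overlap, point-to-plane
#' matching, exact nearest-neighbour correspondence search, 100% point
#' sampling, and a fixed 50 iterations with no early exit (set
#' `convergence_tol` to enable one).
#'
#' @param overlap_fraction Assumed shared fraction of the meshes; the
#'   `(1 - overlap)` worst-matching points are discarded each iteration.
#' @param matching `"point_to_plane"` or `"point_to_point"`.
#' @param nn_search Correspondence search; only `"exact"` is provided.
#' @param sampling_fraction Fraction of moving vertices used (deterministic
#'   stride subsampling).
#' @param iterations Number of ICP iterations.
#' @param convergence_tol Optional early-exit tolerance on the parameter
#'   update norm; `NULL` (default) runs all iterations.
#' @return An object of class `icp_settings`.
#' @export
icp_settings <- function(overlap_fraction = 1,
                         matching = c("point_to_plane", "point_to_point"),
                         nn_search = "exact",
                         sampling_fraction = 1,
                         iterations = 50L,
                         convergence_tol = NULL) {
  matching <- match.arg(matching)
  if (!identical(nn_search, "exact"))
    stop_ts("only exact nearest-neighbour search is supported")
  if (overlap_fraction <= 0 || overlap_fraction > 1)
    stop_ts("`overlap_fraction` must be in (0, 1]")
  if (sampling_fraction <= 0 || sampling_fraction > 1)
    stop_ts("`sampling_fraction` must be in (0, 1]")
  structure(list(overlap_fraction = overlap_fraction, matching = matching,
                 nn_search = nn_search,
                 sampling_fraction = sampling_fraction,
                 iterations = as.integer(iterations),
                 convergence_tol = convergence_tol),
            class = "icp_settings")
}

#' Best-fit superimposition by iterative closest point
#'
#' Registers `moving` onto `reference` with rigid ICP. Each iteration
#' matches every sampled moving vertex to its exact closest point on the
#' reference surface (point-to-triangle, BVH-accelerated) and minimises
#' the point-to-plane objective `sum(((R p + t - q) . n_q)^2)` (normal
#' taken from the matched triangle) through its small-angle linearisation;
#' the incremental motion is re-orthonormalised via Rodrigues' formula, so
#' the accumulated transform is exactly rigid. With
#' `matching = "point_to_point"` the full point distance is minimised
#' instead (closed-form Kabsch update).
#'
#' @param moving,reference [surface_mesh()] objects.
#' @param settings An [icp_settings()].
#' @param index Optional precomputed [mesh_index()] of `reference`.
#' @return A [rigid_transform()] mapping `moving` onto `reference`, with
#'   the per-iteration root-mean-square objective in
#'   `attr(, "objective_trace")` and the settings in `attr(, "settings")`.
#' @export
icp_register <- function(moving, reference, settings = icp_settings(),
                         index = NULL) {
  stopifnot(inherits(moving, "surface_mesh"),
            inherits(reference, "surface_mesh"))
  if (is.null(index)) index <- mesh_index(reference)
  refN <- face_normals(reference)
  # degenerate reference: all normals parallel leaves in-plane translation
  # (and in-plane rotation) unconstrained
  if (nrow(refN) > 1) {
    sv <- svd(crossprod(refN))$d
    if (sv[2] / sv[1] < 1e-10)
      warning("all reference normals are parallel: translation within the ",
              "plane is unidentifiable", call. = FALSE)
  }
  P0 <- moving$vertices
  if (settings$sampling_fraction < 1) {
    stride <- max(1L, round(1 / settings$sampling_fraction))
    P0 <- P0[seq(1L, nrow(P0), by = stride), , drop = FALSE]
  }
  centre <- mesh_centroid(reference)
  tf <- rigid_transform()
  trace <- numeric(0)
  for (it in seq_len(settings$iterations)) {
    P <- transform_points(tf, P0)
    cp <- .cpp_bvh_query(index, P)
    use <- seq_len(nrow(P))
    if (settings$overlap_fraction < 1) {
      k <- max(6L, floor(settings$overlap_fraction * nrow(P)))
      use <- order(cp$distance)[seq_len(k)]
    }
    Pc <- sweep(P[use, , drop = FALSE], 2, centre)
    Q <- cp$point[use, , drop = FALSE]
    Qc <- sweep(Q, 2, centre)
    if (settings$matching == "point_to_plane") {
      N <- refN[cp$triangle[use], , drop = FALSE]
      r <- rowSums((Pc - Qc) * N)
      trace <- c(trace, sqrt(mean(r^2)))
      cxn <- cbind(Pc[, 2] * N[, 3] - Pc[, 3] * N[, 2],
                   Pc[, 3] * N[, 1] - Pc[, 1] * N[, 3],
                   Pc[, 1] * N[, 2] - Pc[, 2] * N[, 1])
      A <- cbind(cxn, N)
      AtA <- crossprod(A)
      Atb <- crossprod(A, -r)
      x <- tryCatch(solve(AtA, Atb), error = function(e) {
        s <- svd(AtA)
        keep <- s$d > 1e-10 * s$d[1]
        s$v[, keep, drop = FALSE] %*%
          ((t(s$u[, keep, drop = FALSE]) %*% Atb) / s$d[keep])
      })
      dR <- rotation_from_omega(x[1:3])
      dt <- x[4:6]
    } else {
      trace <- c(trace, sqrt(mean(rowSums((Pc - Qc)^2))))
      mp <- colMeans(Pc); mq <- colMeans(Qc)
      H <- crossprod(sweep(Pc, 2, mp), sweep(Qc, 2, mq))
      s <- svd(H)
      D <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
      dR <- s$v %*% D %*% t(s$u)
      dt <- mq - as.numeric(dR %*% mp)
    }
    # incremental motion about `centre`: x -> dR (x - centre) + centre + dt
    inc <- rigid_transform(dR, centre + dt - as.numeric(dR %*% centre))
    tf <- compose_transforms(inc, tf)
    if (!is.null(settings$convergence_tol)) {
      upd <- sqrt(sum(dt^2)) + sqrt(sum((dR - diag(3))^2))
      if (upd < settings$convergence_tol) break
    }
  }
  attr(tf, "objective_trace") <- trace
  attr(tf, "settings") <- settings
  attr(tf, "centre") <- centre
  tf
}

#' Decompose a rigid transform into six movement components
#'
#' Reports the transform as three translations (mm) and three rotations
#' (degrees) about a reference point, in the anatomical frame used
#' throughout: x lateral (positive right), y anteroposterior (positive
#' posterior), z vertical (positive up). Rotations are intrinsic
#' x -> y -> z Euler angles (`R = Rx Ry Rz`); translations are the
#' displacement of `centre`. At gimbal lock (`|ry| = 90` degrees) the x/z
#' split is resolved by the convention `rz = 0`, with a warning.
#'
#' @param tf A [rigid_transform()].
#' @param centre Rotation centre (mm); defaults to the centre stored by
#'   [icp_register()] (the reference-mesh centroid), else the origin.
#' @return A one-row tibble with `tx, ty, tz` (mm) and `rx, ry, rz`
#'   (degrees), the centre kept in `attr(, "centre")`.
#' @export
decompose_transform <- function(tf, centre = NULL) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (is.null(centre)) centre <- attr(tf, "centre")
  if (is.null(centre)) centre <- c(0, 0, 0)
  centre <- as.numeric(centre)
  R <- tf$rotation
  tcomp <- as.numeric(R %*% centre) + tf$translation - centre
  # R = Rx(rx) Ry(ry) Rz(rz):
  #   R[1,3] = sin(ry); R[2,3] = -sin(rx) cos(ry); R[3,3] = cos(rx) cos(ry)
  #   R[1,2] = -cos(ry) sin(rz); R[1,1] = cos(ry) cos(rz)
  if (abs(R[1, 3]) >= 1 - 1e-12) {
    warning("gimbal lock (|ry| = 90 deg): rz set to 0 by convention",
            call. = FALSE)
    ry <- sign(R[1, 3]) * pi / 2
    rz <- 0
    rx <- atan2(R[2, 1] * sign(R[1, 3]), R[2, 2])
  } else {
    ry <- asin(R[1, 3])
    rx <- atan2(-R[2, 3], R[3, 3])
    rz <- atan2(-R[1, 2], R[1, 1])
  }
  out <- tibble::tibble(tx = tcomp[1], ty = tcomp[2], tz = tcomp[3],
                        rx = rx * 180 / pi, ry = ry * 180 / pi,
                        rz = rz * 180 / pi)
  attr(out, "centre") <- centre
  out
}

#' Rebuild a rigid transform from movement components
#'
#' Inverse of [decompose_transform()]: `x -> R (x - centre) + centre + t`
#' with `R = Rx(rx) Ry(ry) Rz(rz)`.
#'
#' @param components One-row data frame with `tx, ty, tz, rx, ry, rz`.
#' @param centre Rotation centre (mm); defaults to the one stored on
#'   `components`.
#' @return A [rigid_transform()].
#' @export
recompose_components <- function(components, centre = NULL) {
  if (is.null(centre)) centre <- attr(components, "centre")
  if (is.null(centre)) centre <- c(0, 0, 0)
  R <- rotation_about("x", components$rx) %*%
    rotation_about("y", components$ry) %*%
    rotation_about("z", components$rz)
  t_ <- c(components$tx, components$ty, components$tz)
  rigid_transform(R, centre + t_ - as.numeric(R %*% centre))
}
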