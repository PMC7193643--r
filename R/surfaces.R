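#' Triangle surface mesh
#'
#' Vertices are world-mm coordinates (rows of an `n x 3` matrix), faces are
#' 1-based vertex-index triples (`m x 3` integer matrix). Optional
#' per-vertex scalars (e.g. distances for colour maps) ride along in
#' `scalars`.
#'
#' @param vertices `n x 3` numeric matrix.
#' @param faces `m x 3` integer matrix of 1-based vertex indices.
#' @param scalars Optional numeric vector of length `n`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, scalars = NULL) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L || !is.numeric(vertices))
    stop_ts("`vertices` must be an n x 3 numeric matrix")
  if (any(!is.finite(vertices))) stop_ts("vertex coordinates must be finite")
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (nrow(faces) < 1L) stop_ts("mesh must have at least one face")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop_ts("face indices out of range")
  if (!is.null(scalars)) {
    scalars <- as.numeric(scalars)
    if (length(scalars) != nrow(vertices))
      stop_ts("`scalars` must have one value per vertex")
  }
  dimnames(vertices) <- NULL
  structure(list(vertices = vertices, faces = faces, scalars = scalars),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces", if (!is.null(x$scalars)) ", per-vertex scalars", "\n",
      sep = "")
  invisible(x)
}

face_areas <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - a
  e2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

face_normals <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - a
  e2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

mesh_centroid <- function(mesh) colMeans(mesh$vertices)

# drop degenerate faces (zero area or repeated indices) and unreferenced
# vertices, preserving vertex order
clean_mesh <- function(vertices, faces, scalars = NULL) {
  dup <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
    faces[, 2] == faces[, 3]
  faces <- faces[!dup, , drop = FALSE]
  m <- list(vertices = vertices, faces = faces)
  faces <- faces[face_areas(m) > 0, , drop = FALSE]
  keep <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(vertices))
  remap[keep] <- seq_along(keep)
  surface_mesh(vertices[keep, , drop = FALSE],
               matrix(remap[faces], ncol = 3L),
               scalars = if (!is.null(scalars)) scalars[keep])
}

#' Extract an isosurface from a volume
#'
#' Marching-tetrahedra isosurfacing (a topology-consistent marching-cubes
#' variant on the Kuhn 6-tetrahedra cell subdivision). Surface vertices are
#' placed by linear interpolation along cell edges whose endpoint samples
#' bracket `iso`, then mapped to world mm via the volume's spacing and
#' origin. Degenerate (zero-area) faces are removed.
#'
#' @param vol A [voxel_volume()].
#' @param iso Iso-intensity; must lie strictly between the volume's
#'   minimum and maximum.
#' @return A [surface_mesh()]; the iso value and variant name are stored in
#'   `attr(, "provenance")`.
#' @export
extract_isosurface <- function(vol, iso) {
  stopifnot(inherits(vol, "voxel_volume"))
  iso <- assert_scalar_num(iso, "iso")
  rng <- range(vol$data)
  if (iso <= rng[1] || iso >= rng[2])
    stop_ts("iso value ", iso, " is outside the volume's intensity range [",
            signif(rng[1], 6), ", ", signif(rng[2], 6),
            "]; no isosurface exists")
  raw <- .cpp_marching_tets(vol$data, iso, vol$spacing, vol$origin)
  if (nrow(raw$faces) == 0L) stop_ts("isosurface at ", iso, " is empty")
  mesh <- clean_mesh(raw$vertices, raw$faces)
  attr(mesh, "provenance") <- list(
    iso = iso, variant = "marching tetrahedra (Kuhn subdivision)")
  mesh
}

#' Axis-aligned region of interest
#'
#' @param min_corner,max_corner Opposite box corners in world mm;
#'   `-Inf`/`Inf` components make the box a half-space.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(min_corner, max_corner) {
  min_corner <- as.numeric(min_corner)
  max_corner <- as.numeric(max_corner)
  if (length(min_corner) != 3L || length(max_corner) != 3L)
    stop_ts("box corners must be length-3 (mm)")
  if (any(!(max_corner > min_corner)))
    stop_ts("ROI box must have positive extent on all axes")
  structure(list(min = min_corner, max = max_corner), class = "roi_box")
}

mesh_components <- function(mesh) {
  # connected components over shared vertices (union-find with path halving)
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (col in 2:3) {
    a <- mesh$faces[, 1]
    b <- mesh$faces[, col]
    for (i in seq_along(a)) {
      ra <- find(a[i])
      rb <- find(b[i])
      if (ra != rb) parent[ra] <- rb
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Crop a mesh to a region of interest
#'
#' Keeps faces whose three vertices all lie inside the ROI (a deterministic
#' all-vertices-in rule), reindexes vertices, and optionally keeps only the
#' largest connected component of the result.
#'
#' @param mesh A [surface_mesh()].
#' @param roi A [roi_box()], or a logical per-vertex selection mask.
#' @param keep_largest Keep only the largest connected component.
#' @return The cropped [surface_mesh()].
#' @export
crop_mesh <- function(mesh, roi, keep_largest = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (inherits(roi, "roi_box")) {
    v <- mesh$vertices
    inside <- v[, 1] >= roi$min[1] & v[, 1] <= roi$max[1] &
      v[, 2] >= roi$min[2] & v[, 2] <= roi$max[2] &
      v[, 3] >= roi$min[3] & v[, 3] <= roi$max[3]
  } else if (is.logical(roi) && length(roi) == nrow(mesh$vertices)) {
    inside <- roi
  } else {
    stop_ts("`roi` must be an roi_box or a per-vertex logical mask")
  }
  keep_face <- inside[mesh$faces[, 1]] & inside[mesh$faces[, 2]] &
    inside[mesh$faces[, 3]]
  if (!any(keep_face))
    stop_ts("ROI does not overlap the mesh: empty crop")
  out <- clean_mesh(mesh$vertices, mesh$faces[keep_face, , drop = FALSE],
                    mesh$scalars)
  if (keep_largest) {
    comp <- mesh_components(out)
    sizes <- table(comp)
    big <- as.integer(names(sizes)[which.max(sizes)])
    vkeep <- comp == big
    fkeep <- vkeep[out$faces[, 1]]
    out <- clean_mesh(out$vertices, out$faces[fkeep, , drop = FALSE],
                      out$scalars)
  }
  out
}
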