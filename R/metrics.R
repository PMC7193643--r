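#' Spatial index for closest-point queries
#'
#' Builds the bounding-volume hierarchy over a mesh's triangles once, so
#' repeated exact closest-point queries (MAD, ICP iterations) against the
#' same reference mesh skip the construction cost.
#'
#' @param mesh A [surface_mesh()].
#' @return An opaque index handle tied to this R session.
#' @export
mesh_index <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  .cpp_bvh_build(mesh$vertices, mesh$faces)
}

#' Mean absolute distance between meshes
#'
#' For every vertex of `moving`, the Euclidean distance to the exact
#' closest point on the `reference` surface (triangle interior, edge or
#' vertex — not nearest-vertex), and their mean, the MAD. The metric is
#' directed: `mean_absolute_distance(a, b)` and
#' `mean_absolute_distance(b, a)` differ in general; the analysis pipeline
#' always measures threshold model -> reference.
#'
#' @param moving,reference [surface_mesh()] objects.
#' @param index Optional precomputed spatial index of `reference` from
#'   [mesh_index()], reused across repeated queries against the same mesh.
#' @return An object of class `distance_pair`: list with `per_vertex`
#'   (mm, one per moving vertex), `mad` (their mean, mm), `n_vertices`
#'   and `direction`.
#' @export
mean_absolute_distance <- function(moving, reference, index = NULL) {
  stopifnot(inherits(moving, "surface_mesh"),
            inherits(reference, "surface_mesh"))
  if (is.null(index)) index <- mesh_index(reference)
  cp <- .cpp_bvh_query(index, moving$vertices)
  structure(list(per_vertex = cp$distance, mad = mean(cp$distance),
                 n_vertices = nrow(moving$vertices),
                 direction = "moving_to_reference"),
            class = "distance_pair")
}

#' @export
print.distance_pair <- function(x, ...) {
  cat("<distance_pair> MAD ", signif(x$mad, 6), " mm over ", x$n_vertices,
      " vertices (", x$direction, ")\n", sep = "")
  invisible(x)
}

#' @rdname mean_absolute_distance
#' @param x A `distance_pair`.
#' @param ... Unused.
#' @export
tidy.distance_pair <- function(x, ...) {
  tibble::tibble(mad_mm = x$mad, n_vertices = x$n_vertices,
                 min_mm = min(x$per_vertex), max_mm = max(x$per_vertex),
                 direction = x$direction)
}

#' Attach per-vertex distances to a mesh as a colour map
#'
#' Stores the distances of a [mean_absolute_distance()] result as
#' per-vertex scalars on the moving mesh (values are kept as-is, not
#' rescaled), ready to be written to PLY for colour-mapped rendering.
#'
#' @param pair A `distance_pair`.
#' @param mesh The moving [surface_mesh()] the distances refer to.
#' @return `mesh` with `scalars` set and the colour range recorded in
#'   `attr(, "colour_range")`.
#' @export
distance_colour_map <- function(pair, mesh) {
  stopifnot(inherits(pair, "distance_pair"), inherits(mesh, "surface_mesh"))
  if (length(pair$per_vertex) != nrow(mesh$vertices))
    stop_ts("distance count (", length(pair$per_vertex),
            ") does not match the mesh vertex count (", nrow(mesh$vertices),
            ")")
  out <- surface_mesh(mesh$vertices, mesh$faces, scalars = pair$per_vertex)
  attr(out, "colour_range") <- range(pair$per_vertex)
  out
}
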