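neighbour_offsets <- function(connectivity) {
  if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
          c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26) {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
  } else {
    stop_ts("`connectivity` must be 6 or 26")
  }
}

interface_mask <- function(mask, connectivity) {
  d <- dim(mask)
  out <- array(FALSE, d)
  offs <- neighbour_offsets(connectivity)
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
    sx <- ix[ix + off[1] >= 1 & ix + off[1] <= d[1]]
    sy <- iy[iy + off[2] >= 1 & iy + off[2] <= d[2]]
    sz <- iz[iz + off[3] >= 1 & iz + off[3] <= d[3]]
    differs <- mask[sx, sy, sz, drop = FALSE] !=
      mask[sx + off[1], sy + off[2], sz + off[3], drop = FALSE]
    out[sx, sy, sz] <- out[sx, sy, sz, drop = FALSE] | differs
  }
  out
}

#' Interface-voxel intensities
#'
#' Given a volume and a binary label mask (structure vs surround), returns
#' the intensities of every voxel — from both classes — that has at least
#' one neighbour, under the chosen connectivity, in the opposite class.
#' Voxels completely surrounded by their own class are excluded;
#' out-of-grid neighbours are ignored. Because interface voxels straddle
#' the bone / soft-tissue boundary, partial-volume averaging gives them
#' intermediate intensities.
#'
#' @param vol A [voxel_volume()] (typically rescaled to 0-1000).
#' @param mask Logical 3D array congruent with `vol`; `TRUE` marks the
#'   structure of interest.
#' @param connectivity 6 (face neighbours, default) or 26 (face, edge and
#'   corner neighbours).
#' @return Numeric vector of interface-voxel intensities.
#' @export
interface_voxels <- function(vol, mask, connectivity = 6) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!is.array(mask) || !identical(dim(mask), dim(vol$data)))
    stop_ts("`mask` must be an array with the same shape as the volume")
  mask <- array(as.logical(mask), dim(mask))
  if (anyNA(mask)) stop_ts("`mask` must not contain NA")
  if (!any(mask) || all(mask))
    stop_ts("both classes of the label mask must be non-empty")
  vol$data[interface_mask(mask, connectivity)]
}

#' Reference threshold from interface voxels
#'
#' The arithmetic mean intensity of the interface voxels: the single
#' segmentation threshold that the partial-volume effect places midway
#' between the two materials.
#'
#' @inheritParams interface_voxels
#' @return Reference threshold (scalar intensity).
#' @export
reference_threshold <- function(vol, mask, connectivity = 6) {
  mean(interface_voxels(vol, mask, connectivity))
}

#' Threshold family around a reference value
#'
#' The reference threshold plus `n_each_side` offsets of `step` intensity
#' units on either side — by default the seven values
#' reference + \{-60, -40, -20, 0, +20, +40, +60\}.
#'
#' @param reference Reference threshold on the 0-1000 scale.
#' @param step Offset spacing in intensity units (default 20).
#' @param n_each_side Number of offsets on each side (default 3).
#' @return An object of class `threshold_set` with elements `reference`,
#'   `offsets` (signed, including 0) and `values`.
#' @export
threshold_set <- function(reference, step = 20, n_each_side = 3) {
  reference <- assert_scalar_num(reference, "reference")
  if (step < 0) stop_ts("`step` must be >= 0")
  offsets <- step * seq(-n_each_side, n_each_side)
  values <- reference + offsets
  bad <- values < 0 | values > 1000
  if (any(bad))
    stop_ts("threshold values leave the 0-1000 scale at offset(s) ",
            paste(offsets[bad], collapse = ", "))
  structure(list(reference = reference, step = step,
                 offsets = offsets, values = values),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set> reference ", signif(x$reference, 6), ", values ",
      paste(signif(x$values, 6), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @rdname threshold_set
#' @param x A `threshold_set`.
#' @param ... Unused.
#' @export
as_tibble.threshold_set <- function(x, ...) {
  tibble::tibble(offset = x$offsets, value = x$values)
}
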