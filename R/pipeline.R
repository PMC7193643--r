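default_phantom_roi <- function(truth) {
  # upper part of the outer dome: analogous to selecting the upper surface
  # of the anterior cranial fossa floor on the reference model
  zcut <- truth$centre[3] + 0.45 * truth$radius[3]
  roi_box(c(-Inf, -Inf, zcut), c(Inf, Inf, Inf))
}

sweep_one_volume <- function(vol, mask, id, mode, connectivity, step,
                             n_each_side, icp, roi, keep_largest) {
  ref <- reference_threshold(vol, mask, connectivity)
  ts <- threshold_set(ref, step, n_each_side)
  meshes <- purrr::map(ts$values, function(iso) {
    m <- extract_isosurface(vol, iso)
    if (!is.null(roi)) m <- crop_mesh(m, roi, keep_largest = keep_largest)
    m
  })
  iref <- n_each_side + 1L  # the reference threshold's position
  ref_mesh <- meshes[[iref]]
  ref_index <- mesh_index(ref_mesh)
  centre <- mesh_centroid(ref_mesh)
  rows <- list()
  for (j in seq_along(ts$offsets)) {
    if (j == iref) next
    moving <- meshes[[j]]
    before <- mean_absolute_distance(moving, ref_mesh, index = ref_index)
    tf <- icp_register(moving, ref_mesh, icp, index = ref_index)
    after <- mean_absolute_distance(apply_transform(moving, tf), ref_mesh,
                                    index = ref_index)
    comps <- decompose_transform(tf, centre)
    base <- tibble::tibble(volume_id = id, mode = mode,
                           threshold_offset = ts$offsets[j],
                           reference_threshold = ref,
                           n_vertices = nrow(moving$vertices))
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      base, tibble::tibble(status = "before", mad_mm = before$mad,
                           tx = NA_real_, ty = NA_real_, tz = NA_real_,
                           rx = NA_real_, ry = NA_real_, rz = NA_real_))
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      base, tibble::tibble(status = "after", mad_mm = after$mad), comps)
  }
  dplyr::bind_rows(rows)
}

#' Run the threshold sweep experiment
#'
#' For each input volume: estimate the interface-voxel reference
#' threshold, build the threshold family, extract the surface model at
#' every threshold, crop to the region of interest, and compare each
#' offset model with the reference model three ways — MAD in the original
#' position, the rigid movement required for best-fit ICP superimposition,
#' and MAD after superimposition.
#'
#' @param entries A list whose elements are either [phantom_spec()]s
#'   (volume, truth mask and default ROI are generated) or lists with
#'   elements `volume` (a [voxel_volume()]), `mask` (structure label
#'   array), `id`, `mode` and optionally `roi`.
#' @param connectivity Neighbourhood for interface voxels (6 or 26).
#' @param step,n_each_side Threshold family layout (see [threshold_set()]).
#' @param icp [icp_settings()] for the superimposition.
#' @param roi Default [roi_box()] for non-phantom entries (`NULL` = no
#'   crop); phantom entries derive their ROI from the truth geometry.
#' @param keep_largest Keep only the largest component after cropping.
#' @param on_error `"skip"` logs a warning and drops the failing volume;
#'   `"stop"` aborts.
#' @return A tibble of sweep records: `volume_id`, `mode`,
#'   `threshold_offset`, `status` (before/after), `mad_mm`, and the six
#'   movement components `tx, ty, tz` (mm) / `rx, ry, rz` (degrees) on the
#'   "after" rows (12 rows per volume with the default family).
#' @export
run_threshold_sweep <- function(entries, connectivity = 6, step = 20,
                                n_each_side = 3, icp = icp_settings(),
                                roi = NULL, keep_largest = TRUE,
                                on_error = c("skip", "stop")) {
  on_error <- match.arg(on_error)
  if (inherits(entries, "phantom_spec") ||
      (is.list(entries) && !is.null(entries$volume)))
    entries <- list(entries)
  out <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    run <- function() {
      if (inherits(e, "phantom_spec")) {
        ph <- generate_phantom(e)
        id <- sprintf("phantom_seed%03d", e$seed)
        sweep_one_volume(ph$volume, ph$truth$mask, id,
                         mode = attr(e, "mode") %||% e$geometry,
                         connectivity, step, n_each_side, icp,
                         roi = default_phantom_roi(ph$truth),
                         keep_largest = keep_largest)
      } else {
        sweep_one_volume(e$volume, e$mask, e$id %||% paste0("volume", i),
                         e$mode %||% "scan", connectivity, step,
                         n_each_side, icp, roi = e$roi %||% roi,
                         keep_largest = keep_largest)
      }
    }
    if (on_error == "stop") {
      out[[i]] <- run()
    } else {
      out[[i]] <- tryCatch(run(), error = function(err) {
        warning("volume ", i, " skipped: ", conditionMessage(err),
                call. = FALSE)
        NULL
      })
    }
  }
  rec <- dplyr::bind_rows(out)
  class(rec) <- c("threshsurf_sweep", class(rec))
  rec
}

#' Phantom threshold-sweep study
#'
#' Generates `n_per_mode` seeded phantoms for each acquisition-mode preset
#' and runs the full threshold sweep on each, mirroring a multi-group,
#' multi-scan study with ground-truth segmentation masks.
#'
#' @param modes Preset names (see [phantom_preset()]).
#' @param n_per_mode Phantoms per mode.
#' @param seed Master seed; per-phantom seeds are drawn from it.
#' @param ... Passed on to [run_threshold_sweep()].
#' @return Sweep-record tibble with one `volume_id` per phantom.
#' @export
phantom_study <- function(modes = c("ct", "cbct_regular", "cbct_low"),
                          n_per_mode = 10, seed = 1, ...) {
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L,
                      length(modes) * n_per_mode)
  entries <- list()
  idx <- 1L
  for (m in modes) {
    for (i in seq_len(n_per_mode)) {
      sp <- phantom_preset(m, seed = seeds[idx])
      attr(sp, "mode") <- m
      entries[[idx]] <- sp
      idx <- idx + 1L
    }
  }
  run_threshold_sweep(entries, ...)
}

#' Summarise sweep records
#'
#' Median, minimum and maximum MAD per (mode, threshold offset,
#' superimposition status) — the numbers behind the box plots.
#'
#' @param records Sweep-record tibble from [run_threshold_sweep()].
#' @return Tibble with one row per (mode, offset, status).
#' @export
summarize_sweep <- function(records) {
  if (nrow(records) == 0L) stop_ts("no sweep records to summarise")
  dplyr::summarise(
    dplyr::group_by(records, .data$mode, .data$threshold_offset,
                    .data$status),
    n = dplyr::n(),
    mad_median = stats::median(.data$mad_mm),
    mad_min = min(.data$mad_mm),
    mad_max = max(.data$mad_mm),
    .groups = "drop")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
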