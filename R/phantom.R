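#' Phantom specification
#'
#' Describes a synthetic two-material (bone / soft tissue) phantom on the
#' 0-1000 intensity scale. The binary geometry is blurred with a Gaussian
#' of width `edge_sigma` (mm) to emulate the partial-volume effect,
#' optionally multiplied by a smooth bias field (the CBCT positional
#' intensity dependence), and corrupted with additive Gaussian noise.
#'
#' Geometries: a solid sphere (radius `radius`, optionally a length-3
#' vector for an ellipsoid), or a hemispherical shell — the region between
#' two concentric (ellipsoidal) surfaces of radii `radius` and
#' `radius - thickness`, kept on the upper (`z >= centre`) side. The shell
#' emulates the bowl of the anterior cranial fossa; ellipsoidal radii break
#' rotational symmetry, as real anatomy does, so rigid registration is
#' well-posed.
#'
#' @param geometry `"solid_sphere"` or `"hemispherical_shell"`.
#' @param radius Outer radius in mm; length 1 or 3 (ellipsoid semi-axes).
#' @param thickness Shell thickness in mm (shell geometry only).
#' @param spacing Voxel size in mm (scalar or length 3).
#' @param grid_shape Voxels per axis; `NULL` sizes the grid to the geometry
#'   plus a margin of `3 * edge_sigma + 2` mm per side.
#' @param intensity_soft,intensity_bone Material levels on the 0-1000
#'   scale; `intensity_soft < intensity_bone` is required.
#' @param edge_sigma Partial-volume Gaussian blur, mm (standard deviation).
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units).
#' @param bias_amplitude Relative amplitude `a` of the multiplicative bias
#'   field; the field is bounded in `[1 - a, 1 + a]`. `0` disables it.
#' @param bias_scale Bias field correlation length in mm.
#' @param seed Integer seed; all randomness (noise, bias) flows from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = c("hemispherical_shell", "solid_sphere"),
                         radius = 10, thickness = 2, spacing = 0.4,
                         grid_shape = NULL,
                         intensity_soft = 300, intensity_bone = 700,
                         edge_sigma = 0.6, noise_sd = 0,
                         bias_amplitude = 0, bias_scale = 30, seed = 1L) {
  geometry <- match.arg(geometry)
  if (length(radius) == 1L) radius <- rep(radius, 3L)
  if (length(radius) != 3L || any(radius <= 0))
    stop_ts("`radius` must be 1 or 3 positive semi-axes (mm)")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (intensity_soft >= intensity_bone)
    stop_ts("`intensity_soft` must be below `intensity_bone`")
  if (edge_sigma < 0 || noise_sd < 0)
    stop_ts("`edge_sigma` and `noise_sd` must be >= 0")
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stop_ts("`bias_amplitude` must be in [0, 1)")
  if (geometry == "hemispherical_shell" &&
      (thickness <= 0 || thickness >= min(radius)))
    stop_ts("shell `thickness` must be in (0, min(radius))")
  structure(list(geometry = geometry, radius = as.numeric(radius),
                 thickness = as.numeric(thickness),
                 spacing = as.numeric(spacing),
                 grid_shape = grid_shape,
                 intensity_soft = as.numeric(intensity_soft),
                 intensity_bone = as.numeric(intensity_bone),
                 edge_sigma = as.numeric(edge_sigma),
                 noise_sd = as.numeric(noise_sd),
                 bias_amplitude = as.numeric(bias_amplitude),
                 bias_scale = as.numeric(bias_scale),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Acquisition-mode presets
#'
#' Phantom parameters emulating the three image classes studied: high
#' quality CT (0.5 mm voxels, low noise, no bias field), regular-quality
#' CBCT (0.3 mm voxels, moderate noise, mild bias field) and low-quality
#' CBCT (0.3 mm voxels, highest noise and bias). Partial-volume blur grows
#' with voxel size (1.5 x spacing), so the CT preset has the widest bone
#' edge, which is what drives its larger threshold sensitivity.
#'
#' @param mode `"ct"`, `"cbct_low"` or `"cbct_regular"`.
#' @param seed Seed stored in the returned spec.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(mode = c("ct", "cbct_low", "cbct_regular"),
                           seed = 1L) {
  mode <- match.arg(mode)
  sp <- switch(mode, ct = 0.5, cbct_low = 0.3, cbct_regular = 0.3)
  phantom_spec(geometry = "hemispherical_shell",
               radius = c(12, 10, 8), thickness = 2,
               spacing = sp, edge_sigma = 1.5 * sp,
               noise_sd = switch(mode, ct = 10, cbct_low = 40,
                                 cbct_regular = 25),
               bias_amplitude = switch(mode, ct = 0, cbct_low = 0.10,
                                       cbct_regular = 0.05),
               bias_scale = 30, seed = seed)
}

phantom_grid <- function(spec) {
  margin <- 3 * spec$edge_sigma + 2
  if (is.null(spec$grid_shape)) {
    extent <- 2 * (spec$radius + margin)
    shape <- pmax(8L, as.integer(ceiling(extent / spec$spacing)) + 1L)
  } else {
    shape <- as.integer(spec$grid_shape)
    if (length(shape) == 1L) shape <- rep(shape, 3L)
    extent_needed <- 2 * (spec$radius + 3 * spec$edge_sigma)
    if (any((shape - 1L) * spec$spacing < extent_needed))
      stop_ts("geometry (plus 3*edge_sigma margin) exceeds the grid")
  }
  centre <- (shape - 1) / 2 * spec$spacing
  list(shape = shape, centre = centre)
}

phantom_mask <- function(spec, grid) {
  ax <- lapply(1:3, function(a) (seq_len(grid$shape[a]) - 1) * spec$spacing[a])
  u2 <- lapply(1:3, function(a) ((ax[[a]] - grid$centre[a]) / spec$radius[a])^2)
  s_outer <- outer(outer(u2[[1]], u2[[2]], "+"), u2[[3]], "+")
  if (spec$geometry == "solid_sphere") return(s_outer <= 1)
  r_in <- spec$radius - spec$thickness
  v2 <- lapply(1:3, function(a) ((ax[[a]] - grid$centre[a]) / r_in[a])^2)
  s_inner <- outer(outer(v2[[1]], v2[[2]], "+"), v2[[3]], "+")
  upper <- outer(outer(rep(TRUE, grid$shape[1]), rep(TRUE, grid$shape[2]),
                       "&"),
                 ax[[3]] >= grid$centre[3], "&")
  s_outer <= 1 & s_inner > 1 & upper
}

phantom_bias_field <- function(spec, grid) {
  # smooth multiplicative field: heavily blurred white noise, max-normalised
  # so it is exactly bounded in [1 - a, 1 + a]
  g <- array(rnorm(prod(grid$shape)), dim = grid$shape)
  g <- .cpp_gaussian_blur(g, spec$bias_scale / spec$spacing)
  m <- max(abs(g))
  if (m == 0) return(array(1, dim = grid$shape))
  1 + spec$bias_amplitude * g / m
}

#' Generate a synthetic phantom volume with ground truth
#'
#' Builds the binary geometry on the voxel grid, maps it to
#' `[intensity_soft, intensity_bone]`, applies the partial-volume blur,
#' multiplies by the bias field (if enabled) and adds noise. Identical
#' spec + seed give a bit-identical volume.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` (a [voxel_volume()] on the 0-1000 scale)
#'   and `truth` — the analytic parameters (`centre`, `radius`,
#'   `thickness`, `geometry`), the pre-blur binary `mask`, and
#'   `boundary_intensity = (intensity_soft + intensity_bone) / 2`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- phantom_grid(spec)
  mask <- phantom_mask(spec, grid)
  img <- array(spec$intensity_soft, dim = grid$shape)
  img[mask] <- spec$intensity_bone
  if (spec$edge_sigma > 0)
    img <- .cpp_gaussian_blur(img, spec$edge_sigma / spec$spacing)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  if (spec$bias_amplitude > 0)
    img <- img * phantom_bias_field(spec, grid)
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(prod(grid$shape), sd = spec$noise_sd),
                       dim = grid$shape)
  vol <- voxel_volume(img, spec$spacing, origin = c(0, 0, 0))
  truth <- list(centre = grid$centre, radius = spec$radius,
                thickness = if (spec$geometry == "hemispherical_shell")
                  spec$thickness else NA_real_,
                geometry = spec$geometry, mask = mask,
                boundary_intensity =
                  (spec$intensity_soft + spec$intensity_bone) / 2)
  list(volume = vol, truth = truth, spec = spec)
}
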