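#' Voxel volume
#'
#' Container for a 3D scalar intensity grid with physical voxel spacing.
#' World coordinates use 0-based voxel indices: the centre of voxel
#' `(i, j, k)` (0-based) sits at `origin + c(i, j, k) * spacing` (mm).
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param spacing Voxel edge lengths in mm; length 1 (isotropic) or 3.
#' @param origin World position (mm) of the centre of voxel (0,0,0).
#' @return An object of class `voxel_volume` with elements `data`,
#'   `spacing`, `origin`.
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.numeric(data))
    stop_ts("`data` must be a 3D numeric array")
  if (any(dim(data) < 2L))
    stop_ts("volume must have at least 2 voxels per axis")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_ts("`spacing` must be 3 positive voxel edge lengths (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop_ts("`origin` must be a finite length-3 position (mm)")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm\n", sep = "")
  cat("  intensity range [", signif(min(x$data), 6), ", ",
      signif(max(x$data), 6), "]", sep = "")
  w <- attr(x, "window")
  if (!is.null(w))
    cat(", rescaled from window [", w$low, ", ", w$high, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Intensity window
#'
#' The grayscale range of interest of a scan: `low` at the soft-tissue end,
#' `high` at the hard-tissue end. Used to rescale volumes (and thresholds)
#' onto a common 0-1000 scale.
#'
#' @param low,high Window bounds in the volume's native intensity units;
#'   `low < high` is required.
#' @return An object of class `intensity_window`.
#' @export
intensity_window <- function(low, high) {
  low <- assert_scalar_num(low, "low")
  high <- assert_scalar_num(high, "high")
  if (low >= high)
    stop_ts("degenerate intensity window: `low` must be < `high`")
  structure(list(low = low, high = high), class = "intensity_window")
}

#' Rescale a volume onto the 0-1000 scale
#'
#' Applies the affine map `1000 * (v - low) / (high - low)` to every voxel.
#' Intensities outside the window are clamped to 0 or 1000 (and the number
#' of clamped voxels reported); the mapping is monotone and affine on
#' `[low, high]`.
#'
#' @param vol A [voxel_volume()].
#' @param window An [intensity_window()].
#' @return A `voxel_volume` (additional class `rescaled_volume`) whose
#'   intensities lie in `[0, 1000]`, with the window stored in
#'   `attr(, "window")`.
#' @export
rescale_volume <- function(vol, window) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!inherits(window, "intensity_window"))
    window <- do.call(intensity_window, as.list(window))
  v <- 1000 * (vol$data - window$low) / (window$high - window$low)
  n_clamped <- sum(v < 0 | v > 1000)
  if (n_clamped > 0)
    message(n_clamped, " voxel(s) outside the intensity window were clamped")
  v[v < 0] <- 0
  v[v > 1000] <- 1000
  out <- voxel_volume(v, vol$spacing, vol$origin)
  attr(out, "window") <- window
  class(out) <- c("rescaled_volume", class(out))
  out
}

#' Rescale a scalar threshold onto the 0-1000 scale
#'
#' Same affine map as [rescale_volume()], applied to a single intensity, so
#' thresholds estimated on native intensities commute with volume rescaling.
#' Values outside the window are clamped with a warning.
#'
#' @param threshold Intensity in native units.
#' @inheritParams rescale_volume
#' @return Threshold on the 0-1000 scale.
#' @export
rescale_threshold <- function(threshold, window) {
  threshold <- assert_scalar_num(threshold, "threshold")
  if (!inherits(window, "intensity_window"))
    window <- do.call(intensity_window, as.list(window))
  t2 <- 1000 * (threshold - window$low) / (window$high - window$low)
  if (t2 < 0 || t2 > 1000) {
    warning("threshold ", threshold, " lies outside the intensity window; ",
            "clamped to the 0-1000 scale", call. = FALSE)
    t2 <- min(max(t2, 0), 1000)
  }
  t2
}

#' Read a radiographic volume
#'
#' Reads a NIfTI file or a DICOM series directory into a [voxel_volume()].
#' For DICOM, the rescale slope/intercept are applied so intensities are on
#' the stored physical scale, slices are sorted by position, and
#' non-uniform slice spacing beyond 1% is an error.
#'
#' @param path A `.nii`/`.nii.gz` file or a directory of single-frame DICOM
#'   files.
#' @param format `"auto"` (directory implies DICOM), `"nifti"` or `"dicom"`.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom" else "nifti"
  if (format == "dicom") return(read_dicom_series(path))
  if (!file.exists(path)) stop_ts("file not found: ", path)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  voxel_volume(array(as.numeric(img), dim = dim(img)), spacing, origin)
}

#' Write a volume as NIfTI
#'
#' Data and spacing round-trip bit-exactly through [read_volume()].
#'
#' @param vol A [voxel_volume()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  a <- vol$data
  attr(a, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(a, datatype = "double")
  xf <- diag(c(vol$spacing, 1))
  xf[1:3, 4] <- vol$origin
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  # NIfTI-2: double-precision header geometry, so spacing and origin
  # round-trip exactly
  RNifti::writeNifti(img, path, version = 2)
  invisible(path)
}
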