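# minimal explicit-VR little-endian DICOM writer for fixtures built at test
# time: enough structure for a single-frame axial CT slice

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                   endian = "little")

dcm_element <- function(group, element, vr, value) {
  if (vr %in% c("DS", "UI", "CS", "LO")) {
    value <- charToRaw(value)
    pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
    if (length(value) %% 2 == 1) value <- c(value, pad)
  } else if (vr == "US") {
    value <- dcm_uint16(value)
  } else if (vr == "OW") {
    stopifnot(is.raw(value))
  }
  header <- c(dcm_uint16(group), dcm_uint16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW")) {
    header <- c(header, as.raw(c(0, 0)),
                writeBin(length(value), raw(), size = 4, endian = "little"))
  } else {
    header <- c(header, dcm_uint16(length(value)))
  }
  c(header, value)
}

# pixels: integer matrix [x (columns), y (rows)] of stored values
write_test_dicom <- function(path, pixels, position, spacing_xy = c(0.5, 0.5),
                             slope = 1, intercept = 0) {
  stored <- as.integer(pixels)
  body <- c(
    dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_element(0x0020, 0x0032, "DS",
                paste(sprintf("%g", position), collapse = "\\")),
    dcm_element(0x0028, 0x0010, "US", ncol(pixels)),   # rows (y)
    dcm_element(0x0028, 0x0011, "US", nrow(pixels)),   # columns (x)
    dcm_element(0x0028, 0x0030, "DS",
                sprintf("%g\\%g", spacing_xy[2], spacing_xy[1])),
    dcm_element(0x0028, 0x0100, "US", 16),
    dcm_element(0x0028, 0x0103, "US", 1),
    dcm_element(0x0028, 0x1052, "DS", sprintf("%g", intercept)),
    dcm_element(0x0028, 0x1053, "DS", sprintf("%g", slope)),
    dcm_element(0x7FE0, 0x0010, "OW",
                writeBin(stored, raw(), size = 2, endian = "little")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(body, con)
}

write_test_dicom_series <- function(dir, volume, spacing = c(0.5, 0.5, 0.5),
                                    slope = 1, intercept = 0,
                                    z_positions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(volume)[3]
  if (is.null(z_positions)) z_positions <- (seq_len(nz) - 1) * spacing[3]
  for (k in seq_len(nz)) {
    write_test_dicom(file.path(dir, sprintf("slice%03d.dcm", k)),
                     volume[, , k], position = c(0, 0, z_positions[k]),
                     spacing_xy = spacing[1:2], slope = slope,
                     intercept = intercept)
  }
  dir
}
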