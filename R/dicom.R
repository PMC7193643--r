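# Minimal single-frame DICOM series reader (explicit/implicit VR, little
# endian, uncompressed). Covers the tags needed to assemble an axial scan
# volume: grid shape, pixel spacing, slice positions, rescale slope and
# intercept, and the raw pixel data. Compressed transfer syntaxes and
# multi-frame objects are rejected with a clear error.

DICOM_LONG_VRS <- c("OB", "OW", "OF", "OD", "SQ", "UT", "UN")

read_dicom_element <- function(raw, pos, explicit) {
  grp <- readBin(raw[pos + 0:1], "integer", size = 2, signed = FALSE,
                 endian = "little")
  el <- readBin(raw[pos + 2:3], "integer", size = 2, signed = FALSE,
                endian = "little")
  if (explicit && grp != 0xFFFE) {
    vr <- rawToChar(raw[pos + 4:5])
    if (vr %in% DICOM_LONG_VRS) {
      len <- readBin(raw[pos + 8:11], "integer", size = 4, endian = "little")
      hdr <- 12L
    } else {
      len <- readBin(raw[pos + 6:7], "integer", size = 2, signed = FALSE,
                     endian = "little")
      hdr <- 8L
    }
  } else {
    vr <- NA_character_
    len <- readBin(raw[pos + 4:7], "integer", size = 4, endian = "little")
    hdr <- 8L
  }
  if (is.na(len) || len < 0)
    stop_ts("DICOM element (", sprintf("%04x,%04x", grp, el),
            ") has undefined length; sequences are not supported")
  list(group = grp, element = el, vr = vr, length = len,
       value_at = pos + hdr, next_at = pos + hdr + len)
}

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  explicit <- TRUE
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") {
    pos <- 133L
  }
  tags <- list()
  transfer <- "1.2.840.10008.1.2.1"
  while (pos + 7 <= length(raw)) {
    e <- read_dicom_element(raw, pos, explicit)
    key <- sprintf("%04x,%04x", e$group, e$element)
    val <- raw[e$value_at + seq_len(e$length) - 1L]
    if (key == "0002,0010")
      transfer <- trimws(rawToChar(val[val != as.raw(0)]))
    if (e$group != 0x0002 && transfer == "1.2.840.10008.1.2") explicit <- FALSE
    tags[[key]] <- list(vr = e$vr, value = val)
    pos <- e$next_at
    if (key == "7fe0,0010") break
  }
  if (!transfer %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    stop_ts("unsupported DICOM transfer syntax in ", basename(path),
            ": ", transfer)
  tags
}

dicom_str <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NA_character_)
  trimws(rawToChar(t$value[t$value != as.raw(0)]))
}

dicom_num <- function(tags, key, default = NA_real_) {
  s <- dicom_str(tags, key)
  if (is.na(s) || !nzchar(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_us <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NA_integer_)
  readBin(t$value, "integer", size = 2, signed = FALSE, endian = "little")
}

read_dicom_slice <- function(path) {
  tags <- parse_dicom_file(path)
  rows <- dicom_us(tags, "0028,0010")
  cols <- dicom_us(tags, "0028,0011")
  bits <- dicom_us(tags, "0028,0100")
  signed <- identical(dicom_us(tags, "0028,0103"), 1L)
  px <- tags[["7fe0,0010"]]
  if (is.na(rows) || is.na(cols) || is.null(px))
    stop_ts("DICOM slice ", basename(path), " lacks pixel data or dimensions")
  if (!bits %in% c(8L, 16L))
    stop_ts("unsupported BitsAllocated (", bits, ") in ", basename(path))
  n <- as.integer(rows) * as.integer(cols)
  vals <- readBin(px$value, "integer", n = n, size = bits / 8L,
                  signed = if (bits == 8L) FALSE else signed,
                  endian = "little")
  if (bits == 16L && !signed) vals <- ifelse(vals < 0, vals + 65536, vals)
  slope <- dicom_num(tags, "0028,1053", 1)[1]
  icept <- dicom_num(tags, "0028,1052", 0)[1]
  ps <- dicom_num(tags, "0028,0030")        # row spacing \ column spacing
  ipp <- dicom_num(tags, "0020,0032")       # image position (patient)
  list(pixels = matrix(slope * vals + icept, nrow = cols, ncol = rows),
       rows = rows, cols = cols,
       spacing_xy = c(ps[2], ps[1]), position = ipp, file = basename(path))
}

read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) stop_ts("directory not found: ", dir)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2L)
    stop_ts("DICOM series in ", dir, " has fewer than 2 slices")
  slices <- lapply(files, read_dicom_slice)
  shapes <- vapply(slices, function(s) c(s$cols, s$rows), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    bad <- which(shapes[1, ] != shapes[1, 1] | shapes[2, ] != shapes[2, 1])[1]
    stop_ts("inconsistent slice dimensions at ", slices[[bad]]$file)
  }
  z <- vapply(slices, function(s) s$position[3], numeric(1))
  if (anyNA(z)) stop_ts("missing ImagePositionPatient in series ", dir)
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  dz <- diff(z)
  if (any(dz <= 0)) stop_ts("duplicate slice positions in series ", dir)
  if ((max(dz) - min(dz)) / mean(dz) > 0.01) {
    bad <- which.max(abs(dz - mean(dz)))
    stop_ts("non-uniform slice spacing (beyond 1%) between ",
            slices[[bad]]$file, " and ", slices[[bad + 1L]]$file,
            ": ", signif(dz[bad], 4), " vs mean ", signif(mean(dz), 4), " mm")
  }
  sxy <- slices[[1]]$spacing_xy
  if (anyNA(sxy)) stop_ts("missing PixelSpacing in series ", dir)
  data <- array(0, c(slices[[1]]$cols, slices[[1]]$rows, length(slices)))
  for (k in seq_along(slices)) data[, , k] <- slices[[k]]$pixels
  origin <- slices[[1]]$position
  if (anyNA(origin)) origin <- c(0, 0, z[1])
  voxel_volume(data, c(sxy, mean(dz)), origin)
}
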