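#' Read a multi-page OPD stack with its metadata sidecar
#'
#' The stack is a multi-page 32-bit float TIFF, one page per timepoint,
#' pixel values = optical path difference in µm. Acquisition metadata lives
#' in a JSON or YAML sidecar next to the stack (same basename, extension
#' `.json`, `.yaml` or `.yml`) with keys `pixel_size_um`,
#' `frame_interval_min` and optionally `refractive_increment_um3_per_pg`
#' (default 0.18).
#'
#' @param path path to the TIFF stack
#' @param sidecar optional explicit path to the metadata file
#' @return list with `frames` (list of [PhaseFrame-class], timestamps at
#'   multiples of the frame interval) and `calibration` ([Calibration-class])
#' @export
readOPDStack <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("OPD stack not found: ", path)
  cal <- readCalibrationSidecar(path, sidecar)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(seq_along(pages), function(k) {
    m <- pages[[k]]
    if (length(dim(m)) == 3) m <- m[, , 1] # tolerate greyscale-with-channels
    phaseFrame(m, timestamp = (k - 1) * frameInterval(cal))
  })
  list(frames = frames, calibration = cal)
}

readCalibrationSidecar <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) {
    stem <- tools::file_path_sans_ext(path)
    cand <- paste0(stem, c(".json", ".yaml", ".yml"))
    sidecar <- cand[file.exists(cand)][1]
    if (is.na(sidecar))
      stop("no metadata sidecar found next to ", path,
           " (expected ", paste(basename(cand), collapse = " or "), ")")
  }
  meta <- if (grepl("\\.json$", sidecar)) jsonlite::read_json(sidecar)
          else yaml::read_yaml(sidecar)
  for (key in c("pixel_size_um", "frame_interval_min"))
    if (is.null(meta[[key]]))
      stop("metadata sidecar ", sidecar, " is missing required key '", key, "'")
  alpha <- meta[["refractive_increment_um3_per_pg"]]
  if (is.null(alpha)) alpha <- 0.18
  Calibration(pixelSize = meta$pixel_size_um,
              frameInterval = meta$frame_interval_min,
              refractiveIncrement = alpha)
}

#' Read a binary region mask (TIFF or PNG)
#'
#' Any nonzero pixel counts as inside the region.
#'
#' @param path path to a single-page TIFF or PNG
#' @param label region label ("cell", "nucleus", "cytoplasm")
#' @return a [CellMask-class]
#' @export
readMask <- function(path, label = "cell") {
  if (!file.exists(path)) stop("mask file not found: ", path)
  m <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG masks requires the 'png' package")
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(m)) == 3) m <- m[, , 1]
  cellMask(m != 0, label)
}

#' Write matrices as an uncompressed 32-bit float multi-page TIFF
#'
#' Installed TIFF writers for R only store integer sample formats, which
#' cannot represent negative rates or densities above 1; growth maps and
#' mass stacks need true floats. This writer emits a minimal baseline TIFF
#' (little-endian, one strip per page, SampleFormat = IEEE float) readable
#' by `tiff::readTIFF`, ImageJ/Fiji and tifffile.
#'
#' @param frames a matrix or list of matrices (pages)
#' @param path output path
#' @return `path`, invisibly
#' @export
writeFloatTIFF <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) { u16(tag); u16(type); u32(count); u32(value) }
  nTags <- 9L
  ifdSize <- 2L + nTags * 12L + 4L
  dataBytes <- vapply(frames, function(m) 4L * length(m), integer(1))
  dataOff <- 8L + c(0L, cumsum(dataBytes))[seq_along(frames)]
  ifd0 <- 8L + sum(dataBytes)
  ifdOff <- ifd0 + (seq_along(frames) - 1L) * ifdSize
  # header
  writeBin(charToRaw("II"), con); u16(42L); u32(ifdOff[1])
  # pixel data: TIFF rows are written row-major
  for (m in frames)
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  # IFDs
  for (k in seq_along(frames)) {
    m <- frames[[k]]
    u16(nTags)
    entry(256L, 3L, 1L, ncol(m))            # ImageWidth
    entry(257L, 3L, 1L, nrow(m))            # ImageLength
    entry(258L, 3L, 1L, 32L)                # BitsPerSample
    entry(259L, 3L, 1L, 1L)                 # Compression = none
    entry(262L, 3L, 1L, 1L)                 # Photometric = BlackIsZero
    entry(273L, 4L, 1L, dataOff[k])         # StripOffsets
    entry(278L, 3L, 1L, nrow(m))            # RowsPerStrip
    entry(279L, 4L, 1L, dataBytes[k])       # StripByteCounts
    entry(339L, 3L, 1L, 3L)                 # SampleFormat = IEEE float
    u32(if (k < length(frames)) ifdOff[k + 1] else 0L)
  }
  invisible(path)
}

#' Write a mass-frame stack as a float TIFF
#' @param frames list of [MassFrame-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeMassStack <- function(frames, path) {
  writeFloatTIFF(lapply(frames, density), path)
}

#' Write a growth map as a float TIFF (undefined pixels = NaN)
#' @param map a [GrowthMap-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeGrowthMapTIFF <- function(map, path) {
  r <- growthRaster(map)
  r[is.na(r)] <- NaN
  writeFloatTIFF(r, path)
}

#' Write a velocity field as CSV
#'
#' Long format: one row per grid node with columns `x_um`, `y_um`,
#' `u_um_per_min`, `v_um_per_min`, `valid`.
#'
#' @param field a [VelocityField-class]
#' @param path output path
#' @return the data.frame written, invisibly
#' @export
writeVelocityCSV <- function(field, path) {
  d <- data.frame(
    x_um = rep(field@gridX, each = length(field@gridY)),
    y_um = rep(field@gridY, times = length(field@gridX)),
    u_um_per_min = as.vector(field@u),
    v_um_per_min = as.vector(field@v),
    valid = as.vector(field@valid))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}

#' Write control-volume tracks as CSV
#'
#' Columns: cv_id, frame, t_min, x0..x3, y0..y3 (µm), mass_pg, in_bounds.
#'
#' @param tracks list of [ControlVolumeTrack-class]
#' @param path output path
#' @return the data.frame written, invisibly
#' @export
writeTracksCSV <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    f <- trackTable(tr)
    cbind(cv_id = cvId(tr), frame = seq_len(nrow(f)) - 1L, f)
  })
  d <- do.call(rbind, rows)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}
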