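#' Physical calibration of a QPI acquisition
#'
#' Holds the metadata needed to convert between pixels, micrometres, minutes
#' and picograms: the pixel size (µm/px), the frame interval (min), and the
#' specific refractive increment alpha (µm³/pg) that converts optical path
#' difference to areal dry-mass density via sigma = OPD / alpha.
#'
#' @slot pixelSize length of one pixel side, µm
#' @slot frameInterval time between consecutive frames, min
#' @slot refractiveIncrement specific refractive increment alpha, µm³/pg
#'   (default 0.18, the standard value for cellular dry matter)
#' @export
setClass("Calibration",
  representation(pixelSize = "numeric",
                 frameInterval = "numeric",
                 refractiveIncrement = "numeric"),
  prototype(refractiveIncrement = 0.18))

setValidity("Calibration", function(object) {
  for (s in c("pixelSize", "frameInterval", "refractiveIncrement")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      return(sprintf("'%s' must be a single strictly positive finite number", s))
  }
  TRUE
})

#' Construct a Calibration
#'
#' @param pixelSize pixel size in µm per pixel
#' @param frameInterval frame interval in min
#' @param refractiveIncrement specific refractive increment in µm³/pg
#' @return a [Calibration-class] object
#' @examples
#' Calibration(pixelSize = 0.25, frameInterval = 1)
#' @export
Calibration <- function(pixelSize, frameInterval, refractiveIncrement = 0.18) {
  new("Calibration", pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval),
      refractiveIncrement = as.numeric(refractiveIncrement))
}

#' @rdname accessors
#' @export
setMethod("pixelSize", "Calibration", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("frameInterval", "Calibration", function(x) x@frameInterval)
#' @rdname accessors
#' @export
setMethod("refractiveIncrement", "Calibration", function(x) x@refractiveIncrement)

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration: %.4g um/px, %.4g min/frame, alpha = %.4g um^3/pg\n",
              object@pixelSize, object@frameInterval, object@refractiveIncrement))
})

#' A single quantitative-phase frame
#'
#' One timepoint of a QPI movie: a 2-D matrix of optical path difference (µm)
#' plus its acquisition timestamp (min). Pixel (r, c) covers the physical
#' square x in [(c-1), c]*pixelSize, y in [(r-1), r]*pixelSize, so its centre
#' is at ((c - 0.5)*pixelSize, (r - 0.5)*pixelSize).
#'
#' @slot opd matrix of optical path difference, µm
#' @slot timestamp acquisition time, min
#' @export
setClass("PhaseFrame",
  representation(opd = "matrix", timestamp = "numeric"))

setValidity("PhaseFrame", function(object) {
  if (!is.numeric(object@opd) || !all(is.finite(object@opd)))
    return("'opd' must be a finite numeric matrix")
  if (length(object@timestamp) != 1 || !is.finite(object@timestamp) ||
      object@timestamp < 0)
    return("'timestamp' must be a single non-negative number (min)")
  TRUE
})

#' Construct a PhaseFrame
#' @param opd matrix of optical path difference in µm
#' @param timestamp acquisition time in min
#' @return a [PhaseFrame-class]
#' @export
phaseFrame <- function(opd, timestamp = 0) {
  new("PhaseFrame", opd = opd, timestamp = as.numeric(timestamp))
}

#' @rdname accessors
#' @export
setMethod("opd", "PhaseFrame", function(x) x@opd)
#' @rdname accessors
#' @export
setMethod("timestamp", "PhaseFrame", function(x) x@timestamp)

setMethod("show", "PhaseFrame", function(object) {
  cat(sprintf("PhaseFrame %dx%d px, t = %.3g min, OPD range [%.3g, %.3g] um\n",
              nrow(object@opd), ncol(object@opd), object@timestamp,
              min(object@opd), max(object@opd)))
})

#' A dry-mass density frame
#'
#' A background-corrected phase frame converted to areal dry-mass density
#' sigma (pg/µm²) through the specific refractive increment. The per-pixel
#' dry mass is sigma * pixelSize².
#'
#' @slot density matrix of areal dry-mass density, pg/µm²
#' @slot timestamp acquisition time, min
#' @slot calibration the [Calibration-class] of the acquisition
#' @export
setClass("MassFrame",
  representation(density = "matrix", timestamp = "numeric",
                 calibration = "Calibration"))

setValidity("MassFrame", function(object) {
  if (!is.numeric(object@density) || !all(is.finite(object@density)))
    return("'density' must be a finite numeric matrix")
  if (length(object@timestamp) != 1 || !is.finite(object@timestamp))
    return("'timestamp' must be a single finite number (min)")
  TRUE
})

#' Construct a MassFrame
#' @param density matrix of areal dry-mass density in pg/µm²
#' @param timestamp acquisition time in min
#' @param calibration a [Calibration-class]
#' @return a [MassFrame-class]
#' @export
massFrame <- function(density, timestamp, calibration) {
  new("MassFrame", density = density, timestamp = as.numeric(timestamp),
      calibration = calibration)
}

#' @rdname accessors
#' @export
setMethod("density", "MassFrame", function(x) x@density)
#' @rdname accessors
#' @export
setMethod("timestamp", "MassFrame", function(x) x@timestamp)
#' @rdname accessors
#' @export
setMethod("calibration", "MassFrame", function(x) x@calibration)

setMethod("show", "MassFrame", function(object) {
  px <- object@calibration@pixelSize
  cat(sprintf(
    "MassFrame %dx%d px (%.3g x %.3g um), t = %.3g min, total %.3g pg\n",
    nrow(object@density), ncol(object@density),
    ncol(object@density) * px, nrow(object@density) * px,
    object@timestamp, sum(object@density) * px^2))
})

#' A labelled binary region mask
#'
#' Marks a region of the image (the whole cell, the nucleus, or the
#' cytoplasm). Must match the frame geometry it is used with. When both a
#' cell and a nucleus mask exist, the cytoplasm is cell AND NOT nucleus
#' (see [cytoplasmMask()]).
#'
#' @slot mask logical matrix, TRUE inside the region
#' @slot label one of "cell", "nucleus", "cytoplasm"
#' @export
setClass("CellMask",
  representation(mask = "matrix", label = "character"))

setValidity("CellMask", function(object) {
  if (!is.logical(object@mask))
    return("'mask' must be a logical matrix")
  if (length(object@label) != 1 ||
      !object@label %in% c("cell", "nucleus", "cytoplasm"))
    return("'label' must be one of 'cell', 'nucleus', 'cytoplasm'")
  TRUE
})

#' Construct a CellMask
#' @param mask logical (or coercible) matrix, TRUE/nonzero inside the region
#' @param label region name: "cell", "nucleus" or "cytoplasm"
#' @return a [CellMask-class]
#' @export
cellMask <- function(mask, label = "cell") {
  m <- matrix(as.logical(mask != 0), nrow(mask), ncol(mask))
  new("CellMask", mask = m, label = label)
}

#' Cytoplasm mask from cell and nucleus masks
#' @param cell a [CellMask-class] labelled "cell"
#' @param nucleus a [CellMask-class] labelled "nucleus"
#' @return a [CellMask-class] labelled "cytoplasm" (cell AND NOT nucleus)
#' @export
cytoplasmMask <- function(cell, nucleus) {
  stopifnot(all(dim(cell@mask) == dim(nucleus@mask)))
  cellMask(cell@mask & !nucleus@mask, "cytoplasm")
}

#' @rdname accessors
#' @export
setMethod("maskMatrix", "CellMask", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("maskLabel", "CellMask", function(x) x@label)

setMethod("show", "CellMask", function(object) {
  cat(sprintf("CellMask '%s': %dx%d px, %d px inside (%.1f%%)\n",
              object@label, nrow(object@mask), ncol(object@mask),
              sum(object@mask), 100 * mean(object@mask)))
})

#' Windowed cross-correlation velocimetry settings
#'
#' @slot windowSize interrogation window side, px (>= 8)
#' @slot windowOverlap fractional overlap between neighbouring windows, [0, 1)
#' @slot searchRadius maximum displacement searched, px
#' @slot minDensity windows whose mean density falls below this (pg/µm²) are
#'   flagged invalid (off-cell windows carry no signal)
#' @slot outlierZmax local-median validation threshold in robust z units
#' @slot peakQualityMin minimum ratio of primary to secondary correlation peak
#' @slot highpassSigma Gaussian sigma (px) of the low-frequency component
#'   subtracted from each frame before correlation; 0 disables. Removes the
#'   smooth cell-envelope signal whose truncation at window edges biases
#'   the correlation peak
#' @slot deformPasses number of window-deformation refinement passes
#'   (warp frame B by the current field, re-correlate the residual);
#'   corrects the gradient bias of single-pass correlation in rotational
#'   or shear flow. 0 disables
#' @export
setClass("PIVConfig",
  representation(windowSize = "numeric", windowOverlap = "numeric",
                 searchRadius = "numeric", minDensity = "numeric",
                 outlierZmax = "numeric", peakQualityMin = "numeric",
                 highpassSigma = "numeric", deformPasses = "numeric"))

setValidity("PIVConfig", function(object) {
  if (object@windowSize < 8) return("'windowSize' must be >= 8 px")
  if (object@windowOverlap < 0 || object@windowOverlap >= 1)
    return("'windowOverlap' must be in [0, 1)")
  if (object@searchRadius < 1) return("'searchRadius' must be >= 1 px")
  if (object@minDensity < 0) return("'minDensity' must be >= 0")
  if (object@outlierZmax <= 0) return("'outlierZmax' must be > 0")
  if (object@peakQualityMin < 1) return("'peakQualityMin' must be >= 1")
  if (object@highpassSigma < 0) return("'highpassSigma' must be >= 0")
  if (object@deformPasses < 0) return("'deformPasses' must be >= 0")
  TRUE
})

#' Construct a PIVConfig
#'
#' Defaults: 32-px windows at 75% overlap give the same 8-px node spacing
#' as 16-px windows at 50%, but with 4x the texture per window, which is
#' what holds the displacement error to the ~0.01-0.02 px the Lagrangian
#' tracking error budget demands at these texture scales; windows remain
#' much larger than the 0.7 µm² control volumes they drive, and an 8-px
#' search accommodates the sub-pixel-per-frame displacements the 1-min
#' acquisition design targets.
#'
#' @param windowSize interrogation window side in px
#' @param windowOverlap fraction of window shared by neighbours
#' @param searchRadius maximum displacement searched in px
#' @param minDensity minimum mean window density in pg/µm²
#' @param outlierZmax robust z threshold for vector validation
#' @param peakQualityMin minimum primary/secondary peak ratio
#' @param highpassSigma Gaussian high-pass sigma in px (0 disables)
#' @param deformPasses window-deformation refinement passes (0 disables)
#' @return a [PIVConfig-class]
#' @export
pivConfig <- function(windowSize = 32, windowOverlap = 0.75, searchRadius = 8,
                      minDensity = 0.05, outlierZmax = 3, peakQualityMin = 1.2,
                      highpassSigma = 4, deformPasses = 1) {
  new("PIVConfig", windowSize = windowSize, windowOverlap = windowOverlap,
      searchRadius = searchRadius, minDensity = minDensity,
      outlierZmax = outlierZmax, peakQualityMin = peakQualityMin,
      highpassSigma = highpassSigma, deformPasses = deformPasses)
}

setMethod("show", "PIVConfig", function(object) {
  cat(sprintf(
    "PIVConfig: %d px windows, %.0f%% overlap, +/-%d px search, min density %.3g pg/um^2\n",
    object@windowSize, 100 * object@windowOverlap, object@searchRadius,
    object@minDensity))
})

#' A mass-transport velocity field between two frames
#'
#' One velocity vector per interrogation-window centre, in µm/min. The
#' `valid` flag records which nodes passed the density, peak-quality and
#' median-validation checks; invalid nodes carry median-infilled values so
#' that interpolation is defined everywhere.
#'
#' @slot gridX node x coordinates, µm (length = number of node columns)
#' @slot gridY node y coordinates, µm (length = number of node rows)
#' @slot u x velocity component at each node, µm/min (rows = gridY)
#' @slot v y velocity component, µm/min
#' @slot valid logical matrix of node validity
#' @slot dt time separation of the two frames, min
#' @export
setClass("VelocityField",
  representation(gridX = "numeric", gridY = "numeric",
                 u = "matrix", v = "matrix", valid = "matrix",
                 dt = "numeric"))

setValidity("VelocityField", function(object) {
  dm <- c(length(object@gridY), length(object@gridX))
  for (s in c("u", "v", "valid"))
    if (!all(dim(slot(object, s)) == dm))
      return(sprintf("'%s' must be a %d x %d matrix", s, dm[1], dm[2]))
  if (!is.logical(object@valid)) return("'valid' must be logical")
  if (any(!is.finite(object@u[object@valid])) ||
      any(!is.finite(object@v[object@valid])))
    return("velocities must be finite at valid nodes")
  if (length(object@dt) != 1 || object@dt <= 0)
    return("'dt' must be a single positive number (min)")
  TRUE
})

setMethod("show", "VelocityField", function(object) {
  sp <- sqrt(object@u^2 + object@v^2)
  cat(sprintf(
    "VelocityField %dx%d nodes, dt = %.3g min, %.0f%% valid, median speed %.3g um/min\n",
    length(object@gridY), length(object@gridX), object@dt,
    100 * mean(object@valid), stats::median(sp[object@valid])))
})

#' A square control volume seeded on the cell
#'
#' A small quadrilateral material element (default area 0.7 µm²) whose four
#' corners are advected through the velocity-field sequence. Corners are
#' ordered counter-clockwise in the (x right, y down) image frame.
#'
#' @slot corners 4x2 matrix of (x, y) corner coordinates, µm
#' @slot id integer identifier (row-major over the seeding grid)
#' @slot seedCenter (x, y) of the seeding centre, µm
#' @export
setClass("ControlVolume",
  representation(corners = "matrix", id = "integer", seedCenter = "numeric"))

setValidity("ControlVolume", function(object) {
  if (!all(dim(object@corners) == c(4, 2)))
    return("'corners' must be a 4x2 matrix")
  if (polygonArea(object@corners) <= 0)
    return("corners must be ordered counter-clockwise with positive area")
  if (!polygonIsSimple(object@corners))
    return("polygon must be simple (non-self-intersecting)")
  TRUE
})

setMethod("show", "ControlVolume", function(object) {
  cat(sprintf("ControlVolume #%d: area %.4g um^2, seed centre (%.3g, %.3g) um\n",
              object@id, polygonArea(object@corners),
              object@seedCenter[1], object@seedCenter[2]))
})

#' @rdname accessors
#' @export
setMethod("corners", "ControlVolume", function(x) x@corners)
#' @rdname accessors
#' @export
setMethod("cvId", "ControlVolume", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("seedCenter", "ControlVolume", function(x) x@seedCenter)

#' A control volume's trajectory through a movie
#'
#' Per-frame corner positions and integrated dry mass for one tracked
#' control volume. Tracking stops (the track is truncated) at the first
#' frame where a corner leaves the image or the polygon degenerates.
#'
#' @slot cvId integer identifier matching the seeded volume
#' @slot frames data.frame with columns t_min, x0..x3, y0..y3 (µm),
#'   mass_pg, in_bounds
#' @export
setClass("ControlVolumeTrack",
  representation(cvId = "integer", frames = "data.frame"))

setValidity("ControlVolumeTrack", function(object) {
  f <- object@frames
  need <- c("t_min", paste0("x", 0:3), paste0("y", 0:3), "mass_pg", "in_bounds")
  if (!all(need %in% names(f)))
    return(paste("'frames' must have columns", paste(need, collapse = ", ")))
  if (nrow(f) > 1 && any(diff(f$t_min) <= 0))
    return("timestamps must be strictly increasing")
  if (any(f$mass_pg < 0)) return("mass must be non-negative")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("cvId", "ControlVolumeTrack", function(x) x@cvId)
#' @rdname accessors
#' @export
setMethod("trackTable", "ControlVolumeTrack", function(x) x@frames)

setMethod("show", "ControlVolumeTrack", function(object) {
  f <- object@frames
  cat(sprintf(
    "ControlVolumeTrack #%d: %d frames (%.3g-%.3g min), mass %.3g -> %.3g pg%s\n",
    object@cvId, nrow(f), min(f$t_min), max(f$t_min),
    f$mass_pg[1], f$mass_pg[nrow(f)],
    if (all(f$in_bounds)) "" else " [truncated]"))
})

#' A rasterized growth map
#'
#' Net growth rate (pg/h) of the control volume covering each pixel at the
#' start of the analysis window; pixels covered by no in-bounds volume are
#' NA. Overlapping footprints are resolved in favour of the nearest seed
#' centre.
#'
#' @slot raster matrix of rates, pg/h; NA = undefined
#' @slot window c(t_start, t_end) of the analysis window, min
#' @slot calibration the acquisition [Calibration-class]
#' @export
setClass("GrowthMap",
  representation(raster = "matrix", window = "numeric",
                 calibration = "Calibration"))

setValidity("GrowthMap", function(object) {
  if (length(object@window) != 2 || diff(object@window) <= 0)
    return("'window' must be c(t_start, t_end) with t_end > t_start")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("growthRaster", "GrowthMap", function(x) x@raster)
#' @rdname accessors
#' @export
setMethod("analysisWindow", "GrowthMap", function(x) x@window)
#' @rdname accessors
#' @export
setMethod("calibration", "GrowthMap", function(x) x@calibration)

setMethod("show", "GrowthMap", function(object) {
  def <- !is.na(object@raster)
  rng <- if (any(def)) range(object@raster[def]) else c(NA, NA)
  cat(sprintf(
    "GrowthMap %dx%d px, window %.3g-%.3g min, %d defined px, rate range [%.3g, %.3g] pg/h\n",
    nrow(object@raster), ncol(object@raster), object@window[1],
    object@window[2], sum(def), rng[1], rng[2]))
})
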