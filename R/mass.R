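#' Background-correct a phase frame
#'
#' Fits a plane a*x + b*y + c by least squares to the optical path
#' difference over the off-cell region and subtracts it from the whole
#' frame, so that the background OPD is centred on zero before conversion
#' to dry mass. A plane is the simplest model consistent with slowly
#' varying illumination and residual wavefront tilt.
#'
#' @param frame a [PhaseFrame-class]
#' @param cellMask a [CellMask-class]; pixels *outside* it form the
#'   background region
#' @return a background-corrected [PhaseFrame-class]
#' @export
backgroundCorrect <- function(frame, cellMask) {
  m <- opd(frame)
  bg <- !maskMatrix(cellMask)
  if (!all(dim(bg) == dim(m))) stop("mask shape does not match frame")
  if (!any(bg)) stop("background region is empty; mask covers the whole frame")
  nr <- nrow(m); nc <- ncol(m)
  xs <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr) - 0.5, times = nc), nr, nc)
  fit <- stats::lm.fit(cbind(1, xs[bg], ys[bg]), m[bg])
  plane <- fit$coefficients[1] + fit$coefficients[2] * xs + fit$coefficients[3] * ys
  phaseFrame(m - plane, timestamp(frame))
}

#' Convert a phase frame to areal dry-mass density
#'
#' Applies the specific refractive increment: sigma = OPD / alpha, with
#' sigma in pg/µm², OPD in µm and alpha in µm³/pg (default 0.18). The
#' per-pixel dry mass is sigma * pixelSize².
#'
#' @param frame a background-corrected [PhaseFrame-class]
#' @param cal a [Calibration-class]
#' @return a [MassFrame-class]
#' @examples
#' cal <- Calibration(pixelSize = 1, frameInterval = 1)
#' f <- phaseFrame(matrix(0.18, 4, 4))
#' density(phaseToMass(f, cal))[1, 1] # 1 pg/um^2
#' @export
phaseToMass <- function(frame, cal) {
  alpha <- refractiveIncrement(cal)
  if (!is.finite(alpha) || alpha <= 0)
    stop("refractive increment must be strictly positive")
  massFrame(opd(frame) / alpha, timestamp(frame), cal)
}

#' Segment the cell from a mass frame
#'
#' Deterministic whole-cell segmentation: Gaussian pre-smoothing, a fixed
#' density threshold, largest connected component, hole filling. Intended
#' for whole-cell bookkeeping (total mass, control-volume seeding), not for
#' delineating fine morphology.
#'
#' @param frame a background-corrected [MassFrame-class]
#' @param threshold density threshold in pg/µm² (default 0.05)
#' @param sigma Gaussian pre-smoothing sigma in px (0 disables)
#' @return a [CellMask-class] labelled "cell"
#' @export
segmentCell <- function(frame, threshold = 0.05, sigma = 1) {
  d <- density(frame)
  sm <- if (sigma > 0) EBImage::gblur(d, sigma = sigma) else d
  bin <- sm > threshold
  if (!any(bin))
    stop("empty segmentation: no pixels above density threshold ", threshold)
  lab <- EBImage::bwlabel(bin)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  comp <- EBImage::fillHull(lab == keep)
  cellMask(comp > 0, "cell")
}

#' Total dry mass inside a region
#'
#' Sum of density * pixel area over the masked pixels.
#'
#' @param frame a [MassFrame-class]
#' @param mask a [CellMask-class]
#' @return dry mass in pg
#' @export
totalMass <- function(frame, mask) {
  d <- density(frame)
  m <- maskMatrix(mask)
  if (!all(dim(m) == dim(d))) stop("mask shape does not match frame")
  sum(d[m]) * pixelSize(calibration(frame))^2
}
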