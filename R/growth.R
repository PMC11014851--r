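#' Fit a control volume's net growth rate
#'
#' Ordinary least-squares slope of tracked mass (pg) against time (hours)
#' over the in-bounds frames falling inside the analysis window. In the
#' Lagrangian frame the advective contribution to mass change is absorbed
#' by the tracking itself, so this slope estimates the net local source
#' term: biomass production (positive) or degradation (negative).
#'
#' @param track a [ControlVolumeTrack-class]
#' @param window c(t_start, t_end) in min; default spans the whole track
#' @return one-row data.frame with columns `cv_id`, `rate_pg_per_h`,
#'   `rate_se`, `t_start`, `t_end`, `n_frames`, `mass0_pg` (mass at the
#'   first in-window frame) and `valid` (FALSE when fewer than 3 usable
#'   frames remain)
#' @export
fitGrowthRate <- function(track, window = NULL) {
  f <- trackTable(track)
  if (is.null(window)) window <- range(f$t_min)
  use <- f$in_bounds & f$t_min >= window[1] & f$t_min <= window[2]
  # the truncation row (in_bounds FALSE) still holds a valid mass sample
  lastRow <- which(!f$in_bounds)
  if (length(lastRow) > 0 && f$t_min[lastRow[1]] >= window[1] &&
      f$t_min[lastRow[1]] <= window[2])
    use[lastRow[1]] <- TRUE
  out <- data.frame(cv_id = cvId(track), rate_pg_per_h = NA_real_,
                    rate_se = NA_real_, t_start = window[1],
                    t_end = window[2], n_frames = sum(use),
                    mass0_pg = NA_real_, valid = FALSE)
  if (sum(use) < 3) return(out)
  t_h <- f$t_min[use] / 60
  m <- f$mass_pg[use]
  # closed-form simple OLS (slope and its standard error); avoids the
  # perfect-fit warnings summary.lm() raises on noise-free series
  n <- length(m)
  tc <- t_h - mean(t_h)
  sxx <- sum(tc^2)
  slope <- sum(tc * m) / sxx
  resid <- m - mean(m) - slope * tc
  out$rate_pg_per_h <- slope
  out$rate_se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  out$mass0_pg <- m[1]
  out$valid <- TRUE
  out
}

#' Fit growth rates for a list of tracks
#' @param tracks list of [ControlVolumeTrack-class]
#' @param window c(t_start, t_end) in min
#' @return data.frame, one row per track (see [fitGrowthRate()])
#' @export
fitGrowthRates <- function(tracks, window = NULL) {
  do.call(rbind, lapply(tracks, fitGrowthRate, window = window))
}

#' Rasterize growth estimates into a map
#'
#' Every pixel whose centre lies inside a volume's window-start polygon
#' carries that volume's fitted rate; where polygons overlap, the volume
#' whose seed centre is nearest to the pixel wins. Pixels covered by no
#' valid volume are NA.
#'
#' @param estimates data.frame from [fitGrowthRates()]
#' @param cvs list of [ControlVolume-class] at their window-start
#'   (seeding) positions, ids matching `estimates$cv_id`
#' @param shape c(nrow, ncol) of the target raster
#' @param cal a [Calibration-class]
#' @return a [GrowthMap-class]
#' @export
assembleGrowthMap <- function(estimates, cvs, shape, cal) {
  px <- pixelSize(cal)
  raster <- matrix(NA_real_, shape[1], shape[2])
  bestDist <- matrix(Inf, shape[1], shape[2])
  ids <- vapply(cvs, cvId, integer(1))
  for (k in seq_len(nrow(estimates))) {
    if (!estimates$valid[k]) next
    cv <- cvs[[match(estimates$cv_id[k], ids)]]
    if (is.null(cv)) stop("estimate for unknown control volume ", estimates$cv_id[k])
    p <- corners(cv)
    cover <- .polyPixelMask(shape[1], shape[2], p[, 1] / px, p[, 2] / px)
    hit <- which(cover, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    cx <- (hit[, 2] - 0.5) * px
    cy <- (hit[, 1] - 0.5) * px
    d2 <- (cx - cv@seedCenter[1])^2 + (cy - cv@seedCenter[2])^2
    upd <- d2 < bestDist[hit]
    raster[hit[upd, , drop = FALSE]] <- estimates$rate_pg_per_h[k]
    bestDist[hit[upd, , drop = FALSE]] <- d2[upd]
  }
  new("GrowthMap", raster = raster,
      window = c(estimates$t_start[1], estimates$t_end[1]), calibration = cal)
}

# Window start times for a movie of given duration.
windowSchedule <- function(t0, t1, windowLen, windowStep) {
  if (windowLen > t1 - t0) stop("window length exceeds the movie duration")
  if (windowStep <= 0) stop("window step must be positive")
  starts <- seq(t0, t1 - windowLen, by = windowStep)
  starts
}

#' Sliding-window growth mapping
#'
#' For each analysis window: segments (or reuses) the cell mask at the
#' window start, seeds fresh control volumes on it, tracks them through the
#' window, fits per-volume rates and assembles a growth map. Windows whose
#' whole-cell mass or area jumps by more than `mitosisFrac` between
#' consecutive frames -- the signature of mitotic rounding/division, where
#' a 2-D mass balance breaks down -- are skipped with a warning.
#'
#' @param frames list of [MassFrame-class]
#' @param fields list of [VelocityField-class] (length = frames - 1)
#' @param windowLen window length in min (default 30)
#' @param windowStep step between window starts in min (default windowLen)
#' @param cvArea control-volume area in µm² (default 0.7)
#' @param mask optional fixed [CellMask-class]; NULL re-segments per window
#' @param segThreshold,segSigma segmentation parameters, see [segmentCell()]
#' @param mitosisFrac fractional whole-cell mass/area jump that voids a
#'   window (default 0.2)
#' @param method,scheme integration and advection options passed through
#' @return list with one element per window: list(map, estimates, cvs,
#'   mask, window) or NULL for skipped windows
#' @export
windowedGrowth <- function(frames, fields, windowLen = 30,
                           windowStep = windowLen, cvArea = 0.7,
                           mask = NULL, segThreshold = 0.05, segSigma = 1,
                           mitosisFrac = 0.2,
                           method = c("exact", "supersample"),
                           scheme = c("euler", "rk2")) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  ts <- vapply(frames, timestamp, numeric(1))
  starts <- windowSchedule(ts[1], ts[length(ts)], windowLen, windowStep)
  cal <- calibration(frames[[1]])
  shape <- dim(density(frames[[1]]))
  out <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    t0 <- starts[w]; t1 <- t0 + windowLen
    sel <- which(ts >= t0 - 1e-9 & ts <= t1 + 1e-9)
    wFrames <- frames[sel]
    wFields <- fields[sel[-length(sel)]]
    wm <- if (is.null(mask))
      segmentCell(wFrames[[1]], threshold = segThreshold, sigma = segSigma)
      else mask
    # mitosis-like discontinuity guard on whole-cell mass and area
    tm <- vapply(wFrames, function(f) {
      fm <- if (is.null(mask))
        segmentCell(f, threshold = segThreshold, sigma = segSigma) else mask
      c(totalMass(f, fm), sum(maskMatrix(fm)))
    }, numeric(2))
    jump <- function(x) if (length(x) < 2) 0 else max(abs(diff(x)) / pmax(x[-length(x)], 1e-12))
    if (jump(tm[1, ]) > mitosisFrac || jump(tm[2, ]) > mitosisFrac) {
      warning(sprintf(
        "window %g-%g min: whole-cell mass/area jump exceeds %.0f%%; window excluded (mitosis-like event)",
        t0, t1, 100 * mitosisFrac))
      out[w] <- list(NULL)
      next
    }
    cvs <- seedControlVolumes(wm, cal, cvArea)
    tracks <- trackControlVolumes(wFrames, wFields, cvs,
                                  method = method, scheme = scheme)
    est <- fitGrowthRates(tracks, window = c(t0, t1))
    map <- assembleGrowthMap(est, cvs, shape, cal)
    out[[w]] <- list(map = map, estimates = est, cvs = cvs, tracks = tracks,
                     mask = wm, window = c(t0, t1))
  }
  out
}
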