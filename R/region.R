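#' Region-level growth summary
#'
#' Sums the fitted rates of all control volumes whose seed centre lies in
#' the region and normalizes by the region's dry mass at the window start,
#' giving the region's specific growth rate (1/h).
#'
#' @param estimates data.frame from [fitGrowthRates()]
#' @param cvs list of [ControlVolume-class] at seeding positions
#' @param mask a [CellMask-class] defining the region
#' @param massFrame the [MassFrame-class] at the window start
#' @return one-row data.frame: `region`, `total_rate_pg_per_h`,
#'   `region_mass_pg`, `specific_rate_per_h` (NA, flagged by
#'   `mass_defined = FALSE`, when the region holds no mass), `n_volumes`
#' @export
regionGrowth <- function(estimates, cvs, mask, massFrame) {
  m <- maskMatrix(mask)
  if (!all(dim(m) == dim(density(massFrame))))
    stop("mask shape does not match frame")
  px <- pixelSize(calibration(massFrame))
  ids <- vapply(cvs, cvId, integer(1))
  inRegion <- vapply(cvs, function(cv) {
    r <- min(max(ceiling(cv@seedCenter[2] / px), 1), nrow(m))
    c <- min(max(ceiling(cv@seedCenter[1] / px), 1), ncol(m))
    m[r, c]
  }, logical(1))
  sel <- estimates$valid & inRegion[match(estimates$cv_id, ids)]
  totalRate <- sum(estimates$rate_pg_per_h[sel])
  regionMass <- totalMass(massFrame, mask)
  data.frame(region = maskLabel(mask),
             total_rate_pg_per_h = totalRate,
             region_mass_pg = regionMass,
             specific_rate_per_h = if (regionMass > 0) totalRate / regionMass
                                   else NA_real_,
             mass_defined = regionMass > 0,
             n_volumes = sum(sel))
}

#' Detect growth and degradation puncta in a growth map
#'
#' Connected components of pixels whose rate exceeds +threshold (growth
#' puncta) or falls below -threshold (degradation puncta); components
#' smaller than `minArea` are discarded. The default threshold is
#' `thresholdZ` times the robust noise scale (1.4826 * MAD) of the map's
#' defined pixels: the notion of a punctum is operationalized explicitly
#' since a qualitative "bright spot" is not reproducible. The default
#' multiplier is 4 because the map is piecewise constant over control
#' volumes -- a single noisy volume already spans more than `minArea`, so
#' with hundreds of volumes per cell a ~2-sigma cut would flag spurious
#' puncta on essentially every map, defeating the zero-growth control.
#'
#' @param map a [GrowthMap-class]
#' @param thresholdRate rate threshold in pg/h; NULL = `thresholdZ` * robust
#'   MAD scale of the defined pixels
#' @param minArea minimum punctum area in µm² (default 0.5)
#' @param thresholdZ multiplier for the automatic threshold (default 4)
#' @return data.frame ordered by centroid (x, then y): `centroid_x_um`,
#'   `centroid_y_um`, `area_um2`, `mean_rate_pg_per_h`, `sign`
#' @export
detectPuncta <- function(map, thresholdRate = NULL, minArea = 0.5,
                         thresholdZ = 4) {
  r <- growthRaster(map)
  def <- !is.na(r)
  if (!any(def)) stop("growth map has no defined pixels")
  px <- pixelSize(calibration(map))
  if (is.null(thresholdRate))
    thresholdRate <- thresholdZ * stats::mad(r[def], constant = 1.4826)
  out <- list()
  for (sgn in c(1, -1)) {
    bin <- def & (sgn * r > thresholdRate)
    if (!any(bin)) next
    lab <- EBImage::bwlabel(bin)
    for (k in seq_len(max(lab))) {
      hit <- which(lab == k, arr.ind = TRUE)
      area <- nrow(hit) * px^2
      if (area < minArea) next
      out[[length(out) + 1]] <- data.frame(
        centroid_x_um = mean(hit[, 2] - 0.5) * px,
        centroid_y_um = mean(hit[, 1] - 0.5) * px,
        area_um2 = area,
        mean_rate_pg_per_h = mean(r[hit]),
        sign = if (sgn > 0) "positive" else "negative")
    }
  }
  if (length(out) == 0)
    return(data.frame(centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                      area_um2 = numeric(0), mean_rate_pg_per_h = numeric(0),
                      sign = character(0)))
  d <- do.call(rbind, out)
  d[order(d$centroid_x_um, d$centroid_y_um), , drop = FALSE]
}
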