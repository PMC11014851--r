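# Shared fixtures, all generated in code under fixed seeds.

# Band-limited random texture (the kind of granular structure correlation
# velocimetry needs); sigma is the Gaussian smoothing scale in px.
smoothTexture <- function(n, sigma = 1.3, seed = 1) {
  set.seed(seed)
  tex <- EBImage::gblur(matrix(stats::rnorm(n * n), n, n), sigma = sigma)
  tex / stats::sd(tex)
}

smallCal <- function(px = 0.25, dt = 1, alpha = 0.18) {
  Calibration(pixelSize = px, frameInterval = dt, refractiveIncrement = alpha)
}

# A mass-frame movie from a list of density matrices.
massMovie <- function(mats, cal = smallCal()) {
  lapply(seq_along(mats), function(k)
    massFrame(mats[[k]], (k - 1) * frameInterval(cal), cal))
}

# Uniform velocity field covering a frame.
uniformField <- function(u, v, fov = 30, dt = 1, nNodes = 13) {
  g <- seq(fov / (nNodes + 1), fov - fov / (nNodes + 1), length.out = nNodes)
  new("VelocityField", gridX = g, gridY = g,
      u = matrix(u, nNodes, nNodes), v = matrix(v, nNodes, nNodes),
      valid = matrix(TRUE, nNodes, nNodes), dt = dt)
}

# Default textured-cell movie, background-corrected and mass-converted.
cellMassMovie <- function(mv) {
  cal <- mv$calibration
  alpha <- refractiveIncrement(cal)
  lapply(mv$frames, function(f) {
    prov <- cellMask(EBImage::gblur(opd(f), 1) > 0.05 * alpha)
    phaseToMass(backgroundCorrect(f, prov), cal)
  })
}

# Square control volume around a centre point.
squareCV <- function(cx, cy, side, id = 1L) {
  h <- side / 2
  new("ControlVolume",
      corners = rbind(c(cx - h, cy - h), c(cx + h, cy - h),
                      c(cx + h, cy + h), c(cx - h, cy + h)),
      id = as.integer(id), seedCenter = c(cx, cy))
}

# Track object from a bare mass/time series (for growth-fit tests).
seriesTrack <- function(t_min, mass, id = 1L) {
  n <- length(t_min)
  new("ControlVolumeTrack", cvId = as.integer(id), frames = data.frame(
    t_min = t_min, x0 = 0, x1 = 1, x2 = 1, x3 = 0,
    y0 = rep(0, n), y1 = 0, y2 = 1, y3 = 1,
    mass_pg = mass, in_bounds = TRUE))
}
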