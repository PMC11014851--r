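#' Ground-truth specification for a synthetic QPI movie
#'
#' Describes a moving, deforming, growing 2-D mass distribution: a
#' cell-like textured blob, a prescribed velocity field, a prescribed net
#' source term, and the acquisition parameters under which it is rendered
#' as a noisy OPD movie. Because the velocity field and source term are
#' known exactly, every stage of the inverse pipeline can be validated
#' against them.
#'
#' @slot shape c(nrow, ncol) in px
#' @slot pixelSize µm/px
#' @slot frameInterval min
#' @slot nFrames number of rendered frames
#' @slot velocity list(type = "zero" | "uniform" | "rotation" | "shear",
#'   ...): uniform takes u, v (µm/min); rotation takes omega (rad/min) and
#'   center (µm); shear takes k (1/min), u = k * y
#' @slot source list(type = "zero" | "uniform_specific" | "blobs"):
#'   uniform_specific takes g (1/h); blobs takes a list of
#'   list(center, radius, rate) with rate in pg/µm²/h, advected with the
#'   flow (material sources co-move with the cell)
#' @slot texture list(center, radius, densityScale, granularity, contrast,
#'   edgeWidth): a smooth disk profile times (1 + contrast * band-limited
#'   granular noise) -- featureless disks would defeat correlation
#'   velocimetry, so trackable texture is part of the ground truth;
#'   granularity is the feature FWHM in px (default 3, roughly the
#'   diffraction-limited speckle size at 0.25 µm sampling)
#' @slot noiseSigma OPD noise standard deviation, µm (default 5e-4 = 0.5 nm)
#' @slot refractiveIncrement µm³/pg used to render OPD
#' @slot seed RNG seed; the same scene renders bit-identically
#' @export
setClass("SyntheticScene",
  representation(shape = "integer", pixelSize = "numeric",
                 frameInterval = "numeric", nFrames = "integer",
                 velocity = "list", source = "list", texture = "list",
                 noiseSigma = "numeric", refractiveIncrement = "numeric",
                 seed = "integer"))

setValidity("SyntheticScene", function(object) {
  if (any(object@shape < 16)) return("'shape' must be at least 16 px")
  if (object@pixelSize <= 0 || object@frameInterval <= 0)
    return("pixelSize and frameInterval must be positive")
  if (object@nFrames < 1) return("'nFrames' must be >= 1")
  if (object@noiseSigma < 0) return("'noiseSigma' must be >= 0")
  if (!object@velocity$type %in% c("zero", "uniform", "rotation", "shear"))
    return("unknown velocity type")
  if (!object@source$type %in% c("zero", "uniform_specific", "blobs"))
    return("unknown source type")
  TRUE
})

#' Construct a SyntheticScene
#'
#' Defaults emulate the acquisition this pipeline targets: 0.25 µm pixels,
#' 1-min frames, a ~7 µm-radius cell with peak density ~1.2 pg/µm²
#' (peak OPD ~0.22 µm), granular texture of ~3 px correlation length, and
#' 0.5 nm OPD noise.
#'
#' @param shape c(nrow, ncol) px
#' @param pixelSize µm/px
#' @param frameInterval min
#' @param nFrames frames to render
#' @param velocity,source,texture see [SyntheticScene-class]
#' @param noiseSigma OPD noise sd, µm
#' @param refractiveIncrement µm³/pg
#' @param seed integer RNG seed
#' @return a [SyntheticScene-class]
#' @export
syntheticScene <- function(shape = c(120L, 120L), pixelSize = 0.25,
                           frameInterval = 1, nFrames = 31L,
                           velocity = list(type = "zero"),
                           source = list(type = "zero"),
                           texture = list(), noiseSigma = 5e-4,
                           refractiveIncrement = 0.18, seed = 1L) {
  fov <- rev(shape) * pixelSize # (width, height) um
  tex <- utils::modifyList(list(center = fov / 2, radius = 7,
                                densityScale = 1.2, granularity = 3,
                                contrast = 0.35, edgeWidth = 0.5), texture)
  new("SyntheticScene", shape = as.integer(shape), pixelSize = pixelSize,
      frameInterval = frameInterval, nFrames = as.integer(nFrames),
      velocity = velocity, source = source, texture = tex,
      noiseSigma = noiseSigma, refractiveIncrement = refractiveIncrement,
      seed = as.integer(seed))
}

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf(
    "SyntheticScene %dx%d px, %d frames @ %.3g min, velocity '%s', source '%s', seed %d\n",
    object@shape[1], object@shape[2], object@nFrames, object@frameInterval,
    object@velocity$type, object@source$type, object@seed))
})

#' Evaluate a scene's prescribed velocity at points
#' @param scene a [SyntheticScene-class]
#' @param x,y coordinates in µm
#' @return cbind(u, v) in µm/min
#' @export
sceneVelocity <- function(scene, x, y) {
  sp <- scene@velocity
  switch(sp$type,
    zero = cbind(u = 0 * x, v = 0 * y),
    uniform = cbind(u = rep(sp$u, length(x)), v = rep(sp$v, length(x))),
    rotation = cbind(u = -sp$omega * (y - sp$center[2]),
                     v = sp$omega * (x - sp$center[1])),
    shear = cbind(u = sp$k * y, v = 0 * y))
}

# Smooth cell-like initial density field (pg/um^2), seeded.
textureField <- function(scene) {
  tex <- scene@texture
  nr <- scene@shape[1]; nc <- scene@shape[2]; px <- scene@pixelSize
  xs <- matrix(rep((seq_len(nc) - 0.5) * px, each = nr), nr, nc)
  ys <- matrix(rep((seq_len(nr) - 0.5) * px, times = nc), nr, nc)
  dist <- sqrt((xs - tex$center[1])^2 + (ys - tex$center[2])^2)
  disk <- 1 / (1 + exp((dist - tex$radius) / tex$edgeWidth))
  gran <- EBImage::gblur(matrix(stats::rnorm(nr * nc), nr, nc),
                         sigma = tex$granularity / 2.355) # granularity = FWHM
  gran <- gran / stats::sd(gran)
  pmax(tex$densityScale * disk * (1 + tex$contrast * gran), 0)
}

#' Backward flow map of a scene's velocity field
#'
#' Returns the material (time-0) coordinates of the points that occupy
#' (x, y) at time t. Every supported velocity specification has a
#' closed-form flow map -- uniform translation, solid-body rotation and
#' simple shear -- so trajectories are evaluated exactly rather than by
#' numerical integration.
#'
#' @param scene a [SyntheticScene-class]
#' @param x,y coordinates in µm
#' @param t elapsed time in min
#' @return cbind(x0, y0) in µm
#' @export
sceneFlowBack <- function(scene, x, y, t) {
  sp <- scene@velocity
  switch(sp$type,
    zero = cbind(x0 = x, y0 = y),
    uniform = cbind(x0 = x - sp$u * t, y0 = y - sp$v * t),
    rotation = {
      th <- -sp$omega * t
      dx <- x - sp$center[1]; dy <- y - sp$center[2]
      cbind(x0 = sp$center[1] + cos(th) * dx - sin(th) * dy,
            y0 = sp$center[2] + sin(th) * dx + cos(th) * dy)
    },
    shear = cbind(x0 = x - sp$k * y * t, y0 = y))
}

# Forward flow map (used for co-moving blob centres).
sceneFlowForward <- function(scene, p, t) {
  sp <- scene@velocity
  switch(sp$type,
    zero = p,
    uniform = c(p[1] + sp$u * t, p[2] + sp$v * t),
    rotation = {
      th <- sp$omega * t
      dx <- p[1] - sp$center[1]; dy <- p[2] - sp$center[2]
      c(sp$center[1] + cos(th) * dx - sin(th) * dy,
        sp$center[2] + sin(th) * dx + cos(th) * dy)
    },
    shear = c(p[1] + sp$k * p[2] * t, p[2]))
}

#' Render a synthetic scene as a noisy OPD movie
#'
#' Each frame is generated by the method of characteristics: pixel centres
#' are mapped back to their material (time-0) positions along the exact
#' flow map of the prescribed velocity field and the initial density is
#' sampled there with bicubic interpolation, so advection error does not
#' compound across frames and the scheme is unconditionally stable. All
#' supported flows are divergence-free, so no Jacobian correction is
#' needed. Sources are applied in material coordinates: uniform specific
#' growth multiplies by exp(g t), and blob sources (which co-move with the
#' flow) accumulate rate * t over their static material footprint. OPD is
#' density * alpha plus independent Gaussian noise per frame, clipped at
#' zero. Warns when the prescribed motion exceeds the search capability of
#' the default velocimetry configuration.
#'
#' @param scene a [SyntheticScene-class]
#' @return list with `frames` (list of [PhaseFrame-class]), `calibration`
#'   ([Calibration-class]) and `truth`: list of per-frame `density`
#'   matrices, `totalMass` (pg per frame), `blobCenters` (per frame, for
#'   blob sources) and the `scene` itself
#' @export
renderMovie <- function(scene) {
  px <- scene@pixelSize; dt <- scene@frameInterval
  nr <- scene@shape[1]; nc <- scene@shape[2]
  alpha <- scene@refractiveIncrement
  cal <- Calibration(px, dt, alpha)
  xs <- matrix(rep((seq_len(nc) - 0.5) * px, each = nr), nr, nc)
  ys <- matrix(rep((seq_len(nr) - 0.5) * px, times = nc), nr, nc)
  vel <- sceneVelocity(scene, as.vector(xs), as.vector(ys))
  maxDisp <- max(sqrt(vel[, 1]^2 + vel[, 2]^2)) * dt / px
  if (maxDisp > pivConfig()@searchRadius)
    warning(sprintf(
      "per-frame displacement up to %.1f px exceeds the default search radius (%d px)",
      maxDisp, pivConfig()@searchRadius))
  sp <- scene@source
  withSeed(scene@seed, {
    sigma0 <- textureField(scene)
    densities <- vector("list", scene@nFrames)
    centersPerFrame <- vector("list", scene@nFrames)
    for (k in seq_len(scene@nFrames)) {
      t <- (k - 1) * dt
      if (k == 1) {
        sig <- sigma0
        back <- cbind(as.vector(xs), as.vector(ys))
      } else {
        back <- sceneFlowBack(scene, as.vector(xs), as.vector(ys), t)
        sig <- matrix(sampleBicubic(sigma0, back[, 1] / px, back[, 2] / px),
                      nr, nc)
      }
      if (sp$type == "uniform_specific") {
        sig <- sig * exp(sp$g * t / 60)
      } else if (sp$type == "blobs") {
        for (b in sp$blobs) {
          d0 <- sqrt((back[, 1] - b$center[1])^2 + (back[, 2] - b$center[2])^2)
          prof <- 1 / (1 + exp((d0 - b$radius) / 0.25))
          sig <- sig + matrix(b$rate * (t / 60) * prof, nr, nc)
        }
      }
      densities[[k]] <- pmax(sig, 0)
      centersPerFrame[[k]] <- if (sp$type == "blobs")
        lapply(sp$blobs, function(b) sceneFlowForward(scene, b$center, t))
        else list()
    }
    frames <- lapply(seq_len(scene@nFrames), function(k) {
      noisy <- densities[[k]] * alpha +
        matrix(stats::rnorm(nr * nc, sd = scene@noiseSigma), nr, nc)
      phaseFrame(pmax(noisy, 0), timestamp = (k - 1) * dt)
    })
    list(frames = frames, calibration = cal,
         truth = list(density = densities,
                      totalMass = vapply(densities, function(d) sum(d) * px^2,
                                         numeric(1)),
                      blobCenters = centersPerFrame,
                      scene = scene))
  })
}

#' Fixed-cell drift fixture: a movie with zero growth by construction
#'
#' Renders a rigidly translated copy of a static mass frame at each
#' timepoint (Fourier-shifted by the cumulative drift) plus fresh noise.
#' Any growth the pipeline reports on this movie is error, which is what
#' makes it the canonical negative control.
#'
#' @param baseFrame a [MassFrame-class]
#' @param shifts n x 2 matrix of cumulative (dx, dy) shifts in px, one row
#'   per output frame (row 1 is usually c(0, 0))
#' @param noiseSigma OPD noise sd, µm
#' @param seed RNG seed for the noise
#' @return list(frames, calibration) as in [renderMovie()]; ground-truth
#'   growth is identically zero
#' @export
fixedCellFixture <- function(baseFrame, shifts, noiseSigma = 5e-4, seed = 1L) {
  cal <- calibration(baseFrame)
  px <- pixelSize(cal); alpha <- refractiveIncrement(cal)
  sigma <- density(baseFrame)
  margin <- ceiling(max(abs(shifts))) + 2L
  nr <- nrow(sigma); nc <- ncol(sigma)
  if (2 * margin >= min(nr, nc))
    stop("cell would be clipped at the border under the requested shifts")
  border <- sigma
  border[(margin + 1):(nr - margin), (margin + 1):(nc - margin)] <- 0
  if (max(border) > 0.02 * max(sigma))
    stop("cell would be clipped at the border under the requested shifts")
  withSeed(seed, {
    frames <- lapply(seq_len(nrow(shifts)), function(k) {
      sh <- fourierShift(sigma, shifts[k, 1], shifts[k, 2])
      noisy <- sh * alpha + matrix(stats::rnorm(nr * nc, sd = noiseSigma), nr, nc)
      phaseFrame(pmax(noisy, 0), timestamp = (k - 1) * frameInterval(cal))
    })
    list(frames = frames, calibration = cal)
  })
}
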