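#' Cross-correlate two interrogation windows
#'
#' Normalized zero-mean cross-correlation computed via FFT, searched over
#' lags up to `searchRadius` px, with subpixel refinement by a two-stage
#' upsampled argmax (0.1 px then 0.01 px steps) evaluated at fractional
#' lags directly from the cross-spectrum -- essentially free of the
#' peak-locking bias that three-point fits suffer on smooth imagery.
#'
#' Two geometries are supported. When `winB` has the same shape as `winA`
#' the correlation is circular (matching shift-by-roll semantics). When
#' `winB` is larger -- a search region centred on the template's position,
#' as [computeVelocityField()] extracts -- the template is matched inside
#' the region (ZNCC with per-lag local normalization), so no content
#' enters or leaves the support and the estimate is unbiased for rigid
#' motion.
#'
#' The returned displacement (dx, dy) is the shift of B's content relative
#' to A (positive dx: content moved towards +x/columns).
#'
#' @param winA numeric matrix (template)
#' @param winB numeric matrix, same shape as `winA` or larger by an even
#'   margin in each dimension
#' @param searchRadius maximum displacement searched, px
#' @return list with `dx`, `dy` (px, subpixel), `dxInt`, `dyInt` (integer
#'   peak), `quality` (primary/secondary peak ratio) and `valid` (FALSE for
#'   flat, zero-variance windows)
#' @export
correlateWindow <- function(winA, winB, searchRadius = 8) {
  sr <- as.integer(searchRadius)
  mrow <- nrow(winB) - nrow(winA)
  mcol <- ncol(winB) - ncol(winA)
  if (mrow < 0 || mcol < 0 || mrow %% 2 != 0 || mcol %% 2 != 0)
    stop("winB must match winA or exceed it by an even margin")
  a <- winA - mean(winA)
  if (sum(a^2) == 0 || stats::sd(as.vector(winB)) == 0)
    return(list(dx = NA_real_, dy = NA_real_, dxInt = NA_integer_,
                dyInt = NA_integer_, quality = 0, valid = FALSE))
  n <- length(a)
  if (mrow == 0 && mcol == 0) {
    # circular ZNCC at the window size
    b <- winB - mean(winB)
    pr <- nrow(a); pc <- ncol(a)
    Fx <- Conj(stats::fft(a)) * stats::fft(b)
    R <- Re(stats::fft(Fx, inverse = TRUE)) / (pr * pc) /
      sqrt(sum(a^2) * sum(b^2))
    srr <- min(sr, floor(pr / 2) - 1L); src <- min(sr, floor(pc / 2) - 1L)
    lag <- function(nn, s) ifelse(s >= 0, s + 1L, nn + s + 1L)
    C <- R[lag(pr, -srr:srr), lag(pc, -src:src), drop = FALSE]
    k <- arrayInd(which.max(C), dim(C))
    d0 <- c(k[2] - src - 1L, k[1] - srr - 1L)
    normUp <- function(nu, s1, s2) nu / sqrt(sum(a^2) * sum(b^2))
    spec <- list(Fx = Fx, Fs1 = NULL, Fs2 = NULL, pr = pr, pc = pc,
                 off = c(0L, 0L))
  } else {
    # template matched inside a larger region: per-lag local normalization
    pr <- stats::nextn(nrow(winB), 2); pc <- stats::nextn(ncol(winB), 2)
    A <- matrix(0, pr, pc); A[seq_len(nrow(a)), seq_len(ncol(a))] <- a
    B <- matrix(0, pr, pc)
    B[seq_len(nrow(winB)), seq_len(ncol(winB))] <- winB
    B2 <- matrix(0, pr, pc)
    B2[seq_len(nrow(winB)), seq_len(ncol(winB))] <- winB^2
    I <- matrix(0, pr, pc); I[seq_len(nrow(a)), seq_len(ncol(a))] <- 1
    FI <- stats::fft(I)
    Fx <- Conj(stats::fft(A)) * stats::fft(B)
    Fs1 <- Conj(FI) * stats::fft(B)
    Fs2 <- Conj(FI) * stats::fft(B2)
    num <- Re(stats::fft(Fx, inverse = TRUE)) / (pr * pc)
    s1 <- Re(stats::fft(Fs1, inverse = TRUE)) / (pr * pc)
    s2 <- Re(stats::fft(Fs2, inverse = TRUE)) / (pr * pc)
    Z <- num / sqrt(pmax(s2 - s1^2 / n, 1e-12) * sum(a^2))
    # template offset j (0-based) within the region maps to displacement
    # d = j - margin/2; keep lags with the template inside the region
    dxs <- 0:mcol - mcol %/% 2L
    dys <- 0:mrow - mrow %/% 2L
    keepx <- abs(dxs) <= sr; keepy <- abs(dys) <= sr
    C <- Z[which(keepy), which(keepx), drop = FALSE]
    k <- arrayInd(which.max(C), dim(C))
    d0 <- c(dxs[keepx][k[2]], dys[keepy][k[1]])
    spec <- list(Fx = Fx, Fs1 = Fs1, Fs2 = Fs2, pr = pr, pc = pc,
                 off = c(mcol %/% 2L, mrow %/% 2L))
    normUp <- function(nu, s1u, s2u)
      nu / sqrt(pmax(s2u - s1u^2 / n, 1e-12) * sum(a^2))
  }
  p1 <- C[k]
  Cm <- C
  Cm[max(1, k[1] - 1):min(nrow(C), k[1] + 1),
     max(1, k[2] - 1):min(ncol(C), k[2] + 1)] <- -Inf
  p2 <- max(Cm)
  quality <- abs(p1) / max(abs(p2), 1e-12)
  kfreq <- function(nn)
    2 * pi * ((((0:(nn - 1)) + floor(nn / 2)) %% nn) - floor(nn / 2)) / nn
  kr <- kfreq(spec$pr)
  kc <- kfreq(spec$pc)
  evalAt <- function(sx, sy, Fm) {
    Er <- exp(1i * outer(sy + spec$off[2], kr))
    Ec <- exp(1i * outer(kc, sx + spec$off[1]))
    Re(Er %*% Fm %*% Ec) / (spec$pr * spec$pc)
  }
  d <- d0
  srx <- if (mcol == 0) min(sr, floor(pc / 2) - 1L) else
    min(sr, max(abs(dxs[keepx])))
  sry <- if (mrow == 0) min(sr, floor(pr / 2) - 1L) else
    min(sr, max(abs(dys[keepy])))
  for (step in c(0.1, 0.01)) {
    sx <- pmin(pmax(d[1] + (-5:5) * step, -srx), srx)
    sy <- pmin(pmax(d[2] + (-5:5) * step, -sry), sry)
    nu <- evalAt(sx, sy, spec$Fx)
    Cu <- if (is.null(spec$Fs1)) normUp(nu, NULL, NULL)
          else normUp(nu, evalAt(sx, sy, spec$Fs1), evalAt(sx, sy, spec$Fs2))
    kk <- arrayInd(which.max(Cu), dim(Cu))
    d <- c(sx[kk[2]], sy[kk[1]])
  }
  list(dx = d[1], dy = d[2], dxInt = d0[1], dyInt = d0[2],
       quality = quality, valid = TRUE)
}

#' Estimate the velocity field between two mass frames
#'
#' Tiles the image with interrogation windows, cross-correlates each pair,
#' converts displacements to µm/min, flags windows with too little mass or
#' an ambiguous correlation peak, removes local-median outliers and infills
#' flagged nodes from their neighbours.
#'
#' A resolution guard warns when the 95th-percentile displacement exceeds
#' half the diffraction-limited resolution in pixels: at that point the
#' frame interval undersamples the motion and correlation pairing becomes
#' unreliable (the acquisition design this pipeline expects is ~1-min
#' intervals for typical intracellular speeds of ~0.2 µm/min at ~0.5 µm
#' resolution).
#'
#' @param frameA,frameB consecutive [MassFrame-class] objects (shared
#'   calibration, increasing timestamps)
#' @param mask a [CellMask-class]; used only through the density floor
#'   (off-cell windows fall below `minDensity`), accepted for interface
#'   symmetry and future masking policies
#' @param cfg a [PIVConfig-class]
#' @param resolution diffraction-limited resolution in µm for the sampling
#'   guard (default 0.48)
#' @return a [VelocityField-class]
#' @export
computeVelocityField <- function(frameA, frameB, mask = NULL,
                                 cfg = pivConfig(), resolution = 0.48) {
  calA <- calibration(frameA)
  dt <- timestamp(frameB) - timestamp(frameA)
  if (dt <= 0) stop("frame timestamps must be strictly increasing")
  px <- pixelSize(calA)
  da <- density(frameA); db <- density(frameB)
  if (!all(dim(da) == dim(db))) stop("frames must share geometry")
  w <- as.integer(cfg@windowSize)
  stride <- max(1L, as.integer(round(w * (1 - cfg@windowOverlap))))
  # high-pass: correlate on the granular texture only; the smooth envelope,
  # truncated at window edges, otherwise drags the peak towards zero lag
  if (cfg@highpassSigma > 0) {
    ha <- da - EBImage::gblur(da, cfg@highpassSigma)
    hb <- db - EBImage::gblur(db, cfg@highpassSigma)
  } else {
    ha <- da; hb <- db
  }
  i0 <- seq(1L, nrow(da) - w + 1L, by = stride)
  j0 <- seq(1L, ncol(da) - w + 1L, by = stride)
  if (length(i0) == 0 || length(j0) == 0)
    stop("image smaller than one interrogation window")
  gridY <- (i0 - 1 + w / 2) * px
  gridX <- (j0 - 1 + w / 2) * px
  u <- v <- matrix(NA_real_, length(i0), length(j0))
  valid <- matrix(FALSE, length(i0), length(j0))
  dispPx <- c()
  for (a in seq_along(i0)) {
    ri <- i0[a]:(i0[a] + w - 1L)
    for (b in seq_along(j0)) {
      cj <- j0[b]:(j0[b] + w - 1L)
      if (mean(da[ri, cj]) < cfg@minDensity) next
      # search region around the window, clipped symmetrically at the border
      mr <- min(cfg@searchRadius, i0[a] - 1L, nrow(da) - (i0[a] + w - 1L))
      mc <- min(cfg@searchRadius, j0[b] - 1L, ncol(da) - (j0[b] + w - 1L))
      rb <- (i0[a] - mr):(i0[a] + w - 1L + mr)
      cb <- (j0[b] - mc):(j0[b] + w - 1L + mc)
      r <- correlateWindow(ha[ri, cj], hb[rb, cb], cfg@searchRadius)
      if (!r$valid || r$quality < cfg@peakQualityMin) next
      u[a, b] <- r$dx * px / dt
      v[a, b] <- r$dy * px / dt
      valid[a, b] <- TRUE
      dispPx <- c(dispPx, sqrt(r$dx^2 + r$dy^2))
    }
  }
  if (sum(valid) < 4)
    stop("fewer than 4 valid velocity vectors; frame pair unusable")
  if (cfg@deformPasses > 0) {
    # window-deformation pass(es): warp frame B by the current field and
    # re-correlate the residual. Removes the gradient bias that drags the
    # peak towards the slow side of a window in rotational/shear flow.
    pre <- infillInvalid(medianFilterVectors(
      new("VelocityField", gridX = gridX, gridY = gridY, u = u, v = v,
          valid = valid, dt = dt), cfg@outlierZmax))
    for (pass in seq_len(cfg@deformPasses)) {
      for (a in seq_along(i0)) {
        ri <- i0[a]:(i0[a] + w - 1L)
        for (b in seq_along(j0)) {
          if (!valid[a, b]) next
          cj <- j0[b]:(j0[b] + w - 1L)
          pxx <- rep(cj - 0.5, each = w)     # window pixel centres, px
          pyy <- rep(ri - 0.5, times = w)
          vv <- interpolateVelocity(pre, cbind(pxx * px, pyy * px))
          dx <- vv[, 1] * dt / px; dy <- vv[, 2] * dt / px
          bw <- matrix(sampleBicubic(hb, pxx + dx, pyy + dy), w, w)
          rs <- correlateWindow(ha[ri, cj], bw, min(4L, cfg@searchRadius))
          if (!rs$valid) next
          # node predictor + residual
          nd <- interpolateVelocity(pre, cbind(gridX[b], gridY[a]))
          u[a, b] <- nd[1, 1] + rs$dx * px / dt
          v[a, b] <- nd[1, 2] + rs$dy * px / dt
        }
      }
      pre <- infillInvalid(medianFilterVectors(
        new("VelocityField", gridX = gridX, gridY = gridY, u = u, v = v,
            valid = valid, dt = dt), cfg@outlierZmax))
    }
    u <- pre@u; v <- pre@v
  }
  if (length(dispPx) > 0 &&
      stats::quantile(dispPx, 0.95) > 0.5 * resolution / px)
    warning(sprintf(
      "95th-percentile displacement %.2f px exceeds half the resolution (%.2f px); frame interval may undersample the motion",
      stats::quantile(dispPx, 0.95), 0.5 * resolution / px))
  field <- new("VelocityField", gridX = gridX, gridY = gridY,
               u = u, v = v, valid = valid, dt = dt)
  field <- medianFilterVectors(field, cfg@outlierZmax)
  infillInvalid(field)
}

#' Velocity fields for a whole movie, with a multi-frame baseline
#'
#' Computes one velocity field per consecutive frame interval. With
#' `baseline` = K > 1, the field for interval k is measured by correlating
#' frame k with frame k+K and dividing by the elapsed time: intracellular
#' speeds (~0.2 µm/min) move features by well under a pixel per frame at
#' 1-min sampling, so a longer baseline raises the displacement far above
#' the correlation error floor at the cost of low-pass filtering the
#' velocity in time. Near the end of the movie the baseline shortens to
#' what remains.
#'
#' @param frames list of [MassFrame-class]
#' @param cfg a [PIVConfig-class]
#' @param baseline correlation baseline in frames, or "auto" (default):
#'   a pilot single-interval pass estimates the typical displacement and
#'   the baseline is chosen so that the baseline displacement is about
#'   half the search radius, capped at 15 frames
#' @param resolution passed to [computeVelocityField()]
#' @return list of length(frames) - 1 [VelocityField-class] objects; each
#'   field's `dt` is the frame interval it advects over
#' @export
computeVelocityFields <- function(frames, cfg = pivConfig(),
                                  baseline = "auto", resolution = 0.48) {
  n <- length(frames)
  if (n < 2) stop("need at least two frames")
  if (identical(baseline, "auto")) {
    pilot <- suppressWarnings(
      computeVelocityField(frames[[1]], frames[[2]], cfg = cfg,
                           resolution = resolution))
    px <- pixelSize(calibration(frames[[1]]))
    disp <- sqrt(pilot@u^2 + pilot@v^2)[pilot@valid] * pilot@dt / px
    d95 <- stats::quantile(disp, 0.95)
    baseline <- max(1L, min(15L, n - 1L,
                            as.integer(floor(0.5 * cfg@searchRadius /
                                             max(d95, 0.05)))))
  }
  fields <- vector("list", n - 1)
  cache <- new.env(parent = emptyenv())
  for (k in seq_len(n - 1)) {
    # slide a full-width baseline inside the movie so late intervals are
    # measured as accurately as early ones
    k1 <- max(1L, min(k, n - as.integer(baseline)))
    k2 <- min(k1 + as.integer(baseline), n)
    key <- paste(k1, k2)
    f <- if (!is.null(cache[[key]])) cache[[key]] else {
      # scale the sampling guard to the baseline so it still reads per frame
      cache[[key]] <- computeVelocityField(frames[[k1]], frames[[k2]],
                                           cfg = cfg,
                                           resolution = resolution * (k2 - k1))
      cache[[key]]
    }
    # re-stamp dt as the single-interval step the field will advect over
    fields[[k]] <- new("VelocityField", gridX = f@gridX, gridY = f@gridY,
                       u = f@u, v = f@v, valid = f@valid,
                       dt = timestamp(frames[[k + 1]]) - timestamp(frames[[k]]))
  }
  fields
}

#' Validate vectors against their local median
#'
#' Flags nodes whose vector deviates from the 3x3 neighbourhood median by
#' more than `zmax` times the neighbourhood's median absolute residual
#' (plus a small floor so that noise-free uniform fields are not
#' over-flagged), and replaces flagged vectors with that median.
#'
#' @param field a [VelocityField-class]
#' @param zmax robust z threshold
#' @param eps residual floor in µm/min
#' @return the filtered [VelocityField-class]
#' @export
medianFilterVectors <- function(field, zmax = 3, eps = 0.01) {
  u <- field@u; v <- field@v; valid <- field@valid
  nr <- nrow(u); nc <- ncol(u)
  if (nr < 3 || nc < 3) return(field)
  newU <- u; newV <- v; newValid <- valid
  for (a in seq_len(nr)) {
    for (b in seq_len(nc)) {
      if (!valid[a, b]) next
      ri <- max(1, a - 1):min(nr, a + 1)
      cj <- max(1, b - 1):min(nc, b + 1)
      nb <- valid[ri, cj]
      nb[which(ri == a), which(cj == b)] <- FALSE
      if (sum(nb) < 3) {
        # an isolated vector cannot be corroborated; drop it rather than
        # let an edge-of-cell outlier drive the advection
        newValid[a, b] <- FALSE
        next
      }
      un <- u[ri, cj][nb]; vn <- v[ri, cj][nb]
      mu <- stats::median(un); mv <- stats::median(vn)
      rm <- stats::median(sqrt((un - mu)^2 + (vn - mv)^2))
      r <- sqrt((u[a, b] - mu)^2 + (v[a, b] - mv)^2)
      if (r / (rm + eps) > zmax) {
        newU[a, b] <- mu; newV[a, b] <- mv; newValid[a, b] <- FALSE
      }
    }
  }
  new("VelocityField", gridX = field@gridX, gridY = field@gridY,
      u = newU, v = newV, valid = newValid, dt = field@dt)
}

# Fill invalid nodes with the median of valid (or previously filled)
# neighbours, iterating until stable or 10 passes; unreachable nodes get 0
# (static background). Errors when the field has no valid node at all.
infillInvalid <- function(field, maxIter = 10) {
  u <- field@u; v <- field@v
  have <- field@valid & is.finite(u) & is.finite(v)
  if (!any(have)) stop("cannot infill: no valid velocity vectors")
  filled <- have | (is.finite(u) & is.finite(v)) # median-filter replacements count
  nr <- nrow(u); nc <- ncol(u)
  for (it in seq_len(maxIter)) {
    todo <- which(!filled, arr.ind = TRUE)
    if (nrow(todo) == 0) break
    progress <- FALSE
    for (k in seq_len(nrow(todo))) {
      a <- todo[k, 1]; b <- todo[k, 2]
      ri <- max(1, a - 1):min(nr, a + 1)
      cj <- max(1, b - 1):min(nc, b + 1)
      nb <- filled[ri, cj]
      if (!any(nb)) next
      u[a, b] <- stats::median(u[ri, cj][nb])
      v[a, b] <- stats::median(v[ri, cj][nb])
      filled[a, b] <- TRUE
      progress <- TRUE
    }
    if (!progress) break
  }
  u[!filled] <- 0; v[!filled] <- 0
  new("VelocityField", gridX = field@gridX, gridY = field@gridY,
      u = u, v = v, valid = field@valid, dt = field@dt)
}

#' Interpolate a velocity field at arbitrary points
#'
#' Bilinear interpolation on the node grid; points outside the grid's
#' bounding box are clamped to the nearest edge node.
#'
#' @param field a [VelocityField-class]
#' @param points n x 2 matrix of (x, y) in µm
#' @return n x 2 matrix of (u, v) in µm/min
#' @export
interpolateVelocity <- function(field, points) {
  points <- matrix(points, ncol = 2)
  gx <- field@gridX; gy <- field@gridY
  x <- pmin(pmax(points[, 1], gx[1]), gx[length(gx)])
  y <- pmin(pmax(points[, 2], gy[1]), gy[length(gy)])
  interp1 <- function(g, p) {
    if (length(g) == 1) return(list(i = rep(1L, length(p)), t = rep(0, length(p))))
    i <- pmin(pmax(findInterval(p, g), 1L), length(g) - 1L)
    list(i = i, t = (p - g[i]) / (g[i + 1] - g[i]))
  }
  ix <- interp1(gx, x); iy <- interp1(gy, y)
  bl <- function(m) {
    i <- iy$i; j <- ix$i; tx <- ix$t; ty <- iy$t
    jn <- pmin(j + 1L, ncol(m)); ip <- pmin(i + 1L, nrow(m))
    m[cbind(i, j)] * (1 - tx) * (1 - ty) + m[cbind(i, jn)] * tx * (1 - ty) +
      m[cbind(ip, j)] * (1 - tx) * ty + m[cbind(ip, jn)] * tx * ty
  }
  cbind(u = bl(field@u), v = bl(field@v))
}
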