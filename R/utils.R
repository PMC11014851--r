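#' Signed polygon area (shoelace)
#'
#' Positive for counter-clockwise vertex order in the (x right, y down)
#' image coordinate frame used throughout the package.
#'
#' @param corners n x 2 matrix of (x, y) vertices
#' @return area in the square of the coordinate unit
#' @export
polygonArea <- function(corners) {
  x <- corners[, 1]; y <- corners[, 2]
  j <- c(seq_len(nrow(corners))[-1], 1)
  0.5 * sum(x * y[j] - x[j] * y)
}

segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Test that a quadrilateral is simple (non-self-intersecting)
#' @param corners 4 x 2 matrix of vertices
#' @return TRUE if no two non-adjacent edges cross
#' @export
polygonIsSimple <- function(corners) {
  if (nrow(corners) != 4) return(TRUE)
  a <- corners[1, ]; b <- corners[2, ]; c <- corners[3, ]; d <- corners[4, ]
  !segmentsIntersect(a, b, c, d) && !segmentsIntersect(b, c, d, a)
}

# Evaluate an expression with a temporary RNG state seeded from `seed`,
# restoring the caller's stream afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

#' Subpixel image translation by Fourier phase shift
#'
#' Shifts an image by (dx, dy) pixels (x along columns, y along rows) using
#' the FFT shift theorem. Exact for band-limited content; the standard way
#' to fabricate ground-truth subpixel displacements.
#'
#' @param im numeric matrix
#' @param dx shift along x (columns), px; positive moves content rightwards
#' @param dy shift along y (rows), px; positive moves content downwards
#' @return shifted matrix of the same dimensions
#' @export
fourierShift <- function(im, dx, dy) {
  nr <- nrow(im); nc <- ncol(im)
  kx <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1)) / nc
  ky <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1)) / nr
  if (nc %% 2 == 0) kx[nc / 2 + 1] <- abs(kx[nc / 2 + 1]) # Nyquist: keep real
  if (nr %% 2 == 0) ky[nr / 2 + 1] <- abs(ky[nr / 2 + 1])
  ph <- exp(-2i * pi * (outer(ky, rep(1, nc)) * dy + outer(rep(1, nr), kx) * dx))
  Re(stats::fft(stats::fft(im) * ph, inverse = TRUE)) / (nr * nc)
}

# Catmull-Rom cubic kernel weights for fractional offset t in [0,1):
# weights for samples at offsets -1, 0, 1, 2.
cubicWeights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind(-0.5 * t3 + t2 - 0.5 * t,
        1.5 * t3 - 2.5 * t2 + 1,
        -1.5 * t3 + 2 * t2 + 0.5 * t,
        0.5 * t3 - 0.5 * t2)
}

# Sample `im` at continuous pixel coordinates (x, y) (pixel (r,c) centre at
# (c - 0.5, r - 0.5)) with separable Catmull-Rom interpolation; edge rows and
# columns are clamped. Vectorized over points.
sampleBicubic <- function(im, x, y) {
  nr <- nrow(im); nc <- ncol(im)
  gx <- x + 0.5; gy <- y + 0.5      # in 1-based pixel-centre index units
  j0 <- floor(gx); i0 <- floor(gy)
  tx <- gx - j0; ty <- gy - i0
  wx <- cubicWeights(tx); wy <- cubicWeights(ty)
  out <- numeric(length(x))
  for (a in 1:4) {
    ri <- pmin(pmax(i0 + a - 2L, 1), nr)
    acc <- numeric(length(x))
    for (b in 1:4) {
      cj <- pmin(pmax(j0 + b - 2L, 1), nc)
      acc <- acc + wx[, b] * im[cbind(ri, cj)]
    }
    out <- out + wy[, a] * acc
  }
  out
}

# Bilinear sampling at continuous pixel coordinates, clamped at the border.
sampleBilinear <- function(im, x, y) {
  nr <- nrow(im); nc <- ncol(im)
  gx <- pmin(pmax(x + 0.5, 1), nc); gy <- pmin(pmax(y + 0.5, 1), nr)
  j0 <- pmin(floor(gx), nc - 1); i0 <- pmin(floor(gy), nr - 1)
  tx <- gx - j0; ty <- gy - i0
  im[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
    im[cbind(i0, j0 + 1)] * tx * (1 - ty) +
    im[cbind(i0 + 1, j0)] * (1 - tx) * ty +
    im[cbind(i0 + 1, j0 + 1)] * tx * ty
}
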