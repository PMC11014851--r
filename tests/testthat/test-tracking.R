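test_that("control-volume seeding tiles the mask deterministically", {
  cal <- smallCal(px = 0.5)
  mask <- cellMask(matrix(TRUE, 20, 20)) # exactly 10 x 10 um

  cvs <- seedControlVolumes(mask, cal, targetArea = 1)
  expect_length(cvs, 100)
  areas <- vapply(cvs, function(cv) polygonArea(corners(cv)), numeric(1))
  expect_equal(areas, rep(1, 100), tolerance = 1e-12)
  expect_identical(vapply(cvs, cvId, integer(1)), 1:100)

  cvs7 <- seedControlVolumes(mask, cal, targetArea = 0.7)
  a7 <- vapply(cvs7, function(cv) polygonArea(corners(cv)), numeric(1))
  expect_equal(a7, rep(0.7, length(cvs7)), tolerance = 1e-12)
  side <- corners(cvs7[[1]])[2, 1] - corners(cvs7[[1]])[1, 1]
  expect_equal(side, sqrt(0.7), tolerance = 1e-12)

  expect_error(seedControlVolumes(cellMask(matrix(FALSE, 20, 20)), cal),
               "empty")
})

test_that("advection moves corners with the interpolated flow", {
  cv <- squareCV(15, 15, sqrt(0.7))

  zero <- uniformField(0, 0)
  a0 <- advectControlVolume(cv, zero)
  expect_equal(corners(a0), corners(cv))

  # rigid translation preserves area
  uni <- uniformField(1, 0)
  a1 <- advectControlVolume(cv, uni, dt = 1)
  expect_equal(corners(a1), corners(cv) + cbind(rep(1, 4), rep(0, 4)))
  expect_equal(polygonArea(corners(a1)), 0.7, tolerance = 1e-12)
  expect_true(attr(a1, "inBounds"))

  # linear shear u = k*y: closed-form parallelogram, area preserved
  k <- 0.04
  nn <- 7
  g <- seq(2, 28, length.out = nn)
  shear <- new("VelocityField", gridX = g, gridY = g,
               u = matrix(rep(k * g, times = nn), nn, nn), # u = k*y, rows = y
               v = matrix(0, nn, nn),
               valid = matrix(TRUE, nn, nn), dt = 1)
  a2 <- advectControlVolume(cv, shear, dt = 2)
  p <- corners(cv)
  expected <- p + cbind(k * p[, 2] * 2, 0)
  expect_equal(corners(a2), expected, tolerance = 1e-9)
  expect_equal(polygonArea(corners(a2)), 0.7, tolerance = 1e-12)
})

test_that("mass integration matches closed forms and tiles additively", {
  cal <- smallCal(px = 0.25)
  d <- matrix(1, 80, 80) # uniform 1 pg/um^2
  mf <- massFrame(d, 0, cal)

  cv <- squareCV(10.13, 9.77, sqrt(0.7))
  expect_equal(integrateMass(cv, mf), 0.7, tolerance = 1e-3)
  expect_equal(integrateMass(cv, mf, method = "supersample"), 0.7,
               tolerance = 2e-3)
  # the two integration paths agree closely
  set.seed(2)
  for (i in 1:5) {
    cvr <- squareCV(runif(1, 5, 15), runif(1, 5, 15), sqrt(0.7))
    expect_lt(abs(integrateMass(cvr, mf) -
                  integrateMass(cvr, mf, method = "supersample")), 1e-3)
  }

  # zero-density background
  z <- massFrame(matrix(0, 40, 40), 0, cal)
  expect_equal(integrateMass(cv, z), 0)

  # two volumes tiling a rectangle sum to the region mass
  set.seed(9)
  dr <- matrix(abs(rnorm(80 * 80, 1, 0.3)), 80, 80)
  mfr <- massFrame(dr, 0, cal)
  left <- squareCV(9.5, 10, 1); right <- squareCV(10.5, 10, 1)
  whole <- new("ControlVolume",
               corners = rbind(c(9, 9.5), c(11, 9.5), c(11, 10.5), c(9, 10.5)),
               id = 3L, seedCenter = c(10, 10))
  expect_lt(abs(integrateMass(left, mfr) + integrateMass(right, mfr) -
                integrateMass(whole, mfr)), 2e-3)

  # degenerate polygon reports zero with a flag
  deg <- cv
  deg@corners <- rbind(c(5, 5), c(5, 5), c(5, 5), c(5, 5))
  m <- integrateMass(deg, mf)
  expect_equal(as.numeric(m), 0)
  expect_true(attr(m, "degenerate"))
})

test_that("tracking preserves mass for static and rigidly moving scenes", {
  # static frames + zero fields: constant mass series
  set.seed(4)
  d <- matrix(abs(rnorm(60 * 60, 1, 0.2)), 60, 60)
  frames <- massMovie(rep(list(d), 5))
  fields <- rep(list(uniformField(0, 0, fov = 15)), 4)
  cvs <- list(squareCV(7, 7, sqrt(0.7)), squareCV(8, 8, sqrt(0.7), id = 2L))
  tr <- trackControlVolumes(frames, fields, cvs)
  for (t in tr) {
    m <- trackTable(t)$mass_pg
    expect_equal(m, rep(m[1], 5))
  }
  expect_error(trackControlVolumes(frames, fields[1:2], cvs), "one velocity")

  # rigid-translation movie of a fixed distribution: per-track mass constant
  base <- renderMovie(syntheticScene(shape = c(96L, 96L), nFrames = 1,
                                     texture = list(radius = 5), seed = 8))
  baseMF <- phaseToMass(base$frames[[1]], base$calibration)
  fx <- fixedCellFixture(baseMF, outer(0:9, c(0.3, 0.2)), noiseSigma = 0,
                         seed = 1)
  mf <- lapply(fx$frames, function(f) phaseToMass(f, fx$calibration))
  exact <- uniformField(0.3 * 0.25, 0.2 * 0.25, fov = 24)
  cvsT <- seedControlVolumes(segmentCell(mf[[1]]), fx$calibration)
  trT <- trackControlVolumes(mf, rep(list(exact), 9), cvsT)
  rel <- vapply(trT, function(t) {
    m <- trackTable(t)$mass_pg
    max(abs(m / m[1] - 1))
  }, numeric(1))
  expect_lt(stats::median(rel), 0.02)
})
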