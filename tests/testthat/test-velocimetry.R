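test_that("window correlation recovers known shifts", {
  tex <- smoothTexture(64, sigma = 1.3, seed = 1)
  wa <- tex[25:40, 25:40]

  # identity
  r <- correlateWindow(wa, wa, 8)
  expect_equal(c(r$dx, r$dy), c(0, 0), tolerance = 1e-8)
  expect_true(r$valid)

  # circular integer roll by (+3, -2): exact at the integer stage
  rolled <- wa[c(3:16, 1:2), c(14:16, 1:13)] # rows up 2 => dy -2; cols +3
  r2 <- correlateWindow(wa, rolled, 8)
  expect_identical(c(r2$dxInt, r2$dyInt), c(3, -2))

  # subpixel Fourier shift, template-in-region geometry
  big <- fourierShift(tex, 0.3, 0)[17:48, 17:48]
  r3 <- correlateWindow(wa, big, 8)
  expect_lt(abs(r3$dx - 0.3), 0.05)
  expect_lt(abs(r3$dy), 0.05)

  # flat window flags invalid instead of throwing
  r4 <- correlateWindow(matrix(1, 16, 16), matrix(1, 16, 16), 8)
  expect_false(r4$valid)
})

test_that("subpixel shifts are recovered within 0.05 px RMS over many windows", {
  tex <- smoothTexture(120, sigma = 1.3, seed = 5)
  sh <- fourierShift(tex, 0.3, -0.2)
  err <- c()
  for (i0 in seq(17, 73, 8)) {
    for (j0 in seq(17, 73, 8)) {
      r <- correlateWindow(tex[i0:(i0 + 15), j0:(j0 + 15)],
                           sh[(i0 - 8):(i0 + 23), (j0 - 8):(j0 + 23)], 8)
      err <- c(err, r$dx - 0.3, r$dy + 0.2)
    }
  }
  expect_lt(sqrt(mean(err^2)), 0.05)
})

test_that("velocity field recovers rigid translation and respects bounds", {
  sc <- syntheticScene(shape = c(96L, 96L), nFrames = 2,
                       velocity = list(type = "uniform", u = 0.25, v = 0),
                       seed = 3)
  mv <- renderMovie(sc)
  mf <- lapply(mv$frames, function(f) phaseToMass(f, mv$calibration))
  fld <- suppressWarnings(computeVelocityField(mf[[1]], mf[[2]]))
  uu <- fld@u[fld@valid]; vv <- fld@v[fld@valid]
  expect_gt(sum(fld@valid), 8)
  expect_lt(abs(mean(uu) - 0.25), 0.05 * 0.25)
  expect_lt(abs(mean(vv)), 0.05 * 0.25)

  # magnitude bound: |v| <= searchRadius * pixel / dt
  expect_true(all(sqrt(fld@u^2 + fld@v^2) <= 8 * 0.25 / 1 + 1e-9))

  # antisymmetry under frame-order reversal
  mfR <- list(massFrame(density(mf[[2]]), 0, mv$calibration),
              massFrame(density(mf[[1]]), 1, mv$calibration))
  fldR <- suppressWarnings(computeVelocityField(mfR[[1]], mfR[[2]]))
  both <- fld@valid & fldR@valid
  expect_lt(max(abs(fld@u[both] + fldR@u[both])), 0.1 * 0.25)

  # a pair with no usable texture anywhere is rejected
  flat <- massMovie(list(matrix(0, 96, 96), matrix(0, 96, 96)))
  expect_error(computeVelocityField(flat[[1]], flat[[2]]),
               "valid velocity vectors")
})

test_that("sampling guard warns when displacements outrun the resolution", {
  sc <- syntheticScene(shape = c(96L, 96L), nFrames = 2,
                       velocity = list(type = "uniform", u = 0.5, v = 0),
                       seed = 3)
  mv <- renderMovie(sc)
  mf <- lapply(mv$frames, function(f) phaseToMass(f, mv$calibration))
  expect_warning(computeVelocityField(mf[[1]], mf[[2]]), "undersample")
})

test_that("median validation flags spikes and degenerate fields error", {
  f <- uniformField(0.1, 0, nNodes = 7)
  filtered <- medianFilterVectors(f, 3)
  expect_equal(filtered@u, f@u)
  expect_true(all(filtered@valid))

  spiked <- f
  spiked@u[4, 4] <- 2
  fs <- medianFilterVectors(spiked, 3)
  expect_false(fs@valid[4, 4])
  expect_equal(fs@u[4, 4], 0.1)

  allBad <- new("VelocityField", gridX = f@gridX, gridY = f@gridY,
                u = f@u * NA, v = f@v * NA,
                valid = matrix(FALSE, 7, 7), dt = 1)
  expect_error(qpigrowth:::infillInvalid(allBad), "infill")
})

test_that("velocity interpolation is bilinear and exact on linear fields", {
  f <- uniformField(0.3, -0.1, nNodes = 7)
  # exactly on a node
  p <- cbind(f@gridX[3], f@gridY[5])
  expect_equal(as.numeric(interpolateVelocity(f, p)), c(0.3, -0.1))

  # uniform everywhere, including outside the node hull (clamped)
  pts <- cbind(c(0.1, 15, 29.5), c(0.1, 7.2, 29.9))
  v <- interpolateVelocity(f, pts)
  expect_true(all(abs(v[, 1] - 0.3) < 1e-12))

  # u = x reproduced exactly at interior points
  lin <- f
  lin@u <- matrix(rep(f@gridX, each = 7), 7, 7)
  q <- cbind(c(5.1, 12.34, 20.0), c(6, 14, 22))
  expect_equal(as.numeric(interpolateVelocity(lin, q)[, 1]), q[, 1],
               tolerance = 1e-12)
})
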