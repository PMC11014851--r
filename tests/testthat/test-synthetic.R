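test_that("static scenes render constant movies", {
  sc <- syntheticScene(shape = c(64L, 64L), nFrames = 4, noiseSigma = 0,
                       texture = list(radius = 3.5), seed = 2)
  mv <- renderMovie(sc)
  for (k in 2:4)
    expect_identical(opd(mv$frames[[k]]), opd(mv$frames[[1]]))
  expect_equal(vapply(mv$frames, timestamp, numeric(1)), 0:3)
})

test_that("uniform specific growth follows the exponential closed form", {
  g <- 0.1
  sc <- syntheticScene(shape = c(64L, 64L), nFrames = 13, noiseSigma = 0,
                       texture = list(radius = 3.5),
                       source = list(type = "uniform_specific", g = g),
                       seed = 2)
  mv <- renderMovie(sc)
  m <- mv$truth$totalMass
  expected <- m[1] * exp(g * (0:12) / 60)
  expect_equal(m, expected, tolerance = 1e-3)
})

test_that("pure advection conserves in-frame mass", {
  sc <- syntheticScene(shape = c(96L, 96L), nFrames = 21, noiseSigma = 0,
                       texture = list(radius = 4),
                       velocity = list(type = "uniform", u = 0.2, v = 0.1),
                       seed = 6)
  mv <- renderMovie(sc)
  m <- mv$truth$totalMass
  expect_lt(max(abs(m / m[1] - 1)), 0.005)

  # rotation too (divergence-free)
  scr <- syntheticScene(shape = c(96L, 96L), nFrames = 21, noiseSigma = 0,
                        texture = list(radius = 4),
                        velocity = list(type = "rotation", omega = 0.02,
                                        center = c(12, 12)),
                        seed = 6)
  mr <- renderMovie(scr)$truth$totalMass
  expect_lt(max(abs(mr / mr[1] - 1)), 0.005)
})

test_that("rendering is deterministic in the seed", {
  sc <- syntheticScene(shape = c(48L, 48L), nFrames = 3, seed = 11)
  a <- renderMovie(sc)
  b <- renderMovie(sc)
  for (k in 1:3)
    expect_identical(opd(a$frames[[k]]), opd(b$frames[[k]]))

  # different seed: same deterministic truth family, different noise
  sc2 <- syntheticScene(shape = c(48L, 48L), nFrames = 3, seed = 12)
  c <- renderMovie(sc2)
  expect_false(identical(opd(a$frames[[1]]), opd(c$frames[[1]])))
})

test_that("the flow maps invert the prescribed velocities", {
  sc <- syntheticScene(shape = c(48L, 48L), nFrames = 2,
                       velocity = list(type = "rotation", omega = 0.05,
                                       center = c(6, 6)), seed = 1)
  p <- c(8.3, 4.1)
  fwd <- qpigrowth:::sceneFlowForward(sc, p, t = 7)
  back <- sceneFlowBack(sc, fwd[1], fwd[2], t = 7)
  expect_equal(as.numeric(back), p, tolerance = 1e-12)

  scs <- syntheticScene(shape = c(48L, 48L), nFrames = 2,
                        velocity = list(type = "shear", k = 0.03), seed = 1)
  fs <- qpigrowth:::sceneFlowForward(scs, p, t = 5)
  bs <- sceneFlowBack(scs, fs[1], fs[2], t = 5)
  expect_equal(as.numeric(bs), p, tolerance = 1e-12)
})

test_that("fixed-cell fixture honours its zero-growth and seed contracts", {
  base <- renderMovie(syntheticScene(shape = c(80L, 80L), nFrames = 1,
                                     texture = list(radius = 4), seed = 3))
  baseMF <- phaseToMass(base$frames[[1]], base$calibration)

  # zero shifts, zero noise: a constant movie
  still <- fixedCellFixture(baseMF, matrix(0, 5, 2), noiseSigma = 0)
  for (k in 2:5)
    expect_equal(opd(still$frames[[k]]), opd(still$frames[[1]]),
                 tolerance = 1e-12)

  # same seed, same noise; different seed, different noise, same truth
  a <- fixedCellFixture(baseMF, outer(0:3, c(0.2, 0)), seed = 5)
  b <- fixedCellFixture(baseMF, outer(0:3, c(0.2, 0)), seed = 5)
  c <- fixedCellFixture(baseMF, outer(0:3, c(0.2, 0)), seed = 6)
  expect_identical(opd(a$frames[[2]]), opd(b$frames[[2]]))
  expect_false(identical(opd(a$frames[[2]]), opd(c$frames[[2]])))

  # shifts that would clip the cell are refused
  expect_error(fixedCellFixture(baseMF, outer(0:30, c(3, 0))), "clipped")
})

test_that("scenes that outrun the default search radius warn", {
  sc <- syntheticScene(shape = c(64L, 64L), nFrames = 2,
                       velocity = list(type = "uniform", u = 2.5, v = 0),
                       seed = 1)
  expect_warning(renderMovie(sc), "search radius")
})
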