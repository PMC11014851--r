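test_that("background correction removes constant offsets and planes", {
  set.seed(3)
  nr <- 40
  base <- matrix(0, nr, nr)
  base[15:25, 15:25] <- 0.2 # the "cell"
  mask <- cellMask(base > 0)

  # constant offset comes straight back off
  f <- phaseFrame(base + 0.07)
  corr <- backgroundCorrect(f, mask)
  expect_lt(max(abs(opd(corr) - base)), 1e-9)

  # planar ramp a*x + b*y + c: off-cell residual at numerical zero,
  # matching an independent least-squares plane fit
  xs <- matrix(rep(seq_len(nr) - 0.5, each = nr), nr, nr)
  ys <- matrix(rep(seq_len(nr) - 0.5, times = nr), nr, nr)
  ramp <- 2e-3 * xs - 1e-3 * ys + 0.05
  f2 <- phaseFrame(base + ramp)
  corr2 <- backgroundCorrect(f2, mask)
  bg <- !maskMatrix(mask)
  expect_lt(sqrt(mean(opd(corr2)[bg]^2)), 1e-6)
  oracle <- stats::lm(ramp[bg] ~ xs[bg] + ys[bg])
  expect_lt(max(abs(stats::residuals(oracle))), 1e-9)

  # idempotence: correcting a corrected frame is a no-op
  corr3 <- backgroundCorrect(corr2, mask)
  expect_lt(max(abs(opd(corr3) - opd(corr2))), 1e-9)

  # unusable mask
  full <- cellMask(matrix(TRUE, nr, nr))
  expect_error(backgroundCorrect(f, full), "background")
})

test_that("phase-to-mass conversion applies the refractive increment exactly", {
  cal <- Calibration(pixelSize = 1, frameInterval = 1,
                     refractiveIncrement = 0.18)
  z <- phaseToMass(phaseFrame(matrix(0, 5, 5)), cal)
  expect_true(all(density(z) == 0))

  # uniform 0.18 um OPD at alpha = 0.18 um^3/pg over 1 um^2 pixels -> 1 pg
  m <- phaseToMass(phaseFrame(matrix(0.18, 5, 5)), cal)
  expect_equal(density(m)[3, 3], 1)
  expect_equal(totalMass(m, cellMask(matrix(TRUE, 5, 5))), 25)

  # linearity and exact invertibility
  set.seed(7)
  o <- matrix(abs(rnorm(64, 0.1, 0.03)), 8, 8)
  m1 <- phaseToMass(phaseFrame(o), cal)
  m2 <- phaseToMass(phaseFrame(2 * o), cal)
  expect_equal(density(m2), 2 * density(m1))
  expect_equal(density(m1) * refractiveIncrement(cal), o, tolerance = 1e-15)

  # a non-positive refractive increment is rejected at construction
  expect_error(Calibration(1, 1, refractiveIncrement = -0.1), "positive")
})

test_that("cell segmentation recovers a disk and keeps the largest component", {
  cal <- smallCal(px = 0.25)
  nr <- 80
  xs <- matrix(rep(seq_len(nr) - 0.5, each = nr), nr, nr)
  ys <- matrix(rep(seq_len(nr) - 0.5, times = nr), nr, nr)
  disk <- (sqrt((xs - 40)^2 + (ys - 40)^2) <= 24) * 1.0
  mf <- massFrame(disk, 0, cal)
  # sigma = 0: pure threshold, so the boundary is set by rasterization only
  seg <- segmentCell(mf, sigma = 0)
  band <- abs(sqrt((xs - 40)^2 + (ys - 40)^2) - 24) <= 1.5
  expect_true(all((maskMatrix(seg) == (disk > 0))[!band]))
  # with smoothing on, the mask may dilate slightly but stays a superset
  segS <- segmentCell(mf)
  expect_true(all(maskMatrix(segS)[disk > 0]))

  expect_error(segmentCell(massFrame(matrix(0, 20, 20), 0, cal)), "empty")

  two <- matrix(0, nr, nr)
  two[sqrt((xs - 25)^2 + (ys - 25)^2) <= 15] <- 1
  two[sqrt((xs - 62)^2 + (ys - 62)^2) <= 6] <- 1
  segTwo <- segmentCell(massFrame(two, 0, cal))
  # keep-largest: the small disk is dropped
  expect_false(any(maskMatrix(segTwo)[sqrt((xs - 62)^2 + (ys - 62)^2) <= 4]))
  expect_true(all(maskMatrix(segTwo)[sqrt((xs - 25)^2 + (ys - 25)^2) <= 13]))
})

test_that("total mass sums density over the mask and is additive", {
  cal <- smallCal(px = 0.5)
  d <- matrix(2, 10, 10)
  mask50 <- matrix(FALSE, 10, 10); mask50[1:5, ] <- TRUE # 50 px
  mf <- massFrame(d, 0, cal)
  expect_equal(totalMass(mf, cellMask(mask50)), 2 * 50 * 0.25)

  expect_equal(totalMass(mf, cellMask(matrix(FALSE, 10, 10))), 0)
  expect_equal(totalMass(massFrame(matrix(0, 10, 10), 0, cal),
                         cellMask(matrix(TRUE, 10, 10))), 0)

  other <- !mask50
  expect_equal(totalMass(mf, cellMask(mask50)) + totalMass(mf, cellMask(other)),
               totalMass(mf, cellMask(matrix(TRUE, 10, 10))))
})
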