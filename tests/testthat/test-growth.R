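test_that("growth-rate fitting matches closed-form least squares", {
  t_min <- seq(0, 30, by = 1)

  # constant series: exactly zero slope
  est0 <- fitGrowthRate(seriesTrack(t_min, rep(5, 31)))
  expect_equal(est0$rate_pg_per_h, 0, tolerance = 1e-12)
  expect_true(est0$valid)

  # exact line in hours: 10 + 0.5*t_h
  est1 <- fitGrowthRate(seriesTrack(t_min, 10 + 0.5 * t_min / 60))
  expect_equal(est1$rate_pg_per_h, 0.5, tolerance = 1e-12)
  expect_equal(est1$mass0_pg, 10)

  # too few usable frames
  est2 <- fitGrowthRate(seriesTrack(c(0, 1), c(1, 1)))
  expect_false(est2$valid)

  # window restriction uses only in-window samples
  est3 <- fitGrowthRate(seriesTrack(t_min, c(rep(1, 16), rep(9, 15))),
                        window = c(0, 15))
  expect_equal(est3$rate_pg_per_h, 0)
  expect_equal(est3$n_frames, 16)
})

test_that("OLS slope coverage: 3*SE contains the truth in >= 99% of replicates", {
  t_h <- seq(0, 30, by = 1) / 60
  n <- length(t_h)
  hits <- withr::with_seed(202, {
    vapply(seq_len(1000), function(i) {
      m <- 10 + 0.5 * t_h + stats::rnorm(n, sd = 0.05)
      est <- fitGrowthRate(seriesTrack(t_h * 60, pmax(m, 0)))
      abs(est$rate_pg_per_h - 0.5) < 3 * est$rate_se
    }, logical(1))
  })
  expect_gte(mean(hits), 0.99)
})

test_that("window schedules follow the arithmetic of length and step", {
  expect_equal(qpigrowth:::windowSchedule(0, 240, 120, 60), c(0, 60, 120))
  expect_equal(qpigrowth:::windowSchedule(0, 30, 30, 30), 0)
  expect_error(qpigrowth:::windowSchedule(0, 20, 30, 10), "duration")
  expect_error(qpigrowth:::windowSchedule(0, 240, 120, 0), "positive")
})

test_that("growth maps rasterize per-volume rates onto seed footprints", {
  cal <- smallCal(px = 0.25)
  shape <- c(60, 60)
  side <- sqrt(0.7)
  cvs <- list(squareCV(5, 5, side, 1L), squareCV(5 + side, 5, side, 2L),
              squareCV(5, 5 + side, side, 3L), squareCV(5 + side, 5 + side, side, 4L))
  base <- data.frame(cv_id = 1:4, rate_pg_per_h = 1, rate_se = 0.1,
                     t_start = 0, t_end = 30, n_frames = 31, mass0_pg = 1,
                     valid = TRUE)

  # single volume
  m1 <- assembleGrowthMap(base[1, ], cvs[1], shape, cal)
  r1 <- growthRaster(m1)
  inside <- r1[19:22, 19:22] # pixels around (5, 5) um
  expect_true(all(inside == 1))
  expect_true(all(is.na(r1[40:60, 40:60])))

  # uniform rate over all volumes: constant over the union footprint
  mu <- assembleGrowthMap(base, cvs, shape, cal)
  def <- !is.na(growthRaster(mu))
  expect_true(all(growthRaster(mu)[def] == 1))

  # checkerboard of +/- g
  cb <- base
  cb$rate_pg_per_h <- c(1, -1, -1, 1)
  mc <- assembleGrowthMap(cb, cvs, shape, cal)
  rc <- growthRaster(mc)
  grab <- function(cx, cy) rc[round(cy / 0.25), round(cx / 0.25)]
  expect_equal(grab(5, 5), 1)
  expect_equal(grab(5 + side, 5), -1)
  expect_equal(grab(5, 5 + side), -1)
  expect_equal(grab(5 + side, 5 + side), 1)

  # invalid estimates leave no footprint
  inv <- base; inv$valid <- FALSE
  mi <- assembleGrowthMap(inv, cvs, shape, cal)
  expect_true(all(is.na(growthRaster(mi))))
})

test_that("windowed growth re-seeds per window and flags mitosis-like jumps", {
  sc <- syntheticScene(shape = c(96L, 96L), nFrames = 13,
                       texture = list(radius = 5), noiseSigma = 0, seed = 12)
  mv <- renderMovie(sc)
  mf <- cellMassMovie(mv)
  fields <- rep(list(uniformField(0, 0, fov = 24)), 12)

  res <- windowedGrowth(mf, fields, windowLen = 6, windowStep = 3)
  expect_length(res, 3) # starts at 0, 3, 6 min
  expect_true(all(!vapply(res, is.null, logical(1))))
  rates <- res[[1]]$estimates$rate_pg_per_h
  expect_lt(stats::median(abs(rates), na.rm = TRUE), 1e-6)

  # a mass discontinuity voids the window with a warning
  mfJump <- mf
  mfJump[[7]] <- massFrame(density(mf[[7]]) * 2, timestamp(mf[[7]]),
                           calibration(mf[[7]]))
  expect_warning(resJ <- windowedGrowth(mfJump, fields, windowLen = 12),
                 "mitosis")
  expect_null(resJ[[1]])
})
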