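test_that("region growth normalizes summed rates by region mass", {
  cal <- smallCal(px = 0.5)
  # uniform 1 pg/um^2 over 20x20 px of 0.25 um^2 -> 100 pg
  mf <- massFrame(matrix(1, 20, 20), 0, cal)
  mask <- cellMask(matrix(TRUE, 20, 20))
  cvs <- list(squareCV(5, 5, 1))
  est <- data.frame(cv_id = 1L, rate_pg_per_h = 2, rate_se = 0.1,
                    t_start = 0, t_end = 30, n_frames = 31, mass0_pg = 1,
                    valid = TRUE)
  rg <- regionGrowth(est, cvs, mask, mf)
  expect_equal(rg$total_rate_pg_per_h, 2)
  expect_equal(rg$region_mass_pg, 100)
  expect_equal(rg$specific_rate_per_h, 0.02)
  expect_equal(rg$n_volumes, 1L)

  est0 <- est; est0$rate_pg_per_h <- 0
  expect_equal(regionGrowth(est0, cvs, mask, mf)$specific_rate_per_h, 0)

  # zero-mass region is flagged, not divided
  empty <- massFrame(matrix(0, 20, 20), 0, cal)
  rgz <- regionGrowth(est, cvs, mask, empty)
  expect_false(rgz$mass_defined)
  expect_true(is.na(rgz$specific_rate_per_h))
})

test_that("nucleus and cytoplasm totals add up to the whole cell", {
  cal <- smallCal(px = 0.5)
  set.seed(5)
  mf <- massFrame(matrix(abs(rnorm(400, 1, 0.2)), 20, 20), 0, cal)
  cellM <- matrix(FALSE, 20, 20); cellM[3:18, 3:18] <- TRUE
  nucM <- matrix(FALSE, 20, 20); nucM[8:13, 8:13] <- TRUE
  cell <- cellMask(cellM)
  nuc <- cellMask(nucM, "nucleus")
  cyt <- cytoplasmMask(cell, nuc)

  cvs <- lapply(1:16, function(i)
    squareCV(1.5 + (i - 1) %% 4 * 2, 1.5 + (i - 1) %/% 4 * 2, 1, id = i))
  est <- data.frame(cv_id = 1:16, rate_pg_per_h = rnorm(16, 0.1, 0.3),
                    rate_se = 0.1, t_start = 0, t_end = 30, n_frames = 31,
                    mass0_pg = 1, valid = TRUE)
  whole <- regionGrowth(est, cvs, cell, mf)
  parts <- regionGrowth(est, cvs, nuc, mf)$total_rate_pg_per_h +
    regionGrowth(est, cvs, cyt, mf)$total_rate_pg_per_h
  expect_equal(parts, whole$total_rate_pg_per_h)
  expect_equal(regionGrowth(est, cvs, nuc, mf)$region_mass_pg +
               regionGrowth(est, cvs, cyt, mf)$region_mass_pg,
               whole$region_mass_pg)
})

test_that("puncta detection finds signed blobs and filters small ones", {
  cal <- smallCal(px = 0.25)
  r <- matrix(NA_real_, 80, 80)
  r[20:60, 20:60] <- 0 # defined region
  map0 <- new("GrowthMap", raster = r, window = c(0, 30), calibration = cal)
  expect_equal(nrow(detectPuncta(map0)), 0)

  # 2 um^2 positive blob (32 px at 0.0625 um^2/px) at 3x the threshold
  r1 <- r
  r1[30:37, 30:33] <- 0.3
  map1 <- new("GrowthMap", raster = r1, window = c(0, 30), calibration = cal)
  p1 <- detectPuncta(map1, thresholdRate = 0.1)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$sign, "positive")
  expect_equal(p1$area_um2, 2)
  expect_equal(p1$mean_rate_pg_per_h, 0.3)
  # centroid of the block
  expect_equal(p1$centroid_x_um, mean(c(30:33) - 0.5) * 0.25)
  expect_equal(p1$centroid_y_um, mean(c(30:37) - 0.5) * 0.25)

  # negative blob is reported with its sign
  r2 <- r; r2[40:47, 40:43] <- -0.3
  p2 <- detectPuncta(new("GrowthMap", raster = r2, window = c(0, 30),
                         calibration = cal), thresholdRate = 0.1)
  expect_equal(p2$sign, "negative")

  # below the minimum area: discarded
  r3 <- r; r3[30:31, 30:32] <- 0.3 # 6 px = 0.375 um^2 < 0.5
  expect_equal(nrow(detectPuncta(new("GrowthMap", raster = r3,
                                     window = c(0, 30), calibration = cal),
                                 thresholdRate = 0.1)), 0)

  # translation invariance: shifted map, shifted centroid, same size
  r4 <- r
  r4[35:42, 35:38] <- 0.3
  p4 <- detectPuncta(new("GrowthMap", raster = r4, window = c(0, 30),
                         calibration = cal), thresholdRate = 0.1)
  expect_equal(p4$area_um2, p1$area_um2)
  expect_equal(p4$centroid_x_um - p1$centroid_x_um, 5 * 0.25)
  expect_equal(p4$centroid_y_um - p1$centroid_y_um, 5 * 0.25)
})
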