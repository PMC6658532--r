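# synthetic-data generators: reproducibility and ground-truth physics

test_that("all generators are bit-reproducible under a fixed seed", {
  c1 <- simulateTwoStateTracks(twoStateSimConfig(nTracks = 20, seed = 7))
  c2 <- simulateTwoStateTracks(twoStateSimConfig(nTracks = 20, seed = 7))
  expect_identical(trackData(c1$tracks), trackData(c2$tracks))
  expect_identical(c1$truth, c2$truth)

  f1 <- simulateFixedEmitters(50, seed = 8)
  f2 <- simulateFixedEmitters(50, seed = 8)
  expect_identical(trackData(f1), trackData(f2))

  k1 <- simulateClusterField(clusterSimConfig(seed = 9))
  k2 <- simulateClusterField(clusterSimConfig(seed = 9))
  expect_identical(locData(k1$table), locData(k2$table))

  terr <- binaryMap(100, 100, setIdx = cbind(rep(40:60, 21),
                                             rep(40:60, each = 21)))
  d1 <- simulateDualChannelField(terr, 2, 500, seed = 10)
  d2 <- simulateDualChannelField(terr, 2, 500, seed = 10)
  expect_identical(locData(d1), locData(d2))
})

test_that("pure Brownian limit: MSD linear with slope 4D", {
  cfg <- twoStateSimConfig(nTracks = 600, DFree = 0.1, DBound = 0.1,
                           pBound = 0, confineBound = FALSE, sigmaAxis = 0,
                           substepsPerFrame = 1, trackLengthRange = c(20, 20),
                           roi = Rect(0, 0, 50000, 50000), seed = 11)
  sim <- simulateTwoStateTracks(cfg)
  md <- msdData(computeMSD(sim$tracks, maxLag = 4))
  fit <- lm(msd ~ lag, data = md)
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_lt(abs(unname(coef(fit)[2]) / 4 - 0.1), 0.003)
})

test_that("per-state single-step displacement variance matches 2 D dt per axis", {
  # one long unconfined track sampled at substep resolution
  cfg <- twoStateSimConfig(nTracks = 1, DFree = 0.08, DBound = 0.08,
                           pBound = 0, confineBound = FALSE, sigmaAxis = 0,
                           substepsPerFrame = 1,
                           trackLengthRange = c(1e6, 1e6),
                           roi = Rect(0, 0, 1000, 1000), seed = 12)
  sim <- simulateTwoStateTracks(cfg)
  d <- trackData(sim$tracks)
  vx <- stats::var(diff(d$x))
  expect_lt(abs(vx / (2 * 0.08 * 1e6 * 0.05) - 1), 0.01)
})

test_that("bound molecules stay confined to their disc; states follow pBound", {
  disc <- data.frame(cx = 2000, cy = 2000, r = 150)
  cfg <- twoStateSimConfig(nTracks = 200, pBound = 0.5,
                           junctionDiscs = disc, sigmaAxis = 0,
                           trackLengthRange = c(10, 10), seed = 13)
  sim <- simulateTwoStateTracks(cfg)
  bound <- sim$truth$state == "bound"
  expect_gt(mean(tapply(bound, sim$truth$track_id, any)), 0.35)
  rr <- sqrt((sim$truth$trueX[bound] - 2000)^2 +
             (sim$truth$trueY[bound] - 2000)^2)
  expect_true(all(rr <= 150 + 1e-9))
  # error on non-positive disc radius with confinement requested
  expect_error(twoStateSimConfig(junctionDiscs = data.frame(cx = 0, cy = 0,
                                                            r = 0)),
               "radius")
})

test_that("fixed emitters: MSD1 = 4 sigma_axis^2, zero when noiseless, quadratic scaling", {
  f0 <- simulateFixedEmitters(100, sigmaAxis = 0, seed = 14)
  expect_equal(msdData(computeMSD(f0, maxLag = 1))$msd, 0)

  f46 <- simulateFixedEmitters(10000, sigmaAxis = 46, seed = 15)
  msd1 <- msdData(computeMSD(f46, maxLag = 1))$msd
  expect_lt(abs(msd1 / (4 * 0.046^2) - 1), 0.03)

  f92 <- simulateFixedEmitters(10000, sigmaAxis = 92, seed = 15)
  msd2 <- msdData(computeMSD(f92, maxLag = 1))$msd
  expect_lt(abs(msd2 / msd1 - 4), 0.2)

  expect_error(simulateFixedEmitters(10, sigmaAxis = -1), "sigmaAxis")
})

test_that("cluster fields have the exact configured localization counts", {
  sim <- simulateClusterField(clusterSimConfig(seed = 16))
  # 17 x 32 clustered + 0.7% of 400 x 400 pixels background
  expect_equal(nLocalizations(sim$table), 17L * 32L + 1120L)
  expect_equal(sum(sim$truth > 0), 544L)
  expect_equal(sum(sim$truth == 0), 1120L)
  expect_equal(nrow(sim$centers), 17L)
  # all coordinates inside the ROI
  d <- locData(sim$table)
  expect_true(all(d$x >= 0 & d$x <= 4000 & d$y >= 0 & d$y <= 4000))

  # background zero: exactly n_clusters * locsPerCluster records
  sim0 <- simulateClusterField(clusterSimConfig(backgroundPixelFraction = 0,
                                                seed = 17))
  expect_equal(nLocalizations(sim0$table), 544L)

  expect_error(clusterSimConfig(backgroundPixelFraction = 1), "\\[0, 1\\)")
  expect_error(clusterSimConfig(discDiameter = 5000), "fit")
})

test_that("dual-channel fields realize the planted enrichment normalization", {
  # territory covering 10% of the raster
  nx <- 200
  g <- matrix(0, nx, nx)
  g[1:nx, 1:(nx / 10)] <- 1
  terr <- PixelMap(g, 10, c(0, 0), binary = TRUE)

  insideFrac <- function(tab) {
    d <- locData(tab)
    mean(d$y < nx * 10 / 10)   # territory = lowest 10% of rows in y
  }
  # e = 3, 10% territory: expected inside fraction 3*0.1/(3*0.1+0.9) = 0.25
  t3 <- simulateDualChannelField(terr, 3, 8000, seed = 18)
  expect_lt(abs(insideFrac(t3) - 0.25), 0.02)
  # e = 1: uniform, inside fraction = areal fraction
  t1 <- simulateDualChannelField(terr, 1, 8000, seed = 19)
  expect_lt(abs(insideFrac(t1) - 0.10), 0.02)
  # e = 0: no localization inside the territory
  t0 <- simulateDualChannelField(terr, 0, 2000, seed = 20)
  expect_equal(insideFrac(t0), 0)

  expect_error(simulateDualChannelField(terr, -1, 10), "enrichment")
  full <- PixelMap(matrix(1, 10, 10), 10, c(0, 0), binary = TRUE)
  expect_error(simulateDualChannelField(full, 2, 10), "neither empty nor full")
})
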