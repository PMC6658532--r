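# MSD computation, calibration, corrected estimators, confinement, step
# histograms

test_that("computeMSD matches hand-enumerated interval averages", {
  # 3 collinear points with step d = 100 nm
  t3 <- TrackSet(straightTrack(2, 100))
  md <- msdData(computeMSD(t3, maxLag = 2))
  expect_equal(md$msd, c(0.01^2 * 100, 0.02^2 * 100) / 1)  # 1e-4, 4e-4 um^2
  expect_equal(md$msd[2] / md$msd[1], 4)

  # 4-point track (0,0),(1,0),(1,1),(2,1) in units of 100 nm
  t4 <- TrackSet(data.frame(track_id = 1, frame = 0:3,
                            x = c(0, 100, 100, 200), y = c(0, 0, 100, 100)))
  mo <- msdData(computeMSD(t4, maxLag = 2, overlapping = TRUE))
  expect_equal(mo$msd[1], (1 + 1 + 1) / 3 * 0.01)
  expect_equal(mo$msd[2], (2 + 2) / 2 * 0.01)
  expect_equal(mo$n, c(3L, 2L))

  # non-overlapping: lag-1 steps {0-1, 2-3} only
  mn <- msdData(computeMSD(t4, maxLag = 2, overlapping = FALSE))
  expect_equal(mn$n[1], 2L)
  expect_equal(mn$msd[1], (1 + 1) / 2 * 0.01)

  expect_error(computeMSD(t3, maxLag = 10), "maxLag")
})

test_that("localization calibration reproduces the fixed-cell arithmetic", {
  cal <- calibrateLocalization(0.0085)
  expect_equal(cal@sigma2d, sqrt(0.0085 / 2) * 1e3)
  expect_equal(round(cal@sigma2d), 65)
  expect_equal(round(cal@sigmaAxis), 46)

  expect_equal(calibrateLocalization(0)@sigma2d, 0)
  expect_equal(round(calibrateLocalization(0.0170)@sigma2d), 92)
})

test_that("single-step estimator applies the 1.5 blur and fixed-cell corrections", {
  expect_equal(diffusionCoef(estimateD1(0.0147, 0.0085)),
               1.5 * (0.0147 - 0.0085) / 0.2)
  expect_equal(diffusionCoef(estimateD1(0.0085, 0.0085)), 0)
  expect_equal(diffusionCoef(estimateD1(0.0197, 0.0085)), 0.084)
  neg <- estimateD1(0.005, 0.0085)
  expect_true(neg@flagged)
  expect_lt(diffusionCoef(neg), 0)
})

test_that("slope estimator needs no correction and matches the linear case", {
  expect_equal(diffusionCoef(estimateD2(0.02, 0.04)), 0.1)
  expect_equal(diffusionCoef(estimateD2(0.03, 0.03)), 0)
})

test_that("D1 and D2 agree and recover D on simulated free diffusion with blur and noise", {
  cfg <- twoStateSimConfig(nTracks = 2500, DFree = 0.1, DBound = 0.1,
                           pBound = 0, confineBound = FALSE, sigmaAxis = 46,
                           substepsPerFrame = 10, trackLengthRange = c(12, 12),
                           roi = Rect(0, 0, 50000, 50000), seed = 25)
  sim <- simulateTwoStateTracks(cfg)
  md <- msdData(computeMSD(sim$tracks, maxLag = 2))
  msd1Fixed <- 4 * 0.046^2
  D1 <- diffusionCoef(estimateD1(md$msd[1], msd1Fixed))
  D2 <- diffusionCoef(estimateD2(md$msd[1], md$msd[2]))
  expect_lt(abs(D1 - 0.1) / 0.1, 0.03)
  expect_lt(abs(D2 - 0.1) / 0.1, 0.03)
  expect_lt(abs(D1 - D2) / 0.1, 0.03)
})

test_that("confinement radius converts plateaus and recovers a planted disc", {
  cal <- calibrateLocalization(0.0085)
  cc <- estimateConfinementRadius(0.035, cal)
  expect_equal(cc@rc, sqrt(0.035 - 0.0085) * 1e3)
  expect_equal(round(cc@rc / 10) * 10, 160)
  expect_equal(estimateConfinementRadius(0.0085, cal)@rc, 0)
  expect_warning(r0 <- estimateConfinementRadius(0.005, cal), "floor")
  expect_equal(r0@rc, 0)

  # stroboscopic sampling isolates confinement from motion blur
  cfg <- twoStateSimConfig(nTracks = 900, DFree = 0.0394, DBound = 0.0394,
                           pBound = 1,
                           junctionDiscs = data.frame(cx = 2000, cy = 2000,
                                                      r = 150),
                           sigmaAxis = 46, substepsPerFrame = 10,
                           blur = FALSE, trackLengthRange = c(12, 12),
                           seed = 26)
  curve <- computeMSD(simulateTwoStateTracks(cfg)$tracks, maxLag = 10)
  rc <- estimateConfinementRadius(curve, cal)@rc
  expect_lt(abs(rc - 150), 10)
})

test_that("step histograms conserve interval counts and match the moment identity", {
  one <- TrackSet(straightTrack(1, 120))
  h <- stepHistogram(one, lag = 1, binWidth = 50)
  expect_equal(sum(h$count), 1)
  expect_equal(h$count[h$mid == 125], 1)

  cfg <- twoStateSimConfig(nTracks = 400, DFree = 0.1, DBound = 0.1,
                           pBound = 0, confineBound = FALSE, sigmaAxis = 46,
                           substepsPerFrame = 1, trackLengthRange = c(10, 10),
                           roi = Rect(0, 0, 50000, 50000), seed = 27)
  trk <- simulateTwoStateTracks(cfg)$tracks
  h1 <- stepHistogram(trk, lag = 1, binWidth = 10)
  curve <- computeMSD(trk, maxLag = 1)
  expect_equal(sum(h1$count), msdData(curve)$n[1])
  # second moment of the step distribution = 4 D tau + 4 sigma_axis^2
  m2 <- sum(h1$count * (h1$mid / 1e3)^2) / sum(h1$count)
  expect_lt(abs(m2 / (4 * 0.1 * 0.05 + 4 * 0.046^2) - 1), 0.03)
})
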