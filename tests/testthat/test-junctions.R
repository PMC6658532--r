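# junction masks, track classification, excursions, on-junction D,
# engagement fraction

test_that("junction masks follow the density-filter + dilation pipeline", {
  # six co-located STIM1 points: mask is the union of 5-px discs around them
  pts <- data.frame(frame = 0:5, x = 500 + 30 * cos(0:5),
                    y = 500 + 30 * sin(0:5))
  tab <- LocalizationTable(pts, roi = Rect(0, 0, 1000, 1000))
  jm <- buildJunctionMask(tab)
  expect_gt(sum(mapData(maskMap(jm))), 81)       # at least one dilated disc
  expect_equal(jm@provenance$dilatePixels, 5)

  # an isolated point contributes nothing
  iso <- LocalizationTable(rbind(pts, data.frame(frame = 6, x = 50, y = 50)),
                           roi = Rect(0, 0, 1000, 1000))
  jmIso <- buildJunctionMask(iso)
  expect_equal(mapData(maskMap(jmIso)), mapData(maskMap(jm)))

  # nothing survives the filter: empty mask with a warning
  sparse <- LocalizationTable(data.frame(frame = 0:2, x = c(10, 500, 990),
                                         y = c(10, 500, 990)),
                              roi = Rect(0, 0, 1000, 1000))
  expect_warning(jm0 <- buildJunctionMask(sparse), "empty")
  expect_equal(sum(mapData(maskMap(jm0))), 0)
})

test_that("junction mask area tracks planted disc area on simulated junctions", {
  set.seed(28)
  discs <- data.frame(cx = c(1000, 2500, 3200), cy = c(1200, 2800, 900),
                      r = 150)
  pts <- do.call(rbind, lapply(seq_len(nrow(discs)), function(i) {
    rr <- discs$r[i] * sqrt(runif(40)); th <- runif(40, 0, 2 * pi)
    data.frame(x = discs$cx[i] + rr * cos(th), y = discs$cy[i] + rr * sin(th))
  }))
  tab <- LocalizationTable(data.frame(frame = seq_len(nrow(pts)) - 1,
                                      x = pts$x, y = pts$y),
                           roi = Rect(0, 0, 4000, 4000))
  jm <- buildJunctionMask(tab)
  g <- mapData(maskMap(jm))
  # the mask covers most of each planted disc and never extends beyond the
  # disc expanded by the 50-nm gap-filling dilation
  idx <- which(g > 0, arr.ind = TRUE)
  px <- (idx[, 1] - 0.5) * 10; py <- (idx[, 2] - 0.5) * 10
  dToDisc <- sapply(seq_len(nrow(discs)), function(i)
    sqrt((px - discs$cx[i])^2 + (py - discs$cy[i])^2) - discs$r[i])
  expect_lte(max(apply(dToDisc, 1, min)), 50 + 15)  # + pixel diagonal slack
  probe <- expand.grid(dx = seq(-140, 140, by = 20),
                       dy = seq(-140, 140, by = 20))
  probe <- probe[probe$dx^2 + probe$dy^2 <= 140^2, ]
  coveredFrac <- vapply(seq_len(nrow(discs)), function(i) {
    ix <- junctionPALM:::pixelIndex(discs$cx[i] + probe$dx, 0, 10)
    iy <- junctionPALM:::pixelIndex(discs$cy[i] + probe$dy, 0, 10)
    mean(g[cbind(ix, iy)] > 0)
  }, numeric(1))
  expect_gte(min(coveredFrac), 0.7)
})

test_that("track classification is exhaustive, exclusive, and rule-faithful", {
  mask <- new("JunctionMask",
              mask = binaryMap(100, 100,
                               setIdx = cbind(rep(40:60, 21),
                                              rep(40:60, each = 21))),
              provenance = list())
  trks <- TrackSet(rbind(
    data.frame(track_id = 1, frame = 0:3, x = 500, y = c(500, 510, 505, 495)),
    data.frame(track_id = 2, frame = 0:3, x = 100, y = c(100, 110, 105, 95)),
    data.frame(track_id = 3, frame = 0:3, x = c(385, 390, 405, 500), y = 500)))
  cls <- classifyTracks(trks, mask)
  expect_equal(as.character(cls$class), c("on", "off", "excluded"))
  expect_false(any(is.na(cls$class)))

  # partition property on a simulation with a realistic clustered mask
  sim <- simulateTwoStateTracks(twoStateSimConfig(nTracks = 150, seed = 29))
  stim <- simulateClusterField(clusterSimConfig(seed = 30))$table
  jm <- buildJunctionMask(stim)
  clsSim <- classifyTracks(sim$tracks, jm)
  expect_equal(nrow(clsSim), nTracks(sim$tracks))
  expect_true(all(table(clsSim$track_id) == 1))
})

test_that("maximum excursion measures the largest displacement from the start", {
  # monotone straight track: 6 steps of 50 nm -> 300 nm
  ex1 <- maxExcursion(TrackSet(straightTrack(6, 50)))
  expect_equal(ex1$dMax, 300)
  expect_equal(ex1$nSteps, 6L)

  # 3-4-5 triangle: maximum at the intermediate point
  t2 <- TrackSet(data.frame(track_id = 1, frame = 0:2,
                            x = c(0, 300, 100), y = c(0, 400, 100)))
  expect_equal(maxExcursion(t2, stepRange = NULL)$dMax, 500)

  # invariance under rotation + translation
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  d <- trackData(t2)
  xy <- t(R %*% t(cbind(d$x, d$y))) + 1000
  t2r <- TrackSet(data.frame(track_id = 1, frame = 0:2,
                             x = xy[, 1], y = xy[, 2]))
  expect_equal(maxExcursion(t2r, stepRange = NULL)$dMax, 500)

  # step-range filter keeps 6-25 steps only
  long <- TrackSet(straightTrack(30, 10))
  expect_equal(nrow(maxExcursion(long)), 0L)
})

test_that("excursion sampling is seeded, capped, and stable across seeds", {
  set.seed(31)
  pool <- data.frame(track_id = 1:8000, dMax = rlnorm(8000, 5, 0.5),
                     nSteps = 10L)
  s1 <- sampleExcursions(pool, n = 1500, seed = 32)
  s2 <- sampleExcursions(pool, n = 1500, seed = 32)
  expect_identical(s1$sample, s2$sample)
  s3 <- sampleExcursions(pool, n = 1500, seed = 33)
  semPool <- 1.2533 * sd(pool$dMax) / sqrt(1500)   # SE of a median, approx
  expect_lt(abs(s1$medianDMax - s3$medianDMax), 4 * semPool)
  expect_warning(sAll <- sampleExcursions(pool[1:100, ], n = 1500, seed = 1),
                 "taking all")
  expect_equal(nrow(sAll$sample), 100L)
})

test_that("on-junction single-step D follows the corrected estimator chain", {
  # all first steps 100 nm: mean r^2 = 0.01 um^2
  trks <- TrackSet(do.call(rbind, lapply(1:20, function(i)
    straightTrack(3, 100, id = i))))
  res <- onJunctionSingleStepD(trks, 0.0085)
  expect_equal(res$meanR2, 0.01)
  expect_equal(diffusionCoef(res$estimate), 1.5 * (0.01 - 0.0085) / 0.2)

  # printed worked value: mean r^2 = 0.0191 -> D = 0.0795 ~ 0.080
  expect_equal(diffusionCoef(estimateD1(0.0191, 0.0085)), 0.0795)

  expect_warning(onJunctionSingleStepD(TrackSet(straightTrack(3, 10)), 0.0085),
                 "fewer than 10")
})

test_that("on-junction mixtures sit between the pure-state coefficients, near the bound state", {
  discs <- data.frame(cx = 2000, cy = 2000, r = 160)
  base <- function(p, seed) {
    cfg <- twoStateSimConfig(nTracks = 700, pBound = p, junctionDiscs = discs,
                             startInDiscs = TRUE, trackLengthRange = c(8, 8),
                             seed = seed)
    sim <- simulateTwoStateTracks(cfg)
    onJunctionSingleStepD(sim$tracks, 4 * 0.046^2)$estimate
  }
  DFree <- diffusionCoef(base(0, 34))
  DBound <- diffusionCoef(base(1, 35))
  DMix <- diffusionCoef(base(0.84, 36))
  expect_gt(DMix, DBound)
  expect_lt(DMix, DFree)
  expect_lt(abs(DMix - DBound), abs(DMix - DFree))
})

test_that("engagement fraction reproduces the two-state arithmetic and flags violations", {
  DWt <- estimateD1(0.0147, 0.0085)
  f <- engagedFraction(DWt, 0.0840, 0.0394)
  expect_equal(round(100 * fractionEngaged(f)), 84)

  expect_equal(fractionEngaged(engagedFraction(0.0840, 0.0840, 0.0394)), 0)
  expect_equal(fractionEngaged(engagedFraction(0.0394, 0.0840, 0.0394)), 1)
  expect_true(engagedFraction(0.02, 0.0840, 0.0394)@flagged)
  expect_error(engagedFraction(0.05, 0.03, 0.04), "model violated")
})
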