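# normalized colocalization and stepwise-dilation median distance

test_that("NCG evaluates the defining formula and its forced cases", {
  # 10x10 grid, 20 green px, 10 red px, 4 colocalized -> NCG = 2.0
  green <- binaryMap(10, 10)
  g <- mapData(green); g[1:20] <- 1
  green <- PixelMap(g, 10, c(0, 0), binary = TRUE)
  r <- matrix(0, 10, 10); r[17:26] <- 1       # overlaps green on 17:20
  red <- PixelMap(r, 10, c(0, 0), binary = TRUE)
  res <- computeNCG(green, red)
  expect_equal(res@colocalizedPixels, 4L)
  expect_equal(res@ncg, (4 / 20) / (10 / 100))

  # red everywhere -> NCG = 1 exactly
  all1 <- PixelMap(matrix(1, 10, 10), 10, c(0, 0), binary = TRUE)
  expect_equal(computeNCG(green, all1)@ncg, 1)

  # no overlap -> NCG = 0
  r2 <- matrix(0, 10, 10); r2[91:95] <- 1
  expect_equal(computeNCG(green, PixelMap(r2, 10, c(0, 0), binary = TRUE))@ncg,
               0)

  # empty channels are an undefined-statistic error, not zero
  empty <- binaryMap(10, 10)
  expect_error(computeNCG(empty, red), "undefined")
  expect_error(computeNCG(green, empty), "undefined")
  expect_error(computeNCG(green, binaryMap(5, 5)), "geometry")
})

test_that("NCG is ~1 for CSR red fields against a fixed territory", {
  terr <- binaryMap(150, 150)
  g <- mapData(terr); g[40:80, 40:80] <- 1
  terr <- PixelMap(g, 10, c(0, 0), binary = TRUE)
  vals <- vapply(1:50, function(s) {
    red <- uniformTable(1500, roi = Rect(0, 0, 1500, 1500), seed = 400 + s)
    computeNCG(terr, binarize(renderASH(red, shifts = 1)))@ncg
  }, numeric(1))
  expect_lt(abs(mean(vals) - 1), 2 * sd(vals) / sqrt(length(vals)))
})

test_that("NCG recovers planted enrichment within 10%", {
  # small territory fraction (1%) and low occupancy: NCG compresses toward 1
  # by 1/(1 + a(e-1)) at territory fraction a, and saturates at high
  # per-pixel occupancy
  g <- matrix(0, 1600, 1600); g[720:879, 720:879] <- 1
  terr <- PixelMap(g, 10, c(0, 0), binary = TRUE)
  for (e in c(0.5, 1, 3)) {
    ncg <- mean(vapply(1:4, function(s) {
      red <- simulateDualChannelField(terr, e, 12000, seed = 500 + e * 10 + s)
      computeNCG(terr, binarize(renderASH(red, shifts = 1)))@ncg
    }, numeric(1)))
    expect_lt(abs(ncg - e) / e, 0.10)
  }
})

test_that("median distance follows the 3-pixel stopping rule", {
  # >= 50% of target already inside territory -> 0 steps, 0 nm
  terr <- binaryMap(100, 100, setIdx = cbind(rep(40:60, 21),
                                             rep(40:60, each = 21)))
  targ <- binaryMap(100, 100, setIdx = cbind(c(50, 51, 99), c(50, 51, 99)))
  r0 <- medianDistanceToTerritory(terr, targ)
  expect_equal(r0@medianDistance, 0)
  expect_equal(r0@stepsUsed, 0L)

  # ring of target pixels at Euclidean distance 58-60 px -> 20 steps, 600 nm
  n <- 160
  terr1 <- binaryMap(n, n, setIdx = cbind(80, 80))
  ang <- seq(0, 2 * pi, length.out = 720)
  ring <- unique(round(cbind(80 + 59 * cos(ang), 80 + 59 * sin(ang))))
  dpx <- sqrt((ring[, 1] - 80)^2 + (ring[, 2] - 80)^2)
  ring <- ring[dpx >= 58 & dpx <= 60, ]
  targ1 <- binaryMap(n, n, setIdx = ring)
  r1 <- medianDistanceToTerritory(terr1, targ1)
  expect_equal(r1@medianDistance, 600)
  expect_equal(r1@stepsUsed, 20L)

  # coverage trace is non-decreasing
  expect_true(!is.unsorted(r1@coverage))
})

test_that("median distance brackets the distance-transform median within one step", {
  set.seed(23)
  for (i in 1:60) {
    terrIdx <- cbind(sample(10:90, 8, TRUE), sample(10:90, 8, TRUE))
    targIdx <- cbind(sample(5:95, 25, TRUE), sample(5:95, 25, TRUE))
    terr <- binaryMap(100, 100, setIdx = terrIdx)
    targ <- binaryMap(100, 100, setIdx = targIdx)
    res <- medianDistanceToTerritory(terr, targ)
    dt <- junctionPALM:::distanceToMask(terr)
    # lower median (type-1 quantile): the smallest distance with CDF >= 0.5,
    # matching the dilation stopping rule's "coverage >= 50%"
    m <- unname(quantile(dt[mapData(targ) > 0], 0.5, type = 1)) * 10  # nm
    expect_gte(res@medianDistance, m - 1e-9)
    expect_lt(res@medianDistance, m + 30)
  }
})
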