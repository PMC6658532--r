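# Voronoi tessellation, Monte-Carlo threshold, watershed segmentation,
# particle analysis, summaries

# independent Sutherland-Hodgman oracle: clip the ROI rectangle against the
# perpendicular bisectors of every other point, then take the shoelace area
oracleVoronoiAreas <- function(x, y, x0, y0, x1, y1) {
  shoelace <- function(px, py) {
    n <- length(px)
    abs(sum(px * py[c(2:n, 1)] - px[c(2:n, 1)] * py)) / 2
  }
  vapply(seq_along(x), function(i) {
    px <- c(x0, x1, x1, x0); py <- c(y0, y0, y1, y1)
    for (j in seq_along(x)) {
      if (j == i) next
      mx <- (x[i] + x[j]) / 2; my <- (y[i] + y[j]) / 2
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      f <- (px - mx) * dx + (py - my) * dy
      keep <- f <= 0
      nx <- c(); ny <- c()
      n <- length(px)
      for (k in seq_len(n)) {
        k2 <- if (k == n) 1L else k + 1L
        if (keep[k]) { nx <- c(nx, px[k]); ny <- c(ny, py[k]) }
        if (keep[k] != keep[k2]) {
          t <- f[k] / (f[k] - f[k2])
          nx <- c(nx, px[k] + t * (px[k2] - px[k]))
          ny <- c(ny, py[k] + t * (py[k2] - py[k]))
        }
      }
      px <- nx; py <- ny
      if (!length(px)) break
    }
    if (length(px)) shoelace(px, py) else 0
  }, numeric(1))
}

test_that("Voronoi polygons partition the ROI and match the brute-force oracle", {
  # four points at quadrant centers: equal quarters
  r <- Rect(0, 0, 1000, 1000)
  quad <- LocalizationTable(data.frame(frame = 0:3, x = c(250, 750, 250, 750),
                                       y = c(250, 250, 750, 750)), roi = r)
  expect_equal(cellAreas(voronoiField(quad)), rep(250000, 4))

  # 12 random points vs oracle, 1e-9 relative
  set.seed(37)
  x <- runif(12, 0, 1000); y <- runif(12, 0, 1000)
  tab <- LocalizationTable(data.frame(frame = 0:11, x = x, y = y), roi = r)
  got <- cellAreas(voronoiField(tab))
  want <- oracleVoronoiAreas(x, y, 0, 0, 1000, 1000)
  expect_lt(max(abs(got - want) / want), 1e-9)

  # conservation across many random fields
  for (i in 1:200) {
    tt <- uniformTable(20, roi = r, seed = 1000 + i)
    expect_lt(abs(sum(cellAreas(voronoiField(tt))) - 1e6) / 1e6, 1e-6)
  }

  # degenerate and duplicate handling
  col <- LocalizationTable(data.frame(frame = 0:4, x = 1:5 * 100, y = 1:5 * 100),
                           roi = r)
  expect_error(voronoiField(col), "collinear")
  dup <- LocalizationTable(data.frame(frame = 0:4,
                                      x = c(100, 100, 500, 900, 200),
                                      y = c(100, 100, 900, 100, 700)), roi = r)
  f <- voronoiField(dup)
  expect_equal(f@jittered, 2L)
  expect_true(all(cellAreas(f) > 0))
})

test_that("the Monte-Carlo threshold is seeded, detects planted clusters, and passes CSR through", {
  sim <- simulateClusterField(clusterSimConfig(seed = 38))
  fld <- voronoiField(sim$table)
  t1 <- mcDensityThreshold(fld, iterations = 40, seed = 39)
  t2 <- mcDensityThreshold(fld, iterations = 40, seed = 39)
  expect_identical(t1$threshold, t2$threshold)
  expect_equal(t1$status, "clustered")
  # threshold separates the bulk of cluster localizations from background
  cand <- cellAreas(fld) < t1$threshold
  expect_gt(mean(cand[sim$truth > 0]), 0.65)
  expect_gt(mean(!cand[sim$truth == 0]), 0.80)

  # CSR fields: no clustering detected in most seeds
  det <- vapply(1:8, function(s) {
    tab <- uniformTable(700, seed = 600 + s)
    mcDensityThreshold(voronoiField(tab), iterations = 40,
                       seed = 700 + s)$status
  }, character(1))
  expect_gte(mean(det == "no clustering detected"), 0.9)
})

test_that("watershed segmentation separates well-separated clusters and assigns localizations", {
  set.seed(40)
  d <- data.frame(frame = 0:399,
                  x = c(rnorm(200, 1000, 50), rnorm(200, 3000, 50)),
                  y = c(rnorm(200, 1000, 50), rnorm(200, 3000, 50)))
  tab <- LocalizationTable(d, roi = Rect(0, 0, 4000, 4000))
  fld <- voronoiField(tab)
  thr <- mcDensityThreshold(fld, iterations = 40, seed = 41)
  cs <- segmentClusters(fld, thr$threshold)
  expect_equal(nrow(clusterData(cs)), 2L)
  truth <- rep(1:2, each = 200)
  a <- cs@assignment
  expect_gt(mean(a > 0), 0.9)
  agree <- table(truth[a > 0], a[a > 0])
  expect_gt(sum(apply(agree, 2, max)) / sum(agree), 0.95)

  # empty candidate set yields an empty ClusterSet
  empty <- segmentClusters(fld, min(cellAreas(fld)) * 0.5)
  expect_equal(nrow(clusterData(empty)), 0L)
  expect_error(segmentClusters(fld, NA_real_), "finite")
})

test_that("particle analysis uses 8-connectivity with the lattice-disc geometry", {
  # a single disc of set pixels, radius 5 -> one 81-px cluster
  disc <- dilateBinary(binaryMap(60, 60, setIdx = cbind(30, 30)), 5)
  pa <- particleAnalysis(disc)
  expect_equal(nrow(clusterData(pa)), 1L)
  expect_equal(clusterData(pa)$nPixels, 81L)

  # two blobs touching only diagonally merge under 8-connectivity
  blob <- matrix(0, 40, 40)
  blob[10:13, 10:13] <- 1
  blob[14:17, 14:17] <- 1
  pa2 <- particleAnalysis(PixelMap(blob, 10, c(0, 0), binary = TRUE))
  expect_equal(nrow(clusterData(pa2)), 1L)

  # size filter
  small <- binaryMap(40, 40, setIdx = cbind(5:8, 5))
  expect_equal(nrow(clusterData(particleAnalysis(small))), 0L)
})

test_that("particle analysis and Voronoi segmentation agree on a dense well-separated field", {
  cfg <- clusterSimConfig(nClusters = 6, locsPerCluster = 250, sigmaLoc = 30,
                          backgroundPixelFraction = 0, seed = 42)
  sim <- simulateClusterField(cfg)
  fld <- voronoiField(sim$table)
  thr <- mcDensityThreshold(fld, iterations = 40, seed = 43)
  nv <- nrow(clusterData(segmentClusters(fld, thr$threshold)))
  np <- nrow(clusterData(particleAnalysis(
    binarize(renderASH(sim$table, shifts = 2)), table = sim$table)))
  expect_lte(abs(nv - np), 2)
  expect_lte(abs(nv - 6), 2)
})

test_that("cluster summaries report the field statistics and percent changes", {
  disc <- dilateBinary(binaryMap(100, 100, setIdx = cbind(50, 50)), 10)
  pa <- particleAnalysis(disc)           # one disc, radius 10 px = 100 nm
  cl <- clusterData(pa)
  expect_lt(abs(cl$diameterNm - 200), 10)   # equivalent diameter ~200 nm
  s <- clusterSummary(pa)
  expect_equal(s$nClusters, 1L)
  expect_equal(s$clustersPerUm2, 1)          # 1 um^2 ROI
  expect_equal(s$fractionalArea, cl$areaUm2)

  expect_identical(percentChange(0.031, 0.024), 23L)
  expect_identical(percentChange(0.059, 0.041), 31L)
})
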