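# Monte-Carlo-thresholded Voronoi tessellation segmentation with watershed,
# the connected-component particle-analysis cross-check, and cluster summary
# statistics.

#' Voronoi tessellation of a localization field
#'
#' Tessellates the localizations and clips every polygon to the ROI
#' rectangle, so the polygon areas sum exactly to the ROI area. Duplicate
#' coordinates are broken by a deterministic sub-0.01-nm jitter keyed to the
#' record index (recorded in the result).
#'
#' @param table a [LocalizationTable] (>= 4 records).
#' @param roi [Rect]; defaults to the table's ROI.
#' @return a [VoronoiField].
#' @export
voronoiField <- function(table, roi = NULL) {
  if (is.null(roi)) roi <- roi(table)
  d <- locData(table)
  if (nrow(d) < 4) stop("at least 4 localizations are required")
  x <- d$x; y <- d$y
  dup <- duplicated(cbind(x, y))
  jit <- which(dup)
  if (length(jit)) {
    # deterministic, index-keyed, < 0.01 nm
    x[jit] <- x[jit] + 1e-3 * sin(jit * 1.61803398875)
    y[jit] <- y[jit] + 1e-3 * cos(jit * 2.71828182846)
  }
  sv <- svd(scale(cbind(x, y), scale = FALSE), nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate geometry: all localizations are collinear")
  cells <- voronoi_cells_cpp(x, y, roi@x0, roi@y0,
                             roi@x0 + roi@width, roi@y0 + roi@height)
  new("VoronoiField", x = x, y = y, areas = cells$areas,
      neighbours = cells$neighbours, roi = roi, jittered = as.integer(jit))
}

#' Monte-Carlo polygon-area threshold
#'
#' Simulates `iterations` complete-spatial-randomness (CSR) fields matched in
#' localization count and ROI, and compares the observed Voronoi polygon-area
#' histogram with the mean CSR histogram on a log-spaced grid. The threshold
#' is the polygon area at which the observed excess of small polygons falls
#' back to the CSR expectation (the maximum of the cumulative
#' observed-minus-CSR excess); localizations with polygon area below it are
#' cluster candidates. Detection is accepted only when that maximal excess
#' exceeds the 95th percentile of the same statistic computed for each CSR
#' iteration, otherwise the field is reported as showing no clustering
#' (threshold `NA`).
#'
#' @param field a [VoronoiField].
#' @param iterations CSR iterations (default 100).
#' @param nBins log-spaced histogram bins (default 50).
#' @param seed RNG seed.
#' @return list with `threshold` (nm^2 or NA), `status` (`"clustered"` or
#'   `"no clustering detected"`), `nCandidates`, and the binned histograms
#'   (`breaks`, `observed`, `csrMean`).
#' @export
mcDensityThreshold <- function(field, iterations = 100, nBins = 50,
                               seed = NULL) {
  if (iterations < 1) stop("iterations must be >= 1")
  areas <- cellAreas(field)
  n <- length(areas)
  r <- roi(field)
  withSeed(seed, {
    csrAreas <- matrix(NA_real_, n, iterations)
    for (it in seq_len(iterations)) {
      cx <- stats::runif(n, r@x0, r@x0 + r@width)
      cy <- stats::runif(n, r@y0, r@y0 + r@height)
      csrAreas[, it] <- voronoi_cells_cpp(cx, cy, r@x0, r@y0,
                                          r@x0 + r@width,
                                          r@y0 + r@height)$areas
    }
    lo <- max(min(areas, csrAreas), 1e-6)
    hi <- max(areas, csrAreas)
    breaks <- exp(seq(log(lo), log(hi), length.out = nBins + 1))
    breaks[1] <- 0; breaks[nBins + 1] <- Inf
    hObs <- tabulate(findInterval(areas, breaks,
                                  rightmost.closed = FALSE), nBins)
    hCsr <- matrix(0, nBins, iterations)
    for (it in seq_len(iterations))
      hCsr[, it] <- tabulate(findInterval(csrAreas[, it], breaks), nBins)
    m <- rowMeans(hCsr)
    noClust <- list(threshold = NA_real_,
                    status = "no clustering detected", nCandidates = 0L,
                    breaks = breaks, observed = hObs, csrMean = m)
    if (!any(hObs > m)) return(noClust)
    # the small-polygon excess of a clustered field ends where the observed
    # histogram crosses back under the CSR mean; equivalently, where the
    # cumulative observed-minus-CSR excess is maximal. This form is robust
    # to sparsely populated bins and to the compensating excess of *large*
    # polygons (background diluted by the clusters).
    cumExcess <- cumsum(hObs - m)
    if (max(cumExcess) <= 0) return(noClust)
    threshold <- breaks[which.max(cumExcess) + 1L]   # upper edge of the bin
    # significance gate calibrated on the same maximized statistic: each CSR
    # iteration is scored against the CSR mean exactly as the observed field
    # was, so the nominal false-positive rate of the gate is ~5%
    eCsr <- vapply(seq_len(iterations),
                   function(it) max(cumsum(hCsr[, it] - m)), numeric(1))
    if (max(cumExcess) <= stats::quantile(eCsr, 0.95)) return(noClust)
    list(threshold = threshold, status = "clustered",
         nCandidates = as.integer(sum(areas < threshold)),
         breaks = breaks, observed = hObs, csrMean = m)
  })
}

emptyClusterSet <- function(roi, pixelSize, method, params, nLoc = 0L,
                            dims = c(0L, 0L)) {
  new("ClusterSet",
      clusters = data.frame(id = integer(), nPixels = integer(),
                            areaUm2 = numeric(), diameterNm = numeric(),
                            nLocalizations = integer(),
                            centroidX = numeric(), centroidY = numeric()),
      labels = matrix(0L, dims[1], dims[2]),
      assignment = integer(nLoc), pixelSize = pixelSize, roi = roi,
      method = method, params = params)
}

# shared: build a ClusterSet from a label raster and localization positions
clusterSetFromLabels <- function(labels, minPixels, pixelSize, roi,
                                 lx, ly, method, params, minLocs = 0) {
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= minPixels)
  if (minLocs > 0 && length(keep) && length(lx)) {
    ixAll <- clampIndex(pixelIndex(lx, roi@x0, pixelSize), nrow(labels))
    iyAll <- clampIndex(pixelIndex(ly, roi@y0, pixelSize), ncol(labels))
    locCount <- tabulate(labels[cbind(ixAll, iyAll)], nbins = length(sizes))
    keep <- keep[locCount[keep] >= minLocs]
  }
  if (!length(keep))
    return(emptyClusterSet(roi, pixelSize, method, params,
                           nLoc = length(lx), dims = dim(labels)))
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  lab <- labels
  lab[lab > 0] <- relabel[lab[lab > 0]]
  # localization -> cluster assignment through the pixel it falls in
  ix <- clampIndex(pixelIndex(lx, roi@x0, pixelSize), nrow(lab))
  iy <- clampIndex(pixelIndex(ly, roi@y0, pixelSize), ncol(lab))
  assign <- lab[cbind(ix, iy)]
  px2um2 <- (pixelSize / 1e3)^2
  ids <- seq_along(keep)
  nPix <- sizes[keep]
  idxSet <- which(lab > 0)
  labVal <- lab[idxSet]
  cxPix <- ((idxSet - 1L) %% nrow(lab)) + 0.5
  cyPix <- ((idxSet - 1L) %/% nrow(lab)) + 0.5
  centroidX <- roi@x0 + tapply(cxPix, labVal, mean) * pixelSize
  centroidY <- roi@y0 + tapply(cyPix, labVal, mean) * pixelSize
  areaUm2 <- nPix * px2um2
  clusters <- data.frame(
    id = ids, nPixels = nPix, areaUm2 = areaUm2,
    diameterNm = 2 * sqrt(areaUm2 * 1e6 / pi),
    nLocalizations = as.integer(tabulate(assign[assign > 0],
                                         nbins = length(ids))),
    centroidX = as.numeric(centroidX), centroidY = as.numeric(centroidY))
  new("ClusterSet", clusters = clusters, labels = lab,
      assignment = as.integer(assign), pixelSize = pixelSize, roi = roi,
      method = method, params = params)
}

#' Segment clusters from a thresholded Voronoi field
#'
#' Rasterizes the first-rank Voronoi density (1 / polygon area) to pixels
#' whose centre falls in a candidate (sub-threshold) polygon, smooths the
#' density map with a Gaussian, and applies watershed segmentation restricted
#' to the candidate support. Segments smaller than `minPixels` are excluded.
#'
#' @param field a [VoronoiField].
#' @param threshold polygon-area threshold (nm^2) from
#'   [mcDensityThreshold()]; must be finite.
#' @param pixelSize raster pixel (nm, default 10).
#' @param minPixels minimum cluster size in pixels (default 10).
#' @param minLocs minimum localizations per cluster (default 5, the same
#'   clustering criterion as the density filter used for junction masks);
#'   screens out segments formed by chance pairs of background localizations
#'   whose polygons pass the area threshold.
#' @param smoothSigmaPx Gaussian smoothing sigma in pixels applied to the
#'   density map before watershed (default 3, i.e. 30 nm): enough to fuse
#'   the per-polygon granularity of the first-rank density map without
#'   erasing the density dip between abutting clusters.
#' @param tolerance watershed tolerance on the max-normalized density map
#'   (default 0.1): neighbouring intensity maxima whose separating dip is
#'   shallower than this are merged rather than split.
#' @return a [ClusterSet] (method `"voronoi_watershed"`).
#' @export
segmentClusters <- function(field, threshold, pixelSize = 10, minPixels = 10,
                            minLocs = 5, smoothSigmaPx = 3, tolerance = 0.1) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  r <- roi(field)
  dims <- gridDims(r, pixelSize)
  params <- list(threshold = threshold, minPixels = minPixels,
                 minLocs = minLocs, smoothSigmaPx = smoothSigmaPx,
                 tolerance = tolerance)
  candidate <- cellAreas(field) < threshold
  if (!any(candidate))
    return(emptyClusterSet(r, pixelSize, "voronoi_watershed", params,
                           nLoc = length(field@x), dims = dims))
  nearest <- nearest_seed_map_cpp(field@x, field@y, r@x0, r@y0, pixelSize,
                                  dims["nx"], dims["ny"])
  maskPix <- matrix(candidate[nearest], dims["nx"], dims["ny"])
  dens <- matrix(1 / cellAreas(field)[nearest], dims["nx"], dims["ny"])
  dens[!maskPix] <- 0
  dens <- dens / max(dens)
  if (smoothSigmaPx > 0)
    dens <- EBImage::imageData(EBImage::gblur(EBImage::Image(dens),
                                              sigma = smoothSigmaPx))
  dens[!maskPix] <- 0
  if (max(dens) <= 0)
    return(emptyClusterSet(r, pixelSize, "voronoi_watershed", params,
                           nLoc = length(field@x), dims = dims))
  dens <- dens / max(dens)
  labels <- EBImage::imageData(EBImage::watershed(EBImage::Image(dens),
                                                  tolerance = tolerance,
                                                  ext = 1))
  clusterSetFromLabels(labels, minPixels, pixelSize, r, field@x, field@y,
                       "voronoi_watershed", params, minLocs = minLocs)
}

#' Particle analysis of a binary localization map
#'
#' The independent cross-check segmentation: 8-connected component labelling
#' of a binary map rendered from the same localizations, with the same size
#' filter and summary statistics.
#'
#' @param map a binary [PixelMap] (e.g. `binarize(renderASH(table))`).
#' @param table optional [LocalizationTable] used to count localizations per
#'   cluster.
#' @param minPixels minimum cluster size in pixels (default 10).
#' @return a [ClusterSet] (method `"particle_analysis"`).
#' @export
particleAnalysis <- function(map, table = NULL, minPixels = 10) {
  g <- mapData(map) > 0
  r <- roi(map)
  labels <- label8_cpp(matrix(as.integer(g), nrow(g), ncol(g)))
  if (is.null(table)) {
    lx <- numeric(0); ly <- numeric(0)
  } else {
    d <- locData(table)
    lx <- d$x; ly <- d$y
  }
  clusterSetFromLabels(labels, minPixels, pixelSize(map), r, lx, ly,
                       "particle_analysis", list(minPixels = minPixels))
}

#' Field-level cluster summary
#'
#' @param set a [ClusterSet].
#' @param roi [Rect]; defaults to the set's ROI.
#' @return data.frame with one row: `nClusters`, `clustersPerUm2`,
#'   `fractionalArea` (summed cluster area over ROI area), `medianDiameterNm`,
#'   `medianLocsPerCluster`.
#' @export
clusterSummary <- function(set, roi = NULL) {
  if (is.null(roi)) roi <- roi(set)
  cl <- clusterData(set)
  areaUm2 <- rectAreaUm2(roi)
  data.frame(
    nClusters = nrow(cl),
    clustersPerUm2 = nrow(cl) / areaUm2,
    fractionalArea = sum(cl$areaUm2) / areaUm2,
    medianDiameterNm = if (nrow(cl)) stats::median(cl$diameterNm) else NA_real_,
    medianLocsPerCluster = if (nrow(cl)) stats::median(cl$nLocalizations)
                           else NA_real_)
}

#' Percent change between two summary values
#'
#' `(a - b) / a * 100`, rounded to the nearest integer percent — the
#' convention used to report reductions in fractional junctional area.
#'
#' @param a reference value.
#' @param b comparison value.
#' @return integer percent.
#' @examples
#' percentChange(0.031, 0.024)  # 23
#' percentChange(0.059, 0.041)  # 31
#' @export
percentChange <- function(a, b) {
  as.integer(round((a - b) / a * 100))
}
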