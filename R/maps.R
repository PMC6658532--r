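# Rendering localizations to 10-nm rasters and the spatial filters applied
# before colocalization and junction analysis.

gridDims <- function(roi, pixelSize) {
  c(nx = as.integer(ceiling(roi@width / pixelSize)),
    ny = as.integer(ceiling(roi@height / pixelSize)))
}

#' Render localizations as an averaged shifted histogram
#'
#' Averages `shifts^2` two-dimensional histograms whose bin origins are
#' offset on a sub-pixel lattice (`k / shifts` pixels, k = 0 ... shifts - 1,
#' per axis). `shifts = 1` is a plain 2D histogram. Binning is half-open:
#' a point exactly on a pixel boundary lands in the higher-index pixel.
#' Shifted histograms are clipped at the ROI boundary (edge bins absorb the
#' shifted-out mass), so the total over the raster equals the number of
#' localizations for any number of shifts.
#'
#' @param table a [LocalizationTable].
#' @param pixelSize nm (default 10).
#' @param shifts lateral shift count (>= 1; 2 matches the common rendering
#'   convention).
#' @return a counts [PixelMap] over the table's ROI.
#' @export
renderASH <- function(table, pixelSize = 10, shifts = 2) {
  if (shifts < 1) stop("shifts must be >= 1")
  r <- roi(table)
  dims <- gridDims(r, pixelSize)
  d <- locData(table)
  acc <- matrix(0, dims["nx"], dims["ny"])
  if (nrow(d) == 0L) {
    warning("rendering an empty localization table: all-zero map")
    return(PixelMap(acc, pixelSize, c(r@x0, r@y0)))
  }
  for (sx in seq_len(shifts) - 1L) {
    for (sy in seq_len(shifts) - 1L) {
      ox <- r@x0 - sx * pixelSize / shifts
      oy <- r@y0 - sy * pixelSize / shifts
      ix <- clampIndex(pixelIndex(d$x, ox, pixelSize), dims["nx"])
      iy <- clampIndex(pixelIndex(d$y, oy, pixelSize), dims["ny"])
      h <- matrix(tabulate(ix + (iy - 1L) * dims["nx"],
                           nbins = dims["nx"] * dims["ny"]),
                  dims["nx"], dims["ny"])
      acc <- acc + h
    }
  }
  PixelMap(acc / shifts^2, pixelSize, c(r@x0, r@y0))
}

#' Binarize a counts map
#'
#' @param map a [PixelMap].
#' @param threshold pixel is set iff its value is strictly greater (default 0).
#' @return a binary [PixelMap].
#' @export
binarize <- function(map, threshold = 0) {
  PixelMap((mapData(map) > threshold) + 0, pixelSize(map), map@origin,
           binary = TRUE)
}

#' Density-filter a localization table
#'
#' Retains exactly the records with at least `minNeighbours` *other* records
#' within `radius` (Euclidean). Neighbour counts are taken once on the
#' unfiltered table (single pass, not iterated), so the result does not
#' depend on removal order and is invariant to record permutation.
#'
#' @param table a [LocalizationTable].
#' @param radius nm (default 100).
#' @param minNeighbours required neighbour count (default 5).
#' @return the filtered [LocalizationTable].
#' @export
densityFilter <- function(table, radius = 100, minNeighbours = 5) {
  if (radius <= 0) stop("radius must be > 0")
  d <- locData(table)
  if (!nrow(d)) return(table)
  counts <- count_neighbours_cpp(d$x, d$y, radius)
  LocalizationTable(d[counts >= minNeighbours, , drop = FALSE],
                    roi = roi(table), frameInterval = frameInterval(table),
                    pad = table@pad)
}

#' Euclidean disc structuring element
#'
#' Lattice points with `dx^2 + dy^2 <= r^2` (81 pixels at r = 5).
#'
#' @param radiusPixels integer radius in pixels.
#' @return a (2r+1) x (2r+1) 0/1 matrix.
#' @export
discKernel <- function(radiusPixels) {
  r <- as.integer(radiusPixels)
  if (r < 0) stop("radiusPixels must be >= 0")
  g <- seq(-r, r)
  (outer(g^2, g^2, "+") <= r^2) + 0
}

#' Morphological dilation with a Euclidean disc
#'
#' @param map a binary [PixelMap].
#' @param radiusPixels disc radius in pixels (0 = identity).
#' @return the dilated binary [PixelMap].
#' @export
dilateBinary <- function(map, radiusPixels) {
  if (radiusPixels < 0) stop("radiusPixels must be >= 0")
  if (radiusPixels == 0) return(binarize(map))
  g <- (mapData(map) > 0) + 0
  dil <- EBImage::dilate(EBImage::Image(g), discKernel(radiusPixels))
  PixelMap((EBImage::imageData(dil) > 0) + 0, pixelSize(map), map@origin,
           binary = TRUE)
}

# Euclidean distance (in pixels) from each pixel centre to the nearest set
# pixel of a binary map. Set pixels have distance 0.
distanceToMask <- function(map) {
  g <- (mapData(map) > 0) + 0
  if (!any(g > 0)) stop("mask is empty")
  # distmap measures distance to the nearest background (0) pixel, so feed it
  # the complement of the mask
  EBImage::imageData(EBImage::distmap(EBImage::Image(1 - g)))
}
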