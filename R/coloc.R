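# Normalized colocalization (NCG) and stepwise-dilation median distances
# between two channels' binary maps.

#' Normalized colocalization in green (NCG)
#'
#' `NCG = (colocalized pixels / green pixels) / (red pixels / total pixels)`.
#' The green channel is the reference/territory channel; a value of 1
#' indicates a random relationship between the channels, values consistently
#' above 1 enrichment and below 1 exclusion of the red channel in the green
#' territory.
#'
#' @param green,red binary [PixelMap]s with identical grid geometry; each
#'   must have at least one set pixel (the statistic is undefined otherwise).
#' @param roiId optional identifier carried into the result.
#' @return a [ColocalizationResult].
#' @export
computeNCG <- function(green, red, roiId = "") {
  gg <- mapData(green) > 0
  rr <- mapData(red) > 0
  if (!all(dim(gg) == dim(rr)))
    stop("green and red maps must share the same grid geometry")
  nGreen <- sum(gg); nRed <- sum(rr)
  if (nGreen == 0L || nRed == 0L)
    stop("NCG is undefined when a channel has no set pixels")
  nColoc <- sum(gg & rr)
  nTotal <- length(gg)
  new("ColocalizationResult",
      ncg = (nColoc / nGreen) / (nRed / nTotal),
      colocalizedPixels = as.integer(nColoc),
      greenPixels = as.integer(nGreen), redPixels = as.integer(nRed),
      totalPixels = as.integer(nTotal), roiId = as.character(roiId))
}

#' Stepwise-dilation median distance from a territory
#'
#' The territory is dilated stepwise by `stepPixels` pixels at a time
#' (cumulative Euclidean-disc radius `k * stepPixels` after k steps) and the
#' fractional coverage of target pixels recomputed after each step, until
#' coverage reaches 50%. The total dilation at that point, converted to nm,
#' is the reported median distance, on the `stepPixels * pixelSize`
#' quantization grid without interpolation.
#'
#' @param territory,target non-empty binary [PixelMap]s, same geometry.
#' @param stepPixels pixels dilated per step (default 3, i.e. 30 nm at 10-nm
#'   pixels).
#' @return a [MedianDistanceResult] with the coverage trace per step.
#' @export
medianDistanceToTerritory <- function(territory, target, stepPixels = 3) {
  tg <- mapData(target) > 0
  if (!any(mapData(territory) > 0)) stop("territory is empty")
  if (!any(tg)) stop("target is empty")
  if (!all(dim(mapData(territory)) == dim(tg)))
    stop("territory and target must share the same grid geometry")
  dt <- distanceToMask(territory)[tg]   # pixel distances of target pixels
  nTarget <- length(dt)
  kMax <- ceiling(max(dt) / stepPixels)
  coverage <- vapply(0:kMax,
                     function(k) sum(dt <= k * stepPixels) / nTarget,
                     numeric(1))
  hit <- which(coverage >= 0.5)
  if (!length(hit))
    stop(sprintf("coverage never reached 50%% (max %.1f%%)",
                 100 * max(coverage)))
  steps <- hit[1] - 1L
  new("MedianDistanceResult",
      medianDistance = steps * stepPixels * pixelSize(territory),
      stepsUsed = as.integer(steps),
      coverage = coverage[seq_len(steps + 1L)],
      stepPixels = as.integer(stepPixels),
      pixelSize = pixelSize(territory))
}
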