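# Accessor generics and show methods. Slots are never reached into directly
# by user code; these accessors are the supported surface.

#' Region of interest of an object
#' @param x an object with a region of interest.
#' @return a [Rect].
#' @export
setGeneric("roi", function(x) standardGeneric("roi"))

#' @rdname roi
#' @export
setMethod("roi", "LocalizationTable", function(x) x@roi)

#' @rdname roi
#' @export
setMethod("roi", "VoronoiField", function(x) x@roi)

#' @rdname roi
#' @export
setMethod("roi", "ClusterSet", function(x) x@roi)

#' @rdname roi
#' @export
setMethod("roi", "PixelMap", function(x)
  Rect(x@origin[1], x@origin[2],
       nrow(x@grid) * x@pixelSize, ncol(x@grid) * x@pixelSize))

#' Localization records of a table
#' @param x a [LocalizationTable].
#' @return data.frame of records.
#' @export
setGeneric("locData", function(x) standardGeneric("locData"))

#' @rdname locData
#' @export
setMethod("locData", "LocalizationTable", function(x) x@data)

#' Number of localization records
#' @param x a [LocalizationTable].
#' @export
setGeneric("nLocalizations", function(x) standardGeneric("nLocalizations"))

#' @rdname nLocalizations
#' @export
setMethod("nLocalizations", "LocalizationTable", function(x) nrow(x@data))

#' Frame interval in seconds
#' @param x a [LocalizationTable] or [TrackSet].
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname frameInterval
#' @export
setMethod("frameInterval", "LocalizationTable", function(x) x@frameInterval)

#' @rdname frameInterval
#' @export
setMethod("frameInterval", "TrackSet", function(x) x@frameInterval)

#' Track points of a track set
#' @param x a [TrackSet].
#' @return data.frame with columns track_id, frame, x, y.
#' @export
setGeneric("trackData", function(x) standardGeneric("trackData"))

#' @rdname trackData
#' @export
setMethod("trackData", "TrackSet", function(x) x@data)

#' Number of tracks
#' @param x a [TrackSet].
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' @rdname nTracks
#' @export
setMethod("nTracks", "TrackSet", function(x) length(unique(x@data$track_id)))

#' Track lengths (localizations per track)
#' @param x a [TrackSet].
#' @export
setGeneric("trackLengths", function(x) standardGeneric("trackLengths"))

#' @rdname trackLengths
#' @export
setMethod("trackLengths", "TrackSet", function(x)
  as.integer(table(factor(x@data$track_id,
                          levels = unique(x@data$track_id)))))

#' Raster values of a pixel map
#' @param x a [PixelMap].
#' @return numeric matrix, x along rows.
#' @export
setGeneric("mapData", function(x) standardGeneric("mapData"))

#' @rdname mapData
#' @export
setMethod("mapData", "PixelMap", function(x) x@grid)

#' Pixel size in nanometres
#' @param x a [PixelMap] or [ClusterSet].
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "PixelMap", function(x) x@pixelSize)

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "ClusterSet", function(x) x@pixelSize)

#' Diffusion coefficient of an estimate
#' @param x a [DiffusionEstimate].
#' @return D in um^2/s.
#' @export
setGeneric("diffusionCoef", function(x) standardGeneric("diffusionCoef"))

#' @rdname diffusionCoef
#' @export
setMethod("diffusionCoef", "DiffusionEstimate", function(x) x@D)

#' Voronoi polygon areas
#' @param x a [VoronoiField].
#' @return areas in nm^2, one per localization.
#' @export
setGeneric("cellAreas", function(x) standardGeneric("cellAreas"))

#' @rdname cellAreas
#' @export
setMethod("cellAreas", "VoronoiField", function(x) x@areas)

#' Per-cluster statistics of a cluster set
#' @param x a [ClusterSet].
#' @return data.frame, one row per cluster.
#' @export
setGeneric("clusterData", function(x) standardGeneric("clusterData"))

#' @rdname clusterData
#' @export
setMethod("clusterData", "ClusterSet", function(x) x@clusters)

#' Cluster label raster
#' @param x a [ClusterSet].
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "ClusterSet", function(x) x@labels)

#' Junction mask raster
#' @param x a [JunctionMask].
#' @return the binary [PixelMap].
#' @export
setGeneric("maskMap", function(x) standardGeneric("maskMap"))

#' @rdname maskMap
#' @export
setMethod("maskMap", "JunctionMask", function(x) x@mask)

#' MSD curve as a data.frame
#' @param x an [MSDCurve].
#' @return data.frame with columns lag (s), msd (um^2), sem, n.
#' @export
setGeneric("msdData", function(x) standardGeneric("msdData"))

#' @rdname msdData
#' @export
setMethod("msdData", "MSDCurve", function(x)
  data.frame(lag = x@lags, msd = x@msd, sem = x@sem, n = x@nIntervals))

# --------------------------------------------------------------------------
# show methods
# --------------------------------------------------------------------------

setMethod("show", "Rect", function(object) {
  cat(sprintf("Rect: origin (%.1f, %.1f) nm, %.1f x %.1f nm\n",
              object@x0, object@y0, object@width, object@height))
})

setMethod("show", "LocalizationTable", function(object) {
  cat(sprintf(
    "LocalizationTable: %d localizations, channels: %s\n",
    nrow(object@data),
    paste(unique(object@data$channel), collapse = ", ")))
  cat(sprintf("  ROI %.2f x %.2f um, frame interval %g s\n",
              object@roi@width / 1e3, object@roi@height / 1e3,
              object@frameInterval))
})

setMethod("show", "TrackSet", function(object) {
  n <- length(unique(object@data$track_id))
  cat(sprintf("TrackSet: %d tracks, %d localizations (channel %s)\n",
              n, nrow(object@data), object@channel))
  if (n > 0)
    cat(sprintf("  mean length %.1f frames, frame interval %g s\n",
                nrow(object@data) / n, object@frameInterval))
})

setMethod("show", "PixelMap", function(object) {
  cat(sprintf("PixelMap: %d x %d pixels of %g nm (%s)\n",
              nrow(object@grid), ncol(object@grid), object@pixelSize,
              if (object@binary) "binary" else "counts/density"))
})

setMethod("show", "MSDCurve", function(object) {
  cat(sprintf("MSDCurve: %d lags (%s intervals), MSD(1) = %.4g um^2\n",
              length(object@lags),
              if (object@overlapping) "overlapping" else "non-overlapping",
              object@msd[1]))
})

setMethod("show", "DiffusionEstimate", function(object) {
  cat(sprintf("DiffusionEstimate [%s]: D = %.4g um^2/s%s\n",
              object@method, object@D,
              if (isTRUE(object@flagged)) " (flagged: negative)" else ""))
})

setMethod("show", "LocalizationCalibration", function(object) {
  cat(sprintf(
    "LocalizationCalibration: MSD1,fixed = %.4g um^2 (sigma 2D = %.0f nm, per axis = %.0f nm)\n",
    object@msd1Fixed, object@sigma2d, object@sigmaAxis))
})

setMethod("show", "ConfinementEstimate", function(object) {
  cat(sprintf("ConfinementEstimate: plateau %.4g um^2 -> r_c = %.0f nm\n",
              object@plateau, object@rc))
})

setMethod("show", "ColocalizationResult", function(object) {
  cat(sprintf(
    "ColocalizationResult: NCG = %.3f (coloc %d / green %d / red %d / total %d px)\n",
    object@ncg, object@colocalizedPixels, object@greenPixels,
    object@redPixels, object@totalPixels))
})

setMethod("show", "MedianDistanceResult", function(object) {
  cat(sprintf("MedianDistanceResult: %g nm (%d steps of %d px)\n",
              object@medianDistance, object@stepsUsed, object@stepPixels))
})

setMethod("show", "JunctionMask", function(object) {
  cat(sprintf("JunctionMask: %d of %d pixels set\n",
              sum(object@mask@grid > 0), length(object@mask@grid)))
})

setMethod("show", "EngagementResult", function(object) {
  cat(sprintf(
    "EngagementResult: fraction engaged = %.3f%s  (D_WT %.4g, D_LSLD %.4g, D_STIM1 %.4g um^2/s)\n",
    object@fractionEngaged,
    if (isTRUE(object@flagged)) " (flagged: outside [0, 1])" else "",
    object@DWt, object@DLsld, object@DStim1))
})

setMethod("show", "VoronoiField", function(object) {
  cat(sprintf("VoronoiField: %d polygons, median area %.0f nm^2\n",
              length(object@areas), stats::median(object@areas)))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet [%s]: %d clusters\n",
              object@method, nrow(object@clusters)))
})

setMethod("show", "DriftModel", function(object) {
  cat(sprintf("DriftModel: %d frames, max |offset| %.1f nm\n",
              length(object@frames),
              if (length(object@dx)) max(sqrt(object@dx^2 + object@dy^2)) else 0))
})
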