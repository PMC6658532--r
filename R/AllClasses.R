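#' @import methods
NULL

# ---------------------------------------------------------------------------
# Rect
# ---------------------------------------------------------------------------

#' Rectangular region of interest
#'
#' A rectangle in nanometre coordinates, origin at its lower-left corner with
#' y increasing upward. All localization tables and rasters carry one.
#'
#' @slot x0,y0 lower-left corner (nm).
#' @slot width,height extent (nm); both must be positive.
#' @export
setClass("Rect", representation(x0 = "numeric", y0 = "numeric",
                                width = "numeric", height = "numeric"),
         validity = function(object) {
           if (length(object@width) != 1L || length(object@height) != 1L ||
               object@width <= 0 || object@height <= 0)
             return("width and height must be single positive numbers")
           TRUE
         })

#' @param x0,y0 lower-left corner (nm).
#' @param width,height extent (nm).
#' @rdname Rect-class
#' @export
Rect <- function(x0 = 0, y0 = 0, width, height) {
  new("Rect", x0 = as.numeric(x0), y0 = as.numeric(y0),
      width = as.numeric(width), height = as.numeric(height))
}

rectArea <- function(r) r@width * r@height          # nm^2
rectAreaUm2 <- function(r) rectArea(r) / 1e6

# ---------------------------------------------------------------------------
# LocalizationTable
# ---------------------------------------------------------------------------

#' Per-frame single-molecule localizations
#'
#' The universal input of the package: one record per detected emitter per
#' frame, with coordinates in nanometres. Records live in a data.frame with
#' columns `frame` (integer, >= 0), `x`, `y` (nm), `channel` (label) and the
#' optional `uncertainty` (nm) and `intensity` columns.
#'
#' @slot data data.frame of records.
#' @slot roi [Rect] the field of view.
#' @slot frameInterval frame spacing in seconds (default 0.05).
#' @slot pad margin (nm) by which records may lie outside the ROI, e.g. after
#'   drift correction.
#' @export
setClass("LocalizationTable",
         representation(data = "data.frame", roi = "Rect",
                        frameInterval = "numeric", pad = "numeric"),
         validity = function(object) {
           d <- object@data
           need <- c("frame", "x", "y", "channel")
           if (!all(need %in% names(d)))
             return(sprintf("data must contain columns %s",
                            paste(need, collapse = ", ")))
           if (nrow(d)) {
             if (any(d$frame < 0) || any(d$frame != floor(d$frame)))
               return("frame indices must be non-negative integers")
             r <- object@roi; p <- object@pad
             if (any(d$x < r@x0 - p | d$x > r@x0 + r@width + p |
                     d$y < r@y0 - p | d$y > r@y0 + r@height + p))
               return("coordinates outside the ROI (plus pad)")
           }
           if (object@frameInterval <= 0)
             return("frameInterval must be > 0")
           TRUE
         })

#' @param data data.frame with columns frame, x, y and optionally channel,
#'   uncertainty, intensity.
#' @param roi [Rect]; defaults to the bounding box of the records.
#' @param frameInterval seconds between frames.
#' @param channel default channel label applied when `data` has no channel
#'   column.
#' @param pad allowed margin outside the ROI (nm).
#' @rdname LocalizationTable-class
#' @export
LocalizationTable <- function(data, roi = NULL, frameInterval = 0.05,
                              channel = "green", pad = 0) {
  data <- as.data.frame(data)
  if (is.null(data$channel)) data$channel <- rep(channel, nrow(data))
  data$frame <- as.integer(data$frame)
  if (is.null(roi)) {
    if (!nrow(data)) stop("an explicit 'roi' is required for an empty table")
    roi <- Rect(min(data$x), min(data$y),
                max(diff(range(data$x)), 1), max(diff(range(data$y)), 1))
  }
  new("LocalizationTable", data = data, roi = roi,
      frameInterval = frameInterval, pad = as.numeric(pad))
}

# ---------------------------------------------------------------------------
# DriftModel
# ---------------------------------------------------------------------------

#' Per-frame drift offsets estimated from fiducial markers
#'
#' @slot frames frame indices covered.
#' @slot dx,dy offsets (nm) relative to the reference frame; zero at the
#'   reference frame.
#' @slot referenceFrame frame at which the offset is defined to be (0, 0).
#' @slot fiducialIds ids of the fiducial tracks used.
#' @export
setClass("DriftModel",
         representation(frames = "integer", dx = "numeric", dy = "numeric",
                        referenceFrame = "integer", fiducialIds = "character"),
         validity = function(object) {
           if (length(object@frames) != length(object@dx) ||
               length(object@frames) != length(object@dy))
             return("frames, dx, dy must have equal length")
           i <- match(object@referenceFrame, object@frames)
           if (!is.na(i) && (abs(object@dx[i]) > 1e-9 || abs(object@dy[i]) > 1e-9))
             return("offset at the reference frame must be (0, 0)")
           TRUE
         })

# ---------------------------------------------------------------------------
# TrackSet
# ---------------------------------------------------------------------------

#' Time-ordered single-molecule trajectories
#'
#' Stores linked trajectories as a long-format data.frame with columns
#' `track_id`, `frame`, `x`, `y` (nm). Frames within a track are strictly
#' consecutive: a blink terminates the track.
#'
#' @slot data data.frame of track points.
#' @slot channel channel label.
#' @slot frameInterval seconds between frames.
#' @slot maxDisp maximum displacement (nm) enforced at linking; `NA` for
#'   simulated tracks.
#' @export
setClass("TrackSet",
         representation(data = "data.frame", channel = "character",
                        frameInterval = "numeric", maxDisp = "numeric"),
         validity = function(object) {
           d <- object@data
           need <- c("track_id", "frame", "x", "y")
           if (!all(need %in% names(d)))
             return(sprintf("data must contain columns %s",
                            paste(need, collapse = ", ")))
           if (nrow(d)) {
             df <- unlist(tapply(d$frame, d$track_id,
                                 function(f) diff(sort(f)), simplify = FALSE),
                          use.names = FALSE)
             if (length(df) && any(df != 1L))
               return("frames within a track must be strictly consecutive")
           }
           if (object@frameInterval <= 0) return("frameInterval must be > 0")
           TRUE
         })

#' @param data data.frame with columns track_id, frame, x, y.
#' @param channel channel label.
#' @param frameInterval seconds between frames.
#' @param maxDisp linking displacement cap in nm (NA for simulated tracks).
#' @rdname TrackSet-class
#' @export
TrackSet <- function(data, channel = "red", frameInterval = 0.05,
                     maxDisp = NA_real_) {
  data <- as.data.frame(data)
  data$frame <- as.integer(data$frame)
  o <- order(data$track_id, data$frame)
  new("TrackSet", data = data[o, , drop = FALSE], channel = channel,
      frameInterval = frameInterval, maxDisp = as.numeric(maxDisp))
}

# ---------------------------------------------------------------------------
# PixelMap
# ---------------------------------------------------------------------------

#' Raster rendered from localizations
#'
#' A 2D raster (counts, densities or a binary mask) on a regular grid of
#' square pixels, default 10 nm. `grid[i, j]` covers the half-open cell
#' `[origin_x + (i-1) p, origin_x + i p) x [origin_y + (j-1) p, origin_y + j p)`.
#'
#' @slot grid numeric matrix, x along rows, y along columns.
#' @slot pixelSize pixel edge in nm.
#' @slot origin nm coordinates of the lower-left corner of pixel (1, 1).
#' @slot binary whether the map is a {0, 1} mask.
#' @export
setClass("PixelMap",
         representation(grid = "matrix", pixelSize = "numeric",
                        origin = "numeric", binary = "logical"),
         validity = function(object) {
           if (object@pixelSize <= 0) return("pixelSize must be > 0")
           if (length(object@origin) != 2L) return("origin must be length 2")
           if (object@binary && length(object@grid) &&
               !all(object@grid %in% c(0, 1)))
             return("binary map may contain only 0 and 1")
           TRUE
         })

#' @param grid numeric matrix.
#' @param pixelSize pixel edge (nm).
#' @param origin length-2 nm offset of pixel (1, 1).
#' @param binary logical.
#' @rdname PixelMap-class
#' @export
PixelMap <- function(grid, pixelSize = 10, origin = c(0, 0), binary = FALSE) {
  new("PixelMap", grid = grid, pixelSize = as.numeric(pixelSize),
      origin = as.numeric(origin), binary = binary)
}

# ---------------------------------------------------------------------------
# MSD / diffusion results
# ---------------------------------------------------------------------------

#' Mean squared displacement curve
#'
#' @slot lags time lags (s), multiples of the frame interval starting at one.
#' @slot msd mean squared displacement per lag (um^2).
#' @slot sem standard error of the mean per lag (um^2), ignoring interval
#'   correlation.
#' @slot nIntervals number of displacement intervals per lag.
#' @slot overlapping whether overlapping intervals were used.
#' @slot frameInterval seconds.
#' @export
setClass("MSDCurve",
         representation(lags = "numeric", msd = "numeric", sem = "numeric",
                        nIntervals = "integer", overlapping = "logical",
                        frameInterval = "numeric"),
         validity = function(object) {
           if (any(object@msd < 0)) return("msd must be >= 0")
           if (is.unsorted(-object@nIntervals))
             return("nIntervals must be non-increasing in lag")
           TRUE
         })

#' Corrected diffusion-coefficient estimate
#'
#' @slot D diffusion coefficient (um^2/s); may be negative, in which case
#'   `flagged` is TRUE.
#' @slot method `"single_step_D1"` or `"slope_D2"`.
#' @slot msd1FixedUsed fixed-cell MSD subtracted (um^2; NA for D2).
#' @slot blurFactor motion-blur factor (1.5 for D1, NA for D2).
#' @slot sem standard error (um^2/s) when available.
#' @slot flagged TRUE when the estimate is negative.
#' @export
setClass("DiffusionEstimate",
         representation(D = "numeric", method = "character",
                        msd1FixedUsed = "numeric", blurFactor = "numeric",
                        sem = "numeric", flagged = "logical"))

#' Localization-error calibration from fixed-cell tracks
#'
#' @slot msd1Fixed single-interval MSD of stationary emitters (um^2).
#' @slot sigma2d two-dimensional localization error (nm),
#'   `sqrt(msd1Fixed / 2)` expressed in nm.
#' @slot sigmaAxis per-axis localization error (nm), `sigma2d / sqrt(2)`.
#' @slot nIntervals intervals averaged.
#' @export
setClass("LocalizationCalibration",
         representation(msd1Fixed = "numeric", sigma2d = "numeric",
                        sigmaAxis = "numeric", nIntervals = "integer"),
         validity = function(object) {
           s2 <- sqrt(object@msd1Fixed / 2) * 1e3
           if (abs(object@sigma2d - s2) > 1e-6 * max(1, s2))
             return("sigma2d inconsistent with msd1Fixed")
           if (abs(object@sigmaAxis - object@sigma2d / sqrt(2)) > 1e-9 * max(1, s2))
             return("sigmaAxis inconsistent with sigma2d")
           TRUE
         })

#' Equivalent confinement radius from an MSD plateau
#'
#' @slot plateau late-lag MSD plateau (um^2).
#' @slot rc equivalent confinement radius (nm),
#'   `sqrt(max(plateau - msd1Fixed, 0))` expressed in nm.
#' @slot msd1FixedUsed calibration value subtracted (um^2).
#' @export
setClass("ConfinementEstimate",
         representation(plateau = "numeric", rc = "numeric",
                        msd1FixedUsed = "numeric"))

# ---------------------------------------------------------------------------
# Colocalization results
# ---------------------------------------------------------------------------

#' Normalized colocalization (NCG) result
#'
#' NCG = (colocalized pixels / green pixels) / (red pixels / total pixels);
#' 1 indicates a random relationship, > 1 enrichment, < 1 exclusion.
#'
#' @slot ncg the statistic.
#' @slot colocalizedPixels,greenPixels,redPixels,totalPixels pixel counts.
#' @slot roiId optional identifier.
#' @export
setClass("ColocalizationResult",
         representation(ncg = "numeric", colocalizedPixels = "integer",
                        greenPixels = "integer", redPixels = "integer",
                        totalPixels = "integer", roiId = "character"),
         validity = function(object) {
           if (object@ncg < 0) return("ncg must be >= 0")
           if (object@colocalizedPixels >
               min(object@greenPixels, object@redPixels))
             return("colocalized pixels cannot exceed either channel")
           TRUE
         })

#' Stepwise-dilation median distance result
#'
#' @slot medianDistance nm; `stepsUsed * stepPixels * pixelSize`.
#' @slot stepsUsed dilation steps taken to reach 50% coverage.
#' @slot coverage fractional coverage of target pixels after 0, 1, 2, ...
#'   steps (non-decreasing).
#' @slot stepPixels pixels dilated per step.
#' @slot pixelSize nm.
#' @export
setClass("MedianDistanceResult",
         representation(medianDistance = "numeric", stepsUsed = "integer",
                        coverage = "numeric", stepPixels = "integer",
                        pixelSize = "numeric"),
         validity = function(object) {
           if (is.unsorted(object@coverage, strictly = FALSE))
             return("coverage trace must be non-decreasing")
           d <- object@stepsUsed * object@stepPixels * object@pixelSize
           if (abs(object@medianDistance - d) > 1e-9)
             return("medianDistance must equal steps * stepPixels * pixelSize")
           TRUE
         })

# ---------------------------------------------------------------------------
# Junction analysis
# ---------------------------------------------------------------------------

#' STIM1-marked junction mask
#'
#' Binary raster of ER-PM junction territory built from density-filtered
#' reference-channel (STIM1) localizations, with the construction parameters
#' recorded.
#'
#' @slot mask binary [PixelMap].
#' @slot provenance list with the density-filter radius and neighbour count
#'   and the gap-filling dilation radius used.
#' @export
setClass("JunctionMask",
         representation(mask = "PixelMap", provenance = "list"))

#' Two-state STIM-engagement estimate
#'
#' Fraction of junctional ORAI1 engaged with STIM1 under the two-state
#' free/bound model: `(D_LSLD - D_WT) / (D_LSLD - D_STIM1)`.
#'
#' @slot DWt,DLsld,DStim1 inputs (um^2/s).
#' @slot fractionEngaged the estimate (dimensionless).
#' @slot flagged TRUE when the estimate falls outside [0, 1].
#' @export
setClass("EngagementResult",
         representation(DWt = "numeric", DLsld = "numeric",
                        DStim1 = "numeric", fractionEngaged = "numeric",
                        flagged = "logical"))

# ---------------------------------------------------------------------------
# Clustering
# ---------------------------------------------------------------------------

#' Voronoi tessellation of a localization field
#'
#' Per-localization Voronoi polygons clipped to the ROI rectangle. The
#' first-rank density of a localization is 1 / polygon area.
#'
#' @slot x,y localization coordinates (nm), after duplicate jittering.
#' @slot areas clipped polygon areas (nm^2).
#' @slot neighbours list of integer vectors: indices of the polygons whose
#'   bisectors cut each cell.
#' @slot roi [Rect].
#' @slot jittered indices of records that received duplicate-breaking jitter.
#' @export
setClass("VoronoiField",
         representation(x = "numeric", y = "numeric", areas = "numeric",
                        neighbours = "list", roi = "Rect",
                        jittered = "integer"))

#' Segmented cluster set
#'
#' @slot clusters data.frame: id, nPixels, areaUm2, diameterNm (equivalent
#'   diameter), nLocalizations, centroidX, centroidY (nm).
#' @slot labels integer label raster (x along rows).
#' @slot assignment cluster id per localization (0 = unassigned).
#' @slot pixelSize nm.
#' @slot roi [Rect].
#' @slot method `"voronoi_watershed"` or `"particle_analysis"`.
#' @slot params list of segmentation parameters.
#' @export
setClass("ClusterSet",
         representation(clusters = "data.frame", labels = "matrix",
                        assignment = "integer", pixelSize = "numeric",
                        roi = "Rect", method = "character", params = "list"))
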