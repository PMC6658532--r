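# Junction masks from STIM1 localizations, on/off-junction track
# classification, maximum excursions, on-junction single-step diffusion and
# the two-state STIM-engagement estimator.

#' Build a STIM1-marked junction mask
#'
#' ER-PM junctions are defined as regions where the reference channel
#' (STIM1) localized and clustered after store depletion: localizations not
#' within `radius` of at least `minNeighbours` others are discarded, the
#' survivors are rasterized at `pixelSize`, and gaps are filled with a
#' `dilatePixels`-pixel dilation (50 nm at the defaults).
#'
#' @param stim1 a [LocalizationTable] of the reference channel.
#' @param radius density-filter radius (nm, default 100).
#' @param minNeighbours density-filter neighbour count (default 5).
#' @param pixelSize raster pixel (nm, default 10).
#' @param dilatePixels gap-filling dilation radius in pixels (default 5).
#' @return a [JunctionMask]; an empty mask (with a warning) when nothing
#'   survives the density filter.
#' @export
buildJunctionMask <- function(stim1, radius = 100, minNeighbours = 5,
                              pixelSize = 10, dilatePixels = 5) {
  filtered <- densityFilter(stim1, radius = radius,
                            minNeighbours = minNeighbours)
  if (!nLocalizations(filtered))
    warning("no localizations survive the density filter: empty mask")
  rendered <- suppressWarnings(renderASH(filtered, pixelSize = pixelSize,
                                         shifts = 1))
  mask <- if (any(mapData(rendered) > 0))
    dilateBinary(binarize(rendered), dilatePixels)
  else binarize(rendered)
  new("JunctionMask", mask = mask,
      provenance = list(radius = radius, minNeighbours = minNeighbours,
                        pixelSize = pixelSize, dilatePixels = dilatePixels))
}

# TRUE for each (x, y) inside the mask (points outside the raster are FALSE)
inMask <- function(mask, x, y) {
  m <- maskMap(mask)
  g <- mapData(m)
  ix <- pixelIndex(x, m@origin[1], pixelSize(m))
  iy <- pixelIndex(y, m@origin[2], pixelSize(m))
  ok <- ix >= 1L & ix <= nrow(g) & iy >= 1L & iy <= ncol(g)
  res <- logical(length(x))
  res[ok] <- g[cbind(ix[ok], iy[ok])] > 0
  res
}

#' Classify tracks relative to a junction mask
#'
#' A track is "on" junction if its first localization falls inside the mask,
#' "off" if every localization falls outside, and "excluded" otherwise (it
#' starts outside and enters later, satisfying neither rule). The partition
#' is exhaustive and exclusive.
#'
#' @param tracks a [TrackSet] in the same coordinate frame as the mask.
#' @param mask a [JunctionMask].
#' @return data.frame with one row per track: `track_id`, `class` (factor
#'   on/off/excluded), `nSteps`.
#' @export
classifyTracks <- function(tracks, mask) {
  d <- trackData(tracks)
  inside <- inMask(mask, d$x, d$y)
  byTrack <- split(inside, d$track_id)
  ids <- names(byTrack)
  cls <- vapply(byTrack, function(v) {
    if (v[1]) "on" else if (!any(v)) "off" else "excluded"
  }, character(1))
  data.frame(track_id = type.convert(ids, as.is = TRUE),
             class = factor(cls, levels = c("on", "off", "excluded")),
             nSteps = vapply(byTrack, length, integer(1)) - 1L,
             row.names = NULL)
}

#' Maximum excursion of tracks
#'
#' For each track, `d_max` is the largest displacement from the first
#' localization to any later localization. Only tracks of `stepRange` steps
#' (6-25 by default) are retained.
#'
#' @param tracks a [TrackSet].
#' @param classes optional result of [classifyTracks()]; its `class` column
#'   is joined onto the output.
#' @param stepRange inclusive (min, max) number of steps; NULL to keep all.
#' @return data.frame: `track_id`, `dMax` (nm), `nSteps`, and `class` when
#'   available.
#' @export
maxExcursion <- function(tracks, classes = NULL, stepRange = c(6, 25)) {
  xys <- splitTracks(tracks)
  ids <- names(xys)
  dMax <- vapply(xys, function(xy) {
    sqrt(max((xy[-1, 1] - xy[1, 1])^2 + (xy[-1, 2] - xy[1, 2])^2))
  }, numeric(1))
  out <- data.frame(track_id = type.convert(ids, as.is = TRUE),
                    dMax = dMax,
                    nSteps = vapply(xys, nrow, integer(1)) - 1L,
                    row.names = NULL)
  if (!is.null(stepRange))
    out <- out[out$nSteps >= stepRange[1] & out$nSteps <= stepRange[2], ,
               drop = FALSE]
  if (!is.null(classes))
    out$class <- classes$class[match(out$track_id, classes$track_id)]
  out
}

#' Randomly sample excursion records
#'
#' Seeded uniform sample without replacement of `n` records (1500 by
#' default, the conventional per-condition sample); when fewer records are
#' available all are taken with a warning.
#'
#' @param records data.frame from [maxExcursion()].
#' @param n sample size.
#' @param seed RNG seed.
#' @return list with `sample` (the sampled records) and `medianDMax` (nm),
#'   overall and per class when a `class` column is present.
#' @export
sampleExcursions <- function(records, n = 1500, seed = NULL) {
  take <- withSeed(seed, {
    if (nrow(records) < n) {
      warning(sprintf("only %d records available (requested %d): taking all",
                      nrow(records), n))
      records
    } else records[sample.int(nrow(records), n), , drop = FALSE]
  })
  med <- stats::median(take$dMax)
  out <- list(sample = take, medianDMax = med)
  if (!is.null(take$class))
    out$medianByClass <- tapply(take$dMax, take$class, stats::median)
  out
}

#' On-junction single-step diffusion estimate
#'
#' The squared displacement of the first 50-ms step is computed for each
#' on-junction track, the sample average r^2 taken over tracks (one step per
#' track), and the single-step estimator applied with that average in place
#' of MSD1. Outlying steps with r^2 above `outlierCut` can be excluded from
#' plots; following the stated procedure they are retained in the mean by
#' default (`applyCutToMean = FALSE`).
#'
#' @param onTracks a [TrackSet] of tracks classified on-junction.
#' @param calibration a [LocalizationCalibration] or `MSD1,fixed` (um^2).
#' @param frameInterval seconds.
#' @param outlierCut r^2 threshold (um^2) used only when `applyCutToMean`.
#' @param applyCutToMean exclude outlying steps from the mean as well.
#' @return list with `meanR2` (um^2), `n`, `estimate` (a
#'   [DiffusionEstimate]) and `r2` (per-track first-step r^2, um^2).
#' @export
onJunctionSingleStepD <- function(onTracks, calibration,
                                  frameInterval = 0.05, outlierCut = 0.1,
                                  applyCutToMean = FALSE) {
  xys <- splitTracks(onTracks)
  r2 <- vapply(xys, function(xy) {
    if (nrow(xy) < 2) return(NA_real_)
    nm2ToUm2((xy[2, 1] - xy[1, 1])^2 + (xy[2, 2] - xy[1, 2])^2)
  }, numeric(1))
  r2 <- r2[!is.na(r2)]
  if (length(r2) < 10)
    warning("fewer than 10 on-junction tracks: estimate is unreliable")
  used <- if (applyCutToMean) r2[r2 <= outlierCut] else r2
  meanR2 <- mean(used)
  sem <- stats::sd(used) / sqrt(length(used))
  list(meanR2 = meanR2, n = length(used),
       estimate = estimateD1(meanR2, calibration,
                             frameInterval = frameInterval, sem = sem),
       r2 = r2)
}

#' Two-state STIM-engagement fraction
#'
#' Under the simplifying assumption that junctional ORAI1 is either free
#' (diffusing like the STIM-blind ORAI1-LSLD mutant) or STIM1-bound
#' (diffusing like STIM1), the bound fraction is
#' `(D_LSLD - D_WT) / (D_LSLD - D_STIM1)`. Values outside [0, 1] are flagged,
#' not clamped.
#'
#' @param DWt measured wildtype on-junction D (um^2/s), or a
#'   [DiffusionEstimate].
#' @param DLsld free-state reference D (um^2/s) from ORAI1-LSLD.
#' @param DStim1 bound-state reference D (um^2/s) from STIM1.
#' @return an [EngagementResult].
#' @examples
#' engagedFraction(0.0465, 0.0840, 0.0394)  # ~0.84
#' @export
engagedFraction <- function(DWt, DLsld, DStim1) {
  if (is(DWt, "DiffusionEstimate")) DWt <- diffusionCoef(DWt)
  if (DLsld <= DStim1)
    stop("two-state model violated: D_LSLD must exceed D_STIM1")
  f <- (DLsld - DWt) / (DLsld - DStim1)
  new("EngagementResult", DWt = DWt, DLsld = DLsld, DStim1 = DStim1,
      fractionEngaged = f, flagged = f < 0 || f > 1)
}

#' Fraction engaged of an engagement result
#' @param x an [EngagementResult].
#' @export
setGeneric("fractionEngaged", function(x) standardGeneric("fractionEngaged"))

#' @rdname fractionEngaged
#' @export
setMethod("fractionEngaged", "EngagementResult", function(x) x@fractionEngaged)

#' Extract a subset of tracks by id
#'
#' @param tracks a [TrackSet].
#' @param ids track ids to keep.
#' @return a [TrackSet].
#' @export
subsetTracks <- function(tracks, ids) {
  d <- trackData(tracks)
  TrackSet(d[d$track_id %in% ids, , drop = FALSE],
           channel = tracks@channel, frameInterval = frameInterval(tracks),
           maxDisp = tracks@maxDisp)
}
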