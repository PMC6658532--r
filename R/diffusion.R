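# MSD curves, corrected diffusion estimators, localization-error calibration,
# confinement radius, step-length histograms.
#
# Units: track coordinates are nm; MSD values are um^2; D is um^2/s.

# squared displacements (nm^2) at a given lag for one track's coordinate
# matrix; non-overlapping intervals share no localization (stride k + 1)
lagSquaredDisp <- function(xy, k, overlapping) {
  n <- nrow(xy)
  if (n <= k) return(numeric(0))
  starts <- if (overlapping) seq_len(n - k) else seq(1, n - k, by = k + 1)
  (xy[starts + k, 1] - xy[starts, 1])^2 + (xy[starts + k, 2] - xy[starts, 2])^2
}

splitTracks <- function(tracks) {
  d <- trackData(tracks)
  lapply(split(seq_len(nrow(d)), d$track_id),
         function(i) cbind(d$x[i], d$y[i]))
}

#' Mean squared displacement curve
#'
#' For each lag k the mean of squared displacements over all index pairs
#' (i, i + k) in all tracks — overlapping pairs by default, matching common
#' practice (at the cost of correlated intervals; the non-overlapping
#' alternative, in which intervals share no localization, is exposed). SEM
#' per lag is the sample SD over intervals
#' divided by sqrt(n), ignoring interval correlation.
#'
#' @param tracks a [TrackSet].
#' @param maxLag largest lag in frames.
#' @param overlapping use overlapping intervals (default TRUE).
#' @return an [MSDCurve] (lags in seconds, MSD in um^2).
#' @export
computeMSD <- function(tracks, maxLag = 10, overlapping = TRUE) {
  xys <- splitTracks(tracks)
  if (!length(xys)) stop("no tracks supplied")
  msd <- sem <- numeric(maxLag)
  n <- integer(maxLag)
  for (k in seq_len(maxLag)) {
    sq <- unlist(lapply(xys, lagSquaredDisp, k = k,
                        overlapping = overlapping), use.names = FALSE)
    n[k] <- length(sq)
    if (n[k] == 0L)
      stop("maxLag exceeds every track length: no intervals at lag ", k)
    sqUm <- nm2ToUm2(sq)
    msd[k] <- mean(sqUm)
    sem[k] <- if (n[k] > 1) stats::sd(sqUm) / sqrt(n[k]) else NA_real_
  }
  new("MSDCurve", lags = seq_along(msd) * frameInterval(tracks),
      msd = msd, sem = sem, nIntervals = n, overlapping = overlapping,
      frameInterval = frameInterval(tracks))
}

#' Localization-error calibration from fixed-cell tracks
#'
#' The single-interval MSD of stationary emitters estimates
#' `2 sigma_localization^2` (each axis contributes the variance of the
#' difference of two independent errors). From `MSD1,fixed` the
#' two-dimensional localization error is `sigma = sqrt(MSD1,fixed / 2)` and
#' the per-axis error `sigma / sqrt(2)`.
#'
#' @param fixedTracks a [TrackSet] from stationary emitters, or a single
#'   numeric `MSD1,fixed` value in um^2.
#' @return a [LocalizationCalibration].
#' @examples
#' calibrateLocalization(0.0085)  # sigma = 65 nm, per-axis 46 nm
#' @export
calibrateLocalization <- function(fixedTracks) {
  if (is.numeric(fixedTracks)) {
    msd1 <- fixedTracks
    nInt <- NA_integer_
  } else {
    curve <- computeMSD(fixedTracks, maxLag = 1)
    msd1 <- curve@msd[1]
    nInt <- curve@nIntervals[1]
  }
  sigma2d <- sqrt(msd1 / 2) * 1e3      # um -> nm
  new("LocalizationCalibration", msd1Fixed = msd1, sigma2d = sigma2d,
      sigmaAxis = sigma2d / sqrt(2), nIntervals = nInt)
}

#' Single-step corrected diffusion estimate (D1)
#'
#' `D1 = 1.5 * (MSD1 - MSD1,fixed) / (4 * tau)`: the fixed-cell MSD removes
#' the localization-error contribution and the factor 1.5 undoes the apparent
#' step contraction introduced by continuous acquisition (motion blur). A
#' negative result is reported and flagged, never clamped.
#'
#' @param msd1 observed single-interval MSD (um^2).
#' @param calibration a [LocalizationCalibration], or `MSD1,fixed` in um^2.
#' @param frameInterval tau in seconds (default 0.05).
#' @param sem optional SEM of `msd1`, propagated linearly.
#' @return a [DiffusionEstimate].
#' @examples
#' estimateD1(0.0147, 0.0085)  # 0.0465 um^2/s
#' @export
estimateD1 <- function(msd1, calibration, frameInterval = 0.05,
                       sem = NA_real_) {
  stopifnotScalar(frameInterval, "frameInterval", positive = TRUE)
  msd1Fixed <- if (is(calibration, "LocalizationCalibration"))
    calibration@msd1Fixed else calibration
  D <- 1.5 * (msd1 - msd1Fixed) / (4 * frameInterval)
  new("DiffusionEstimate", D = D, method = "single_step_D1",
      msd1FixedUsed = msd1Fixed, blurFactor = 1.5,
      sem = 1.5 * sem / (4 * frameInterval), flagged = D < 0)
}

#' Two-point slope diffusion estimate (D2)
#'
#' `D2 = (MSD2 - MSD1) / (4 * tau)`: localization error and motion blur make
#' the same average contribution to both points and cancel upon subtraction,
#' so no correction is applied.
#'
#' @param msd1,msd2 MSD at one and two frame intervals (um^2).
#' @param frameInterval tau in seconds (default 0.05).
#' @param sem optional SEM of the difference, propagated linearly.
#' @return a [DiffusionEstimate].
#' @export
estimateD2 <- function(msd1, msd2, frameInterval = 0.05, sem = NA_real_) {
  stopifnotScalar(frameInterval, "frameInterval", positive = TRUE)
  D <- (msd2 - msd1) / (4 * frameInterval)
  new("DiffusionEstimate", D = D, method = "slope_D2",
      msd1FixedUsed = NA_real_, blurFactor = NA_real_,
      sem = sem / (4 * frameInterval), flagged = D < 0)
}

#' Equivalent confinement radius from an MSD plateau
#'
#' For positions uniform in a disc of radius R the expected squared
#' separation of two independent samples is R^2, so after subtracting the
#' localization-error plateau the long-lag MSD plateau converts to an
#' equivalent confinement radius `r_c = sqrt(plateau - MSD1,fixed)`.
#'
#' @param plateau the plateau (um^2), or an [MSDCurve] from which the plateau
#'   is taken as the mean MSD over `lateWindow`.
#' @param calibration a [LocalizationCalibration] or `MSD1,fixed` (um^2).
#' @param lateWindow lag window (s) for plateau averaging when an MSD curve
#'   is supplied (default 0.4-0.5 s).
#' @return a [ConfinementEstimate] with `rc` in nm; a plateau below the
#'   calibration value yields zero radius with a warning.
#' @export
estimateConfinementRadius <- function(plateau, calibration,
                                      lateWindow = c(0.4, 0.5)) {
  if (is(plateau, "MSDCurve")) {
    sel <- plateau@lags >= lateWindow[1] & plateau@lags <= lateWindow[2]
    if (!any(sel)) stop("no MSD lags inside the plateau window")
    plateau <- mean(plateau@msd[sel])
  }
  if (plateau < 0) stop("plateau must be >= 0")
  msd1Fixed <- if (is(calibration, "LocalizationCalibration"))
    calibration@msd1Fixed else calibration
  excess <- plateau - msd1Fixed
  if (excess < 0) {
    warning("plateau below the localization-error floor; r_c set to 0")
    excess <- 0
  }
  new("ConfinementEstimate", plateau = plateau, rc = sqrt(excess) * 1e3,
      msd1FixedUsed = msd1Fixed)
}

#' Step-length histogram
#'
#' Histogram of displacement magnitudes at a given lag over all (by default
#' overlapping) intervals in all tracks. The histogram total equals the
#' interval count of [computeMSD()] at the same lag.
#'
#' @param tracks a [TrackSet].
#' @param lag lag in frames (1, 2 or 3 for 50/100/150-ms steps).
#' @param binWidth bin width in nm.
#' @param overlapping use overlapping intervals.
#' @param normalize return densities instead of counts.
#' @return data.frame with `mid` (bin midpoint, nm) and `count` (or
#'   `density`).
#' @export
stepHistogram <- function(tracks, lag = 1, binWidth = 20, overlapping = TRUE,
                          normalize = FALSE) {
  stopifnotScalar(binWidth, "binWidth", positive = TRUE)
  sq <- unlist(lapply(splitTracks(tracks), lagSquaredDisp, k = lag,
                      overlapping = overlapping), use.names = FALSE)
  if (!length(sq)) stop("no intervals at this lag")
  r <- sqrt(sq)
  nBins <- as.integer(max(r) %/% binWidth) + 1L
  idx <- pmin(as.integer(r %/% binWidth) + 1L, nBins)  # half-open bins
  counts <- tabulate(idx, nbins = nBins)
  out <- data.frame(mid = (seq_len(nBins) - 0.5) * binWidth, count = counts)
  if (normalize) {
    out$density <- counts / sum(counts) / binWidth
    out$count <- NULL
  }
  out
}
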