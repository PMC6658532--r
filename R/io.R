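# Localization/track table I/O, fiducial drift correction, channel
# registration.

#' Column dialect for localization tables
#'
#' Maps the package's internal field names onto file column names. The default
#' follows the common SMLM export convention (`"frame"`, `"x [nm]"`,
#' `"y [nm]"`, `"uncertainty [nm]"`, `"intensity [photon]"`).
#'
#' @param frame,x,y mandatory column names.
#' @param uncertainty,intensity optional column names (`NA` to skip).
#' @param scale multiplier converting file coordinate units to nm.
#' @return named list used by [readLocalizations()]/[writeLocalizations()].
#' @export
smlmDialect <- function(frame = "frame", x = "x [nm]", y = "y [nm]",
                        uncertainty = "uncertainty [nm]",
                        intensity = "intensity [photon]", scale = 1) {
  list(frame = frame, x = x, y = y, uncertainty = uncertainty,
       intensity = intensity, scale = scale)
}

#' Read a localization table
#'
#' Reads a delimited text localization table (one row per detected emitter per
#' frame) into a [LocalizationTable], converting coordinates to nm. Rows with
#' non-numeric coordinates are dropped with a warning reporting the count;
#' missing mandatory columns are an error.
#'
#' @param path file path (comma-delimited, header row).
#' @param dialect column mapping from [smlmDialect()].
#' @param roi optional [Rect]; defaults to the bounding box of the records.
#' @param frameInterval seconds between frames.
#' @param channel channel label applied to all records.
#' @return a [LocalizationTable]; row order of the file is preserved.
#' @export
readLocalizations <- function(path, dialect = smlmDialect(), roi = NULL,
                              frameInterval = 0.05, channel = "green") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  for (col in c("frame", "x", "y"))
    if (!dialect[[col]] %in% names(raw))
      stop(sprintf("missing mandatory column '%s' in %s", dialect[[col]], path))
  n <- nrow(raw)
  if (n == 0L) {
    warning("localization file contains a header only: ", path)
    return(LocalizationTable(
      data.frame(frame = integer(), x = numeric(), y = numeric()),
      roi = if (is.null(roi)) Rect(0, 0, 1, 1) else roi,
      frameInterval = frameInterval, channel = channel))
  }
  xs <- suppressWarnings(as.numeric(raw[[dialect$x]])) * dialect$scale
  ys <- suppressWarnings(as.numeric(raw[[dialect$y]])) * dialect$scale
  fr <- suppressWarnings(as.numeric(raw[[dialect$frame]]))
  bad <- is.na(xs) | is.na(ys) | is.na(fr)
  if (any(bad))
    warning(sprintf("dropped %d row(s) with non-numeric coordinates", sum(bad)))
  d <- data.frame(frame = as.integer(fr[!bad]), x = xs[!bad], y = ys[!bad])
  for (opt in c("uncertainty", "intensity")) {
    colName <- dialect[[opt]]
    if (!is.na(colName) && colName %in% names(raw)) {
      v <- suppressWarnings(as.numeric(raw[[colName]]))[!bad]
      if (opt == "uncertainty") v <- v * dialect$scale
      d[[opt]] <- v
    }
  }
  LocalizationTable(d, roi = roi, frameInterval = frameInterval,
                    channel = channel)
}

#' Write a localization table
#'
#' Writes records with full double precision (`%.17g`) so that a
#' write-then-read round trip reproduces coordinates bit-identically.
#'
#' @param table a [LocalizationTable].
#' @param path output file path.
#' @param dialect column mapping from [smlmDialect()] (scale is applied in
#'   reverse on output).
#' @export
writeLocalizations <- function(table, path, dialect = smlmDialect()) {
  d <- locData(table)
  fmt <- function(v) sprintf("%.17g", v)
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                    f = d$frame,
                    x = fmt(d$x / dialect$scale),
                    y = fmt(d$y / dialect$scale))
  names(out) <- c(dialect$frame, dialect$x, dialect$y)
  if (!is.null(d$uncertainty) && !is.na(dialect$uncertainty))
    out[[dialect$uncertainty]] <- fmt(d$uncertainty / dialect$scale)
  if (!is.null(d$intensity) && !is.na(dialect$intensity))
    out[[dialect$intensity]] <- fmt(d$intensity)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write track tables
#'
#' Tracks are stored as comma-delimited text with columns `track_id`, `frame`,
#' `x`, `y` (nm).
#'
#' @param path file path.
#' @param frameInterval seconds between frames.
#' @param channel channel label.
#' @return [readTracks()] returns a [TrackSet].
#' @export
readTracks <- function(path, frameInterval = 0.05, channel = "red") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path)
  need <- c("track_id", "frame", "x", "y")
  if (!all(need %in% names(raw)))
    stop("track table must contain columns ", paste(need, collapse = ", "))
  TrackSet(raw[need], channel = channel, frameInterval = frameInterval)
}

#' @param tracks a [TrackSet].
#' @rdname readTracks
#' @export
writeTracks <- function(tracks, path) {
  d <- trackData(tracks)
  out <- data.frame(track_id = d$track_id, frame = d$frame,
                    x = sprintf("%.17g", d$x), y = sprintf("%.17g", d$y))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --------------------------------------------------------------------------
# Drift correction
# --------------------------------------------------------------------------

#' Estimate stage drift from fiducial tracks
#'
#' The per-frame offset is the mean displacement of the fiducial markers from
#' their position at the reference frame (the first frame of the table, by
#' convention). Fiducial gaps are bridged by linear interpolation; frames
#' outside every fiducial's span hold the nearest estimated offset. More than
#' `maxUncovered` of the table's frames without fiducial coverage is an error.
#'
#' @param table a [LocalizationTable].
#' @param fiducials a [TrackSet] of stationary fiducial trajectories.
#' @param maxUncovered maximum tolerated fraction of frames without coverage.
#' @return a [DriftModel].
#' @export
estimateDrift <- function(table, fiducials, maxUncovered = 0.1) {
  fd <- trackData(fiducials)
  if (!nrow(fd)) stop("no fiducial tracks supplied")
  frames <- seq(min(locData(table)$frame), max(locData(table)$frame))
  refFrame <- frames[1]
  ids <- unique(fd$track_id)
  covered <- rep(FALSE, length(frames))
  dxs <- dys <- matrix(NA_real_, length(frames), length(ids))
  for (k in seq_along(ids)) {
    f <- fd[fd$track_id == ids[k], ]
    covered <- covered | (frames >= min(f$frame) & frames <= max(f$frame))
    # interpolate the fiducial position onto every frame (constant beyond span)
    xi <- stats::approx(f$frame, f$x, xout = frames, rule = 2)$y
    yi <- stats::approx(f$frame, f$y, xout = frames, rule = 2)$y
    dxs[, k] <- xi - xi[1]
    dys[, k] <- yi - yi[1]
  }
  if (mean(!covered) > maxUncovered)
    stop(sprintf("fiducials cover only %.0f%% of frames",
                 100 * mean(covered)))
  new("DriftModel", frames = as.integer(frames),
      dx = rowMeans(dxs), dy = rowMeans(dys),
      referenceFrame = as.integer(refFrame),
      fiducialIds = as.character(ids))
}

#' Apply a drift model to a localization table
#'
#' Subtracts the per-frame offsets from all records. The table's `pad` is
#' expanded by the maximum offset so corrected coordinates may lie slightly
#' outside the original ROI.
#'
#' @param table a [LocalizationTable].
#' @param drift a [DriftModel].
#' @return the corrected [LocalizationTable].
#' @export
applyDrift <- function(table, drift) {
  d <- locData(table)
  i <- match(d$frame, drift@frames)
  if (anyNA(i)) stop("drift model does not cover all frames in the table")
  d$x <- d$x - drift@dx[i]
  d$y <- d$y - drift@dy[i]
  maxOff <- if (length(drift@dx)) max(sqrt(drift@dx^2 + drift@dy^2)) else 0
  LocalizationTable(d, roi = roi(table), frameInterval = frameInterval(table),
                    pad = table@pad + maxOff + 1e-9)
}

#' @param maxUncovered maximum tolerated fraction of frames without fiducial
#'   coverage.
#' @rdname applyDrift
#' @return `estimateAndApplyDrift` returns `list(table =, drift =)`.
#' @param fiducials a [TrackSet] of fiducial trajectories.
#' @export
estimateAndApplyDrift <- function(table, fiducials, maxUncovered = 0.1) {
  drift <- estimateDrift(table, fiducials, maxUncovered = maxUncovered)
  list(table = applyDrift(table, drift), drift = drift)
}

# --------------------------------------------------------------------------
# Channel registration
# --------------------------------------------------------------------------

#' Register one channel onto another from matched fiducial positions
#'
#' Least-squares rigid transform (translation, optionally plus rotation via
#' the 2D Kabsch solution) mapping target-channel coordinates into the
#' reference channel's frame: `ref ~ R %*% target + t`.
#'
#' @param ref,target n x 2 matrices of matched fiducial positions (nm).
#' @param rotation include a rotation (needs >= 2 distinct pairs).
#' @return list with `translation` (nm), `rotationAngle` (radians), `R`
#'   (2 x 2 matrix) and `residualRms` (nm).
#' @export
registerChannels <- function(ref, target, rotation = FALSE) {
  ref <- as.matrix(ref); target <- as.matrix(target)
  if (!all(dim(ref) == dim(target)) || ncol(ref) != 2)
    stop("ref and target must be matched n x 2 matrices")
  n <- nrow(ref)
  if (n < 1) stop("at least one matched pair is required")
  if (!rotation) {
    t <- colMeans(ref) - colMeans(target)
    R <- diag(2)
  } else {
    if (n < 2) stop("rotation requires at least two matched pairs")
    A <- sweep(ref, 2, colMeans(ref))
    B <- sweep(target, 2, colMeans(target))
    if (max(abs(B)) < 1e-12 || max(abs(A)) < 1e-12)
      stop("degenerate geometry: matched pairs are coincident")
    C <- t(B) %*% A
    sv <- svd(C)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
    t <- colMeans(ref) - as.vector(R %*% colMeans(target))
  }
  fitted <- t(R %*% t(target)) + matrix(t, n, 2, byrow = TRUE)
  rms <- sqrt(mean(rowSums((fitted - ref)^2)))
  list(translation = as.numeric(t),
       rotationAngle = atan2(R[2, 1], R[1, 1]),
       R = R, residualRms = rms)
}

#' Apply a channel registration transform
#'
#' @param table a [LocalizationTable] (of the target channel).
#' @param transform result of [registerChannels()].
#' @return the transformed [LocalizationTable] (`pad` expanded by the
#'   translation magnitude).
#' @export
applyTransform <- function(table, transform) {
  d <- locData(table)
  xy <- t(transform$R %*% t(cbind(d$x, d$y)))
  d$x <- xy[, 1] + transform$translation[1]
  d$y <- xy[, 2] + transform$translation[2]
  pad <- table@pad + sqrt(sum(transform$translation^2)) +
    0.1 * max(roi(table)@width, roi(table)@height) *
      abs(transform$rotationAngle)
  LocalizationTable(d, roi = roi(table), frameInterval = frameInterval(table),
                    pad = pad + 1e-9)
}
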