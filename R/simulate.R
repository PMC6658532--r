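# Synthetic-data generators with known ground truth. These define the study
# conditions used throughout the test suite: two-state free/bound diffusion
# with sub-frame motion blur and per-axis localization error, stationary
# calibration emitters, randomized cluster fields, and dual-channel
# enrichment fields.

#' Configuration for the two-state diffusion simulator
#'
#' Emulates sptPALM acquisitions of a membrane protein that is either freely
#' diffusing or bound (e.g. STIM1-engaged) and confined at junction discs.
#' Defaults correspond to ORAI1 at ER-PM junctions after store depletion:
#' free diffusion at 0.084 um^2/s, bound diffusion at the STIM1-like
#' 0.0394 um^2/s, 84% bound, 50-ms frames, 46-nm per-axis localization error
#' and 10 substeps of continuous-illumination motion blur.
#'
#' @param nTracks number of trajectories.
#' @param DFree,DBound diffusion coefficients (um^2/s); `DFree >= DBound >= 0`.
#' @param pBound probability a molecule is bound (initial state; the state is
#'   static unless switching rates are given).
#' @param kBind,kRelease optional switching rates (1/s) applied at substep
#'   resolution; 0 disables switching.
#' @param junctionDiscs data.frame with columns `cx`, `cy`, `r` (nm), or NULL
#'   to place `nAutoDiscs` discs of radius `autoDiscRadius` uniformly in the
#'   ROI at simulation time.
#' @param nAutoDiscs,autoDiscRadius automatic disc layout (17 discs of 160 nm
#'   in the default 4 x 4 um ROI, the junction density of the cluster
#'   simulations).
#' @param confineBound bound molecules reflect at their disc boundary.
#' @param startInDiscs free molecules also start inside a disc (for
#'   on-junction mixtures); bound confined molecules always do.
#' @param sigmaAxis per-axis Gaussian localization error (nm).
#' @param frameInterval seconds (50-ms frames).
#' @param substepsPerFrame substeps per frame for motion blur (>= 1; 1 means
#'   no blur).
#' @param blur when TRUE (default) the reported frame position is the mean of
#'   the substep positions (continuous illumination); when FALSE it is the
#'   instantaneous position at the last substep (stroboscopic sampling),
#'   which isolates confinement physics from motion blur while keeping the
#'   fine-grained boundary reflection.
#' @param trackLengthRange (min, max) track length in frames; min >= 3.
#' @param roi [Rect] field of view.
#' @param seed RNG seed.
#' @return a validated configuration list of class `TwoStateSimConfig`.
#' @export
twoStateSimConfig <- function(nTracks = 1500, DFree = 0.084, DBound = 0.0394,
                              pBound = 0.84, kBind = 0, kRelease = 0,
                              junctionDiscs = NULL, nAutoDiscs = 17,
                              autoDiscRadius = 160, confineBound = TRUE,
                              startInDiscs = FALSE, sigmaAxis = 46,
                              frameInterval = 0.05, substepsPerFrame = 10,
                              blur = TRUE,
                              trackLengthRange = c(7, 26),
                              roi = Rect(0, 0, 4000, 4000), seed = NULL) {
  if (DFree < DBound || DBound < 0) stop("need DFree >= DBound >= 0")
  if (pBound < 0 || pBound > 1) stop("pBound must be in [0, 1]")
  if (substepsPerFrame < 1) stop("substepsPerFrame must be >= 1")
  if (trackLengthRange[1] < 3) stop("minimum track length is 3 frames")
  if (sigmaAxis < 0) stop("sigmaAxis must be >= 0")
  if (!is.null(junctionDiscs)) {
    junctionDiscs <- as.data.frame(junctionDiscs)
    if (!all(c("cx", "cy", "r") %in% names(junctionDiscs)))
      stop("junctionDiscs needs columns cx, cy, r")
    if (confineBound && any(junctionDiscs$r <= 0))
      stop("disc radius must be > 0 when confineBound is set")
  }
  structure(list(nTracks = nTracks, DFree = DFree, DBound = DBound,
                 pBound = pBound, kBind = kBind, kRelease = kRelease,
                 junctionDiscs = junctionDiscs, nAutoDiscs = nAutoDiscs,
                 autoDiscRadius = autoDiscRadius, confineBound = confineBound,
                 startInDiscs = startInDiscs, sigmaAxis = sigmaAxis,
                 frameInterval = frameInterval,
                 substepsPerFrame = as.integer(substepsPerFrame),
                 blur = isTRUE(blur),
                 trackLengthRange = as.integer(trackLengthRange),
                 roi = roi, seed = seed),
            class = "TwoStateSimConfig")
}

# reflect radial coordinate at a circle of radius R (small steps assumed)
reflectIntoDisc <- function(px, py, cx, cy, R) {
  dx <- px - cx; dy <- py - cy
  r <- sqrt(dx^2 + dy^2)
  out <- r > R
  if (any(out)) {
    rNew <- pmin(2 * R - r[out], R)        # clamp pathological large steps
    rNew <- pmax(rNew, 0)
    s <- ifelse(r[out] > 0, rNew / r[out], 0)
    px[out] <- cx + dx[out] * s
    py[out] <- cy + dy[out] * s
  }
  cbind(px, py)
}

#' Simulate two-state trajectories with motion blur and localization error
#'
#' True motion is Brownian at the state's diffusion coefficient, advanced at
#' substep resolution; bound molecules reflect at their junction-disc
#' boundary when confinement is enabled. Each reported frame position is the
#' mean of the substep true positions within that frame (continuous
#' illumination blur) plus independent per-axis Gaussian localization error.
#'
#' @param config a [twoStateSimConfig()].
#' @return list with `tracks` (a [TrackSet]), `truth` (data.frame: track_id,
#'   frame, state "free"/"bound", trueX, trueY, disc index), and `discs` (the
#'   disc layout used).
#' @export
simulateTwoStateTracks <- function(config) {
  stopifnot(inherits(config, "TwoStateSimConfig"))
  withSeed(config$seed, {
    r <- config$roi
    discs <- config$junctionDiscs
    if (is.null(discs)) {
      rad <- config$autoDiscRadius
      discs <- data.frame(
        cx = stats::runif(config$nAutoDiscs, r@x0 + rad, r@x0 + r@width - rad),
        cy = stats::runif(config$nAutoDiscs, r@y0 + rad, r@y0 + r@height - rad),
        r = rad)
    }
    if (config$confineBound && any(discs$r <= 0))
      stop("disc radius must be > 0 when confineBound is set")
    S <- config$substepsPerFrame
    dtSub <- config$frameInterval / S
    sdFree <- sqrt(2 * config$DFree * 1e6 * dtSub)   # nm per axis per substep
    sdBound <- sqrt(2 * config$DBound * 1e6 * dtSub)
    pBindSub <- config$kBind * dtSub
    pReleaseSub <- config$kRelease * dtSub
    switching <- pBindSub > 0 || pReleaseSub > 0
    out <- vector("list", config$nTracks)
    truth <- vector("list", config$nTracks)
    lens <- if (config$trackLengthRange[1] == config$trackLengthRange[2])
      rep(config$trackLengthRange[1], config$nTracks)
    else sample(seq(config$trackLengthRange[1], config$trackLengthRange[2]),
                config$nTracks, replace = TRUE)
    for (i in seq_len(config$nTracks)) {
      L <- lens[i]
      N <- L * S
      bound0 <- stats::runif(1) < config$pBound
      state <- if (switching) {
        st <- logical(N); cur <- bound0
        u <- stats::runif(N)
        for (k in seq_len(N)) {
          st[k] <- cur
          cur <- if (cur) (u[k] >= pReleaseSub) else (u[k] < pBindSub)
        }
        st
      } else rep(bound0, N)
      discIdx <- 0L
      inDisc <- bound0 && config$confineBound
      if ((inDisc || config$startInDiscs) && nrow(discs) > 0) {
        discIdx <- sample.int(nrow(discs), 1)
        rr <- discs$r[discIdx] * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        p0 <- c(discs$cx[discIdx] + rr * cos(th),
                discs$cy[discIdx] + rr * sin(th))
      } else {
        p0 <- c(stats::runif(1, r@x0, r@x0 + r@width),
                stats::runif(1, r@y0, r@y0 + r@height))
      }
      sd <- ifelse(state, sdBound, sdFree)
      incX <- stats::rnorm(N, 0, sd)
      incY <- stats::rnorm(N, 0, sd)
      confined <- config$confineBound && discIdx > 0
      if (confined && any(state)) {
        px <- numeric(N); py <- numeric(N)
        cur <- p0
        for (k in seq_len(N)) {
          cur <- cur + c(incX[k], incY[k])
          if (state[k]) {
            cur <- as.numeric(reflectIntoDisc(cur[1], cur[2],
                                              discs$cx[discIdx],
                                              discs$cy[discIdx],
                                              discs$r[discIdx]))
          }
          px[k] <- cur[1]; py[k] <- cur[2]
        }
      } else {
        px <- p0[1] + cumsum(incX)
        py <- p0[2] + cumsum(incY)
      }
      if (config$blur) {
        tx <- colMeans(matrix(px, nrow = S))
        ty <- colMeans(matrix(py, nrow = S))
      } else {
        tx <- px[seq_len(L) * S]
        ty <- py[seq_len(L) * S]
      }
      stateFrame <- state[seq(1, N, by = S)]
      ox <- tx + stats::rnorm(L, 0, config$sigmaAxis)
      oy <- ty + stats::rnorm(L, 0, config$sigmaAxis)
      out[[i]] <- data.frame(track_id = i, frame = seq_len(L) - 1L,
                             x = ox, y = oy)
      truth[[i]] <- data.frame(track_id = i, frame = seq_len(L) - 1L,
                               state = ifelse(stateFrame, "bound", "free"),
                               trueX = tx, trueY = ty, disc = discIdx)
    }
    list(tracks = TrackSet(do.call(rbind, out), channel = "red",
                           frameInterval = config$frameInterval),
         truth = do.call(rbind, truth), discs = discs)
  })
}

#' Simulate stationary calibration emitters
#'
#' Fixed-cell control: emitters with stationary true positions observed over
#' `nFrames` frames with independent per-axis Gaussian localization error.
#' The single-interval MSD of these tracks estimates `2 sigma_localization^2 =
#' 4 sigma_axis^2`.
#'
#' @param nEmitters number of emitters (one track each).
#' @param nFrames frames per track (>= 2).
#' @param sigmaAxis per-axis localization error (nm).
#' @param roi [Rect] for the true positions.
#' @param frameInterval seconds.
#' @param seed RNG seed.
#' @return a [TrackSet].
#' @export
simulateFixedEmitters <- function(nEmitters, nFrames = 2, sigmaAxis = 46,
                                  roi = Rect(0, 0, 20000, 20000),
                                  frameInterval = 0.05, seed = NULL) {
  if (nFrames < 2) stop("nFrames must be >= 2")
  if (sigmaAxis < 0) stop("sigmaAxis must be >= 0")
  withSeed(seed, {
    cx <- stats::runif(nEmitters, roi@x0, roi@x0 + roi@width)
    cy <- stats::runif(nEmitters, roi@y0, roi@y0 + roi@height)
    d <- data.frame(
      track_id = rep(seq_len(nEmitters), each = nFrames),
      frame = rep(seq_len(nFrames) - 1L, nEmitters),
      x = rep(cx, each = nFrames) +
        stats::rnorm(nEmitters * nFrames, 0, sigmaAxis),
      y = rep(cy, each = nFrames) +
        stats::rnorm(nEmitters * nFrames, 0, sigmaAxis))
    TrackSet(d, channel = "fixed", frameInterval = frameInterval)
  })
}

#' Configuration for the randomized cluster-field simulator
#'
#' The reference conditions: 17 cluster centers placed randomly in a
#' 4 x 4 um ROI, 32 localizations per 200-nm disc (or 100 per 400-nm disc),
#' each localization jittered by a 70-nm isotropic Gaussian, plus background
#' localizations at 0.7% of the 10-nm pixels.
#'
#' @param nClusters number of cluster centers.
#' @param roi [Rect].
#' @param discDiameter nm (200 or 400).
#' @param locsPerCluster localizations per cluster (32 or 100).
#' @param sigmaLoc per-axis localization uncertainty (nm).
#' @param backgroundPixelFraction fraction of pixels receiving one background
#'   localization (in `[0, 1)`), interpreted as an exact count of distinct
#'   pixels.
#' @param pixelSize nm.
#' @param seed RNG seed.
#' @return a validated configuration list of class `ClusterSimConfig`.
#' @export
clusterSimConfig <- function(nClusters = 17, roi = Rect(0, 0, 4000, 4000),
                             discDiameter = 200, locsPerCluster = 32,
                             sigmaLoc = 70, backgroundPixelFraction = 0.007,
                             pixelSize = 10, seed = NULL) {
  if (backgroundPixelFraction < 0 || backgroundPixelFraction >= 1)
    stop("backgroundPixelFraction must be in [0, 1)")
  if (discDiameter > min(roi@width, roi@height))
    stop("disc does not fit in the ROI")
  structure(list(nClusters = nClusters, roi = roi,
                 discDiameter = discDiameter,
                 locsPerCluster = locsPerCluster, sigmaLoc = sigmaLoc,
                 backgroundPixelFraction = backgroundPixelFraction,
                 pixelSize = pixelSize, seed = seed),
            class = "ClusterSimConfig")
}

#' Simulate a clustered localization field
#'
#' Cluster centers are uniform in the ROI (inset so each disc fits); each
#' cluster localization is a uniform point in the disc plus isotropic
#' Gaussian uncertainty (re-drawn until inside the ROI, so the total count is
#' exact). Background localizations sit at `round(fraction * nPixels)`
#' distinct, uniformly chosen pixels, at the pixel center plus sub-pixel
#' jitter.
#'
#' @param config a [clusterSimConfig()].
#' @return list with `table` (a [LocalizationTable], channel "green"),
#'   `centers` (data.frame cx, cy), and `truth` (integer vector: cluster id
#'   per record, 0 for background).
#' @export
simulateClusterField <- function(config) {
  stopifnot(inherits(config, "ClusterSimConfig"))
  withSeed(config$seed, {
    r <- config$roi
    rad <- config$discDiameter / 2
    cx <- stats::runif(config$nClusters, r@x0 + rad, r@x0 + r@width - rad)
    cy <- stats::runif(config$nClusters, r@y0 + rad, r@y0 + r@height - rad)
    m <- config$locsPerCluster
    xs <- ys <- numeric(config$nClusters * m)
    for (i in seq_len(config$nClusters)) {
      idx <- (i - 1) * m + seq_len(m)
      for (k in seq_len(m)) {
        repeat {
          rr <- rad * sqrt(stats::runif(1))
          th <- stats::runif(1, 0, 2 * pi)
          px <- cx[i] + rr * cos(th) + stats::rnorm(1, 0, config$sigmaLoc)
          py <- cy[i] + rr * sin(th) + stats::rnorm(1, 0, config$sigmaLoc)
          if (px >= r@x0 && px <= r@x0 + r@width &&
              py >= r@y0 && py <= r@y0 + r@height) break
        }
        xs[idx[k]] <- px; ys[idx[k]] <- py
      }
    }
    truth <- rep(seq_len(config$nClusters), each = m)
    p <- config$pixelSize
    nx <- ceiling(r@width / p); ny <- ceiling(r@height / p)
    nBg <- round(config$backgroundPixelFraction * nx * ny)
    if (nBg > 0) {
      pix <- sample.int(nx * ny, nBg)           # distinct pixels
      ix <- (pix - 1) %% nx
      iy <- (pix - 1) %/% nx
      bx <- r@x0 + (ix + 0.5) * p + stats::runif(nBg, -p / 2, p / 2)
      by <- r@y0 + (iy + 0.5) * p + stats::runif(nBg, -p / 2, p / 2)
      xs <- c(xs, bx); ys <- c(ys, by)
      truth <- c(truth, rep(0L, nBg))
    }
    d <- data.frame(frame = seq_along(xs) - 1L, x = xs, y = ys)
    list(table = LocalizationTable(d, roi = r, channel = "green"),
         centers = data.frame(cx = cx, cy = cy),
         truth = as.integer(truth))
  })
}

#' Simulate a dual-channel field with planted enrichment
#'
#' Places `nRed` red-channel localizations with probability density
#' `enrichment`-fold higher (lower, if < 1) inside a territory mask than
#' outside, normalized to the requested total.
#'
#' @param territory a binary [PixelMap]; must be neither empty nor full.
#' @param enrichment planted enrichment factor e >= 0 (e = 1 is spatially
#'   uniform; e = 0 excludes the territory entirely).
#' @param nRed number of red localizations.
#' @param seed RNG seed.
#' @return a [LocalizationTable] (channel "red") over the territory's ROI.
#' @export
simulateDualChannelField <- function(territory, enrichment, nRed,
                                     seed = NULL) {
  stopifnot(is(territory, "PixelMap"))
  if (enrichment < 0) stop("enrichment must be >= 0")
  g <- mapData(territory) > 0
  nIn <- sum(g); nOut <- sum(!g)
  if (nIn == 0 || nOut == 0)
    stop("territory must be neither empty nor full")
  withSeed(seed, {
    pIn <- enrichment * nIn / (enrichment * nIn + nOut)
    kIn <- stats::rbinom(1, nRed, pIn)
    p <- pixelSize(territory)
    o <- territory@origin
    drawIn <- function(cells, k) {
      sel <- cells[sample.int(length(cells), k, replace = TRUE)]
      ix <- (sel - 1) %% nrow(g)
      iy <- (sel - 1) %/% nrow(g)
      cbind(o[1] + ix * p + stats::runif(k, 0, p),
            o[2] + iy * p + stats::runif(k, 0, p))
    }
    inside <- if (kIn > 0) drawIn(which(g), kIn) else NULL
    outside <- if (nRed - kIn > 0) drawIn(which(!g), nRed - kIn) else NULL
    xy <- rbind(inside, outside)
    d <- data.frame(frame = seq_len(nRed) - 1L, x = xy[, 1], y = xy[, 2])
    LocalizationTable(d, roi = roi(territory), channel = "red")
  })
}

#' Convert a track set to a localization table
#'
#' @param tracks a [TrackSet].
#' @param roi optional [Rect]; defaults to the bounding box of the points.
#' @param channel channel label.
#' @return a [LocalizationTable] with one record per track point.
#' @export
tracksToLocalizations <- function(tracks, roi = NULL, channel = "red") {
  d <- trackData(tracks)
  LocalizationTable(data.frame(frame = d$frame, x = d$x, y = d$y),
                    roi = roi, frameInterval = frameInterval(tracks),
                    channel = channel)
}
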