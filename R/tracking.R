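# Frame-to-frame linking of localizations into trajectories.

#' Link localizations into trajectories
#'
#' Frame-to-frame assignment minimizing the total squared displacement over
#' the candidate pairs within `maxDisp` (optimal bipartite assignment per
#' frame pair, solved exactly). Detections left unmatched start or terminate
#' tracks; there is no gap closing, so a blink terminates the track. Tracks
#' shorter than `minLength` localizations are discarded.
#'
#' The assignment augments the cost matrix with birth/death entries at cost
#' `maxDisp^2`, so a link is made only when it is cheaper than leaving both
#' detections unmatched; candidate pairs farther apart than `maxDisp` are
#' forbidden outright.
#'
#' @param table a [LocalizationTable].
#' @param maxDisp maximum displacement between consecutive frames (nm;
#'   default 480, i.e. three 160-nm camera pixels at 50-ms frames).
#' @param minLength minimum track length in localizations (default 3).
#' @return a [TrackSet]; each retained localization belongs to exactly one
#'   track.
#' @export
linkTracks <- function(table, maxDisp = 480, minLength = 3) {
  stopifnotScalar(maxDisp, "maxDisp", positive = TRUE)
  d <- locData(table)
  if (!nrow(d))
    return(TrackSet(data.frame(track_id = integer(), frame = integer(),
                               x = numeric(), y = numeric()),
                    frameInterval = frameInterval(table)))
  o <- order(d$frame)
  d <- d[o, , drop = FALSE]
  frames <- sort(unique(d$frame))
  byFrame <- split(seq_len(nrow(d)), d$frame)
  trackOf <- integer(nrow(d))          # track id per localization row
  nextTrack <- 0L
  prevIdx <- byFrame[[1]]
  trackOf[prevIdx] <- nextTrack + seq_along(prevIdx)
  nextTrack <- nextTrack + length(prevIdx)
  big <- maxDisp^2                     # birth/death cost
  forbid <- 4 * big                    # forbidden pairing, never chosen
  for (f in seq_along(frames)[-1]) {
    curIdx <- byFrame[[f]]
    linked <- integer(length(curIdx))  # row index in d of predecessor, 0 = new
    if (frames[f] - frames[f - 1] == 1L && length(prevIdx)) {
      n1 <- length(prevIdx); n2 <- length(curIdx)
      dx <- outer(d$x[prevIdx], d$x[curIdx], "-")
      dy <- outer(d$y[prevIdx], d$y[curIdx], "-")
      cost <- dx^2 + dy^2
      cost[cost > big] <- forbid
      # square (n1+n2) augmented matrix: top-right death block, bottom-left
      # birth block, bottom-right zero block
      N <- n1 + n2
      aug <- matrix(0, N, N)
      aug[seq_len(n1), seq_len(n2)] <- cost
      death <- matrix(forbid, n1, n1); diag(death) <- big
      aug[seq_len(n1), n2 + seq_len(n1)] <- death
      birth <- matrix(forbid, n2, n2); diag(birth) <- big
      aug[n1 + seq_len(n2), seq_len(n2)] <- birth
      assign <- hungarian_lsap_cpp(aug)
      for (i in seq_len(n1)) {
        j <- assign[i]
        if (j <= n2 && cost[i, j] <= big) linked[j] <- prevIdx[i]
      }
    }
    for (k in seq_along(curIdx)) {
      if (linked[k] > 0L) {
        trackOf[curIdx[k]] <- trackOf[linked[k]]
      } else {
        nextTrack <- nextTrack + 1L
        trackOf[curIdx[k]] <- nextTrack
      }
    }
    prevIdx <- curIdx
  }
  keep <- trackOf %in% as.integer(names(which(table(trackOf) >= minLength)))
  dd <- data.frame(track_id = trackOf[keep], frame = d$frame[keep],
                   x = d$x[keep], y = d$y[keep])
  # renumber tracks consecutively in order of first appearance
  dd$track_id <- match(dd$track_id, unique(dd$track_id))
  TrackSet(dd, channel = locData(table)$channel[1] %||% "red",
           frameInterval = frameInterval(table), maxDisp = maxDisp)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a
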