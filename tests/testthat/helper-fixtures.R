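# shared fixture builders

uniformTable <- function(n, roi = Rect(0, 0, 4000, 4000), seed = NULL,
                         channel = "green") {
  junctionPALM:::withSeed(seed, {
    LocalizationTable(
      data.frame(frame = seq_len(n) - 1L,
                 x = runif(n, roi@x0, roi@x0 + roi@width),
                 y = runif(n, roi@y0, roi@y0 + roi@height)),
      roi = roi, channel = channel)
  })
}

# binary PixelMap with the given pixel indices set (1-based matrix indices)
binaryMap <- function(nx, ny, setIdx = NULL, pixelSize = 10,
                      origin = c(0, 0)) {
  g <- matrix(0, nx, ny)
  if (!is.null(setIdx)) g[setIdx] <- 1
  PixelMap(g, pixelSize, origin, binary = TRUE)
}

# straight track along x with constant step (nm)
straightTrack <- function(nSteps, step, id = 1L, y = 0) {
  data.frame(track_id = id, frame = 0:nSteps,
             x = step * (0:nSteps), y = y)
}
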