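# internal helpers

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL leaves the stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer or NULL")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# half-open binning [k*p, (k+1)*p): 1-based pixel index of a coordinate
# relative to `origin`; a point exactly on a boundary lands in the
# higher-index pixel.
pixelIndex <- function(coord, origin, pixelSize) {
  as.integer(floor((coord - origin) / pixelSize)) + 1L
}

clampIndex <- function(i, n) pmin(pmax(i, 1L), n)

stopifnotScalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name))
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}

# nm^2 -> um^2
nm2ToUm2 <- function(x) x / 1e6
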