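# internal helpers

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
# All generators funnel their randomness through this so that identical
# arguments (including seed) give bit-identical output.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Histogram counts over fixed equal-width bins; values clamped into range.
binCounts <- function(x, from, to, nBins) {
  x <- clamp(x, from, to)
  idx <- pmin(floor((x - from) / (to - from) * nBins), nBins - 1) + 1
  tabulate(idx, nbins = nBins)
}

shannonEntropyBits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# grid of pixel-centre coordinates: x along columns, y along rows
pixelGrid <- function(nr, nc) {
  list(x = matrix(rep(seq_len(nc), each = nr), nr, nc),
       y = matrix(rep(seq_len(nr), times = nc), nr, nc))
}

jaccard <- function(a, b) {
  sum(a & b) / sum(a | b)
}
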