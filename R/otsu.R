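#' Otsu's threshold from a binned intensity histogram
#'
#' Returns the level maximizing the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} over all candidate splits,
#' where class 0 collects bins at or below the candidate level and class 1
#' the bins strictly above it. Foreground is defined as intensity strictly
#' greater than the returned threshold; ties in the objective are broken
#' toward the smallest threshold, making the split bit-reproducible.
#'
#' @param counts histogram counts (typically 256 bins).
#' @param levels intensity value of each bin (default 0..length(counts)-1).
#' @return the threshold level (an element of \code{levels}).
#' @examples
#' counts <- integer(256); counts[51] <- 10; counts[201] <- 10
#' otsuThreshold(counts)  # 50: smallest of the tied separating levels
#' @export
otsuThreshold <- function(counts, levels = seq_along(counts) - 1) {
  stopifnot(length(counts) == length(levels), all(counts >= 0))
  if (sum(counts > 0) < 2)
    stop("degenerate histogram: fewer than 2 non-empty bins")
  n <- sum(counts)
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * levels)
  mu <- m0[length(m0)] / n
  # candidate k: class0 = bins 1..k, class1 = rest; k = length is no split
  k <- seq_len(length(counts) - 1)
  omega0 <- w0[k] / n
  omega1 <- 1 - omega0
  valid <- omega0 > 0 & omega1 > 0
  sigmaB <- rep(-Inf, length(k))
  mu0 <- m0[k][valid] / w0[k][valid]
  mu1 <- (m0[length(m0)] - m0[k][valid]) / (n - w0[k][valid])
  sigmaB[valid] <- omega0[valid] * omega1[valid] * (mu0 - mu1)^2
  best <- which.max(sigmaB)  # which.max returns the first (smallest) maximizer
  levels[best]
}

# Two-threshold (3-class) exhaustive Otsu on binned counts: maximizes
# sum_k omega_k * (mu_k - mu)^2 over all pairs t1 < t2. Ties broken toward
# the smallest (t1, t2) in lexicographic order. Returns levels[c(t1, t2)].
otsuThreshold2 <- function(counts, levels = seq_along(counts) - 1) {
  stopifnot(length(counts) == length(levels))
  if (sum(counts > 0) < 3)
    stop("degenerate histogram: fewer than 3 non-empty bins")
  n <- sum(counts)
  W <- c(0, cumsum(counts))
  M <- c(0, cumsum(counts * levels))
  B <- length(counts)
  # class sums for bins (a+1)..b via prefix differences
  classTerm <- function(a, b) {
    w <- W[b + 1] - W[a + 1]
    m <- M[b + 1] - M[a + 1]
    ifelse(w > 0, m^2 / w, 0)
  }
  t1 <- rep(seq_len(B - 2), times = (B - 2):1)
  t2 <- unlist(lapply(seq_len(B - 2), function(a) (a + 1):(B - 1)))
  obj <- classTerm(0, t1) + classTerm(t1, t2) + classTerm(t2, B)
  best <- which.max(obj)
  levels[c(t1[best], t2[best])]
}

# Bin a numeric matrix/vector into nBins equal-width bins over its observed
# range and return the Otsu threshold as an intensity (the upper edge of the
# last class-0 bin), so foreground = x > threshold.
imageOtsu <- function(x, nBins = 256) {
  rng <- range(x)
  if (diff(rng) == 0)
    stop("degenerate histogram: fewer than 2 non-empty bins")
  counts <- binCounts(x, rng[1], rng[2], nBins)
  lev <- otsuThreshold(counts, levels = seq_len(nBins) - 1)
  rng[1] + (lev + 1) * diff(rng) / nBins
}

# 3-class variant; returns the two intensity thresholds (bin upper edges).
imageOtsu2 <- function(x, nBins = 256) {
  rng <- range(x)
  if (diff(rng) == 0)
    stop("degenerate histogram: fewer than 2 non-empty bins")
  counts <- binCounts(x, rng[1], rng[2], nBins)
  lev <- otsuThreshold2(counts, levels = seq_len(nBins) - 1)
  rng[1] + (lev + 1) * diff(rng) / nBins
}
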