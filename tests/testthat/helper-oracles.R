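# Shared fixtures and independent oracles, built in code at test time.

# Coarse imaging geometry (8 um/px) used for the simulation suites so the
# multi-seed loops stay fast; the scientific geometry (colony size, annulus
# placement, intensities) is unchanged from the defaults.
coarseGeometry <- function(...) colonyGeometry(pixelSize = 8, ...)
COARSE_MIN_AREA <- 5000  # colony is ~12e3 px at 8 um/px

# Brute-force Otsu oracle: literal double loop over every candidate split,
# computing class weights and means from scratch. Keeps the smallest
# threshold on ties (strict improvement required to move).
bruteOtsu <- function(counts, levels = seq_along(counts) - 1) {
  n <- sum(counts)
  best <- -Inf; bestLevel <- NA_real_
  for (k in seq_len(length(counts) - 1)) {
    w0 <- sum(counts[1:k]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:k] * levels[1:k]) / w0
    mu1 <- sum(counts[(k + 1):length(counts)] *
                 levels[(k + 1):length(counts)]) / w1
    s <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (s > best) { best <- s; bestLevel <- levels[k] }
  }
  bestLevel
}

# Closed-form mean radius of a uniform annulus a <= r <= b:
# integral of r * 2*pi*r dr / area = 2(b^3 - a^3) / (3(b^2 - a^2))
annulusMeanRadius <- function(a, b) 2 * (b^3 - a^3) / (3 * (b^2 - a^2))

# Synthetic feature table driven by one latent annulus parameter: every
# feature is an affine transform of the latent plus small noise, except
# those named in `randomCols`, which are independent uniform draws.
latentFeatureTable <- function(n = 30, randomCols = character(), seed = 1) {
  set.seed(seed)
  latent <- runif(n)
  nm <- morphFeatureNames()
  X <- sapply(seq_along(nm), function(j)
    (j %% 5 + 1) * latent * (-1)^j + rnorm(n, sd = 0.05))
  colnames(X) <- nm
  for (rc in randomCols) X[, rc] <- runif(n)
  cbind(data.frame(compound = "x",
                   group = rep(c("control", "low", "medium", "high"),
                               length.out = n),
                   replicate = seq_len(n)),
        as.data.frame(X))
}

# Gaussian readout table for the dose-response statistics module
makeReadouts <- function(groupMeans, n = 5, sd = 1, nClusters = 1,
                         seed = NULL) {
  groups <- c("control", "low", "medium", "high")
  draw <- function() unlist(lapply(groupMeans, function(m) rnorm(n, m, sd)))
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(group = rep(groups, each = n))
  for (cl in seq_len(nClusters)) out[[paste0("CL", cl)]] <- draw()
  out
}

fourGroupDesign <- function(conc = c(control = 0, low = 1, medium = 10,
                                     high = 100), unit = "uM")
  doseDesign("testdrug", conc, unit)

# 90-degree rotation of a square matrix
rot90 <- function(m) t(m[nrow(m):1, ])
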