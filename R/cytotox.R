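# analytic inversion of the fitted 4PL at v = 0.75 * top
.ic25FromFit <- function(top, bottom, ic50, hill) {
  target <- 0.75 * top
  if (target <= bottom) return(NA_real_)  # curve never reaches 25% inhibition
  ic50 * ((top - bottom) / (target - bottom) - 1)^(1 / hill)
}

#' Fit a cytotoxicity curve and estimate the IC25
#'
#' Fits the four-parameter logistic \code{v(c) = bottom + (top - bottom) /
#' (1 + (c / ic50)^hill)} to replicate viability measurements by
#' least squares (Levenberg-Marquardt with fixed, data-driven starting
#' values, so the fit is deterministic). The IC25 -- the concentration
#' inhibiting viability by 25% relative to the fitted vehicle level
#' \code{top} -- is obtained by analytic inversion at \code{v = 0.75 *
#' top}. When the fitted curve never drops to 0.75 * top within the tested
#' range, the IC25 is right-censored and reported as "> cMax". If the
#' least-squares fit fails to converge, the estimate falls back to direct
#' curve reading: linear interpolation of mean viability against
#' log-concentration.
#'
#' @param viability data.frame with columns \code{concentration} and
#'   \code{viability} (and optionally \code{cell_line}); vehicle rows have
#'   concentration 0 and viability normalized so the vehicle reads ~1.
#' @param cellLine restrict to this cell line (when the table mixes lines).
#' @return A [CytotoxCurve-class].
#' @examples
#' vt <- generateViabilityData(viabilityDesign(noiseSd = 0, ic50 = 100))
#' fitIC25(vt)  # IC25 = 100/3 for hill = 1
#' @export
fitIC25 <- function(viability, cellLine = NULL) {
  if (!is.null(cellLine) && "cell_line" %in% names(viability))
    viability <- viability[viability$cell_line == cellLine, , drop = FALSE]
  if (is.null(cellLine))
    cellLine <- if ("cell_line" %in% names(viability))
      as.character(viability$cell_line[1]) else "unknown"
  viability <- viability[!is.na(viability$viability), , drop = FALSE]
  if (!nrow(viability)) stop("no usable viability measurements")
  conc <- viability$concentration
  v <- viability$viability
  nz <- sort(unique(conc[conc > 0]))
  if (length(nz) < 4)
    stop("need at least 4 distinct non-zero concentrations")
  cMax <- max(nz)

  # deterministic starts: top from the vehicle (or the largest mean),
  # bottom from the smallest observed mean, ic50 at the dose nearest
  # half-range, hill 1
  means <- tapply(v, conc, mean)
  top0 <- if (any(conc == 0)) means[["0"]] else max(means)
  bottom0 <- max(min(means), 0)
  half <- (top0 + bottom0) / 2
  nzMeans <- means[names(means) != "0"]
  ic500 <- nz[which.min(abs(nzMeans[as.character(nz)] - half))]

  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ bottom + (top - bottom) / (1 + (conc / ic50)^hill),
      start = list(top = top0, bottom = bottom0, ic50 = ic500, hill = 1),
      lower = c(top = 0, bottom = 0, ic50 = cMax * 1e-9, hill = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (!is.null(fit)) {
    p <- stats::coef(fit)
    ic25 <- .ic25FromFit(p[["top"]], p[["bottom"]], p[["ic50"]], p[["hill"]])
    censored <- is.na(ic25) || ic25 > cMax ||
      fourPL(cMax, p[["top"]], p[["bottom"]], p[["ic50"]], p[["hill"]]) >
        0.75 * p[["top"]]
    return(new("CytotoxCurve", cellLine = cellLine, fit = p,
               ic25 = if (censored) cMax else unname(ic25),
               censored = censored, cMax = cMax, method = "logistic_fit"))
  }

  # curve reading: interpolate mean viability vs log10(concentration)
  topHat <- unname(top0)
  target <- 0.75 * topHat
  m <- nzMeans[as.character(nz)]
  below <- which(m <= target)
  if (!length(below))
    return(new("CytotoxCurve", cellLine = cellLine, fit = numeric(0),
               ic25 = cMax, censored = TRUE, cMax = cMax,
               method = "curve_reading"))
  i <- below[1]
  ic25 <- if (i == 1) nz[1] else {
    x <- log10(nz[c(i - 1, i)]); y <- m[c(i - 1, i)]
    10^(x[1] + (target - y[1]) * diff(x) / diff(y))
  }
  new("CytotoxCurve", cellLine = cellLine, fit = numeric(0),
      ic25 = unname(ic25), censored = FALSE, cMax = cMax,
      method = "curve_reading")
}

#' Parameter-recovery check for the IC25 estimator
#'
#' Simulates one viability table from a [ViabilityDesign-class], fits it
#' with [fitIC25()], and reports the relative error against the design's
#' true IC25 (itself obtained by analytic inversion of the true curve).
#' Looping this over seeds characterizes estimator accuracy at a given
#' noise level.
#'
#' @param design a [ViabilityDesign-class].
#' @param seed integer seed for the simulated table.
#' @return list: trueIC25, estimate ([CytotoxCurve-class]), relative error
#'   (NA when censored).
#' @export
recoverIC25 <- function(design = viabilityDesign(), seed = NULL) {
  trueIC25 <- .ic25FromFit(design@top, design@bottom, design@ic50,
                           design@hill)
  tab <- generateViabilityData(design, seed = seed)
  est <- fitIC25(tab)
  rel <- if (est@censored) NA_real_ else abs(est@ic25 - trueIC25) / trueIC25
  list(trueIC25 = trueIC25, estimate = est, relativeError = rel)
}
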