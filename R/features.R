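#' The 19-attribute morphometric feature roster
#'
#' Names, in canonical order, of the 19 features extracted from the T+
#' region of each colony. Lengths are in um; rho denotes the radial
#' distance of a T+ pixel to the colony centroid normalized by the
#' equivalent colony radius R = sqrt(colony area / pi), so rho is
#' dimensionless and comparable across colony sizes.
#'
#' \describe{
#'   \item{area_T}{area of the T+ region, um^2}
#'   \item{area_fraction}{T+ area / colony area}
#'   \item{mean_dist_centroid}{mean distance of T+ pixels to the colony
#'     centroid, um}
#'   \item{mean_dist_outline}{mean distance of T+ pixels to the nearest
#'     colony outline pixel, um}
#'   \item{mean_rho, median_rho, std_rho, cv_rho, skew_rho, kurt_rho}{moments
#'     of the rho distribution (kurtosis is Fisher excess)}
#'   \item{entropy_rho, energy_rho}{Shannon entropy (bits) and energy
#'     (sum of squared bin probabilities) of a 64-bin histogram of rho on
#'     [0, 1.2]}
#'   \item{iqr_rho}{interquartile range of rho}
#'   \item{inner_edge_rho, outer_edge_rho}{5th and 95th percentiles of rho}
#'   \item{intensity_sd}{standard deviation of T+ pixel intensities, a.u.}
#'   \item{intensity_entropy, intensity_energy}{entropy (bits) and energy of
#'     a 256-bin histogram of T+ pixel intensities}
#'   \item{n_components}{number of connected components of the T+ mask}
#' }
#'
#' @return character vector of length 19.
#' @export
morphFeatureNames <- function() {
  c("area_T", "area_fraction", "mean_dist_centroid", "mean_dist_outline",
    "mean_rho", "median_rho", "std_rho", "cv_rho", "skew_rho", "kurt_rho",
    "entropy_rho", "energy_rho", "iqr_rho", "inner_edge_rho",
    "outer_edge_rho", "intensity_sd", "intensity_entropy",
    "intensity_energy", "n_components")
}

# distance (px) from every pixel to the nearest outline pixel, via a
# distance map on the complement of the outline set
.outlineDistance <- function(dimIm, outlinePts) {
  m <- matrix(1, dimIm[1], dimIm[2])
  m[cbind(outlinePts[, "y"], outlinePts[, "x"])] <- 0
  matrix(EBImage::distmap(m), dimIm[1], dimIm[2])
}

#' Extract the 19-feature morphometric vector from one colony
#'
#' All features describe the spatial and intensity distribution of the T+
#' region relative to the colony: absolute mean distances to centroid and
#' outline in um, plus the distribution of the normalized radial position
#' rho = d(pixel, centroid) / R with R the equivalent colony radius
#' sqrt(colony area / pi). Radial entropy/energy use a fixed 64-bin
#' histogram on rho in [0, 1.2]; intensity entropy/energy a 256-bin
#' histogram over the observed T+ intensity range. Extraction is fully
#' deterministic.
#'
#' @param image a [ColonyImage-class].
#' @param segmentation a completed [ColonySegmentation-class].
#' @param pixelSize um per px; defaults to the image's.
#' @return named numeric vector of length 19 (see [morphFeatureNames()]);
#'   all NA when the colony has no T+ pattern.
#' @examples
#' ci <- generateColonyImage(noiseSd = 0, seed = 1)
#' f <- extractFeatures(ci, segmentColony(ci))
#' round(f[["mean_dist_outline"]])  # ~ 197 um: the ~200 um displacement
#' @export
extractFeatures <- function(image, segmentation,
                            pixelSize = NULL) {
  stopifnot(is(image, "ColonyImage"), is(segmentation, "ColonySegmentation"))
  if (is.null(pixelSize)) pixelSize <- image@pixelSize
  nm <- morphFeatureNames()
  if (segmentation@noTpos || !any(segmentation@tMask)) {
    out <- rep(NA_real_, length(nm)); names(out) <- nm
    return(out)
  }
  tm <- segmentation@tMask
  cm <- segmentation@colonyMask
  cen <- segmentation@centroid
  nT <- sum(tm)
  nC <- sum(cm)
  R <- sqrt(nC * pixelSize^2 / pi)  # equivalent colony radius, um

  ij <- which(tm, arr.ind = TRUE)
  dCen <- sqrt((ij[, 2] - cen[1])^2 + (ij[, 1] - cen[2])^2) * pixelSize
  dOut <- .outlineDistance(dim(tm), segmentation@outline)[tm] * pixelSize
  rho <- dCen / R

  mu <- mean(rho); sdv <- stats::sd(rho)
  q <- stats::quantile(rho, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  pRho <- binCounts(rho, 0, 1.2, 64) / nT

  v <- image@intensity[tm]
  rngV <- range(v)
  if (diff(rngV) == 0) {
    pInt <- c(1, rep(0, 255))
  } else {
    pInt <- binCounts(v, rngV[1], rngV[2], 256) / nT
  }
  nComp <- max(EBImage::bwlabel(tm))

  out <- c(
    area_T = nT * pixelSize^2,
    area_fraction = nT / nC,
    mean_dist_centroid = mean(dCen),
    mean_dist_outline = mean(dOut),
    mean_rho = mu,
    median_rho = q[3],
    std_rho = sdv,
    cv_rho = sdv / mu,
    skew_rho = e1071::skewness(rho, type = 1),
    kurt_rho = e1071::kurtosis(rho, type = 1),
    entropy_rho = shannonEntropyBits(pRho),
    energy_rho = sum(pRho^2),
    iqr_rho = q[4] - q[2],
    inner_edge_rho = q[1],
    outer_edge_rho = q[5],
    intensity_sd = stats::sd(v),
    intensity_entropy = shannonEntropyBits(pInt),
    intensity_energy = sum(pInt^2),
    n_components = nComp
  )
  names(out) <- nm
  out
}

#' Extract the per-colony feature table for a colony set
#'
#' Runs [segmentColony()] and [extractFeatures()] over every colony and
#' assembles the keyed feature table. Colonies without a T+ pattern get NA
#' features and \code{qc_no_tpos = TRUE}; they are excluded from downstream
#' statistics (the exclusion count is reported via a message).
#'
#' @param colonies a [ColonySet-class].
#' @param minArea,minComponentArea segmentation parameters, px.
#' @param useTruth use the generator's ground-truth masks instead of image
#'   segmentation (for oracle checks).
#' @return data.frame: key columns (compound, group, replicate), 19 feature
#'   columns, and a qc_no_tpos flag.
#' @export
extractFeatureTable <- function(colonies, minArea = 1e4,
                                minComponentArea = 20, useTruth = FALSE) {
  stopifnot(is(colonies, "ColonySet"))
  rows <- lapply(seq_len(length(colonies)), function(i) {
    ci <- colonies[[i]]
    seg <- if (useTruth) truthSegmentation(ci)
           else segmentColony(ci, minArea = minArea,
                              minComponentArea = minComponentArea)
    extractFeatures(ci, seg)
  })
  feats <- do.call(rbind, rows)
  out <- cbind(colonies@info[, c("compound", "group", "replicate")],
               as.data.frame(feats),
               qc_no_tpos = apply(feats, 1, function(r) all(is.na(r))))
  n_missing <- sum(out$qc_no_tpos)
  if (n_missing > 0)
    message(sprintf("%d colonies had no T+ pattern and are flagged qc_no_tpos",
                    n_missing))
  out
}
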