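#' Boundary pixels of a mask
#'
#' The 8-connected boundary: mask pixels with at least one 4-neighbour
#' outside the mask (or lying on the image border).
#'
#' @param mask logical matrix.
#' @return integer matrix (n x 2, columns x, y) of boundary pixel
#'   coordinates.
#' @export
maskOutline <- function(mask) {
  stopifnot(is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  interior <- core &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  ij <- which(core & !interior, arr.ind = TRUE)
  cbind(x = ij[, 2], y = ij[, 1])
}

#' Detect the colony in a whole-colony fluorescence image
#'
#' Identifies the colony by its intensity difference from the background:
#' the full-image 256-bin histogram is split by a two-threshold (3-class)
#' exhaustive Otsu and everything above the lowest threshold is taken as
#' candidate colony (so both the dim T- carpet and the bright T+ ring are
#' captured); for near-bimodal histograms (fewer than 3 occupied bins) the
#' plain 2-class split is used. The colony mask is the largest connected
#' component with holes filled, its centroid the unweighted mean of mask
#' pixel coordinates, and its outline the 8-connected boundary.
#'
#' @param image a [ColonyImage-class].
#' @param minArea minimum acceptable component area, px (default 1e4).
#' @return A [ColonySegmentation-class] with an empty T+ mask (see
#'   [segmentTpos()]).
#' @examples
#' seg <- detectColony(generateColonyImage(seed = 1))
#' centroid(seg)
#' @export
detectColony <- function(image, minArea = 1e4) {
  stopifnot(is(image, "ColonyImage"))
  img <- image@intensity
  thr <- tryCatch(imageOtsu2(img)[1],
                  error = function(e) tryCatch(imageOtsu(img),
                                               error = function(e2) NA_real_))
  if (is.na(thr)) stop("no colony found: image has a single intensity level")
  fg <- img > thr
  lab <- EBImage::bwlabel(fg)
  if (max(lab) == 0) stop("no colony found: nothing above threshold")
  areas <- tabulate(lab[lab > 0])
  biggest <- which.max(areas)
  if (areas[biggest] < minArea)
    stop(sprintf("no colony found: largest component %d px < minArea %d px",
                 areas[biggest], as.integer(minArea)))
  mask <- matrix(EBImage::fillHull(lab == biggest) > 0, nrow(img), ncol(img))
  ij <- which(mask, arr.ind = TRUE)
  new("ColonySegmentation",
      colonyMask = mask,
      centroid = c(x = mean(ij[, 2]), y = mean(ij[, 1])),
      outline = maskOutline(mask),
      otsuThreshold = NA_real_,
      tMask = matrix(FALSE, nrow(img), ncol(img)),
      noTpos = TRUE)
}

#' Segment the colony into T+ and T- regions
#'
#' Applies 2-class Otsu thresholding to the colony pixels only; T+ pixels
#' are colony pixels with intensity strictly greater than the threshold.
#' Connected components smaller than \code{minComponentArea} are removed as
#' speckle. An empty result is not an error: the colony is flagged as
#' having no T+ pattern, a biologically meaningful outcome (complete
#' suppression of mesoendoderm differentiation).
#'
#' @param image a [ColonyImage-class].
#' @param segmentation a [ColonySegmentation-class] from [detectColony()].
#' @param minComponentArea minimum T+ component area, px (default 20).
#' @return The segmentation with \code{tMask}, \code{otsuThreshold} and
#'   \code{noTpos} filled in.
#' @export
segmentTpos <- function(image, segmentation, minComponentArea = 20) {
  stopifnot(is(image, "ColonyImage"), is(segmentation, "ColonySegmentation"))
  mask <- segmentation@colonyMask
  if (!any(mask)) stop("colony mask is empty")
  vals <- image@intensity[mask]
  thr <- tryCatch(imageOtsu(vals), error = function(e) NA_real_)
  tm <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!is.na(thr)) {
    tm[mask] <- image@intensity[mask] > thr
    if (any(tm) && minComponentArea > 1) {
      lab <- EBImage::bwlabel(tm)
      areas <- tabulate(lab[lab > 0])
      small <- which(areas < minComponentArea)
      if (length(small)) tm[matrix(lab, nrow(tm)) %in% small] <- FALSE
    }
  }
  out <- segmentation
  out@tMask <- tm
  out@otsuThreshold <- thr
  out@noTpos <- !any(tm)
  validObject(out)
  out
}

#' Full segmentation of one colony image
#'
#' Convenience wrapper: [detectColony()] followed by [segmentTpos()].
#'
#' @inheritParams detectColony
#' @inheritParams segmentTpos
#' @return A completed [ColonySegmentation-class].
#' @export
segmentColony <- function(image, minArea = 1e4, minComponentArea = 20) {
  segmentTpos(image, detectColony(image, minArea = minArea),
              minComponentArea = minComponentArea)
}
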