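# bilinear interpolation of matrix img (rows = y, cols = x) at continuous
# points; coordinates in pixel units with pixel centres at integers
.bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- clamp(floor(x), 1, nc - 1); y0 <- clamp(floor(y), 1, nr - 1)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
}

# nearest-neighbour variant (bit-exact sampling)
.nearest <- function(img, x, y) {
  img[cbind(clamp(round(y), 1, nrow(img)), clamp(round(x), 1, ncol(img)))]
}

# unit-spaced sample points along a polyline (n x 2 matrix, columns x, y),
# endpoints included; also returns the unit normal at each sample
.polylineSamples <- function(polyline) {
  seg <- diff(polyline)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) stop("polyline has duplicate consecutive control points")
  L <- sum(len)
  m <- max(2L, as.integer(round(L)) + 1L)
  s <- seq(0, L, length.out = m)
  cumLen <- c(0, cumsum(len))
  idx <- pmin(findInterval(s, cumLen, rightmost.closed = TRUE),
              nrow(seg))
  t <- (s - cumLen[idx]) / len[idx]
  pts <- polyline[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * t
  tang <- seg[idx, , drop = FALSE] / len[idx]
  normal <- cbind(-tang[, 2], tang[, 1])
  list(points = pts, normal = normal, arcLength = L)
}

#' Build a kymograph from a time-lapse stack
#'
#' For every frame, samples intensity at unit-spaced points along a
#' polyline (by bilinear interpolation, or nearest-neighbour for bit-exact
#' sampling) and stacks the profiles into a position-by-time raster: one
#' row per frame, one column per sample point. For \code{lineWidth} w > 1
#' (odd), the profile is averaged over the w perpendicular offsets centred
#' on the line, which suppresses uncorrelated noise by about 1/sqrt(w).
#'
#' @param stack numeric array (height x width x frames), e.g. from
#'   [generateTimelapse()] or [readStackTiff()].
#' @param polyline n x 2 matrix of control points (columns x, y, px).
#' @param lineWidth odd integer >= 1.
#' @param frameInterval minutes between frames (metadata).
#' @param interpolation "bilinear" or "nearest".
#' @return A [Kymograph-class].
#' @examples
#' tl <- generateTimelapse(60, 5, frontStartPx = 10,
#'                         frontVelocityPxPerFrame = 2)
#' line <- cbind(x = c(2, 58), y = c(16, 16))
#' ky <- buildKymograph(tl$stack, line)
#' dim(raster(ky))  # 5 frames x 57 positions
#' @export
buildKymograph <- function(stack, polyline, lineWidth = 1,
                           frameInterval = 20,
                           interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(length(dim(stack)) == 3, is.matrix(polyline),
            ncol(polyline) == 2, nrow(polyline) >= 2)
  if (lineWidth < 1 || lineWidth %% 2 != 1)
    stop("lineWidth must be an odd integer >= 1")
  nr <- dim(stack)[1]; nc <- dim(stack)[2]; nf <- dim(stack)[3]
  smp <- .polylineSamples(polyline)
  offsets <- seq(-(lineWidth - 1) / 2, (lineWidth - 1) / 2)
  np <- nrow(smp$points)
  allX <- matrix(smp$points[, 1], np, lineWidth) +
    outer(smp$normal[, 1], offsets)
  allY <- matrix(smp$points[, 2], np, lineWidth) +
    outer(smp$normal[, 2], offsets)
  bad <- which(allX < 1 | allX > nc | allY < 1 | allY > nr, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]
    stop(sprintf("polyline exits the image at sample point (%.1f, %.1f) [frame is %d x %d px]",
                 allX[bad[1, 1], bad[1, 2]], allY[bad[1, 1], bad[1, 2]],
                 nc, nr))
  }
  sampler <- if (interpolation == "bilinear") .bilinear else .nearest
  ras <- matrix(0, nf, nrow(smp$points))
  for (f in seq_len(nf)) {
    frame <- stack[, , f]
    prof <- matrix(sampler(frame, as.vector(allX), as.vector(allY)),
                   nrow(smp$points), lineWidth)
    ras[f, ] <- rowMeans(prof)
  }
  new("Kymograph", raster = ras, polyline = polyline,
      lineWidth = lineWidth, frameInterval = frameInterval)
}

#' Average-intensity Z-projection of a stack
#'
#' Mean intensity over frames; the projection on which a region of
#' interest (e.g. the colony periphery) is drawn before restoring the
#' polyline onto the time series.
#'
#' @param stack numeric array (height x width x frames).
#' @return numeric matrix (height x width).
#' @export
zProjection <- function(stack) {
  stopifnot(length(dim(stack)) == 3)
  apply(stack, c(1, 2), mean)
}

#' Locate a step edge in each kymograph row
#'
#' Utility for validating front motion: for each row (frame) of a
#' kymograph raster, finds the sub-pixel column where intensity crosses
#' the midpoint between the row's extremes, by linear interpolation
#' between the flanking samples.
#'
#' @param kymo a [Kymograph-class] or a numeric matrix.
#' @return numeric vector, one edge position (column units) per row.
#' @export
kymographEdgePositions <- function(kymo) {
  m <- if (is(kymo, "Kymograph")) kymo@raster else kymo
  apply(m, 1, function(row) {
    half <- (max(row) + min(row)) / 2
    below <- which(row <= half)
    if (!length(below) || below[1] == 1) return(NA_real_)
    i <- below[1]
    (i - 1) + (row[i - 1] - half) / (row[i - 1] - row[i])
  })
}
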