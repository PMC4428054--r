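#' Construct a colony geometry
#'
#' User-facing constructor for [ColonyGeometry-class]. The defaults encode
#' the day-3 screening phenotype: a 1-mm circular colony (radius 500 um)
#' imaged at 2 um/px, with the T+ mesoendoderm annulus spanning radii
#' 250-350 um so that its mean distance to the colony outline is about
#' 200 um.
#'
#' @param shape micropattern shape; only "circle" is implemented.
#' @param colonyDiameter colony diameter, um.
#' @param pixelSize um per pixel.
#' @param annulusCenterRadius radius of the annulus centre line, um.
#' @param annulusHalfWidth annulus half-width, um.
#' @param tIntensity,backgroundIntensity,colonyBaselineIntensity mean
#'   intensities (a.u., 16-bit range) of T+ pixels, background, and T-
#'   colony pixels; background < baseline < tIntensity.
#' @param imageMargin image margin around the colony, fraction of its radius.
#' @return A validated \code{ColonyGeometry}.
#' @examples
#' geo <- colonyGeometry()
#' colonyArea(geo)  # 7.85e5 um^2 for the 1-mm circle
#' @export
colonyGeometry <- function(shape = "circle",
                           colonyDiameter = 1000,
                           pixelSize = 2,
                           annulusCenterRadius = 300,
                           annulusHalfWidth = 50,
                           tIntensity = 200,
                           backgroundIntensity = 20,
                           colonyBaselineIntensity = 60,
                           imageMargin = 0.2) {
  new("ColonyGeometry", shape = shape, colonyDiameter = colonyDiameter,
      pixelSize = pixelSize, annulusCenterRadius = annulusCenterRadius,
      annulusHalfWidth = annulusHalfWidth, tIntensity = tIntensity,
      backgroundIntensity = backgroundIntensity,
      colonyBaselineIntensity = colonyBaselineIntensity,
      imageMargin = imageMargin)
}

#' Micropattern area
#'
#' Area of the adhesive micropattern island in um^2; for the default 1-mm
#' circle this is pi * 500^2 = 7.85e5 um^2.
#'
#' @param geometry a [ColonyGeometry-class].
#' @return area in um^2.
#' @export
colonyArea <- function(geometry) {
  stopifnot(is(geometry, "ColonyGeometry"))
  pi * (geometry@colonyDiameter / 2)^2
}

#' Construct a disruption model
#'
#' Defaults emulate the thalidomide-like phenotype: at full disruption the
#' annulus doubles in width (widenCoeff 1) and its centre line moves 150 um
#' toward the colony centre. The default group mapping spreads disruption
#' evenly over the low/medium/high doses.
#'
#' @param widenCoeff half-width multiplier per unit disruption.
#' @param inwardCoeff inward displacement, um per unit disruption.
#' @param fragmentationProb per-sector loss probability per unit disruption.
#' @param disruptionByGroup named numeric (control, low, medium, high).
#' @return A validated [DisruptionModel-class].
#' @export
disruptionModel <- function(widenCoeff = 1,
                            inwardCoeff = 150,
                            fragmentationProb = 0,
                            disruptionByGroup = c(control = 0, low = 1 / 3,
                                                  medium = 2 / 3, high = 1)) {
  new("DisruptionModel", widenCoeff = widenCoeff, inwardCoeff = inwardCoeff,
      fragmentationProb = fragmentationProb,
      disruptionByGroup = disruptionByGroup)
}

#' Construct a viability assay design
#'
#' Eight concentrations in 5-fold serial dilution from \code{cMax} plus the
#' vehicle at 0, three independent tests each, with ground-truth viability
#' following a 4PL curve.
#'
#' @param cMax top concentration; the dose series is cMax, cMax/5, ...,
#'   cMax/5^7.
#' @param nDoses number of non-zero doses (default 8).
#' @param top,bottom,ic50,hill true 4PL parameters (viability normalized so
#'   the vehicle reads \code{top}).
#' @param noiseSd replicate noise sd in viability units.
#' @param nReplicates independent tests per concentration.
#' @param cellLine label for the simulated line.
#' @return A validated [ViabilityDesign-class].
#' @export
viabilityDesign <- function(cMax = 1000, nDoses = 8,
                            top = 1, bottom = 0, ic50 = 100, hill = 1,
                            noiseSd = 0.05, nReplicates = 3,
                            cellLine = "H9") {
  new("ViabilityDesign", doses = cMax / 5^(seq_len(nDoses) - 1),
      top = top, bottom = bottom, ic50 = ic50, hill = hill,
      noiseSd = noiseSd, nReplicates = nReplicates, cellLine = cellLine)
}

# Render one colony raster plus ground-truth masks. Internal: assumes the
# RNG stream is already positioned (seeding handled by callers).
.renderColony <- function(geometry, disruption, model, noiseSd,
                          centerOffset = c(0, 0), radiusScale = 1) {
  px <- geometry@pixelSize
  R <- geometry@colonyDiameter / 2 * radiusScale
  acr <- (geometry@annulusCenterRadius - model@inwardCoeff * disruption) *
    radiusScale
  hw <- geometry@annulusHalfWidth * (1 + model@widenCoeff * disruption) *
    radiusScale
  if (acr - hw < 0)
    stop(sprintf(paste0("disrupted annulus extends past the colony centroid: ",
                        "inner edge %.1f um < 0 ",
                        "(centerRadius %.1f - halfWidth %.1f)"),
                 acr - hw, acr, hw))
  if (acr + hw > R)
    stop(sprintf(paste0("disrupted annulus extends past the colony edge: ",
                        "outer edge %.1f um > colony radius %.1f um"),
                 acr + hw, R))
  n <- 2L * as.integer(ceiling(geometry@colonyDiameter / 2 *
                                 (1 + geometry@imageMargin) / px))
  cx <- (n + 1) / 2 + centerOffset[1]
  cy <- (n + 1) / 2 + centerOffset[2]
  g <- pixelGrid(n, n)
  r <- sqrt((g$x - cx)^2 + (g$y - cy)^2) * px  # radial distance, um
  colony <- r <= R
  tmask <- colony & abs(r - acr) <= hw
  fragP <- clamp(model@fragmentationProb * disruption, 0, 1)
  if (fragP > 0) {
    nSect <- 12L
    keep <- stats::runif(nSect) >= fragP
    if (!any(keep)) keep[sample.int(nSect, 1)] <- TRUE  # ring never fully lost
    theta <- atan2(g$y - cy, g$x - cx)              # (-pi, pi]
    sect <- pmin(floor((theta + pi) / (2 * pi) * nSect), nSect - 1) + 1
    tmask <- tmask & matrix(keep[sect], n, n)
  }
  img <- matrix(geometry@backgroundIntensity, n, n)
  img[colony] <- geometry@colonyBaselineIntensity
  img[tmask] <- geometry@tIntensity
  if (noiseSd > 0)
    img <- img + matrix(stats::rnorm(n * n, sd = noiseSd), n, n)
  img <- clamp(img, 0, 65535)
  list(img = img, colonyMask = colony, tMask = tmask,
       centroid = c(x = cx, y = cy),
       annulusInner = acr - hw, annulusOuter = acr + hw, colonyRadius = R)
}

#' Generate a synthetic colony image with ground truth
#'
#' Renders a circular colony at the image centre on a dark background, with
#' a T+ annulus whose half-width is \code{annulusHalfWidth * (1 + widenCoeff
#' * disruption)} and whose centre-line radius is \code{annulusCenterRadius -
#' inwardCoeff * disruption}, plus additive zero-mean Gaussian noise clipped
#' to the 16-bit range. The exact masks used for rendering are attached as
#' ground truth, so downstream segmentation accuracy can be scored against
#' them. Identical arguments (including \code{seed}) give a bit-identical
#' raster.
#'
#' @param geometry a [ColonyGeometry-class].
#' @param disruption disruption level in [0, 1].
#' @param model a [DisruptionModel-class] supplying widen/inward/fragmentation
#'   coefficients.
#' @param noiseSd additive Gaussian noise sd, a.u.
#' @param seed integer seed; NULL draws from the current RNG stream.
#' @param centerOffset c(x, y) px offset of the colony centre (jitter).
#' @param radiusScale multiplicative jitter on all radii.
#' @return A [ColonyImage-class] whose \code{truth} holds \code{colonyMask},
#'   \code{tMask}, \code{centroid}, annulus radii and colony radius.
#' @examples
#' ci <- generateColonyImage(disruption = 0, noiseSd = 0, seed = 1)
#' range(truth(ci)$tMask)  # logical ground-truth annulus
#' @export
generateColonyImage <- function(geometry = colonyGeometry(),
                                disruption = 0,
                                model = disruptionModel(),
                                noiseSd = 0,
                                seed = NULL,
                                centerOffset = c(0, 0),
                                radiusScale = 1) {
  stopifnot(is(geometry, "ColonyGeometry"), is(model, "DisruptionModel"),
            disruption >= 0, disruption <= 1, noiseSd >= 0)
  validObject(geometry)
  r <- withSeed(seed, .renderColony(geometry, disruption, model, noiseSd,
                                    centerOffset, radiusScale))
  new("ColonyImage", intensity = r$img, pixelSize = geometry@pixelSize,
      metadata = list(disruption = disruption, noiseSd = noiseSd,
                      seed = seed, generator = "generateColonyImage"),
      truth = r[c("colonyMask", "tMask", "centroid", "annulusInner",
                  "annulusOuter", "colonyRadius")])
}

#' Generate a four-group dose series of colony images
#'
#' Produces \code{4 * nPerGroup} colonies for the groups control, low,
#' medium and high, mapping each group to a disruption level via
#' \code{model@disruptionByGroup}. Replicate-to-replicate variation comes
#' from geometric jitter (centroid offset uniform in +/- \code{jitterPx} px
#' per axis, all radii scaled by a factor uniform in 1 +/-
#' \code{jitterRadius}) and from the pixel noise.
#'
#' @inheritParams generateColonyImage
#' @param nPerGroup colonies per group (>= 2; ANOVA needs within-group
#'   variance).
#' @param compound compound label carried into the annotations.
#' @param jitterPx centroid jitter half-range, px.
#' @param jitterRadius radius jitter half-range, fraction.
#' @param seed integer seed for the whole series.
#' @return A [ColonySet-class] with info columns compound, group, replicate,
#'   disruption.
#' @examples
#' cs <- generateDoseSeries(nPerGroup = 2, noiseSd = 5, seed = 1)
#' colonyInfo(cs)
#' @export
generateDoseSeries <- function(geometry = colonyGeometry(),
                               model = disruptionModel(),
                               nPerGroup = 10,
                               noiseSd = 5,
                               seed = NULL,
                               compound = "compound",
                               jitterPx = 10,
                               jitterRadius = 0.05) {
  stopifnot(is(geometry, "ColonyGeometry"), is(model, "DisruptionModel"))
  if (nPerGroup < 2)
    stop("nPerGroup must be >= 2 (one-way ANOVA needs within-group variance)")
  groups <- names(model@disruptionByGroup)
  withSeed(seed, {
    images <- list()
    info <- data.frame(compound = character(), group = character(),
                       replicate = integer(), disruption = numeric())
    for (gname in groups) {
      d <- model@disruptionByGroup[[gname]]
      for (rep in seq_len(nPerGroup)) {
        off <- stats::runif(2, -jitterPx, jitterPx)
        rs <- 1 + stats::runif(1, -jitterRadius, jitterRadius)
        r <- .renderColony(geometry, d, model, noiseSd,
                           centerOffset = off, radiusScale = rs)
        ci <- new("ColonyImage", intensity = r$img,
                  pixelSize = geometry@pixelSize,
                  metadata = list(compound = compound, group = gname,
                                  replicate = rep, disruption = d),
                  truth = r[c("colonyMask", "tMask", "centroid",
                              "annulusInner", "annulusOuter", "colonyRadius")])
        images[[length(images) + 1L]] <- ci
        info <- rbind(info, data.frame(compound = compound, group = gname,
                                       replicate = rep, disruption = d))
      }
    }
    new("ColonySet", images = images, info = info)
  })
}

#' Four-parameter logistic viability curve
#'
#' \deqn{v(c) = bottom + (top - bottom) / (1 + (c / ic50)^{hill})}
#' The vehicle (c = 0) reads \code{top}; viability decreases monotonically
#' with concentration for \code{hill > 0}.
#'
#' @param conc concentration(s), same unit as \code{ic50}.
#' @param top,bottom,ic50,hill curve parameters.
#' @return viability at \code{conc}.
#' @examples
#' fourPL(100, top = 1, bottom = 0, ic50 = 100, hill = 1)  # 0.5
#' @export
fourPL <- function(conc, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Generate a replicated viability table
#'
#' Simulates the 8-point, 5-fold-dilution cytotoxicity assay: for each
#' concentration (including the vehicle at 0) and replicate, viability is
#' the true 4PL value plus Gaussian noise.
#'
#' @param design a [ViabilityDesign-class].
#' @param seed integer seed; NULL draws from the current stream.
#' @return data.frame with columns cell_line, concentration, replicate,
#'   viability; \code{(nDoses + 1) * nReplicates} rows.
#' @examples
#' head(generateViabilityData(viabilityDesign(noiseSd = 0), seed = 1))
#' @export
generateViabilityData <- function(design = viabilityDesign(), seed = NULL) {
  stopifnot(is(design, "ViabilityDesign"))
  validObject(design)
  conc <- c(0, sort(design@doses))
  withSeed(seed, {
    tab <- expand.grid(replicate = seq_len(design@nReplicates),
                       concentration = conc)
    v <- fourPL(tab$concentration, design@top, design@bottom,
                design@ic50, design@hill)
    if (design@noiseSd > 0)
      v <- v + stats::rnorm(length(v), sd = design@noiseSd)
    data.frame(cell_line = design@cellLine,
               concentration = tab$concentration,
               replicate = tab$replicate,
               viability = v)
  })
}

#' Generate a time-lapse stack with a moving front
#'
#' Renders frames in which a bright region advances along x as a step edge
#' moving at constant velocity, with sub-pixel edge placement by partial
#' pixel coverage. Used to validate kymograph construction against a known
#' trajectory.
#'
#' @param widthPx,heightPx frame size, px.
#' @param nFrames number of frames.
#' @param frontStartPx edge position in frame 0 (px, continuous).
#' @param frontVelocityPxPerFrame edge advance per frame (px; may be
#'   sub-pixel).
#' @param highIntensity,lowIntensity intensities behind/ahead of the front.
#' @param noiseSd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return list with \code{stack} (array height x width x frames) and
#'   \code{edgePositions} (ground-truth edge x per frame, frames indexed
#'   from 0).
#' @examples
#' tl <- generateTimelapse(40, 6, frontStartPx = 10,
#'                         frontVelocityPxPerFrame = 2)
#' tl$edgePositions  # 10 12 14 16 18 20
#' @export
generateTimelapse <- function(widthPx, nFrames, frontStartPx,
                              frontVelocityPxPerFrame,
                              heightPx = 32,
                              highIntensity = 200, lowIntensity = 20,
                              noiseSd = 0, seed = NULL) {
  pos <- frontStartPx + frontVelocityPxPerFrame * (seq_len(nFrames) - 1)
  if (any(pos < 1) || any(pos > widthPx - 1))
    stop(sprintf("front exits the frame: position %.1f px at frame %d (frame width %d px)",
                 pos[which(pos < 1 | pos > widthPx - 1)[1]],
                 which(pos < 1 | pos > widthPx - 1)[1] - 1, widthPx))
  withSeed(seed, {
    stack <- array(0, dim = c(heightPx, widthPx, nFrames))
    xleft <- seq_len(widthPx) - 1  # pixel i covers [i-1, i]
    for (f in seq_len(nFrames)) {
      cov <- clamp(pos[f] - xleft, 0, 1)  # fraction of pixel behind the front
      row <- lowIntensity + (highIntensity - lowIntensity) * cov
      frame <- matrix(row, heightPx, widthPx, byrow = TRUE)
      if (noiseSd > 0)
        frame <- frame + matrix(stats::rnorm(heightPx * widthPx, sd = noiseSd),
                                heightPx, widthPx)
      stack[, , f] <- clamp(frame, 0, 65535)
    }
    list(stack = stack, edgePositions = pos)
  })
}

#' Segmentation built from a synthetic image's ground truth
#'
#' Packages the generator's exact masks as a [ColonySegmentation-class],
#' bypassing image analysis. Useful as the reference when benchmarking
#' [detectColony()] / [segmentTpos()] and for feature oracles on ideal
#' masks.
#'
#' @param image a synthetic [ColonyImage-class] carrying ground truth.
#' @return A \code{ColonySegmentation} (otsuThreshold is NA: no threshold
#'   was applied).
#' @export
truthSegmentation <- function(image) {
  tr <- truth(image)
  if (!length(tr)) stop("image carries no ground truth")
  new("ColonySegmentation",
      colonyMask = tr$colonyMask,
      centroid = tr$centroid,
      outline = maskOutline(tr$colonyMask),
      otsuThreshold = NA_real_,
      tMask = tr$tMask,
      noTpos = !any(tr$tMask))
}
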