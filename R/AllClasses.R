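#' @import methods
NULL

#' Geometry of a micropatterned colony
#'
#' Describes the day-3 phenotype of a micropatterned hPSC colony: a circular
#' colony of given diameter bearing an annular BRACHYURY-positive (T+)
#' mesoendoderm ring. Defaults correspond to the screening geometry: a 1-mm
#' circle (area 7.85e5 um^2) whose T+ annulus spans radii 250-350 um, so the
#' mean T+-to-outline distance is approximately 200 um.
#'
#' @slot shape micropattern shape; only \code{"circle"} is implemented (the
#'   screening assay used circular micropatterns exclusively).
#' @slot colonyDiameter colony diameter in um.
#' @slot pixelSize pixel size in um per pixel.
#' @slot annulusCenterRadius radius (um) of the centre line of the T+ annulus.
#' @slot annulusHalfWidth half-width (um) of the T+ annulus.
#' @slot tIntensity mean fluorescence of T+ pixels (arbitrary units, 16-bit
#'   range).
#' @slot backgroundIntensity mean background fluorescence (a.u.).
#' @slot colonyBaselineIntensity mean fluorescence of T- colony pixels (a.u.).
#' @slot imageMargin margin around the colony as a fraction of its radius;
#'   controls the rendered image size.
#'
#' @seealso [colonyGeometry()] for the user-facing constructor,
#'   [generateColonyImage()].
#' @exportClass ColonyGeometry
setClass("ColonyGeometry",
  representation(
    shape = "character",
    colonyDiameter = "numeric",
    pixelSize = "numeric",
    annulusCenterRadius = "numeric",
    annulusHalfWidth = "numeric",
    tIntensity = "numeric",
    backgroundIntensity = "numeric",
    colonyBaselineIntensity = "numeric",
    imageMargin = "numeric"
  )
)

setValidity("ColonyGeometry", function(object) {
  msg <- character()
  if (!identical(object@shape, "circle"))
    msg <- c(msg, sprintf(
      "shape '%s' is not implemented; only 'circle' micropatterns are supported",
      object@shape))
  R <- object@colonyDiameter / 2
  if (object@colonyDiameter <= 0) msg <- c(msg, "colonyDiameter must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@annulusHalfWidth < 0) msg <- c(msg, "annulusHalfWidth must be >= 0")
  if (object@annulusCenterRadius + object@annulusHalfWidth > R)
    msg <- c(msg, sprintf(
      "annulusCenterRadius + annulusHalfWidth (%.1f um) exceeds the colony radius (%.1f um)",
      object@annulusCenterRadius + object@annulusHalfWidth, R))
  if (object@annulusCenterRadius - object@annulusHalfWidth < 0)
    msg <- c(msg, "annulus inner edge (centerRadius - halfWidth) is negative")
  ints <- c(object@backgroundIntensity, object@colonyBaselineIntensity,
            object@tIntensity)
  if (any(ints < 0) || any(ints > 65535))
    msg <- c(msg, "all intensities must lie in [0, 65535]")
  if (!(object@backgroundIntensity < object@colonyBaselineIntensity &&
        object@colonyBaselineIntensity < object@tIntensity))
    msg <- c(msg, "need backgroundIntensity < colonyBaselineIntensity < tIntensity")
  if (object@imageMargin < 0) msg <- c(msg, "imageMargin must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Dose-dependent disruption model for the mesoendoderm pattern
#'
#' Maps a dimensionless disruption level in [0, 1] to the teratogen phenotype:
#' the T+ annulus widens by a factor (1 + widenCoeff * disruption) and its
#' centre line moves inward by inwardCoeff * disruption micrometres, and the
#' ring may fragment into disconnected arcs.
#'
#' @slot widenCoeff dimensionless annulus half-width multiplier per unit
#'   disruption (>= 0).
#' @slot inwardCoeff inward displacement of the annulus centre line, um per
#'   unit disruption.
#' @slot fragmentationProb probability per unit disruption that any one
#'   angular sector of the ring is lost.
#' @slot disruptionByGroup named numeric mapping the four dose groups
#'   (control, low, medium, high) to disruption levels in [0, 1]; control is 0
#'   and levels are monotone non-decreasing.
#'
#' @seealso [disruptionModel()], [generateDoseSeries()]
#' @exportClass DisruptionModel
setClass("DisruptionModel",
  representation(
    widenCoeff = "numeric",
    inwardCoeff = "numeric",
    fragmentationProb = "numeric",
    disruptionByGroup = "numeric"
  )
)

setValidity("DisruptionModel", function(object) {
  msg <- character()
  if (object@widenCoeff < 0) msg <- c(msg, "widenCoeff must be >= 0")
  if (object@fragmentationProb < 0 || object@fragmentationProb > 1)
    msg <- c(msg, "fragmentationProb must be in [0, 1]")
  g <- object@disruptionByGroup
  if (!identical(names(g), c("control", "low", "medium", "high")))
    msg <- c(msg, "disruptionByGroup must be named control, low, medium, high (in order)")
  else {
    if (g[["control"]] != 0) msg <- c(msg, "disruptionByGroup['control'] must be 0")
    if (any(diff(g) < 0))
      msg <- c(msg, "disruption levels must be monotone non-decreasing control <= low <= medium <= high")
    if (any(g < 0 | g > 1)) msg <- c(msg, "disruption levels must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Design of an 8-point cytotoxicity viability assay
#'
#' Eight concentrations in 5-fold serial dilution from \code{cMax}, plus the
#' vehicle control at 0, each measured in \code{nReplicates} independent
#' tests. Ground-truth viability follows a four-parameter logistic (4PL)
#' curve.
#'
#' @slot doses non-zero concentrations, strictly decreasing by a factor 5.
#' @slot top,bottom,ic50,hill 4PL parameters of the true viability curve;
#'   viability is normalized so the vehicle (c = 0) reads \code{top}.
#' @slot noiseSd replicate noise standard deviation, as a fraction of
#'   viability units.
#' @slot nReplicates number of independent tests per concentration.
#' @slot cellLine label of the simulated cell line (e.g. H9, aHDF).
#'
#' @seealso [viabilityDesign()], [generateViabilityData()]
#' @exportClass ViabilityDesign
setClass("ViabilityDesign",
  representation(
    doses = "numeric",
    top = "numeric",
    bottom = "numeric",
    ic50 = "numeric",
    hill = "numeric",
    noiseSd = "numeric",
    nReplicates = "numeric",
    cellLine = "character"
  )
)

setValidity("ViabilityDesign", function(object) {
  msg <- character()
  d <- object@doses
  if (length(d) < 2 || any(d <= 0))
    msg <- c(msg, "doses must be positive non-zero concentrations")
  else if (any(abs(d[-length(d)] / d[-1] - 5) > 1e-8))
    msg <- c(msg, "doses must decrease strictly by a factor of 5 between consecutive points")
  if (!(object@bottom >= 0 && object@bottom < object@top))
    msg <- c(msg, "need 0 <= bottom < top")
  if (object@hill <= 0) msg <- c(msg, "hill must be > 0")
  if (object@ic50 <= 0) msg <- c(msg, "ic50 must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@nReplicates < 1) msg <- c(msg, "nReplicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A single-channel whole-colony fluorescence image
#'
#' A 2-D intensity raster (matrix, rows = y, columns = x, values on the
#' 16-bit scale) with its pixel size and provenance metadata. Synthetic
#' images additionally carry the exact ground-truth masks used to render
#' them, so segmentation accuracy is measurable as Jaccard overlap.
#'
#' @slot intensity numeric matrix of intensities in [0, 65535].
#' @slot pixelSize um per pixel.
#' @slot metadata free-form provenance list (generator parameters, seed,
#'   group, replicate, source path ...).
#' @slot truth list of ground-truth objects for synthetic images
#'   (\code{colonyMask}, \code{tMask}, logical matrices; \code{centroid},
#'   c(x, y) px; annulus radii in um); empty for images read from disk.
#'
#' @seealso [generateColonyImage()], [readColonyTiff()]
#' @exportClass ColonyImage
setClass("ColonyImage",
  representation(
    intensity = "matrix",
    pixelSize = "numeric",
    metadata = "list",
    truth = "list"
  )
)

setValidity("ColonyImage", function(object) {
  msg <- character()
  if (!is.numeric(object@intensity)) msg <- c(msg, "intensity must be numeric")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  v <- range(object@intensity)
  if (v[1] < 0 || v[2] > 65535)
    msg <- c(msg, "intensities must lie in the 16-bit range [0, 65535]")
  if (length(msg)) msg else TRUE
})

#' A set of colony images with sample annotations
#'
#' Container for a dose series: a list of [ColonyImage] objects plus a
#' per-colony annotation data frame (compound, group, replicate, disruption).
#'
#' @slot images list of \code{ColonyImage}.
#' @slot info data.frame with one row per image; columns at least
#'   \code{compound}, \code{group}, \code{replicate}.
#'
#' @seealso [generateDoseSeries()]
#' @exportClass ColonySet
setClass("ColonySet",
  representation(images = "list", info = "data.frame")
)

setValidity("ColonySet", function(object) {
  msg <- character()
  if (length(object@images) != nrow(object@info))
    msg <- c(msg, "length(images) must equal nrow(info)")
  if (!all(vapply(object@images, is, TRUE, "ColonyImage")))
    msg <- c(msg, "all elements of images must be ColonyImage objects")
  need <- c("compound", "group", "replicate")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, "info must have columns compound, group, replicate")
  if (length(msg)) msg else TRUE
})

#' Segmentation of a colony image
#'
#' The colony mask (colony vs background), its centroid and 8-connected
#' outline, and the Otsu split of colony pixels into T+ and T- regions.
#' An empty T+ mask is a biologically meaningful outcome (no mesoendoderm
#' pattern) recorded in \code{noTpos}, not an error.
#'
#' @slot colonyMask logical matrix, colony pixels.
#' @slot centroid c(x, y), unweighted centre of colony pixels, px
#'   (continuous).
#' @slot outline integer matrix (n x 2, columns x, y) of boundary pixels of
#'   the colony mask.
#' @slot otsuThreshold intensity threshold used for the T+/T- split (a.u.);
#'   NA before [segmentTpos()] has run.
#' @slot tMask logical matrix, T+ pixels (subset of colonyMask).
#' @slot noTpos TRUE when no T+ pattern was found.
#'
#' @seealso [detectColony()], [segmentTpos()], [segmentColony()]
#' @exportClass ColonySegmentation
setClass("ColonySegmentation",
  representation(
    colonyMask = "matrix",
    centroid = "numeric",
    outline = "matrix",
    otsuThreshold = "numeric",
    tMask = "matrix",
    noTpos = "logical"
  )
)

setValidity("ColonySegmentation", function(object) {
  msg <- character()
  if (!is.logical(object@colonyMask)) msg <- c(msg, "colonyMask must be logical")
  if (!is.logical(object@tMask)) msg <- c(msg, "tMask must be logical")
  if (!identical(dim(object@colonyMask), dim(object@tMask)))
    msg <- c(msg, "colonyMask and tMask must have identical dimensions")
  else if (any(object@tMask & !object@colonyMask))
    msg <- c(msg, "tMask must be a subset of colonyMask")
  if (length(object@centroid) != 2)
    msg <- c(msg, "centroid must be c(x, y)")
  else if (any(object@colonyMask)) {
    ij <- which(object@colonyMask, arr.ind = TRUE)
    if (object@centroid[1] < min(ij[, 2]) || object@centroid[1] > max(ij[, 2]) ||
        object@centroid[2] < min(ij[, 1]) || object@centroid[2] > max(ij[, 1]))
      msg <- c(msg, "centroid must lie inside the colony mask bounding box")
  }
  if (length(msg)) msg else TRUE
})

#' A partition of morphometric features into morphologic clusters
#'
#' Result of complete-linkage hierarchical clustering of the retained
#' features on the correlation distance 1 - r, cut at k clusters.
#'
#' @slot retained ordered character vector of retained feature names.
#' @slot dropped data.frame (feature, reason) of excluded features.
#' @slot linkage the \code{hclust} merge tree (as a list).
#' @slot k number of clusters.
#' @slot assignment named integer vector: feature -> cluster id in 1..k.
#'
#' @seealso [clusterFeatures()], [clusterReadouts()], [linkageNewick()]
#' @exportClass MorphClusterSet
setClass("MorphClusterSet",
  representation(
    retained = "character",
    dropped = "data.frame",
    linkage = "list",
    k = "numeric",
    assignment = "integer"
  )
)

setValidity("MorphClusterSet", function(object) {
  msg <- character()
  a <- object@assignment
  if (!identical(sort(names(a)), sort(object@retained)))
    msg <- c(msg, "assignment must cover exactly the retained features")
  if (length(a) && !identical(sort(unique(unname(a))), seq_len(object@k)))
    msg <- c(msg, "cluster ids must be contiguous 1..k with every cluster non-empty")
  if (length(msg)) msg else TRUE
})

#' A fitted cytotoxicity dose-response curve and its IC25
#'
#' Four-parameter logistic fit of viability against concentration, with the
#' 25% inhibitory concentration obtained by analytic inversion at
#' v = 0.75 * top. When the curve never reaches 0.75 * top within the tested
#' range the IC25 is right-censored and reported as "> cMax"; censoring is
#' carried explicitly and never silently converted to a number.
#'
#' @slot cellLine cell line label (e.g. H9, aHDF).
#' @slot fit named numeric (top, bottom, ic50, hill), or empty when the
#'   least-squares fit failed and curve reading was used.
#' @slot ic25 the IC25 concentration; when censored, the lower bound (cMax).
#' @slot censored TRUE when ic25 is a lower bound "> cMax".
#' @slot cMax largest tested concentration.
#' @slot method "logistic_fit" or "curve_reading".
#'
#' @seealso [fitIC25()]
#' @exportClass CytotoxCurve
setClass("CytotoxCurve",
  representation(
    cellLine = "character",
    fit = "numeric",
    ic25 = "numeric",
    censored = "logical",
    cMax = "numeric",
    method = "character"
  )
)

#' Dose-response statistics for one compound
#'
#' Per-cluster one-way ANOVA p-values, the 6-comparison post-hoc unpaired
#' t-test matrix, the Bonferroni-adjusted critical p-value, and the
#' disruption concentration (DC): the lowest tested concentration whose
#' vs-control contrast is significant within a cluster that passed ANOVA.
#'
#' @slot anovaP named numeric, cluster -> unadjusted ANOVA p-value.
#' @slot posthocP numeric matrix (6 pairwise comparisons x clusters) of
#'   two-sided unpaired t-test p-values; NA for clusters not consulted.
#' @slot alphaAdjusted Bonferroni-adjusted critical p (family alpha / 6).
#' @slot familyAlpha family-wise significance level for the ANOVA screen.
#' @slot dc the disruption concentration, NA when none ("none").
#' @slot dcUnit concentration unit.
#' @slot dcClusterSupport clusters at which the DC contrast was significant.
#'
#' @seealso [posthocDC()], [anovaPerCluster()]
#' @exportClass DoseStatsResult
setClass("DoseStatsResult",
  representation(
    anovaP = "numeric",
    posthocP = "matrix",
    alphaAdjusted = "numeric",
    familyAlpha = "numeric",
    dc = "numeric",
    dcUnit = "character",
    dcClusterSupport = "character"
  )
)

#' Per-compound teratogenicity report
#'
#' The final classification by the DC < IC25 rule together with everything
#' needed to audit it: the disruption concentration, the embryonic (and
#' optionally adult) IC25 with censoring status, the per-cluster statistics,
#' and provenance.
#'
#' @slot compound compound name.
#' @slot dc disruption concentration (NA = none determined).
#' @slot unit concentration unit shared by dc and the IC25 values.
#' @slot ic25Embryonic IC25 on embryonic cells (lower bound when censored).
#' @slot ic25EmbryonicCensored TRUE when ic25Embryonic is a lower bound.
#' @slot ic25Adult IC25 on adult cells (informational; NA when not measured).
#' @slot ic25AdultCensored censoring flag for ic25Adult.
#' @slot call "teratogenic" or "non-teratogenic".
#' @slot rationale human-readable justification of the call.
#' @slot stats the [DoseStatsResult-class] behind the DC (may be an empty
#'   placeholder when the report was built from printed DC/IC25 values).
#' @slot provenance list: package version, seeds, configuration.
#'
#' @seealso [callTeratogenicity()], [runPipeline()]
#' @exportClass TeratogenicityReport
setClass("TeratogenicityReport",
  representation(
    compound = "character",
    dc = "numeric",
    unit = "character",
    ic25Embryonic = "numeric",
    ic25EmbryonicCensored = "logical",
    ic25Adult = "numeric",
    ic25AdultCensored = "logical",
    call = "character",
    rationale = "character",
    stats = "ANY",
    provenance = "list"
  )
)

setValidity("TeratogenicityReport", function(object) {
  msg <- character()
  if (!object@call %in% c("teratogenic", "non-teratogenic"))
    msg <- c(msg, "call must be 'teratogenic' or 'non-teratogenic'")
  terat <- !is.na(object@dc) && object@dc < object@ic25Embryonic
  if (terat != (object@call == "teratogenic"))
    msg <- c(msg, "call must equal (dc defined AND dc < lower bound of ic25Embryonic)")
  if (length(msg)) msg else TRUE
})

#' A position-by-time kymograph
#'
#' Intensity raster with one row per frame and one column per unit-spaced
#' sample point along a polyline, as produced from a time-lapse stack.
#'
#' @slot raster numeric matrix, rows = frames, columns = positions along the
#'   polyline.
#' @slot polyline control points (n x 2 matrix, columns x, y, px).
#' @slot lineWidth odd integer; perpendicular averaging width in px.
#' @slot frameInterval minutes between frames.
#'
#' @seealso [buildKymograph()]
#' @exportClass Kymograph
setClass("Kymograph",
  representation(
    raster = "matrix",
    polyline = "matrix",
    lineWidth = "numeric",
    frameInterval = "numeric"
  )
)
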