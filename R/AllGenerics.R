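#' Accessors for teratoMorph objects
#'
#' Small accessor generics so that user code never touches slots directly:
#' \code{intensity} and \code{pixelSize} for [ColonyImage-class],
#' \code{truth} for its ground-truth list, \code{colonyMask}, \code{tMask},
#' \code{centroid}, \code{outline} and \code{segThreshold} for
#' [ColonySegmentation-class], \code{colonyInfo} for [ColonySet-class],
#' \code{clusterAssignment} for [MorphClusterSet-class], \code{ic25} for
#' [CytotoxCurve-class] and \code{raster} for [Kymograph-class].
#'
#' @param x the object.
#' @return The slot contents (see each class's documentation).
#' @name accessors
#' @examples
#' ci <- generateColonyImage(seed = 1)
#' pixelSize(ci)
#' dim(intensity(ci))
NULL

#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))
#' @rdname accessors
#' @export
setGeneric("colonyMask", function(x) standardGeneric("colonyMask"))
#' @rdname accessors
#' @export
setGeneric("tMask", function(x) standardGeneric("tMask"))
#' @rdname accessors
#' @export
setGeneric("centroid", function(x) standardGeneric("centroid"))
#' @rdname accessors
#' @export
setGeneric("outline", function(x) standardGeneric("outline"))
#' @rdname accessors
#' @export
setGeneric("segThreshold", function(x) standardGeneric("segThreshold"))
#' @rdname accessors
#' @export
setGeneric("colonyInfo", function(x) standardGeneric("colonyInfo"))
#' @rdname accessors
#' @export
setGeneric("clusterAssignment", function(x) standardGeneric("clusterAssignment"))
#' @rdname accessors
#' @export
setGeneric("ic25", function(x) standardGeneric("ic25"))
#' @rdname accessors
#' @export
setGeneric("raster", function(x) standardGeneric("raster"))

#' @rdname accessors
setMethod("intensity", "ColonyImage", function(x) x@intensity)
#' @rdname accessors
setMethod("pixelSize", "ColonyImage", function(x) x@pixelSize)
#' @rdname accessors
setMethod("truth", "ColonyImage", function(x) x@truth)
#' @rdname accessors
setMethod("colonyMask", "ColonySegmentation", function(x) x@colonyMask)
#' @rdname accessors
setMethod("tMask", "ColonySegmentation", function(x) x@tMask)
#' @rdname accessors
setMethod("centroid", "ColonySegmentation", function(x) x@centroid)
#' @rdname accessors
setMethod("outline", "ColonySegmentation", function(x) x@outline)
#' @rdname accessors
setMethod("segThreshold", "ColonySegmentation", function(x) x@otsuThreshold)
#' @rdname accessors
setMethod("colonyInfo", "ColonySet", function(x) x@info)
#' @rdname accessors
setMethod("clusterAssignment", "MorphClusterSet", function(x) x@assignment)
#' @rdname accessors
setMethod("ic25", "CytotoxCurve", function(x) x@ic25)
#' @rdname accessors
setMethod("raster", "Kymograph", function(x) x@raster)

#' @describeIn accessors number of colonies in the set
#' @export
setMethod("length", "ColonySet", function(x) length(x@images))

#' @describeIn accessors extract the i-th ColonyImage
#' @param i index
#' @export
setMethod("[[", "ColonySet", function(x, i) x@images[[i]])

setMethod("show", "ColonyImage", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("ColonyImage: %d x %d px, %.3g um/px (%.0f x %.0f um)\n",
              d[2], d[1], object@pixelSize,
              d[2] * object@pixelSize, d[1] * object@pixelSize))
  cat(sprintf("  intensity range [%.1f, %.1f]\n",
              min(object@intensity), max(object@intensity)))
  if (length(object@truth))
    cat("  carries ground truth:", paste(names(object@truth), collapse = ", "), "\n")
})

setMethod("show", "ColonySet", function(object) {
  cat(sprintf("ColonySet of %d colonies\n", length(object@images)))
  print(table(group = object@info$group))
})

setMethod("show", "ColonySegmentation", function(object) {
  cat(sprintf("ColonySegmentation: colony %d px, T+ %d px, centroid (%.1f, %.1f)\n",
              sum(object@colonyMask), sum(object@tMask),
              object@centroid[1], object@centroid[2]))
  if (object@noTpos) cat("  flagged: no T+ pattern\n")
  else cat(sprintf("  Otsu threshold %.2f a.u.\n", object@otsuThreshold))
})

setMethod("show", "MorphClusterSet", function(object) {
  cat(sprintf("MorphClusterSet: %d features in %d clusters (%d dropped)\n",
              length(object@retained), object@k, nrow(object@dropped)))
  for (cl in seq_len(object@k))
    cat(sprintf("  CL%d: %s\n", cl,
                paste(names(object@assignment)[object@assignment == cl],
                      collapse = ", ")))
})

setMethod("show", "CytotoxCurve", function(object) {
  cat(sprintf("CytotoxCurve [%s, %s]: IC25 = %s\n",
              object@cellLine, object@method,
              if (object@censored) sprintf(">%g", object@cMax)
              else sprintf("%g", object@ic25)))
})

setMethod("show", "DoseStatsResult", function(object) {
  cat("DoseStatsResult\n  ANOVA p by cluster:\n")
  print(signif(object@anovaP, 3))
  cat(sprintf("  adjusted critical p = %.4f; DC = %s %s\n",
              object@alphaAdjusted,
              if (is.na(object@dc)) "none" else format(object@dc),
              object@dcUnit))
})

setMethod("show", "TeratogenicityReport", function(object) {
  cat(sprintf("TeratogenicityReport: %s -> %s\n", object@compound, object@call))
  cat(sprintf("  DC = %s %s; IC25 (embryonic) = %s%s %s\n",
              if (is.na(object@dc)) "none" else format(object@dc), object@unit,
              if (object@ic25EmbryonicCensored) ">" else "",
              format(object@ic25Embryonic), object@unit))
  cat(" ", object@rationale, "\n")
})

setMethod("show", "Kymograph", function(object) {
  cat(sprintf("Kymograph: %d frames x %d positions, line width %d px, %g min/frame\n",
              nrow(object@raster), ncol(object@raster),
              object@lineWidth, object@frameInterval))
})
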