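#' Drop extraneous features before clustering
#'
#' Features that follow "random trends" carry no morphologic signal. Two
#' modes: \code{manual_list} drops an explicit list of feature names;
#' \code{auto} operationalizes "random trend" as correlating with nothing,
#' dropping every feature whose maximum absolute Pearson correlation with
#' all other features stays below \code{threshold}. Zero-variance features
#' (whose correlation is undefined) are also dropped in auto mode.
#'
#' @param features feature table from [extractFeatureTable()].
#' @param mode "auto" or "manual_list".
#' @param threshold correlation floor for auto mode (default 0.4).
#' @param dropList feature names to drop in manual_list mode.
#' @return list with \code{retained} (character), \code{dropped}
#'   (data.frame feature, reason).
#' @export
filterExtraneous <- function(features, mode = c("auto", "manual_list"),
                             threshold = 0.4, dropList = character()) {
  mode <- match.arg(mode)
  X <- featureMatrix(features)
  if (nrow(X) < 6)
    stop("need at least 6 colonies to judge feature trends")
  all_feats <- colnames(X)
  if (mode == "manual_list") {
    unknown <- setdiff(dropList, all_feats)
    if (length(unknown))
      stop("unknown features in dropList: ", paste(unknown, collapse = ", "))
    dropped <- data.frame(feature = dropList,
                          reason = rep("manual", length(dropList)))
  } else {
    sds <- apply(X, 2, stats::sd)
    zeroVar <- all_feats[sds == 0]
    varying <- setdiff(all_feats, zeroVar)
    r <- abs(stats::cor(X[, varying, drop = FALSE]))
    diag(r) <- 0
    maxr <- apply(r, 2, max)
    uncorrelated <- varying[maxr < threshold]
    dropped <- rbind(
      data.frame(feature = zeroVar,
                 reason = rep("zero variance", length(zeroVar))),
      data.frame(feature = uncorrelated,
                 reason = sprintf("max |r| = %.2f < %.2f",
                                  maxr[match(uncorrelated, varying)],
                                  threshold))
    )
  }
  retained <- setdiff(all_feats, dropped$feature)
  if (length(retained) < 2)
    stop("fewer than 2 features retained after filtering")
  list(retained = retained, dropped = dropped)
}

# numeric feature matrix from a feature table, rows = usable colonies
featureMatrix <- function(features) {
  nm <- intersect(morphFeatureNames(), names(features))
  if (!length(nm)) stop("no feature columns found")
  X <- as.matrix(features[, nm, drop = FALSE])
  keep <- stats::complete.cases(X)
  X[keep, , drop = FALSE]
}

#' Cluster features into morphologic clusters
#'
#' Computes the correlation distance d(f, g) = 1 - r(f, g) between retained
#' features across colonies (signed, not |r|: anti-correlated features must
#' not share a cluster, or their z-scores would cancel in the cluster
#' average), agglomerates by complete linkage, and cuts the tree at k
#' clusters. Cluster ids are contiguous 1..k in order of first appearance
#' over the canonical feature order, so the labelling is deterministic.
#'
#' @param features feature table from [extractFeatureTable()].
#' @param k number of morphologic clusters (default 7).
#' @param retained feature names to cluster; default all 19.
#' @return A [MorphClusterSet-class].
#' @examples
#' \dontrun{
#' cs <- generateDoseSeries(nPerGroup = 3, seed = 1)
#' ft <- extractFeatureTable(cs)
#' clusterFeatures(ft, k = 7)
#' }
#' @export
clusterFeatures <- function(features, k = 7,
                            retained = morphFeatureNames()) {
  X <- featureMatrix(features)[, retained, drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 colonies to correlate features")
  sds <- apply(X, 2, stats::sd)
  zeroVar <- retained[sds == 0]
  if (length(zeroVar)) {
    warning("excluding zero-variance features before clustering: ",
            paste(zeroVar, collapse = ", "))
    retained <- setdiff(retained, zeroVar)
    X <- X[, retained, drop = FALSE]
  }
  if (length(retained) < k)
    stop(sprintf("cannot form %d clusters from %d retained features",
                 k, length(retained)))
  d <- stats::as.dist(1 - stats::cor(X))
  hc <- stats::hclust(d, method = "complete")
  raw <- stats::cutree(hc, k = k)
  # relabel so cluster ids follow first appearance in canonical order
  ids <- unique(raw[retained])
  assignment <- as.integer(match(raw[retained], ids))
  names(assignment) <- retained
  new("MorphClusterSet",
      retained = retained,
      dropped = data.frame(feature = zeroVar,
                           reason = rep("zero variance", length(zeroVar))),
      linkage = unclass(hc),
      k = k,
      assignment = assignment)
}

#' Linkage tree as a Newick string
#'
#' Serializes the complete-linkage merge tree of a [MorphClusterSet-class]
#' for dendrogram inspection in any tree viewer.
#'
#' @param clusters a [MorphClusterSet-class].
#' @return a single Newick string.
#' @export
linkageNewick <- function(clusters) {
  stopifnot(is(clusters, "MorphClusterSet"))
  hc <- structure(clusters@linkage, class = "hclust")
  ape::write.tree(ape::as.phylo(hc))
}

#' Per-colony morphologic cluster readouts
#'
#' Each retained feature is z-scored across all usable colonies of the
#' experiment (so features with incompatible units become comparable), then
#' averaged within its cluster for every colony. Columns CL1..CLk are the
#' assay's per-colony readouts.
#'
#' @param features feature table from [extractFeatureTable()].
#' @param clusters a [MorphClusterSet-class] built from the same roster.
#' @return data.frame: key columns plus CL1..CLk.
#' @export
clusterReadouts <- function(features, clusters) {
  stopifnot(is(clusters, "MorphClusterSet"))
  if (!all(clusters@retained %in% names(features)))
    stop("clusters were built from a different feature roster")
  keep <- stats::complete.cases(features[, clusters@retained, drop = FALSE])
  X <- as.matrix(features[keep, clusters@retained, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  usable <- clusters@retained[sds > 0]
  if (length(usable) < length(clusters@retained))
    warning("excluding zero-variance features from cluster averages: ",
            paste(setdiff(clusters@retained, usable), collapse = ", "))
  Z <- scale(X[, usable, drop = FALSE])
  asg <- clusters@assignment[usable]
  readouts <- vapply(seq_len(clusters@k), function(cl) {
    members <- names(asg)[asg == cl]
    if (!length(members)) return(rep(NA_real_, nrow(Z)))
    rowMeans(Z[, members, drop = FALSE])
  }, numeric(nrow(Z)))
  colnames(readouts) <- paste0("CL", seq_len(clusters@k))
  keys <- intersect(c("compound", "group", "replicate"), names(features))
  cbind(features[keep, keys, drop = FALSE], as.data.frame(readouts))
}
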