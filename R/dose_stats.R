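#' Construct a four-group dose design
#'
#' @param compound compound name.
#' @param concentrations named numeric c(control = 0, low, medium, high),
#'   strictly increasing.
#' @param unit concentration unit string (e.g. "uM", "ug/ml").
#' @return a validated list of class "doseDesign".
#' @export
doseDesign <- function(compound,
                       concentrations = c(control = 0, low = 1, medium = 10,
                                          high = 100),
                       unit = "uM") {
  if (!identical(names(concentrations), c("control", "low", "medium", "high")))
    stop("concentrations must be named control, low, medium, high (in order)")
  if (concentrations[["control"]] != 0)
    stop("control concentration must be 0")
  if (any(diff(concentrations) <= 0))
    stop("concentrations must be strictly increasing from control")
  structure(list(compound = compound, concentrations = concentrations,
                 unit = unit, groups = names(concentrations)),
            class = "doseDesign")
}

#' Bonferroni-adjusted critical p-value
#'
#' For n groups there are choose(n, 2) pairwise comparisons; the adjusted
#' critical p-value is the family alpha divided by that count. For the
#' standard 4-group design at alpha = 0.05 this is 0.05 / 6 = 0.0083.
#'
#' @param nGroups number of groups (>= 2).
#' @param familyAlpha family-wise significance level.
#' @return adjusted critical p-value.
#' @examples
#' bonferroniAlpha(4, 0.05)  # 0.008333...
#' @export
bonferroniAlpha <- function(nGroups, familyAlpha = 0.05) {
  if (nGroups < 2) stop("need at least 2 groups")
  familyAlpha / choose(nGroups, 2)
}

# check readout table structure and group sizes; returns the group factor
.checkGroups <- function(readouts, design) {
  g <- factor(readouts$group, levels = design$groups)
  if (any(is.na(g))) stop("readouts contain groups outside the design")
  cnt <- table(g)
  if (length(cnt) != 4 || any(cnt == 0))
    stop("all 4 groups (control, low, medium, high) must be present")
  small <- names(cnt)[cnt < 2]
  if (length(small))
    stop("group(s) with fewer than 2 colonies: ", paste(small, collapse = ", "))
  g
}

#' One-way ANOVA per morphologic cluster
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F-test) of each
#' cluster readout across the four dose groups. P-values are reported
#' unadjusted across clusters: each cluster is screened at the family
#' alpha, mirroring how the assay inspects every cluster's dose-response
#' plot.
#'
#' @param readouts readout table from [clusterReadouts()] (needs a
#'   \code{group} column and CL columns).
#' @param design a [doseDesign()].
#' @return named numeric: cluster -> ANOVA p-value.
#' @export
anovaPerCluster <- function(readouts, design) {
  g <- .checkGroups(readouts, design)
  cls <- grep("^CL[0-9]+$", names(readouts), value = TRUE)
  if (!length(cls)) stop("no cluster readout columns (CL1..CLk) found")
  vapply(cls, function(cl) {
    y <- readouts[[cl]]
    # F = 0 (identical group means) gives p = 1; zero residual variance with
    # differing means gives p = 0
    fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
    p <- fit$p.value
    if (is.nan(p)) p <- 1  # all values identical: no evidence of any effect
    p
  }, numeric(1))
}

# two-sided unpaired t-test p-value; pooled variance by default (the
# assay's "unpaired t-test"), Welch optionally
.pairP <- function(y1, y2, welch = FALSE) {
  out <- tryCatch(stats::t.test(y1, y2, var.equal = !welch)$p.value,
                  error = function(e) NA_real_)  # e.g. constant data
  out
}

#' Post-hoc analysis and disruption concentration
#'
#' Implements the assay's decision logic. If no cluster reaches ANOVA
#' significance at the family alpha, the compound shows no morphologic
#' disruption and DC is "none". Otherwise, within every significant
#' cluster all 6 pairwise two-sided unpaired t-tests are computed; a dose
#' is disruptive in that cluster when its vs-control comparison has
#' p < familyAlpha / 6 (Bonferroni, fixed by the 4-group design). The DC is
#' the lowest disruptive concentration over all significant clusters.
#'
#' @param readouts readout table from [clusterReadouts()].
#' @param design a [doseDesign()].
#' @param anovaP per-cluster ANOVA p-values; computed when NULL.
#' @param familyAlpha family-wise significance level (default 0.05).
#' @param welch use Welch instead of pooled-variance t-tests.
#' @return A [DoseStatsResult-class].
#' @examples
#' \dontrun{
#' res <- posthocDC(readouts, doseDesign("thalidomide",
#'   c(control = 0, low = 30, medium = 300, high = 800), "uM"))
#' }
#' @export
posthocDC <- function(readouts, design, anovaP = NULL,
                      familyAlpha = 0.05, welch = FALSE) {
  g <- .checkGroups(readouts, design)
  if (is.null(anovaP)) anovaP <- anovaPerCluster(readouts, design)
  cls <- names(anovaP)
  pairs <- utils::combn(design$groups, 2)
  pairNames <- paste(pairs[1, ], pairs[2, ], sep = "-")
  alphaAdj <- bonferroniAlpha(length(design$groups), familyAlpha)

  posthoc <- matrix(NA_real_, nrow = ncol(pairs), ncol = length(cls),
                    dimnames = list(pairNames, cls))
  sig <- cls[anovaP < familyAlpha]
  for (cl in sig) {
    y <- readouts[[cl]]
    for (j in seq_len(ncol(pairs)))
      posthoc[j, cl] <- .pairP(y[g == pairs[1, j]], y[g == pairs[2, j]],
                               welch = welch)
  }

  dc <- NA_real_
  support <- character()
  if (length(sig)) {
    doses <- c("low", "medium", "high")
    contrasts <- paste("control", doses, sep = "-")
    pvc <- posthoc[contrasts, sig, drop = FALSE]  # vs-control p, dose x cluster
    disruptive <- !is.na(pvc) & pvc < alphaAdj
    if (any(disruptive)) {
      lowest <- which(apply(disruptive, 1, any))[1]
      dc <- design$concentrations[[doses[lowest]]]
      support <- sig[disruptive[lowest, ]]
    }
  }
  new("DoseStatsResult", anovaP = anovaP, posthocP = posthoc,
      alphaAdjusted = alphaAdj, familyAlpha = familyAlpha,
      dc = dc, dcUnit = design$unit, dcClusterSupport = support)
}
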