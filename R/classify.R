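#' Classify a compound by the DC < IC25 rule
#'
#' A compound is teratogenic when it disrupts the mesoendoderm pattern at a
#' concentration below its cytotoxic threshold on embryonic cells: DC <
#' IC25(embryonic). No DC (no significant disruption at any dose) means
#' non-teratogenic; DC at or above the IC25 means the disruption is
#' attributable to embryonic cytotoxicity rather than a specific
#' developmental effect, also non-teratogenic. A right-censored IC25
#' ("> x") is compared through its lower bound x, which is conservative:
#' DC < x implies DC < IC25. The rule is strict; DC equal to the IC25
#' bound is non-teratogenic. DC and IC25 must share their unit -- no
#' silent conversion.
#'
#' @param dc disruption concentration; NA for "none".
#' @param ic25Embryonic IC25 on embryonic cells (lower bound if censored).
#' @param unit concentration unit of \code{dc}.
#' @param ic25Unit concentration unit of \code{ic25Embryonic}; must equal
#'   \code{unit}.
#' @param ic25Censored TRUE when ic25Embryonic is a lower bound.
#' @param compound compound label.
#' @param ic25Adult,ic25AdultCensored optional adult-cell IC25
#'   (informational only; not part of the rule).
#' @param stats optional [DoseStatsResult-class] behind the DC.
#' @param provenance optional provenance list.
#' @return A [TeratogenicityReport-class].
#' @examples
#' callTeratogenicity(30, 1000, "uM", ic25Censored = TRUE,
#'                    compound = "Thalidomide")  # teratogenic
#' callTeratogenicity(1000, 787, "ug/ml", compound = "Penicillin G")
#' @export
callTeratogenicity <- function(dc, ic25Embryonic, unit = "",
                               ic25Unit = unit, ic25Censored = FALSE,
                               compound = "compound",
                               ic25Adult = NA_real_,
                               ic25AdultCensored = FALSE,
                               stats = NULL,
                               provenance = list()) {
  if (!identical(unit, ic25Unit))
    stop(sprintf("unit mismatch: DC in '%s' but IC25 in '%s' (no silent conversion)",
                 unit, ic25Unit))
  ic25Str <- paste0(if (ic25Censored) ">" else "", format(ic25Embryonic),
                    " ", unit)
  if (is.na(dc)) {
    call <- "non-teratogenic"
    rationale <- "no disruption concentration: no morphologic cluster showed significant dose-dependent disruption"
  } else if (dc < ic25Embryonic) {
    call <- "teratogenic"
    rationale <- sprintf(
      "DC = %s %s < IC25(embryonic) = %s: pattern disruption occurs below embryonic cytotoxicity",
      format(dc), unit, ic25Str)
  } else {
    call <- "non-teratogenic"
    rationale <- sprintf(
      "DC = %s %s >= IC25(embryonic) = %s: disruption attributable to embryonic cytotoxicity",
      format(dc), unit, ic25Str)
  }
  prov <- utils::modifyList(
    list(package = "teratoMorph",
         version = as.character(utils::packageVersion("teratoMorph"))),
    provenance)
  new("TeratogenicityReport", compound = compound, dc = dc, unit = unit,
      ic25Embryonic = ic25Embryonic, ic25EmbryonicCensored = ic25Censored,
      ic25Adult = ic25Adult, ic25AdultCensored = ic25AdultCensored,
      call = call, rationale = rationale,
      stats = if (is.null(stats)) NA else stats, provenance = prov)
}

#' Run the full morphometric screening pipeline
#'
#' Executes the assay end to end on one compound: segmentation and feature
#' extraction for every colony, extraneous-feature filtering, morphologic
#' clustering, per-cluster ANOVA with post-hoc DC determination, IC25
#' estimation from the viability table, and the final DC < IC25 call. All
#' intermediate tables are returned (and optionally written to
#' \code{outDir}), so every number in the report can be audited.
#'
#' @param colonies a [ColonySet-class] (images + plate annotations).
#' @param design a [doseDesign()] mapping groups to concentrations.
#' @param viability viability table (see [fitIC25()]) for embryonic cells.
#' @param viabilityAdult optional viability table for adult cells.
#' @param k number of morphologic clusters.
#' @param dropMode,dropThreshold,dropList see [filterExtraneous()].
#' @param minArea,minComponentArea segmentation parameters, px.
#' @param familyAlpha family-wise significance level.
#' @param outDir when non-NULL, directory to persist intermediates
#'   (features.csv, clusters.csv, readouts.csv, linkage.nwk, stats.json,
#'   report.json).
#' @return list: report ([TeratogenicityReport-class]), features, filter,
#'   clusters, readouts, stats ([DoseStatsResult-class]), cytotox
#'   ([CytotoxCurve-class]), cytotoxAdult.
#' @examples
#' \dontrun{
#' cs <- generateDoseSeries(nPerGroup = 10, noiseSd = 5, seed = 1)
#' vt <- generateViabilityData(viabilityDesign(cMax = 1000, ic50 = 5000))
#' res <- runPipeline(cs, doseDesign("drugX",
#'   c(control = 0, low = 1, medium = 10, high = 100), "uM"), vt)
#' res$report
#' }
#' @export
runPipeline <- function(colonies, design, viability, viabilityAdult = NULL,
                        k = 7, dropMode = c("auto", "manual_list"),
                        dropThreshold = 0.4, dropList = character(),
                        minArea = 1e4, minComponentArea = 20,
                        familyAlpha = 0.05, outDir = NULL) {
  dropMode <- match.arg(dropMode)
  stage <- function(label, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE))

  features <- stage("morphometry",
    extractFeatureTable(colonies, minArea = minArea,
                        minComponentArea = minComponentArea))
  filt <- stage("feature_filter",
    filterExtraneous(features, mode = dropMode, threshold = dropThreshold,
                     dropList = dropList))
  clusters <- stage("feature_clustering",
    clusterFeatures(features, k = k, retained = filt$retained))
  readouts <- stage("cluster_readouts", clusterReadouts(features, clusters))
  anovaP <- stage("anova", anovaPerCluster(readouts, design))
  stats <- stage("posthoc_dc",
    posthocDC(readouts, design, anovaP = anovaP, familyAlpha = familyAlpha))
  cyt <- stage("cytotoxicity", fitIC25(viability))
  cytA <- if (!is.null(viabilityAdult))
    stage("cytotoxicity_adult", fitIC25(viabilityAdult)) else NULL

  report <- callTeratogenicity(
    dc = stats@dc, ic25Embryonic = cyt@ic25, unit = design$unit,
    ic25Censored = cyt@censored, compound = design$compound,
    ic25Adult = if (is.null(cytA)) NA_real_ else cytA@ic25,
    ic25AdultCensored = if (is.null(cytA)) FALSE else cytA@censored,
    stats = stats,
    provenance = list(nColonies = length(colonies), k = k,
                      dropMode = dropMode, familyAlpha = familyAlpha))

  out <- list(report = report, features = features, filter = filt,
              clusters = clusters, readouts = readouts, stats = stats,
              cytotox = cyt, cytotoxAdult = cytA)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(features, file.path(outDir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(feature = names(clusters@assignment),
                 cluster = paste0("CL", clusters@assignment)),
      file.path(outDir, "clusters.csv"), row.names = FALSE)
    utils::write.csv(readouts, file.path(outDir, "readouts.csv"),
                     row.names = FALSE)
    writeLines(linkageNewick(clusters), file.path(outDir, "linkage.nwk"))
    jsonlite::write_json(
      list(anova_p = as.list(stats@anovaP),
           posthoc_p = as.data.frame(stats@posthocP),
           alpha_adjusted = stats@alphaAdjusted,
           dc = if (is.na(stats@dc)) "none" else stats@dc,
           dc_unit = stats@dcUnit,
           dc_cluster_support = stats@dcClusterSupport),
      file.path(outDir, "stats.json"), auto_unbox = TRUE, digits = NA)
    writeReport(report, file.path(outDir, "report.json"))
  }
  out
}

#' Write / read a teratogenicity report as JSON
#'
#' The JSON round-trips losslessly: censored values keep their censoring
#' flag and an undefined DC is serialized as the distinct token "none",
#' never as infinity.
#'
#' @param report a [TeratogenicityReport-class].
#' @param path file path.
#' @return \code{writeReport} returns \code{path} invisibly;
#'   \code{readReport} returns the reconstructed
#'   [TeratogenicityReport-class].
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "TeratogenicityReport"))
  jsonlite::write_json(list(
    compound = report@compound,
    dc = if (is.na(report@dc)) "none" else report@dc,
    unit = report@unit,
    ic25_embryonic = report@ic25Embryonic,
    ic25_embryonic_censored = report@ic25EmbryonicCensored,
    ic25_adult = if (is.na(report@ic25Adult)) "none" else report@ic25Adult,
    ic25_adult_censored = report@ic25AdultCensored,
    call = report@call,
    rationale = report@rationale,
    provenance = report@provenance
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  callTeratogenicity(
    dc = if (identical(x$dc, "none")) NA_real_ else as.numeric(x$dc),
    ic25Embryonic = as.numeric(x$ic25_embryonic),
    unit = x$unit,
    ic25Censored = isTRUE(x$ic25_embryonic_censored),
    compound = x$compound,
    ic25Adult = if (identical(x$ic25_adult, "none")) NA_real_
                else as.numeric(x$ic25_adult),
    ic25AdultCensored = isTRUE(x$ic25_adult_censored),
    provenance = as.list(x$provenance))
}
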