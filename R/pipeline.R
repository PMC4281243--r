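# Full-pipeline orchestration and the bookkeeping tally report.

#' Assemble a pipeline configuration
#'
#' Either file inputs (\code{expressionPath} + \code{metadataPath}, with
#' optional \code{ihcPath} and \code{referenceListPaths}) or synthetic mode
#' (\code{simConfig}) must be chosen -- supplying both is a configuration
#' error, never resolved silently.
#'
#' @param targetTissue target tissue name (required).
#' @param outDir output directory for the report bundle, or \code{NULL} to
#'   skip writing files.
#' @param expressionPath,metadataPath,ihcPath,referenceListPaths file
#'   inputs; \code{referenceListPaths} is a named character vector of
#'   gene-list files.
#' @param simConfig a \linkS4class{SimulationConfig} for synthetic mode.
#' @param thresholds a \linkS4class{SpecThresholds}.
#' @param topN size of the top-expressed report (default 30).
#' @param maxPartners sharing-network partner cutoff (default 3).
#' @param maxOtherTissues restricted-query cutoff (default 6).
#' @return A validated pipeline configuration (list).
#' @export
pipelineConfig <- function(targetTissue, outDir = NULL,
                           expressionPath = NULL, metadataPath = NULL,
                           ihcPath = NULL, referenceListPaths = NULL,
                           simConfig = NULL,
                           thresholds = SpecThresholds(),
                           topN = 30L, maxPartners = 3L,
                           maxOtherTissues = 6L) {
  if (missing(targetTissue) || is.null(targetTissue) ||
      !nzchar(targetTissue))
    tsStop("config field 'targetTissue' is required", "ts_config_error")
  synthetic <- !is.null(simConfig)
  files <- !is.null(expressionPath) || !is.null(metadataPath)
  if (synthetic && files)
    tsStop("supply either file inputs or simConfig, not both",
           "ts_config_error")
  if (!synthetic && (is.null(expressionPath) || is.null(metadataPath)))
    tsStop("file mode needs both expressionPath and metadataPath",
           "ts_config_error")
  structure(list(targetTissue = targetTissue, outDir = outDir,
                 expressionPath = expressionPath,
                 metadataPath = metadataPath, ihcPath = ihcPath,
                 referenceListPaths = referenceListPaths,
                 simConfig = simConfig, thresholds = thresholds,
                 topN = as.integer(topN),
                 maxPartners = as.integer(maxPartners),
                 maxOtherTissues = as.integer(maxOtherTissues)),
            class = "tsPipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of \code{\link{pipelineConfig}};
#' \code{thresholds:} and \code{simulation:} subsections override the
#' respective defaults field by field.
#'
#' @param path YAML file.
#' @return A validated pipeline configuration.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path))
    tsStop(sprintf("config file not found: %s", path),
           c("ts_missing_file", "ts_config_error"))
  y <- yaml::read_yaml(path)
  th <- do.call(SpecThresholds, as.list(y$thresholds))
  sim <- NULL
  if (isTRUE(y$synthetic) || !is.null(y$simulation)) {
    args <- as.list(y$simulation)
    if (!is.null(args$nGenesPerCategory))
      args$nGenesPerCategory <- unlist(args$nGenesPerCategory)
    if (!is.null(args$compartmentCounts))
      args$compartmentCounts <- unlist(args$compartmentCounts)
    if (!is.null(y$targetTissue)) args$targetTissue <- y$targetTissue
    sim <- do.call(SimulationConfig, args)
  }
  refs <- NULL
  if (!is.null(y$referenceListPaths)) refs <- unlist(y$referenceListPaths)
  pipelineConfig(targetTissue = y$targetTissue, outDir = y$outDir,
                 expressionPath = y$expressionPath,
                 metadataPath = y$metadataPath, ihcPath = y$ihcPath,
                 referenceListPaths = refs, simConfig = sim,
                 thresholds = th,
                 topN = if (is.null(y$topN)) 30L else y$topN,
                 maxPartners = if (is.null(y$maxPartners)) 3L
                               else y$maxPartners,
                 maxOtherTissues = if (is.null(y$maxOtherTissues)) 6L
                                   else y$maxOtherTissues)
}

stage <- function(name, expr) {
  tryCatch(expr, ts_error = function(e) {
    stop(errorCondition(sprintf("[stage %s] %s", name,
                                conditionMessage(e)),
                        class = class(e)))
  }, error = function(e) {
    if (inherits(e, "ts_error")) stop(e)
    tsStop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           "ts_data_error")
  })
}

#' Run the full analysis pipeline
#'
#' Stages, in order: input (read or simulate) -> replicate averaging ->
#' sample QC correlations -> classification -> pool fractions -> top-N ->
#' sharing network -> IHC integration (when annotations are available) ->
#' tally report -> file output. Any stage error aborts with the stage name
#' in the message. The run is idempotent for fixed inputs and seed; the
#' run log records thresholds, seed and input digests and contains no
#' timestamps, so repeated runs are byte-identical.
#'
#' @param config a configuration from \code{\link{pipelineConfig}} or
#'   \code{\link{readPipelineConfig}}.
#' @return A report bundle (list): \code{classification}, \code{tally},
#'   \code{poolFractions}, \code{topExpressed}, \code{network},
#'   \code{correlations}, \code{compartmentCalls}, \code{concordance},
#'   \code{referenceOverlap}, \code{tallyReport}, \code{truth} (synthetic
#'   mode only), \code{log}.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "tsPipelineConfig"))
    tsStop("config must come from pipelineConfig()", "ts_config_error")
  log <- c("TissueSpec pipeline run",
           sprintf("target_tissue: %s", config$targetTissue))
  truth <- NULL
  ihc <- NULL
  if (!is.null(config$simConfig)) {
    study <- stage("simulate", generateSyntheticStudy(config$simConfig))
    te <- study$expression
    truth <- study$truth
    ihc <- stage("simulate",
                 generateSyntheticIHC(study$truth, config$simConfig))
    log <- c(log, sprintf("mode: synthetic (seed %d)",
                          config$simConfig@seed))
  } else {
    fpkm <- stage("input", readExpressionTable(config$expressionPath))
    samples <- stage("input", readSampleMetadata(config$metadataPath))
    te <- stage("input", TissueExpression(fpkm, samples))
    if (!is.null(config$ihcPath))
      ihc <- stage("input", loadIHCAnnotations(config$ihcPath))
    log <- c(log, "mode: files",
             sprintf("expression_md5: %s",
                     unname(tools::md5sum(config$expressionPath))),
             sprintf("metadata_md5: %s",
                     unname(tools::md5sum(config$metadataPath))))
  }
  th <- config$thresholds
  log <- c(log, sprintf(
    "thresholds: detection=%g high=%g moderate=%g group=%g (%d-%d, %s) enhanced=%g floor=%g",
    th@detectionLimit, th@highEnrichmentFold, th@enrichmentFold,
    th@groupFold, th@groupMinSize, th@groupMaxSize, th@groupComparator,
    th@enhancedFold, th@tsDenominatorFloor))

  profile <- stage("average", averageByTissue(te))
  correlations <- stage("qc", pairwiseSampleCorrelation(te))
  classification <- stage("classify",
    classifyProfile(profile, config$targetTissue, th))
  tally <- stage("classify", categoryTally(classification))
  pool <- stage("pool", mrnaPoolFractions(classification))
  top <- stage("top", topExpressed(classification, config$topN))
  network <- stage("network",
    buildSharingNetwork(classification, config$maxPartners))

  calls <- NULL
  concordance <- NULL
  refOverlap <- NULL
  if (!is.null(ihc) && nrow(ihc)) {
    restricted <- stage("ihc",
      restrictedExpressionQuery(ihc, config$targetTissue,
                                config$maxOtherTissues))
    elevGenes <- specTable(classification)$gene_id[
      specTable(classification)$category %in% elevatedCategories()]
    calls <- stage("ihc", assignUniqueCompartment(ihc, elevGenes))
    concordance <- stage("ihc",
      rnaIhcConcordance(classification, restricted))
    if (!is.null(config$referenceListPaths)) {
      refs <- lapply(config$referenceListPaths, readGeneList)
      names(refs) <- names(config$referenceListPaths)
      refOverlap <- stage("ihc", compareToReferenceSets(calls, refs))
    }
  }
  report <- stage("report", tallyReport(tally, calls))

  bundle <- list(classification = classification, tally = tally,
                 poolFractions = pool, topExpressed = top,
                 network = network, correlations = correlations,
                 compartmentCalls = calls, concordance = concordance,
                 referenceOverlap = refOverlap, tallyReport = report,
                 truth = truth, log = log)
  if (!is.null(config$outDir))
    stage("output", writeReportBundle(bundle, config$outDir))
  bundle
}

#' Write a report bundle as TSV files
#'
#' @param bundle list from \code{\link{runPipeline}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
writeReportBundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  writeClassificationTable(bundle$classification,
                           file.path(dir, "classification.tsv"))
  tl <- bundle$tally
  wt(data.frame(category = names(tallyCounts(tl)),
                count = as.integer(tallyCounts(tl))),
     "category_tally.tsv")
  wt(data.frame(group = names(bundle$poolFractions),
                fraction = unname(bundle$poolFractions)),
     "pool_fractions.tsv")
  wt(as.data.frame(bundle$topExpressed), "top_expressed.tsv")
  writeNetworkEdgelist(bundle$network, dir)
  writeCorrelationMatrix(bundle$correlations,
                         file.path(dir, "sample_correlations.tsv"))
  if (!is.null(bundle$compartmentCalls))
    wt(bundle$compartmentCalls, "compartment_calls.tsv")
  if (!is.null(bundle$concordance))
    wt(data.frame(category = c(names(bundle$concordance$by_category),
                               "total"),
                  count = c(unname(bundle$concordance$by_category),
                            bundle$concordance$total)),
       "concordance.tsv")
  if (!is.null(bundle$referenceOverlap)) {
    wt(bundle$referenceOverlap$per_list, "reference_overlap.tsv")
    wt(data.frame(metric = "absent_from_all",
                  count = bundle$referenceOverlap$absent_from_all),
       "reference_absent_from_all.tsv")
  }
  wt(bundle$tallyReport, "tally_report.tsv")
  if (!is.null(bundle$truth)) wt(bundle$truth, "truth.tsv")
  writeLines(bundle$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Bookkeeping summary with recomputed sums
#'
#' Emits per-category counts, the elevated sum, the four-way top-level
#' partition (not detected / elevated / mixed / expressed in all) with its
#' total, and -- when compartment calls are supplied -- per-compartment
#' counts with their sum. Every sum is recomputed from the row-level
#' counts; a tally whose stored derived values disagree with its own
#' counts indicates an internal bug and raises a hard failure.
#'
#' @param tally a \linkS4class{CategoryTally}.
#' @param calls optional compartment-call data.frame
#'   (\code{\link{assignUniqueCompartment}}).
#' @return data.frame with columns \code{metric} and \code{count}.
#' @examples
#' tallyReport(CategoryTally(c(highly_enriched = 64,
#'                             group_enriched = 156, enhanced = 167)))
#' @export
tallyReport <- function(tally, calls = NULL) {
  cnt <- tallyCounts(tally)
  elevated <- sum(cnt[elevatedCategories()])
  total <- sum(cnt)
  if (elevated != tallyElevated(tally) || total != tallyTotal(tally))
    tsStop("inconsistent CategoryTally: derived sums disagree with counts",
           c("ts_inconsistent_tally", "ts_data_error"))
  out <- data.frame(
    metric = c(names(cnt), "elevated",
               "toplevel_not_detected", "toplevel_elevated",
               "toplevel_mixed", "toplevel_expressed_in_all", "total"),
    count = c(as.integer(cnt), elevated,
              cnt[["not_detected"]], elevated, cnt[["mixed"]],
              cnt[["expressed_in_all"]], total),
    stringsAsFactors = FALSE)
  if (!is.null(calls)) {
    comp <- table(factor(calls$compartment,
                         levels = nephronCompartments()))
    out <- rbind(out, data.frame(
      metric = c(paste0("compartment_", names(comp)),
                 "compartment_intercalated_only", "compartment_total"),
      count = c(as.integer(comp), sum(calls$intercalated_only),
                sum(comp)),
      stringsAsFactors = FALSE))
  }
  out
}
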