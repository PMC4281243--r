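#' @import methods
#' @importFrom S4Vectors DataFrame
#' @import SummarizedExperiment
NULL

#' Specificity categories
#'
#' The seven mutually exclusive categories a gene can receive relative to a
#' target tissue, in precedence order: below the detection limit in the
#' target; at least \code{highEnrichmentFold} above every other tissue;
#' at least \code{enrichmentFold} above every other tissue; part of a small
#' tissue group whose mean expression stands out against all remaining
#' tissues; above \code{enhancedFold} times the across-tissue average;
#' detected in every tissue; everything else.
#'
#' @return Character vector of the seven category labels, in precedence order.
#' @examples
#' specCategories()
#' @export
specCategories <- function() {
  c("not_detected", "highly_enriched", "moderately_enriched",
    "group_enriched", "enhanced", "expressed_in_all", "mixed")
}

#' Categories forming the "elevated" superset
#'
#' Elevated genes are those enriched (highly or moderately), group enriched
#' or enhanced in the target tissue.
#'
#' @return Character vector of the four elevated category labels.
#' @examples
#' elevatedCategories()
#' @export
elevatedCategories <- function() {
  c("highly_enriched", "moderately_enriched", "group_enriched", "enhanced")
}

#' Kidney cell-type vocabulary for IHC annotations
#'
#' Controlled vocabulary for the \code{cell_type} field of kidney IHC
#' annotation rows: the four nephron/collecting-duct compartments, the
#' intercalated-cell subtype of the collecting duct, and \code{"other"} for
#' structures outside the nephron (vessels, interstitium).
#'
#' @return Character vector of allowed kidney cell types.
#' @examples
#' kidneyCellTypes()
#' @export
kidneyCellTypes <- function() {
  c("glomeruli", "proximal_tubule", "distal_tubule",
    "collecting_duct", "collecting_duct_intercalated", "other")
}

#' Nephron compartments eligible for unique-localisation calls
#'
#' @return Character vector of the four compartment labels.
#' @examples
#' nephronCompartments()
#' @export
nephronCompartments <- function() {
  c("glomeruli", "proximal_tubule", "distal_tubule", "collecting_duct")
}

# ---- SpecThresholds ---------------------------------------------------------

#' Classification thresholds
#'
#' Holds the numeric cutoffs of the specificity classification. Defaults:
#' detection limit 1 FPKM; 50-fold for high enrichment; 5-fold for moderate
#' enrichment, group enrichment and enhancement; groups of 2--7 tissues;
#' a small floor (0.01 FPKM) on the denominator of the tissue-specificity
#' score that only guards division by exactly zero.
#'
#' @slot detectionLimit FPKM level at or above which a gene counts as
#'   detected in a tissue.
#' @slot highEnrichmentFold fold-change over the highest other tissue
#'   required for the highly-enriched category.
#' @slot enrichmentFold fold-change over the highest other tissue required
#'   for the moderately-enriched category.
#' @slot groupFold fold-change of the group mean over every outside tissue
#'   required for group enrichment.
#' @slot groupMinSize,groupMaxSize allowed group sizes (tissues, target
#'   included).
#' @slot enhancedFold fold-change over the all-tissue mean (target included)
#'   required for the enhanced category.
#' @slot tsDenominatorFloor positive floor applied to the maximum
#'   non-target FPKM before division.
#' @slot groupComparator \code{"max"} (default) compares the group mean to
#'   the maximum outside tissue; \code{"mean"} to the outside mean.
#' @export
setClass("SpecThresholds",
  representation(
    detectionLimit     = "numeric",
    highEnrichmentFold = "numeric",
    enrichmentFold     = "numeric",
    groupFold          = "numeric",
    groupMinSize       = "integer",
    groupMaxSize       = "integer",
    enhancedFold       = "numeric",
    tsDenominatorFloor = "numeric",
    groupComparator    = "character"
  ),
  prototype(
    detectionLimit     = 1,
    highEnrichmentFold = 50,
    enrichmentFold     = 5,
    groupFold          = 5,
    groupMinSize       = 2L,
    groupMaxSize       = 7L,
    enhancedFold       = 5,
    tsDenominatorFloor = 0.01,
    groupComparator    = "max"
  )
)

setValidity("SpecThresholds", function(object) {
  msg <- character()
  if (object@detectionLimit <= 0) msg <- c(msg, "detectionLimit must be > 0")
  if (object@enrichmentFold <= 1) msg <- c(msg, "enrichmentFold must be > 1")
  if (object@highEnrichmentFold < object@enrichmentFold)
    msg <- c(msg, "highEnrichmentFold must be >= enrichmentFold")
  if (object@groupMinSize < 2L)
    msg <- c(msg, "groupMinSize must be >= 2")
  if (object@groupMaxSize < object@groupMinSize)
    msg <- c(msg, "groupMaxSize must be >= groupMinSize")
  if (object@tsDenominatorFloor <= 0)
    msg <- c(msg, "tsDenominatorFloor must be > 0")
  if (!object@groupComparator %in% c("max", "mean"))
    msg <- c(msg, "groupComparator must be 'max' or 'mean'")
  if (length(msg)) msg else TRUE
})

#' Construct a SpecThresholds object
#'
#' @param detectionLimit,highEnrichmentFold,enrichmentFold,groupFold numeric
#'   cutoffs; see the class documentation for meaning and defaults.
#' @param groupMinSize,groupMaxSize integer group-size bounds.
#' @param enhancedFold,tsDenominatorFloor numeric cutoffs.
#' @param groupComparator \code{"max"} or \code{"mean"}.
#' @return A validated \linkS4class{SpecThresholds} object.
#' @examples
#' SpecThresholds()
#' SpecThresholds(detectionLimit = 0.5)
#' @export
SpecThresholds <- function(detectionLimit = 1, highEnrichmentFold = 50,
                           enrichmentFold = 5, groupFold = 5,
                           groupMinSize = 2L, groupMaxSize = 7L,
                           enhancedFold = 5, tsDenominatorFloor = 0.01,
                           groupComparator = "max") {
  new("SpecThresholds",
      detectionLimit = as.numeric(detectionLimit),
      highEnrichmentFold = as.numeric(highEnrichmentFold),
      enrichmentFold = as.numeric(enrichmentFold),
      groupFold = as.numeric(groupFold),
      groupMinSize = as.integer(groupMinSize),
      groupMaxSize = as.integer(groupMaxSize),
      enhancedFold = as.numeric(enhancedFold),
      tsDenominatorFloor = as.numeric(tsDenominatorFloor),
      groupComparator = groupComparator)
}

# ---- TissueExpression -------------------------------------------------------

#' Per-sample FPKM expression container
#'
#' A \linkS4class{SummarizedExperiment} with a single \code{fpkm} assay
#' (genes x samples) and column metadata holding \code{tissue} and
#' \code{individual} per sample. Values must be finite and non-negative and
#' gene identifiers unique.
#'
#' @export
setClass("TissueExpression", contains = "SummarizedExperiment")

setValidity("TissueExpression", function(object) {
  msg <- character()
  if (!"fpkm" %in% assayNames(object))
    msg <- c(msg, "assay 'fpkm' is required")
  else {
    v <- assay(object, "fpkm")
    if (any(!is.finite(v))) msg <- c(msg, "FPKM values must be finite")
    else if (any(v < 0)) msg <- c(msg, "FPKM values must be non-negative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers must be present and unique")
  if (!all(c("tissue", "individual") %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain 'tissue' and 'individual'")
  else if (any(!nzchar(as.character(colData(object)$tissue))))
    msg <- c(msg, "tissue names must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a TissueExpression object
#'
#' @param fpkm numeric matrix of FPKM values, genes in rows (unique
#'   rownames), samples in columns.
#' @param samples data.frame of sample metadata with columns
#'   \code{sample_id}, \code{tissue}, \code{individual}; every column of
#'   \code{fpkm} must appear in \code{sample_id}.
#' @return A validated \linkS4class{TissueExpression} object with samples
#'   ordered as in \code{fpkm}.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' md <- data.frame(sample_id = c("s1", "s2"),
#'                  tissue = c("kidney", "liver"),
#'                  individual = c("i1", "i1"))
#' TissueExpression(m, md)
#' @export
TissueExpression <- function(fpkm, samples) {
  if (!is.matrix(fpkm) || !is.numeric(fpkm))
    tsStop("fpkm must be a numeric matrix", "ts_data_error")
  missing <- setdiff(colnames(fpkm), samples$sample_id)
  if (length(missing))
    tsStop(sprintf("samples missing from metadata: %s",
                   paste(missing, collapse = ", ")),
           c("ts_missing_metadata", "ts_data_error"))
  idx <- match(colnames(fpkm), samples$sample_id)
  cd <- DataFrame(tissue = as.character(samples$tissue[idx]),
                  individual = as.character(samples$individual[idx]),
                  row.names = colnames(fpkm))
  new("TissueExpression",
      SummarizedExperiment(assays = list(fpkm = fpkm), colData = cd))
}

# ---- TissueProfile ----------------------------------------------------------

#' Tissue-level mean expression profile
#'
#' A \linkS4class{SummarizedExperiment} with a single \code{meanFPKM} assay
#' (genes x tissues, tissues in lexicographic order) and a per-tissue
#' \code{n_samples} column recording how many replicate samples were
#' averaged.
#'
#' @export
setClass("TissueProfile", contains = "SummarizedExperiment")

setValidity("TissueProfile", function(object) {
  msg <- character()
  if (!"meanFPKM" %in% assayNames(object))
    msg <- c(msg, "assay 'meanFPKM' is required")
  else {
    v <- assay(object, "meanFPKM")
    if (any(!is.finite(v)) || any(v < 0))
      msg <- c(msg, "mean FPKM values must be finite and non-negative")
  }
  if (!"n_samples" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'n_samples'")
  else if (any(colData(object)$n_samples < 1))
    msg <- c(msg, "each tissue needs >= 1 sample")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct a TissueProfile from a mean-FPKM matrix
#'
#' @param meanFPKM numeric matrix, genes x tissues, with unique dimnames.
#' @param nSamples integer vector of replicate counts per tissue (recycled
#'   to one if omitted).
#' @return A validated \linkS4class{TissueProfile}; tissues are reordered
#'   lexicographically.
#' @examples
#' m <- matrix(c(5, 1, 0.2, 3), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("kidney", "liver")))
#' TissueProfile(m)
#' @export
TissueProfile <- function(meanFPKM, nSamples = rep(1L, ncol(meanFPKM))) {
  ord <- order(colnames(meanFPKM))
  meanFPKM <- meanFPKM[, ord, drop = FALSE]
  nSamples <- as.integer(nSamples[ord])
  cd <- DataFrame(n_samples = nSamples, row.names = colnames(meanFPKM))
  new("TissueProfile",
      SummarizedExperiment(assays = list(meanFPKM = meanFPKM), colData = cd))
}

# ---- CategoryTally ----------------------------------------------------------

#' Category bookkeeping for one classification run
#'
#' Per-category gene counts plus the derived elevated count (sum of the
#' four elevated categories) and the grand total. The derived slots are
#' always recomputable from \code{counts}; \code{\link{tallyReport}} fails
#' hard if they disagree, which signals an internal bug rather than a data
#' problem.
#'
#' @slot counts named integer vector over \code{\link{specCategories}()}.
#' @slot elevated integer, sum over \code{\link{elevatedCategories}()}.
#' @slot total integer, sum of all counts.
#' @export
setClass("CategoryTally",
  representation(counts = "integer", elevated = "integer", total = "integer"))

setValidity("CategoryTally", function(object) {
  msg <- character()
  if (!identical(names(object@counts), specCategories()))
    msg <- c(msg, "counts must be named by specCategories()")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a CategoryTally from per-category counts
#'
#' @param counts named integer vector; names must be a subset of
#'   \code{\link{specCategories}()}; missing categories count zero.
#' @param elevated,total optional overrides of the derived sums; by default
#'   they are computed from \code{counts}. Overriding them creates an
#'   inconsistent tally that \code{\link{tallyReport}} will reject -- only
#'   useful for testing the consistency check.
#' @return A \linkS4class{CategoryTally}.
#' @examples
#' CategoryTally(c(highly_enriched = 64, group_enriched = 156,
#'                 enhanced = 167))
#' @export
CategoryTally <- function(counts, elevated = NULL, total = NULL) {
  bad <- setdiff(names(counts), specCategories())
  if (length(bad))
    tsStop(sprintf("unknown categories: %s", paste(bad, collapse = ", ")),
           "ts_data_error")
  full <- stats::setNames(integer(7), specCategories())
  full[names(counts)] <- as.integer(counts)
  if (is.null(elevated)) elevated <- sum(full[elevatedCategories()])
  if (is.null(total)) total <- sum(full)
  new("CategoryTally", counts = full, elevated = as.integer(elevated),
      total = as.integer(total))
}

# ---- SpecClassification -----------------------------------------------------

#' Per-gene classification results
#'
#' Wraps the per-gene result table of a classification run together with
#' the target tissue and the thresholds used. The table holds one row per
#' gene (input order preserved) with its category, tissue-specificity
#' score, target-tissue FPKM, the highest non-target FPKM and the tissue
#' carrying it, the enriched group (semicolon-joined, empty unless group
#' enriched) and the number of tissues in which the gene is detected.
#'
#' @slot table a \link[S4Vectors]{DataFrame} as described above.
#' @slot target target tissue name.
#' @slot thresholds the \linkS4class{SpecThresholds} used.
#' @export
setClass("SpecClassification",
  representation(table = "DataFrame", target = "character",
                 thresholds = "SpecThresholds"))

setValidity("SpecClassification", function(object) {
  need <- c("gene_id", "category", "ts_score", "target_fpkm",
            "max_other_fpkm", "second_tissue", "enriched_group",
            "n_detected_tissues")
  msg <- character()
  if (!all(need %in% colnames(object@table)))
    msg <- c(msg, "result table is missing required columns")
  else {
    if (!all(object@table$category %in% specCategories()))
      msg <- c(msg, "unknown category label in table")
    grp <- nzchar(object@table$enriched_group)
    if (!all(grp == (object@table$category == "group_enriched")))
      msg <- c(msg, "enriched_group must be non-empty iff group_enriched")
  }
  if (length(object@target) != 1L) msg <- c(msg, "single target tissue")
  if (length(msg)) msg else TRUE
})

# ---- SharingNetwork ---------------------------------------------------------

#' Bipartite tissue-sharing network
#'
#' Group nodes (one per distinct enriched-tissue set) connected to the
#' tissues in their set. Each group node carries the number of genes with
#' that exact set and a display size equal to the square root of that
#' count.
#'
#' @slot nodes data.frame with columns \code{id}, \code{type}
#'   ("group"/"tissue"), \code{gene_count}, \code{display_size}.
#' @slot edges data.frame with columns \code{source} (group id),
#'   \code{target} (tissue).
#' @slot targetTissue the tissue the classification was run against.
#' @export
setClass("SharingNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 targetTissue = "character"))

setValidity("SharingNetwork", function(object) {
  msg <- character()
  if (!all(c("id", "type", "gene_count", "display_size") %in%
           colnames(object@nodes)))
    msg <- c(msg, "nodes need id/type/gene_count/display_size")
  if (!all(c("source", "target") %in% colnames(object@edges)))
    msg <- c(msg, "edges need source/target")
  grp <- object@nodes[object@nodes$type == "group", , drop = FALSE]
  if (nrow(grp)) {
    if (any(grp$gene_count < 1)) msg <- c(msg, "gene_count must be >= 1")
    if (any(abs(grp$display_size - sqrt(grp$gene_count)) > 1e-9))
      msg <- c(msg, "display_size must equal sqrt(gene_count)")
  }
  if (length(msg)) msg else TRUE
})

# ---- SimulationConfig -------------------------------------------------------

#' Configuration of the synthetic multi-tissue study generator
#'
#' Defaults emulate a 27-tissue human compendium with four replicate
#' samples per tissue, log-normal replicate noise of 0.2 on the log2
#' scale, a detection floor at 1 FPKM, 100 planted genes per specificity
#' category, and planted fold changes at twice each category threshold
#' (100x for highly enriched, 10x for the 5x-threshold categories) so that
#' recovery is expected to be exact under the default noise.
#'
#' @slot nTissues number of tissues (>= 9 so that mixed-category genes can
#'   be detected in at least 12 tissues and group sizes up to 7 leave
#'   outside tissues).
#' @slot replicatesPerTissue replicate samples (individuals) per tissue.
#' @slot nGenesPerCategory named integer vector over
#'   \code{\link{specCategories}()}.
#' @slot plantedFold named numeric: fold changes used when planting
#'   \code{highly_enriched}, \code{moderately_enriched},
#'   \code{group_enriched} and \code{enhanced} genes.
#' @slot groupSizeRange integer length-2: planted group sizes (inclusive).
#' @slot baselineLog2Mean,baselineLog2SD location/half-width of the
#'   log2-uniform baseline expression level (FPKM) of detected genes.
#' @slot noiseSDLog2 SD of the log2-normal multiplicative replicate noise.
#' @slot detectionFloor FPKM detection limit the plants are anchored to.
#' @slot targetTissue tissue the plants refer to.
#' @slot compartmentCounts named integer vector: how many elevated genes
#'   are planted in each IHC compartment (the
#'   \code{collecting_duct_intercalated} entry plants collecting-duct genes
#'   confined to intercalated cells).
#' @slot distractorFraction fraction of compartment-planted genes that also
#'   receive a positive annotation in a second compartment, to exercise the
#'   exclusivity filter.
#' @slot seed integer seed making the generator deterministic.
#' @export
setClass("SimulationConfig",
  representation(
    nTissues = "integer", replicatesPerTissue = "integer",
    nGenesPerCategory = "integer", plantedFold = "numeric",
    groupSizeRange = "integer", baselineLog2Mean = "numeric",
    baselineLog2SD = "numeric", noiseSDLog2 = "numeric",
    detectionFloor = "numeric", targetTissue = "character",
    compartmentCounts = "integer", distractorFraction = "numeric",
    seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nTissues < 9L)
    msg <- c(msg, "nTissues must be >= 9")
  if ("enhanced" %in% names(object@nGenesPerCategory) &&
      object@nGenesPerCategory[["enhanced"]] > 0 && object@nTissues < 26L)
    msg <- c(msg,
      "planting enhanced genes needs >= 26 tissues (the decaying-head construction)")
  if (object@replicatesPerTissue < 1L)
    msg <- c(msg, "replicatesPerTissue must be >= 1")
  if (!identical(names(object@nGenesPerCategory), specCategories()))
    msg <- c(msg, "nGenesPerCategory must be named by specCategories()")
  if (any(object@nGenesPerCategory < 0))
    msg <- c(msg, "gene counts must be >= 0")
  if (object@groupSizeRange[2] >= object@nTissues)
    msg <- c(msg, "group sizes must leave outside tissues")
  if (object@noiseSDLog2 < 0) msg <- c(msg, "noiseSDLog2 must be >= 0")
  if (object@distractorFraction < 0 || object@distractorFraction > 1)
    msg <- c(msg, "distractorFraction must be in [0,1]")
  ncomp <- sum(object@compartmentCounts)
  nelev <- sum(object@nGenesPerCategory[elevatedCategories()])
  if (ncomp > nelev)
    msg <- c(msg, "more compartment plants than elevated genes")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param nTissues,replicatesPerTissue study dimensions.
#' @param nGenesPerCategory named integer vector (missing categories
#'   default to 100 each).
#' @param plantedFold named numeric fold map for the four elevated
#'   categories.
#' @param groupSizeRange planted group-size range, inclusive.
#' @param baselineLog2Mean,baselineLog2SD baseline expression level
#'   (log2 FPKM) of detected genes.
#' @param noiseSDLog2 replicate noise SD on the log2 scale.
#' @param detectionFloor FPKM detection limit.
#' @param targetTissue name of the target tissue.
#' @param compartmentCounts named integer vector of planted compartment
#'   localisations.
#' @param distractorFraction fraction of compartment plants receiving a
#'   second-compartment distractor annotation.
#' @param seed integer seed.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' SimulationConfig(seed = 7)
#' @export
SimulationConfig <- function(nTissues = 27L, replicatesPerTissue = 4L,
                             nGenesPerCategory = integer(),
                             plantedFold = c(highly_enriched = 100,
                                             moderately_enriched = 10,
                                             group_enriched = 10,
                                             enhanced = 10),
                             groupSizeRange = c(2L, 7L),
                             baselineLog2Mean = log2(20),
                             baselineLog2SD = 0.5,
                             noiseSDLog2 = 0.2,
                             detectionFloor = 1,
                             targetTissue = "kidney",
                             compartmentCounts = c(
                               glomeruli = 11L, proximal_tubule = 120L,
                               distal_tubule = 9L, collecting_duct = 5L,
                               collecting_duct_intercalated = 3L),
                             distractorFraction = 0,
                             seed = 1L) {
  full <- stats::setNames(rep(100L, 7), specCategories())
  full[names(nGenesPerCategory)] <- as.integer(nGenesPerCategory)
  new("SimulationConfig",
      nTissues = as.integer(nTissues),
      replicatesPerTissue = as.integer(replicatesPerTissue),
      nGenesPerCategory = full,
      plantedFold = plantedFold,
      groupSizeRange = as.integer(groupSizeRange),
      baselineLog2Mean = as.numeric(baselineLog2Mean),
      baselineLog2SD = as.numeric(baselineLog2SD),
      noiseSDLog2 = as.numeric(noiseSDLog2),
      detectionFloor = as.numeric(detectionFloor),
      targetTissue = targetTissue,
      compartmentCounts = vapply(compartmentCounts, as.integer, integer(1)),
      distractorFraction = as.numeric(distractorFraction),
      seed = as.integer(seed))
}
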