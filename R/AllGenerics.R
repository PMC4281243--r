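#' @rdname averageByTissue
#' @export
setGeneric("averageByTissue", function(x, ...) standardGeneric("averageByTissue"))

#' @rdname pairwiseSampleCorrelation
#' @export
setGeneric("pairwiseSampleCorrelation",
           function(x, ...) standardGeneric("pairwiseSampleCorrelation"))

#' @rdname classifyProfile
#' @export
setGeneric("classifyProfile",
           function(x, target, thresholds = SpecThresholds(), ...)
             standardGeneric("classifyProfile"))

#' Accessors for classification results and profiles
#'
#' \code{specTable} returns the per-gene result table of a
#' \linkS4class{SpecClassification}; \code{targetTissue} its target tissue;
#' \code{thresholds} the cutoffs used; \code{meanFPKM} the genes x tissues
#' matrix of a \linkS4class{TissueProfile}; \code{nSamples} its per-tissue
#' replicate counts; \code{tallyCounts}, \code{tallyElevated} and
#' \code{tallyTotal} the slots of a \linkS4class{CategoryTally};
#' \code{networkNodes} and \code{networkEdges} the tables of a
#' \linkS4class{SharingNetwork}.
#'
#' @param x the object.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("specTable", function(x) standardGeneric("specTable"))
#' @rdname accessors
#' @export
setGeneric("targetTissue", function(x) standardGeneric("targetTissue"))
#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
#' @rdname accessors
#' @export
setGeneric("meanFPKM", function(x) standardGeneric("meanFPKM"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("tallyCounts", function(x) standardGeneric("tallyCounts"))
#' @rdname accessors
#' @export
setGeneric("tallyElevated", function(x) standardGeneric("tallyElevated"))
#' @rdname accessors
#' @export
setGeneric("tallyTotal", function(x) standardGeneric("tallyTotal"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setMethod("specTable", "SpecClassification", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("targetTissue", "SpecClassification", function(x) x@target)
#' @rdname accessors
#' @export
setMethod("targetTissue", "SharingNetwork", function(x) x@targetTissue)
#' @rdname accessors
#' @export
setMethod("thresholds", "SpecClassification", function(x) x@thresholds)
#' @rdname accessors
#' @export
setMethod("meanFPKM", "TissueProfile",
          function(x) assay(x, "meanFPKM"))
#' @rdname accessors
#' @export
setMethod("nSamples", "TissueProfile",
          function(x) stats::setNames(colData(x)$n_samples, colnames(x)))
#' @rdname accessors
#' @export
setMethod("tallyCounts", "CategoryTally", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("tallyElevated", "CategoryTally", function(x) x@elevated)
#' @rdname accessors
#' @export
setMethod("tallyTotal", "CategoryTally", function(x) x@total)
#' @rdname accessors
#' @export
setMethod("networkNodes", "SharingNetwork", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("networkEdges", "SharingNetwork", function(x) x@edges)

setMethod("show", "SpecThresholds", function(object) {
  cat("SpecThresholds: detection >=", object@detectionLimit, "FPKM;",
      "folds", object@highEnrichmentFold, "/", object@enrichmentFold,
      "/", object@groupFold, "(group", object@groupMinSize, "-",
      object@groupMaxSize, "tissues, vs", object@groupComparator,
      "outside) /", object@enhancedFold, "\n")
})

setMethod("show", "SpecClassification", function(object) {
  tl <- categoryTally(object)
  cat("SpecClassification for target tissue '", object@target, "'\n",
      sep = "")
  cat("  ", tallyTotal(tl), " genes; elevated: ", tallyElevated(tl),
      "\n", sep = "")
  print(tallyCounts(tl))
})

setMethod("show", "CategoryTally", function(object) {
  cat("CategoryTally:", object@total, "genes,", object@elevated,
      "elevated\n")
  print(object@counts)
})

setMethod("show", "SharingNetwork", function(object) {
  ng <- sum(object@nodes$type == "group")
  nt <- sum(object@nodes$type == "tissue")
  cat("SharingNetwork for '", object@targetTissue, "': ", ng,
      " group node(s), ", nt, " tissue node(s), ", nrow(object@edges),
      " edge(s)\n", sep = "")
})
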