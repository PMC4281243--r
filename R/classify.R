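# The seven-category specificity classification, tissue-specificity score,
# group-enrichment search, mRNA-pool accounting and top-expressed report.

#' Detection call for a single FPKM value
#'
#' A gene counts as detected in a tissue when its mean FPKM is at or above
#' the detection limit (1 FPKM by default). The boundary itself is
#' detected, so that "below the limit" and "detected" partition the line.
#'
#' @param fpkm non-negative FPKM value(s).
#' @param limit detection limit, default 1 FPKM.
#' @return Logical vector.
#' @examples
#' isDetected(c(0.99, 1, 1421))
#' @export
isDetected <- function(fpkm, limit = 1) {
  if (any(fpkm < 0, na.rm = TRUE))
    tsStop("negative FPKM", c("ts_negative_value", "ts_data_error"))
  fpkm >= limit
}

# Shared helper: checks a per-tissue named profile vector and the target.
checkProfileVector <- function(profile, target) {
  if (is.null(names(profile)) || anyDuplicated(names(profile)))
    tsStop("profile must be a named vector with unique tissue names",
           "ts_data_error")
  if (!target %in% names(profile))
    tsStop(sprintf("target tissue '%s' not in profile", target),
           "ts_config_error")
  if (any(!is.finite(profile)) || any(profile < 0))
    tsStop("profile values must be finite and non-negative",
           "ts_data_error")
}

#' Tissue-specificity (TS) score of one gene
#'
#' The target tissue's mean FPKM divided by the maximum mean FPKM over all
#' other tissues. The denominator is floored at a small positive value
#' (default 0.01 FPKM) that only guards division by exactly zero; the floor
#' deliberately sits far below the detection limit so that genes with
#' trace-level expression elsewhere keep their large scores.
#'
#' @param profile named numeric vector of per-tissue mean FPKM.
#' @param target target tissue name.
#' @param th a \linkS4class{SpecThresholds}.
#' @return Non-negative TS score.
#' @examples
#' tissueSpecificityScore(c(kidney = 100, liver = 4, lung = 1), "kidney")
#' @export
tissueSpecificityScore <- function(profile, target, th = SpecThresholds()) {
  checkProfileVector(profile, target)
  if (length(profile) < 2)
    tsStop("TS score needs >= 2 tissues", "ts_data_error")
  other <- profile[setdiff(names(profile), target)]
  unname(profile[[target]] / max(max(other), th@tsDenominatorFloor))
}

# Name of the most highly expressed non-target tissue (ties broken
# lexicographically).
secondTissueName <- function(profile, target) {
  other <- profile[setdiff(names(profile), target)]
  cand <- names(other)[other == max(other)]
  sort(cand)[1]
}

#' Search for an enriched tissue group
#'
#' Finds the smallest group of \code{groupMinSize}--\code{groupMaxSize}
#' tissues containing the target whose mean FPKM is at least
#' \code{groupFold} times the maximum (default comparator) mean FPKM of
#' every tissue outside the group. Candidate groups are prefixes of the
#' tissues sorted by descending FPKM with the target forced in: for the
#' max-outside criterion the top-k tissues simultaneously maximise the
#' group mean and minimise the outside maximum, so the prefix scan is
#' exact (verified against brute-force subset enumeration in the test
#' suite). Sorting ties are broken lexicographically by tissue name.
#'
#' @param profile named numeric vector of per-tissue mean FPKM.
#' @param target target tissue name.
#' @param th a \linkS4class{SpecThresholds}.
#' @return Character vector of the group's tissue names (lexicographic,
#'   always containing the target), or \code{NULL} if no group qualifies.
#' @examples
#' p <- c(kidney = 50, liver = 40, a = 8, b = 5, c = 2, d = 1,
#'        e = 1, f = 1, g = 1, h = 1)
#' findEnrichedGroup(p, "kidney")
#' @export
findEnrichedGroup <- function(profile, target, th = SpecThresholds()) {
  checkProfileVector(profile, target)
  n <- length(profile)
  if (th@groupMaxSize >= n)
    tsStop("groupMaxSize must be smaller than the number of tissues",
           "ts_config_error")
  other <- profile[setdiff(names(profile), target)]
  # descending FPKM, ties lexicographic by tissue name
  ord <- names(other)[order(-other, names(other))]
  for (k in seq(th@groupMinSize, th@groupMaxSize)) {
    grp <- c(target, ord[seq_len(k - 1L)])
    out <- ord[seq(k, length(ord))]
    outStat <- if (th@groupComparator == "max") max(profile[out])
               else mean(profile[out])
    if (mean(profile[grp]) >=
        th@groupFold * max(outStat, th@tsDenominatorFloor))
      return(sort(grp))
  }
  NULL
}

#' Classify a single gene's tissue profile
#'
#' Applies the seven category rules in precedence order: (1) not detected
#' if the target FPKM is below the detection limit; (2) highly enriched if
#' TS >= \code{highEnrichmentFold}; (3) moderately enriched if TS >=
#' \code{enrichmentFold}; (4) group enriched if a qualifying tissue group
#' exists; (5) enhanced if the target FPKM is at least \code{enhancedFold}
#' times the mean over all tissues (target included); (6) expressed in all
#' if detected in every tissue; (7) mixed otherwise. Precedence makes the
#' categories mutually exclusive; elevated categories deliberately outrank
#' expressed-in-all.
#'
#' @param profile named numeric vector of per-tissue mean FPKM.
#' @param target target tissue name.
#' @param th a \linkS4class{SpecThresholds}.
#' @return Named list: \code{category}, \code{ts_score}, \code{target_fpkm},
#'   \code{max_other_fpkm}, \code{second_tissue}, \code{enriched_group}
#'   (character vector, empty unless group enriched),
#'   \code{n_detected_tissues}.
#' @examples
#' classifyGene(c(kidney = 100, liver = 1.9, lung = 0.2), "kidney")$category
#' @export
classifyGene <- function(profile, target, th = SpecThresholds()) {
  checkProfileVector(profile, target)
  ts <- tissueSpecificityScore(profile, target, th)
  tFpkm <- unname(profile[[target]])
  other <- profile[setdiff(names(profile), target)]
  nDet <- sum(isDetected(profile, th@detectionLimit))
  grp <- character()
  category <- if (tFpkm < th@detectionLimit) {
    "not_detected"
  } else if (ts >= th@highEnrichmentFold) {
    "highly_enriched"
  } else if (ts >= th@enrichmentFold) {
    "moderately_enriched"
  } else {
    g <- findEnrichedGroup(profile, target, th)
    if (!is.null(g)) {
      grp <- g
      "group_enriched"
    } else if (tFpkm >= th@enhancedFold * mean(profile)) {
      "enhanced"
    } else if (nDet == length(profile)) {
      "expressed_in_all"
    } else {
      "mixed"
    }
  }
  list(category = category, ts_score = ts, target_fpkm = tFpkm,
       max_other_fpkm = unname(max(other)),
       second_tissue = secondTissueName(profile, target),
       enriched_group = grp, n_detected_tissues = nDet)
}

#' Classify every gene of a tissue profile
#'
#' @param x a \linkS4class{TissueProfile} (or genes x tissues numeric
#'   matrix).
#' @param target target tissue name.
#' @param thresholds a \linkS4class{SpecThresholds}.
#' @param ... unused.
#' @return A \linkS4class{SpecClassification}; gene order is preserved from
#'   the input.
#' @examples
#' m <- rbind(ND1 = c(kidney = 0.5, liver = 8, lung = 9, heart = 7,
#'                    brain = 6, skin = 5, colon = 4, testis = 3, lung2 = 2),
#'            HK1 = c(5, 5, 5, 5, 5, 5, 5, 5, 5))
#' colnames(m) <- c("kidney", "liver", "lung", "heart", "brain", "skin",
#'                  "colon", "testis", "spleen")
#' specTable(classifyProfile(TissueProfile(m), "kidney"))
#' @export
setMethod("classifyProfile", "TissueProfile",
  function(x, target, thresholds = SpecThresholds(), ...)
    classifyProfile(meanFPKM(x), target, thresholds))

#' @rdname classifyProfile
#' @export
setMethod("classifyProfile", "matrix",
  function(x, target, thresholds = SpecThresholds(), ...) {
    th <- thresholds
    if (!target %in% colnames(x))
      tsStop(sprintf("target tissue '%s' not in profile", target),
             "ts_config_error")
    rows <- lapply(rownames(x), function(g) {
      r <- classifyGene(x[g, ], target, th)
      DataFrame(gene_id = g, category = r$category, ts_score = r$ts_score,
                target_fpkm = r$target_fpkm,
                max_other_fpkm = r$max_other_fpkm,
                second_tissue = r$second_tissue,
                enriched_group = paste(r$enriched_group, collapse = ";"),
                n_detected_tissues = r$n_detected_tissues)
    })
    tab <- if (length(rows)) do.call(rbind, rows) else
      DataFrame(gene_id = character(), category = character(),
                ts_score = numeric(), target_fpkm = numeric(),
                max_other_fpkm = numeric(), second_tissue = character(),
                enriched_group = character(),
                n_detected_tissues = integer())
    new("SpecClassification", table = tab, target = target, thresholds = th)
  })

#' Tally of genes per category
#'
#' @param x a \linkS4class{SpecClassification}.
#' @return A \linkS4class{CategoryTally} with per-category counts, the
#'   elevated sum and the total.
#' @export
categoryTally <- function(x) {
  cnt <- table(factor(x@table$category, levels = specCategories()))
  CategoryTally(stats::setNames(as.integer(cnt), specCategories()))
}

#' mRNA-pool composition of the target tissue
#'
#' The fraction of the target tissue's total mRNA pool (sum of FPKM over
#' all genes) contributed by each top-level category group: not detected,
#' elevated (enriched + group enriched + enhanced), mixed, and expressed in
#' all tissues.
#'
#' @param x a \linkS4class{SpecClassification}.
#' @return Named numeric vector of four fractions summing to 1.
#' @export
mrnaPoolFractions <- function(x) {
  tab <- x@table
  total <- sum(tab$target_fpkm)
  if (total <= 0)
    tsStop("total target-tissue FPKM is zero", "ts_data_error")
  grp <- ifelse(tab$category %in% elevatedCategories(), "elevated",
                tab$category)
  lv <- c("not_detected", "elevated", "mixed", "expressed_in_all")
  sums <- vapply(lv, function(g) sum(tab$target_fpkm[grp == g]), numeric(1))
  sums / total
}

#' Top expressed genes in the target tissue
#'
#' @param x a \linkS4class{SpecClassification}.
#' @param n number of genes to report (default 30); if larger than the gene
#'   count, all genes are returned.
#' @return \link[S4Vectors]{DataFrame} of \code{gene_id},
#'   \code{target_fpkm}, \code{category}, sorted by descending FPKM with
#'   lexicographic tie-break on the gene identifier.
#' @export
topExpressed <- function(x, n = 30) {
  if (n < 1) tsStop("n must be >= 1", "ts_config_error")
  tab <- x@table
  ord <- order(-tab$target_fpkm, tab$gene_id)
  tab <- tab[ord, c("gene_id", "target_fpkm", "category")]
  utils::head(tab, n)
}

#' Write the per-gene classification table as TSV
#'
#' @param x a \linkS4class{SpecClassification}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeClassificationTable <- function(x, path) {
  utils::write.table(as.data.frame(x@table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
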