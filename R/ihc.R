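# Coded immunohistochemistry annotations: scoring bins, validation,
# restricted-expression query, unique-compartment assignment, RNA-IHC
# concordance and external set overlaps.

#' Bin a percentage of positive cells into the 0--3 fraction score
#'
#' Bins: 0 for 0--1\%, 1 for 2--25\%, 2 for 26--75\%, 3 above 75\%.
#' Non-integer percentages between bins fall into the higher bin (0--1
#' means <= 1), so the bins partition the whole 0--100 range and the
#' function is monotone non-decreasing.
#'
#' @param percent numeric in [0, 100].
#' @return Integer score(s) 0--3.
#' @examples
#' fractionToScore(c(1, 26, 80))
#' @export
fractionToScore <- function(percent) {
  if (any(percent < 0 | percent > 100, na.rm = TRUE))
    tsStop("percentage outside [0, 100]", "ts_data_error")
  as.integer(cut(percent, breaks = c(-Inf, 1, 25, 75, Inf),
                 labels = FALSE)) - 1L
}

#' Validate an in-memory IHC annotation table
#'
#' Used by the loader and by callers that build annotation tables
#' programmatically; checks required columns, the 0--3 score ranges and
#' the kidney cell-type vocabulary.
#'
#' @param df data.frame of annotation rows.
#' @return The validated data.frame with integer score columns.
#' @export
validateIHCAnnotations <- function(df) {
  need <- c("gene_id", "antibody_id", "tissue", "cell_type",
            "fraction_score", "intensity_score", "subcellular")
  if (!all(need %in% colnames(df)))
    tsStop(sprintf("IHC table needs columns: %s",
                   paste(need, collapse = ", ")), "ts_data_error")
  df$fraction_score <- as.integer(df$fraction_score)
  df$intensity_score <- as.integer(df$intensity_score)
  ok <- function(s) !anyNA(s) && all(s >= 0L & s <= 3L)
  if (!ok(df$fraction_score) || !ok(df$intensity_score))
    tsStop("IHC scores must be integers in 0..3",
           c("ts_score_range", "ts_data_error"))
  kid <- df$tissue == "kidney"
  bad <- setdiff(unique(df$cell_type[kid]), kidneyCellTypes())
  if (length(bad))
    tsStop(sprintf("unknown kidney cell type(s): %s",
                   paste(bad, collapse = ", ")),
           c("ts_unknown_cell_type", "ts_data_error"))
  df
}

#' Load an IHC annotation table
#'
#' TSV with columns \code{gene_id}, \code{antibody_id}, \code{tissue},
#' \code{cell_type}, \code{fraction_score}, \code{intensity_score},
#' \code{subcellular}. Scores outside 0--3 and kidney rows with a cell
#' type outside \code{\link{kidneyCellTypes}()} are rejected.
#'
#' @param path path to the TSV file.
#' @return Validated data.frame of annotation records.
#' @export
loadIHCAnnotations <- function(path) {
  if (!file.exists(path))
    tsStop(sprintf("IHC table not found: %s", path),
           c("ts_missing_file", "ts_data_error"))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  validateIHCAnnotations(df)
}

# Per gene x tissue summary: positive call plus the reconciled (maximum)
# intensity/fraction level over antibodies, with a disagreement flag when
# antibodies differ by >= 2 intensity units.
ihcTissueLevels <- function(ann) {
  ann <- validateIHCAnnotations(ann)
  key <- paste(ann$gene_id, ann$tissue, sep = "\r")
  idx <- split(seq_len(nrow(ann)), key)
  res <- lapply(idx, function(i) {
    pos <- ann$fraction_score[i] >= 1L & ann$intensity_score[i] >= 1L
    data.frame(gene_id = ann$gene_id[i[1]], tissue = ann$tissue[i[1]],
               expressed = any(pos),
               intensity = max(ann$intensity_score[i]),
               fraction = max(ann$fraction_score[i]),
               antibody_disagreement =
                 diff(range(ann$intensity_score[i])) >= 2L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$gene_id, out$tissue), , drop = FALSE]
}

# Lexicographic (intensity, fraction) comparison: is level a <= level b?
levelLeq <- function(ia, fa, ib, fb, comparison = "pair") {
  if (comparison == "intensity") return(ia <= ib)
  ia < ib | (ia == ib & fa <= fb)
}

#' Query genes with tissue-restricted IHC expression
#'
#' Returns the genes expressed in the target tissue (any annotation with
#' fraction score >= 1 and intensity score >= 1) and in at most
#' \code{maxOtherTissues} other tissues, each such other tissue at a level
#' lower than or equal to the target's. "Level" is the reconciled
#' (intensity, fraction) score pair compared lexicographically with
#' intensity first; set \code{comparison = "intensity"} to compare
#' intensity only. With \code{maxOtherTissues = 0} exactly the uniquely
#' stained genes are returned.
#'
#' @param ann IHC annotation data.frame (see
#'   \code{\link{loadIHCAnnotations}}).
#' @param target target tissue name.
#' @param maxOtherTissues maximum number of other expressing tissues,
#'   default 6.
#' @param comparison \code{"pair"} (default) or \code{"intensity"}.
#' @return Sorted character vector of gene identifiers.
#' @export
restrictedExpressionQuery <- function(ann, target = "kidney",
                                      maxOtherTissues = 6L,
                                      comparison = c("pair", "intensity")) {
  comparison <- match.arg(comparison)
  lv <- ihcTissueLevels(ann)
  if (!target %in% lv$tissue)
    tsStop(sprintf("target tissue '%s' absent from IHC annotations",
                   target), "ts_config_error")
  keep <- vapply(split(lv, lv$gene_id), function(g) {
    tg <- g[g$tissue == target & g$expressed, , drop = FALSE]
    if (!nrow(tg)) return(FALSE)
    oth <- g[g$tissue != target & g$expressed, , drop = FALSE]
    if (nrow(oth) > maxOtherTissues) return(FALSE)
    all(levelLeq(oth$intensity, oth$fraction,
                 tg$intensity, tg$fraction, comparison))
  }, logical(1))
  sort(names(keep)[keep])
}

#' Assign elevated genes to a unique nephron compartment
#'
#' A gene receives a compartment call iff all of its positive kidney
#' annotations (fraction and intensity scores both >= 1) fall into exactly
#' one of the four compartments: glomeruli, proximal tubule, distal tubule
#' or collecting duct. Intercalated-cell annotations count as collecting
#' duct; a collecting-duct call is flagged \code{intercalated_only} when
#' every positive annotation is confined to intercalated cells. Positive
#' staining in \code{"other"} kidney structures blocks a unique call; genes
#' with multi-compartment or no positive staining yield no call.
#'
#' @param ann IHC annotation data.frame.
#' @param genes gene identifiers to consider.
#' @return data.frame with columns \code{gene_id}, \code{compartment},
#'   \code{intercalated_only}, \code{n_annotations}; one row per called
#'   gene.
#' @export
assignUniqueCompartment <- function(ann, genes) {
  ann <- validateIHCAnnotations(ann)
  kid <- ann[ann$tissue == "kidney" & ann$gene_id %in% genes &
             ann$fraction_score >= 1L & ann$intensity_score >= 1L, ,
             drop = FALSE]
  rows <- lapply(split(kid, kid$gene_id), function(g) {
    comp <- ifelse(g$cell_type == "collecting_duct_intercalated",
                   "collecting_duct", g$cell_type)
    u <- unique(comp)
    if (length(u) != 1L || !u %in% nephronCompartments()) return(NULL)
    data.frame(gene_id = g$gene_id[1], compartment = u,
               intercalated_only = u == "collecting_duct" &&
                 all(g$cell_type == "collecting_duct_intercalated"),
               n_annotations = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), compartment = character(),
                      intercalated_only = logical(),
                      n_annotations = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Concordance between RNA-elevated genes and an IHC-derived gene set
#'
#' Intersects an IHC-derived gene set with the RNA-elevated genes of a
#' classification and breaks the overlap down by elevated category; the
#' breakdown always sums to the total overlap.
#'
#' @param x a \linkS4class{SpecClassification}.
#' @param ihcGenes character vector of gene identifiers.
#' @return List with \code{total} (overlap size), \code{by_category}
#'   (named integer over the elevated categories) and \code{genes} (the
#'   overlapping identifiers).
#' @export
rnaIhcConcordance <- function(x, ihcGenes) {
  tab <- x@table
  elev <- tab[tab$category %in% elevatedCategories(), , drop = FALSE]
  hit <- elev[elev$gene_id %in% ihcGenes, , drop = FALSE]
  byCat <- vapply(elevatedCategories(),
                  function(cc) sum(hit$category == cc), integer(1))
  list(total = nrow(hit), by_category = byCat, genes = sort(hit$gene_id))
}

#' Read a plain gene-list file
#'
#' One gene identifier per line; blank lines ignored. The list is named by
#' the file stem.
#'
#' @param path path to the file.
#' @return Character vector of unique identifiers.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path))
    tsStop(sprintf("gene list not found: %s", path),
           c("ts_missing_file", "ts_data_error"))
  x <- readLines(path, warn = FALSE)
  unique(x[nzchar(x)])
}

#' Overlap of compartment calls with external reference gene sets
#'
#' For each reference list, counts how many called genes are present and
#' absent, and additionally how many calls are absent from every list (the
#' "not previously observed" tally).
#'
#' @param calls data.frame of compartment calls
#'   (\code{\link{assignUniqueCompartment}}).
#' @param referenceLists named list of character vectors of gene
#'   identifiers.
#' @return List with \code{per_list} (data.frame: list name, present,
#'   absent) and \code{absent_from_all} (integer).
#' @export
compareToReferenceSets <- function(calls, referenceLists) {
  if (!length(referenceLists))
    tsStop("no reference lists supplied", "ts_config_error")
  if (is.null(names(referenceLists)) || any(!nzchar(names(referenceLists))))
    tsStop("reference lists must be named", "ts_config_error")
  genes <- calls$gene_id
  per <- do.call(rbind, lapply(names(referenceLists), function(nm) {
    inSet <- genes %in% referenceLists[[nm]]
    data.frame(list = nm, present = sum(inSet), absent = sum(!inSet),
               stringsAsFactors = FALSE)
  }))
  anywhere <- genes %in% unique(unlist(referenceLists))
  list(per_list = per, absent_from_all = sum(!anywhere))
}
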