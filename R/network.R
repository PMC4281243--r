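# Bipartite tissue-sharing network of enriched and group-enriched genes.

#' Build the tissue-sharing network
#'
#' Collects target-enriched genes (highly or moderately enriched; their
#' tissue set is the singleton target) and group-enriched genes whose group
#' contains at most \code{maxPartners} tissues besides the target. Genes
#' with the same tissue set share one group node whose display size is the
#' square root of its gene count; each group node is connected to exactly
#' the tissues in its set.
#'
#' @param x a \linkS4class{SpecClassification}.
#' @param maxPartners maximum number of tissues shared besides the target
#'   (default 3, i.e. groups of up to 4 tissues including the target).
#' @return A \linkS4class{SharingNetwork}.
#' @examples
#' m <- matrix(c(100, 1, 1, 1, 1, 1, 1, 1, 1), 1, 9,
#'             dimnames = list("g1", c("kidney", letters[1:8])))
#' net <- buildSharingNetwork(classifyProfile(m, "kidney"))
#' networkNodes(net)
#' @export
buildSharingNetwork <- function(x, maxPartners = 3L) {
  tab <- x@table
  target <- x@target
  sets <- character(0)
  enr <- tab$category %in% c("highly_enriched", "moderately_enriched")
  sets <- c(sets, rep(target, sum(enr)))
  gtab <- tab[tab$category == "group_enriched", , drop = FALSE]
  if (nrow(gtab)) {
    gl <- strsplit(gtab$enriched_group, ";", fixed = TRUE)
    keep <- lengths(gl) <= maxPartners + 1L
    sets <- c(sets,
              vapply(gl[keep],
                     function(g) paste(sort(g), collapse = ";"),
                     character(1)))
  }
  if (!length(sets)) {
    nodes <- data.frame(id = character(), type = character(),
                        gene_count = integer(), display_size = numeric(),
                        stringsAsFactors = FALSE)
    edges <- data.frame(source = character(), target = character(),
                        stringsAsFactors = FALSE)
    return(new("SharingNetwork", nodes = nodes, edges = edges,
               targetTissue = target))
  }
  cnt <- table(sets)
  setNames_ <- sort(names(cnt))
  groupIds <- paste0("group:", gsub(";", "+", setNames_, fixed = TRUE))
  counts <- as.integer(cnt[setNames_])
  tissueList <- strsplit(setNames_, ";", fixed = TRUE)
  tissues <- sort(unique(unlist(tissueList)))
  nodes <- rbind(
    data.frame(id = groupIds, type = "group", gene_count = counts,
               display_size = sqrt(counts), stringsAsFactors = FALSE),
    data.frame(id = tissues, type = "tissue", gene_count = NA_integer_,
               display_size = NA_real_, stringsAsFactors = FALSE))
  edges <- do.call(rbind, Map(function(id, ts)
    data.frame(source = id, target = ts, stringsAsFactors = FALSE),
    groupIds, tissueList))
  rownames(nodes) <- rownames(edges) <- NULL
  new("SharingNetwork", nodes = nodes, edges = edges, targetTissue = target)
}

#' Write a sharing network as node and edge TSV tables
#'
#' Writes \code{network_nodes.tsv} (id, type, gene_count, display_size)
#' and \code{network_edges.tsv} (source, target) into a directory; plain
#' TSV loadable by standard graph tools. The pair round-trips losslessly
#' through \code{\link{readNetworkEdgelist}}.
#'
#' @param x a \linkS4class{SharingNetwork}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
writeNetworkEdgelist <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  np <- file.path(dir, "network_nodes.tsv")
  ep <- file.path(dir, "network_edges.tsv")
  utils::write.table(x@nodes, np, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x@edges, ep, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nodes = np, edges = ep))
}

#' Read back a sharing network written by writeNetworkEdgelist
#'
#' @param dir directory containing \code{network_nodes.tsv} and
#'   \code{network_edges.tsv}.
#' @param targetTissue target tissue to record on the object.
#' @return A \linkS4class{SharingNetwork}.
#' @export
readNetworkEdgelist <- function(dir, targetTissue = NA_character_) {
  np <- file.path(dir, "network_nodes.tsv")
  ep <- file.path(dir, "network_edges.tsv")
  if (!file.exists(np) || !file.exists(ep))
    tsStop("network node/edge tables not found",
           c("ts_missing_file", "ts_data_error"))
  nodes <- utils::read.delim(np, stringsAsFactors = FALSE,
                             colClasses = c(id = "character",
                                            type = "character"))
  edges <- utils::read.delim(ep, stringsAsFactors = FALSE,
                             colClasses = "character")
  nodes$gene_count <- as.integer(nodes$gene_count)
  nodes$display_size <- as.numeric(nodes$display_size)
  new("SharingNetwork", nodes = nodes, edges = edges,
      targetTissue = targetTissue)
}
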