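# Independent oracles and small builders shared across test files.

suppressPackageStartupMessages(library(SummarizedExperiment))

# Brute-force group-enrichment search: enumerates every tissue subset of
# sizes groupMinSize..groupMaxSize containing the target and applies the
# criterion directly. Returns the qualifying groups of the smallest
# qualifying size (a list), or NULL when none qualifies. Deliberately
# independent of the prefix-scan implementation.
bruteForceEnrichedGroups <- function(profile, target,
                                     th = SpecThresholds()) {
  tissues <- names(profile)
  others <- setdiff(tissues, target)
  for (k in seq(th@groupMinSize, th@groupMaxSize)) {
    if (k >= length(tissues)) break
    hits <- list()
    for (cb in utils::combn(others, k - 1L, simplify = FALSE)) {
      grp <- c(target, cb)
      out <- setdiff(tissues, grp)
      stat <- if (th@groupComparator == "max") max(profile[out])
              else mean(profile[out])
      if (mean(profile[grp]) >= th@groupFold *
          max(stat, th@tsDenominatorFloor))
        hits[[length(hits) + 1L]] <- sort(grp)
    }
    if (length(hits)) return(hits)
  }
  NULL
}

# Direct criterion check for one candidate group.
groupQualifies <- function(profile, grp, th = SpecThresholds()) {
  out <- setdiff(names(profile), grp)
  stat <- if (th@groupComparator == "max") max(profile[out])
          else mean(profile[out])
  mean(profile[grp]) >= th@groupFold * max(stat, th@tsDenominatorFloor)
}

# Random per-tissue profile with heavy-tailed FPKM levels.
randomProfile <- function(nTissues) {
  v <- 10^stats::runif(nTissues, -1, 3)
  names(v) <- sprintf("t%02d", seq_len(nTissues))
  v
}

# Small simulation config: few genes per category and compartment plants
# scaled down to fit the reduced number of elevated genes.
tinySim <- function(nPerCategory, seed, ...) {
  SimulationConfig(
    nGenesPerCategory = stats::setNames(rep(as.integer(nPerCategory), 7),
                                        specCategories()),
    compartmentCounts = c(glomeruli = 1L, proximal_tubule = 2L,
                          distal_tubule = 1L, collecting_duct = 1L,
                          collecting_duct_intercalated = 1L),
    seed = seed, ...)
}

# Minimal two-tissue expression set used by the IO tests.
tinyExpression <- function() {
  m <- matrix(c(4, 1, 6, 3, 10, 2, 40, 5), nrow = 2,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  md <- data.frame(sample_id = paste0("s", 1:4),
                   tissue = c("kidney", "kidney", "liver", "liver"),
                   individual = c("i1", "i2", "i1", "i2"),
                   stringsAsFactors = FALSE)
  TissueExpression(m, md)
}

# In-memory IHC annotation row builder.
ihcRow <- function(gene, tissue, cell = "proximal_tubule",
                   fraction = 2L, intensity = 2L,
                   antibody = paste0("AB_", gene),
                   subcellular = "cytoplasm") {
  data.frame(gene_id = gene, antibody_id = antibody, tissue = tissue,
             cell_type = cell, fraction_score = fraction,
             intensity_score = intensity, subcellular = subcellular,
             stringsAsFactors = FALSE)
}
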