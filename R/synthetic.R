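# Synthetic multi-tissue studies with planted specificity categories and
# nephron-compartment localisations.

# sample() treats a length-1 numeric as 1:x; this keeps draws literal.
sample1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)

# Per-category construction of noiseless tissue-level means. Each plant is
# built with a margin of at least ~2x its category threshold so that the
# default replicate noise (log2 SD 0.2, averaged over replicates) cannot
# flip the classification; the noiseless means classify exactly as planted
# by construction (checked by the test suite).
plantTissueMeans <- function(category, tissues, target, cfg) {
  n <- length(tissues)
  others <- setdiff(tissues, target)
  base <- 2^(cfg@baselineLog2Mean +
             stats::runif(1, -cfg@baselineLog2SD, cfg@baselineLog2SD))
  m <- stats::setNames(numeric(n), tissues)
  trueGroup <- character(0)
  if (category == "not_detected") {
    # target parked well below the floor to avoid boundary flakiness
    m[others] <- base * 2^stats::runif(n - 1, -0.5, 0.5)
    m[target] <- stats::runif(1, 0, 0.5 * cfg@detectionFloor)
  } else if (category %in% c("highly_enriched", "moderately_enriched")) {
    m[others] <- base * 2^stats::runif(n - 1, -0.5, 0.5)
    m[target] <- cfg@plantedFold[[category]] * max(m[others])
  } else if (category == "group_enriched") {
    k <- sample1(seq(cfg@groupSizeRange[1], cfg@groupSizeRange[2]))
    grp <- c(target, sample(others, k - 1))
    m[grp] <- base * 2^stats::runif(k, -0.25, 0.25)
    # outside tissues capped at groupMean/fold: exactly the planted margin
    out <- setdiff(tissues, grp)
    m[out] <- mean(m[grp]) / cfg@plantedFold[["group_enriched"]] *
      2^(-stats::runif(length(out), 0, 1))
    trueGroup <- sort(grp)
  } else if (category == "enhanced") {
    # a smooth head of decaying levels keeps the TS score low and defeats
    # every candidate group prefix (each prefix mean stays below 2.5x the
    # next level) while the 19-tissue tail keeps the overall mean low
    head_ <- c(0.4, 0.28, 0.224, 0.19, 0.167, 0.151, 0.138)
    t0 <- base * 8
    m[target] <- t0
    headTissues <- sample(others, length(head_))
    m[headTissues] <- t0 * head_ * 2^stats::runif(length(head_), -0.03, 0.03)
    tail_ <- setdiff(others, headTissues)
    m[tail_] <- t0 * 0.002 * 2^stats::runif(length(tail_), -0.5, 0.5)
  } else if (category == "expressed_in_all") {
    m[tissues] <- base * 2^stats::runif(n, -0.5, 0.5)
  } else if (category == "mixed") {
    # detected-tissue count kept high enough that neither a 7-tissue group
    # nor the enhanced ratio can be approached under noise
    lo <- max(8L, as.integer(ceiling(0.45 * n)))
    d <- sample1(seq(lo, n - 1L))
    det <- c(target, sample(others, d - 1))
    m[det] <- base * 2^stats::runif(d, -0.25, 0.25)
    m[setdiff(tissues, det)] <-
      0.05 * cfg@detectionFloor * 2^stats::runif(n - d, -0.5, 0.5)
  } else {
    tsStop(sprintf("unknown category '%s'", category), "ts_config_error")
  }
  list(means = m, group = trueGroup)
}

#' Generate a synthetic multi-tissue expression study
#'
#' Plants \code{nGenesPerCategory} genes per specificity category: tissue
#' means are constructed so that, before noise, every gene classifies
#' exactly as planted with a margin of about twice its category threshold;
#' replicate samples are then drawn as mean x 2^N(0, noiseSDLog2)
#' (multiplicative log-normal noise, matching the heavy-tailed behaviour
#' of expression data). Compartment localisations are planted on the first
#' elevated genes according to \code{compartmentCounts}. Deterministic
#' given \code{config@seed} (R's default Mersenne-Twister generator under
#' \code{set.seed}).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return List with \code{expression} (a \linkS4class{TissueExpression}),
#'   \code{samples} (metadata data.frame) and \code{truth} (data.frame of
#'   \code{gene_id}, \code{true_category}, \code{true_group}
#'   (semicolon-joined), \code{true_compartment},
#'   \code{intercalated_only}, plus the noiseless tissue means as a
#'   \code{noiselessMeans} attribute-free matrix entry \code{means}).
#' @examples
#' study <- generateSyntheticStudy(SimulationConfig(
#'   nGenesPerCategory = stats::setNames(rep(3L, 7), specCategories()),
#'   seed = 42))
#' table(study$truth$true_category)
#' @export
generateSyntheticStudy <- function(config) {
  cfg <- config
  validObject(cfg)
  withSeed(cfg@seed, {
    tissues <- compendiumTissues(cfg@nTissues, cfg@targetTissue)
    cats <- rep(specCategories(), times = cfg@nGenesPerCategory)
    ng <- length(cats)
    geneIds <- sprintf("SYNT%05d", seq_len(ng))
    plants <- lapply(cats, plantTissueMeans, tissues = tissues,
                     target = cfg@targetTissue, cfg = cfg)
    means <- do.call(rbind, lapply(plants, `[[`, "means"))
    dimnames(means) <- list(geneIds, tissues)
    groups <- vapply(plants, function(p)
      paste(p$group, collapse = ";"), character(1))
    # replicate samples with multiplicative log-normal noise
    reps <- cfg@replicatesPerTissue
    sampleIds <- as.vector(t(outer(tissues, seq_len(reps),
                                   function(t, r) sprintf("%s_s%d", t, r))))
    samples <- data.frame(
      sample_id = sampleIds,
      tissue = rep(tissues, each = reps),
      individual = sprintf("%s_ind%d", rep(tissues, each = reps),
                           rep(seq_len(reps), length(tissues))),
      stringsAsFactors = FALSE)
    noise <- matrix(2^stats::rnorm(ng * length(sampleIds), 0,
                                   cfg@noiseSDLog2),
                    nrow = ng)
    fpkm <- means[, samples$tissue, drop = FALSE] * noise
    colnames(fpkm) <- samples$sample_id
    # plant compartments on elevated genes
    elevated <- geneIds[cats %in% elevatedCategories()]
    compLabels <- rep(names(cfg@compartmentCounts),
                      times = cfg@compartmentCounts)
    compGenes <- elevated[seq_along(compLabels)]
    truth <- data.frame(
      gene_id = geneIds, true_category = cats, true_group = groups,
      true_compartment = NA_character_, intercalated_only = FALSE,
      stringsAsFactors = FALSE)
    idx <- match(compGenes, truth$gene_id)
    truth$true_compartment[idx] <-
      ifelse(compLabels == "collecting_duct_intercalated",
             "collecting_duct", compLabels)
    truth$intercalated_only[idx] <-
      compLabels == "collecting_duct_intercalated"
    list(expression = TissueExpression(fpkm, samples), samples = samples,
         truth = truth, means = means)
  })
}

#' Generate synthetic IHC annotations from planted truth
#'
#' Genes with a planted compartment receive positive kidney annotations
#' (fraction and intensity scores 1--3) confined to that compartment;
#' genes planted as intercalated-only are annotated in intercalated cells
#' exclusively. A configurable fraction of compartment genes additionally
#' receives a positive annotation in a second compartment, to exercise the
#' exclusivity filter. Deterministic given \code{seed}.
#'
#' @param truth truth data.frame from \code{\link{generateSyntheticStudy}}.
#' @param config a \linkS4class{SimulationConfig} (for
#'   \code{distractorFraction} and the seed offset).
#' @param seed integer seed; defaults to \code{config@seed + 1}.
#' @return Validated IHC annotation data.frame.
#' @export
generateSyntheticIHC <- function(truth, config, seed = config@seed + 1L) {
  cfg <- config
  withSeed(seed, {
    comp <- truth[!is.na(truth$true_compartment), , drop = FALSE]
    if (!nrow(comp))
      return(validateIHCAnnotations(data.frame(
        gene_id = character(), antibody_id = character(),
        tissue = character(), cell_type = character(),
        fraction_score = integer(), intensity_score = integer(),
        subcellular = character(), stringsAsFactors = FALSE)))
    cellType <- ifelse(comp$intercalated_only,
                       "collecting_duct_intercalated",
                       comp$true_compartment)
    ann <- data.frame(
      gene_id = comp$gene_id,
      antibody_id = sprintf("AB_%s", comp$gene_id),
      tissue = "kidney",
      cell_type = cellType,
      fraction_score = sample(1:3, nrow(comp), replace = TRUE),
      intensity_score = sample(1:3, nrow(comp), replace = TRUE),
      subcellular = sample(c("cytoplasm", "luminal membrane",
                             "basolateral membrane", "nucleus"),
                           nrow(comp), replace = TRUE),
      stringsAsFactors = FALSE)
    nDis <- floor(cfg@distractorFraction * nrow(comp))
    if (nDis > 0) {
      pick <- seq_len(nDis)
      otherComp <- vapply(comp$true_compartment[pick], function(cc)
        sample(setdiff(nephronCompartments(), cc), 1), character(1))
      dis <- data.frame(
        gene_id = comp$gene_id[pick],
        antibody_id = sprintf("AB_%s", comp$gene_id[pick]),
        tissue = "kidney",
        cell_type = otherComp,
        fraction_score = sample(1:3, nDis, replace = TRUE),
        intensity_score = sample(1:3, nDis, replace = TRUE),
        subcellular = "cytoplasm",
        stringsAsFactors = FALSE)
      ann <- rbind(ann, dis)
    }
    validateIHCAnnotations(ann)
  })
}

#' Per-category recovery of planted labels
#'
#' Compares predicted classifications against the planted truth and
#' reports the confusion table and per-category recall.
#'
#' @param truth truth data.frame from \code{\link{generateSyntheticStudy}}.
#' @param predicted a \linkS4class{SpecClassification} over the same
#'   genes.
#' @return List with \code{confusion} (true x predicted table),
#'   \code{recall} (named numeric per planted category) and
#'   \code{accuracy} (overall fraction correct).
#' @export
evaluateRecovery <- function(truth, predicted) {
  tab <- specTable(predicted)
  if (!setequal(truth$gene_id, tab$gene_id))
    tsStop("truth and prediction cover different gene sets",
           "ts_data_error")
  pred <- tab$category[match(truth$gene_id, tab$gene_id)]
  lv <- specCategories()
  conf <- table(true = factor(truth$true_category, levels = lv),
                predicted = factor(pred, levels = lv))
  recall <- diag(conf) / rowSums(conf)
  list(confusion = conf, recall = recall,
       accuracy = sum(diag(conf)) / sum(conf))
}

#' Write a synthetic study in the pipeline's TSV formats
#'
#' Emits the expression table, sample metadata and truth table so a
#' generated study can be re-consumed through the file-based entry points.
#'
#' @param study list from \code{\link{generateSyntheticStudy}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the file paths.
#' @export
writeSyntheticStudy <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ep <- file.path(dir, "expression.tsv")
  mp <- file.path(dir, "samples.tsv")
  tp <- file.path(dir, "truth.tsv")
  fpkm <- assay(study$expression, "fpkm")
  df <- data.frame(gene_id = rownames(fpkm), fpkm, check.names = FALSE)
  utils::write.table(df, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$samples, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$truth, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expression = ep, samples = mp, truth = tp))
}
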