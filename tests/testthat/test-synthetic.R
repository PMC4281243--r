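test_that("the generator is deterministic under a fixed seed", {
  cfg <- tinySim(5, seed = 21)
  s1 <- generateSyntheticStudy(cfg)
  s2 <- generateSyntheticStudy(cfg)
  expect_identical(assay(s1$expression, "fpkm"),
                   assay(s2$expression, "fpkm"))
  expect_identical(s1$truth, s2$truth)
  expect_identical(generateSyntheticIHC(s1$truth, cfg),
                   generateSyntheticIHC(s2$truth, cfg))
  s3 <- generateSyntheticStudy(tinySim(5, seed = 22))
  expect_false(identical(assay(s1$expression, "fpkm"),
                         assay(s3$expression, "fpkm")))
})

test_that("truth bookkeeping matches the configured plants", {
  cfg <- SimulationConfig(
    nGenesPerCategory = stats::setNames(rep(10L, 7), specCategories()),
    compartmentCounts = c(glomeruli = 3L, proximal_tubule = 8L,
                          distal_tubule = 2L, collecting_duct = 1L,
                          collecting_duct_intercalated = 1L),
    seed = 9)
  study <- generateSyntheticStudy(cfg)
  expect_identical(
    as.integer(table(study$truth$true_category)[specCategories()]),
    rep(10L, 7))
  comp <- study$truth$true_compartment
  expect_identical(sum(!is.na(comp)), 15L)
  expect_identical(sum(comp == "collecting_duct", na.rm = TRUE), 2L)
  expect_identical(sum(study$truth$intercalated_only), 1L)
  # group plants record their tissue set and always contain the target
  grp <- study$truth[study$truth$true_category == "group_enriched", ]
  sets <- strsplit(grp$true_group, ";", fixed = TRUE)
  expect_true(all(vapply(sets, function(s) "kidney" %in% s, logical(1))))
  expect_true(all(lengths(sets) >= 2 & lengths(sets) <= 7))
  # replicate structure: nTissues x replicates samples
  expect_identical(ncol(study$expression), 27L * 4L)
})

test_that("noiseless tissue means classify exactly as planted", {
  cfg <- tinySim(25, seed = 33, noiseSDLog2 = 0)
  study <- generateSyntheticStudy(cfg)
  # with zero noise the averaged replicates equal the planted means
  prof <- averageByTissue(study$expression)
  expect_equal(meanFPKM(prof), study$means[, colnames(meanFPKM(prof))],
               tolerance = 1e-12)
  rec <- evaluateRecovery(study$truth,
                          classifyProfile(prof, "kidney"))
  expect_identical(unname(rec$recall), rep(1, 7))
  # planted groups are recovered exactly, not just the category
  sc <- classifyProfile(prof, "kidney")
  tab <- specTable(sc)
  grp <- study$truth$true_category == "group_enriched"
  expect_identical(tab$enriched_group[grp], study$truth$true_group[grp])
})

test_that("synthetic IHC plants produce the expected compartment calls", {
  # 160 elevated genes comfortably hold the default 148 compartment plants
  cfg <- SimulationConfig(
    nGenesPerCategory = stats::setNames(rep(40L, 7), specCategories()),
    seed = 3)
  study <- generateSyntheticStudy(cfg)
  ann <- generateSyntheticIHC(study$truth, cfg)
  calls <- assignUniqueCompartment(ann, study$truth$gene_id)
  # default plants mirror 11 + 120 + 9 + (5 + 3) compartment genes
  comp <- table(calls$compartment)
  expect_identical(as.integer(comp[c("glomeruli", "proximal_tubule",
                                     "distal_tubule", "collecting_duct")]),
                   c(11L, 120L, 9L, 8L))
  expect_identical(nrow(calls), 148L)
  expect_identical(sum(calls$intercalated_only), 3L)
  truthComp <- study$truth[!is.na(study$truth$true_compartment), ]
  expect_identical(calls$compartment[match(truthComp$gene_id,
                                           calls$gene_id)],
                   truthComp$true_compartment)
  # distractor annotations in a second compartment remove the call
  cfgD <- SimulationConfig(
    nGenesPerCategory = stats::setNames(rep(40L, 7), specCategories()),
    distractorFraction = 1, seed = 3)
  annD <- generateSyntheticIHC(study$truth, cfgD)
  expect_identical(nrow(assignUniqueCompartment(annD,
                                                study$truth$gene_id)), 0L)
})

test_that("evaluateRecovery reports per-category recall and catches mismatches", {
  study <- generateSyntheticStudy(tinySim(5, seed = 2))
  sc <- classifyProfile(TissueProfile(study$means), "kidney")
  rec <- evaluateRecovery(study$truth, sc)
  expect_identical(unname(rec$recall), rep(1, 7))
  expect_identical(rec$accuracy, 1)
  # degrade predictions to all-mixed: recall 0 outside mixed
  tab <- specTable(sc)
  tab$category <- "mixed"
  tab$enriched_group <- ""
  scBad <- new("SpecClassification", table = tab, target = "kidney",
               thresholds = thresholds(sc))
  recBad <- evaluateRecovery(study$truth, scBad)
  expect_identical(unname(recBad$recall[setdiff(specCategories(),
                                                "mixed")]), rep(0, 6))
  expect_identical(unname(recBad$recall["mixed"]), 1)
  other <- study$truth
  other$gene_id <- paste0("X", other$gene_id)
  expect_error(evaluateRecovery(other, sc), class = "ts_data_error")
})

test_that("synthetic studies round-trip through the pipeline TSV formats", {
  cfg <- tinySim(4, seed = 14)
  study <- generateSyntheticStudy(cfg)
  dir <- withr::local_tempdir()
  writeSyntheticStudy(study, dir)
  m <- readExpressionTable(file.path(dir, "expression.tsv"))
  md <- readSampleMetadata(file.path(dir, "samples.tsv"))
  te <- TissueExpression(m, md)
  expect_equal(assay(te, "fpkm"), assay(study$expression, "fpkm"),
               tolerance = 1e-6)
})
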