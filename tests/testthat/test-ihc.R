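test_that("fraction-of-positive-cells binning matches the printed breakpoints", {
  expect_identical(fractionToScore(c(0, 1, 2, 25, 26, 75, 80, 100)),
                   c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  # between-bin percentages fall into the higher bin
  expect_identical(fractionToScore(c(1.5, 25.5, 75.5)), c(1L, 2L, 3L))
  # total monotone step function on [0, 100]
  grid <- seq(0, 100, by = 0.25)
  sc <- fractionToScore(grid)
  expect_true(all(diff(sc) >= 0))
  expect_true(all(sc %in% 0:3))
  expect_error(fractionToScore(-1), class = "ts_data_error")
  expect_error(fractionToScore(101), class = "ts_data_error")
})

test_that("annotation loading validates scores and kidney cell types", {
  ann <- rbind(ihcRow("g1", "kidney"), ihcRow("g2", "kidney", "glomeruli"),
               ihcRow("g3", "liver", "hepatocyte"),
               ihcRow("g4", "kidney", "collecting_duct_intercalated"),
               ihcRow("g5", "kidney", "distal_tubule"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(ann, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- loadIHCAnnotations(tf)
  expect_identical(nrow(got), 5L)

  bad <- ann; bad$fraction_score[1] <- 4L
  expect_error(validateIHCAnnotations(bad), class = "ts_score_range")
  bad2 <- ann; bad2$cell_type[1] <- "hepatocyte"
  expect_error(validateIHCAnnotations(bad2),
               class = "ts_unknown_cell_type")
})

test_that("restricted query filters by tissue count and expression level", {
  ann <- rbind(
    ihcRow("unique", "kidney", intensity = 3L),
    ihcRow("seven", "kidney", intensity = 3L),
    do.call(rbind, lapply(sprintf("l%d", 1:7), function(t)
      ihcRow("seven", t, "other", intensity = 1L))),
    ihcRow("louder", "kidney", intensity = 2L),
    ihcRow("louder", "liver", "other", intensity = 3L),
    ihcRow("ok6", "kidney", intensity = 3L, fraction = 3L),
    do.call(rbind, lapply(sprintf("m%d", 1:6), function(t)
      ihcRow("ok6", t, "other", intensity = 2L))),
    ihcRow("negative", "kidney", fraction = 0L, intensity = 0L))
  got <- restrictedExpressionQuery(ann, "kidney", 6)
  expect_identical(got, c("ok6", "unique"))
  # max_other_tissues = 0 returns exactly the uniquely stained genes
  expect_identical(restrictedExpressionQuery(ann, "kidney", 0), "unique")
  # 7 other tissues admitted once the cutoff is raised
  expect_identical(restrictedExpressionQuery(ann, "kidney", 7),
                   c("ok6", "seven", "unique"))
  expect_error(restrictedExpressionQuery(ann, "spleen"),
               class = "ts_config_error")
  # ties at equal level are allowed ("lower or equal")
  tie <- rbind(ihcRow("t", "kidney", intensity = 2L, fraction = 2L),
               ihcRow("t", "liver", "other", intensity = 2L, fraction = 2L))
  expect_identical(restrictedExpressionQuery(tie, "kidney", 6), "t")
  # intensity-only comparison ignores the fraction component
  frac <- rbind(ihcRow("f", "kidney", intensity = 2L, fraction = 1L),
                ihcRow("f", "liver", "other", intensity = 2L, fraction = 3L))
  expect_identical(restrictedExpressionQuery(frac, "kidney", 6,
                                             comparison = "intensity"), "f")
  expect_identical(restrictedExpressionQuery(frac, "kidney", 6),
                   character(0))
})

test_that("unique-compartment assignment enforces exclusivity", {
  ann <- rbind(
    ihcRow("prox", "kidney", "proximal_tubule"),
    ihcRow("multi", "kidney", "proximal_tubule"),
    ihcRow("multi", "kidney", "distal_tubule"),
    ihcRow("ic", "kidney", "collecting_duct_intercalated"),
    ihcRow("cd", "kidney", "collecting_duct"),
    ihcRow("cd", "kidney", "collecting_duct_intercalated",
           antibody = "AB2_cd"),
    ihcRow("vessel", "kidney", "other"),
    ihcRow("faint", "kidney", "glomeruli", fraction = 0L, intensity = 0L),
    ihcRow("glom", "kidney", "glomeruli"),
    ihcRow("glom", "liver", "hepatocyte"))  # non-kidney rows ignored
  genes <- unique(ann$gene_id)
  calls <- assignUniqueCompartment(ann, genes)
  expect_identical(calls$gene_id, c("cd", "glom", "ic", "prox"))
  expect_identical(calls$compartment[calls$gene_id == "prox"],
                   "proximal_tubule")
  # intercalated-only iff every positive annotation is intercalated
  expect_true(calls$intercalated_only[calls$gene_id == "ic"])
  expect_false(calls$intercalated_only[calls$gene_id == "cd"])
  expect_identical(calls$compartment[calls$gene_id == "ic"],
                   "collecting_duct")
  # multi-compartment, other-structure and unstained genes yield no call
  expect_false(any(c("multi", "vessel", "faint") %in% calls$gene_id))
  # no gene receives two calls; order of input rows is irrelevant
  expect_identical(anyDuplicated(calls$gene_id), 0L)
  shuffled <- ann[rev(seq_len(nrow(ann))), ]
  expect_identical(assignUniqueCompartment(shuffled, genes), calls)
})

test_that("RNA-IHC concordance breaks the overlap down by elevated category", {
  study <- generateSyntheticStudy(tinySim(10, seed = 13))
  sc <- classifyProfile(TissueProfile(study$means), "kidney")
  tab <- specTable(sc)
  pick <- c(tab$gene_id[tab$category == "highly_enriched"][1:3],
            tab$gene_id[tab$category == "group_enriched"][1:2],
            tab$gene_id[tab$category == "enhanced"][1:2],
            tab$gene_id[tab$category == "mixed"][1:4])  # not elevated
  rep_ <- rnaIhcConcordance(sc, pick)
  expect_identical(rep_$total, 7L)
  expect_identical(sum(rep_$by_category), rep_$total)
  expect_identical(unname(rep_$by_category),
                   c(3L, 0L, 2L, 2L))
  # disjoint sets give zero everywhere
  zero <- rnaIhcConcordance(sc, c("nope1", "nope2"))
  expect_identical(zero$total, 0L)
  expect_identical(sum(zero$by_category), 0L)
  # a subset of enriched genes lands entirely in enriched
  sub <- rnaIhcConcordance(sc, tab$gene_id[tab$category == "highly_enriched"])
  expect_identical(unname(sub$by_category), c(10L, 0L, 0L, 0L))
})

test_that("reference-set comparison counts presence and absence from all lists", {
  calls <- data.frame(gene_id = sprintf("G%03d", 1:148),
                      compartment = "proximal_tubule",
                      intercalated_only = FALSE, n_annotations = 1L)
  # three overlapping reference lists leaving exactly 51 calls uncovered
  covered <- calls$gene_id[1:97]
  refs <- list(urine = covered[1:60], plasma = covered[30:80],
               tissue = covered[50:97])
  rep_ <- compareToReferenceSets(calls, refs)
  expect_identical(rep_$absent_from_all, 51L)
  expect_identical(rep_$per_list$present[rep_$per_list$list == "urine"], 60L)
  expect_identical(rowSums(cbind(rep_$per_list$present,
                                 rep_$per_list$absent)),
                   rep(148, 3))
  # disjoint references: everything absent
  none <- compareToReferenceSets(calls, list(a = c("x", "y")))
  expect_identical(none$per_list$present, 0L)
  expect_identical(none$absent_from_all, 148L)
  # identical reference: everything present there
  all_ <- compareToReferenceSets(calls, list(a = calls$gene_id))
  expect_identical(all_$per_list$absent, 0L)
  expect_identical(all_$absent_from_all, 0L)
  expect_error(compareToReferenceSets(calls, list()),
               class = "ts_config_error")
})
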