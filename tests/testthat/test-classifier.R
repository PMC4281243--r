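test_that("detection calls respect the 1-FPKM limit with the boundary detected", {
  expect_false(isDetected(0.99))
  expect_true(isDetected(1))
  expect_true(isDetected(1421))
  expect_error(isDetected(-1), class = "ts_negative_value")
})

test_that("TS score is target over floored max-other", {
  expect_equal(tissueSpecificityScore(
    c(kidney = 100, liver = 4, lung = 1), "kidney"), 25)
  expect_equal(tissueSpecificityScore(
    c(kidney = 100, liver = 0, lung = 0), "kidney"), 10000)
  expect_equal(tissueSpecificityScore(
    c(kidney = 250, a = 50, b = 10, c = 0.5), "kidney"), 5)
  expect_error(tissueSpecificityScore(c(kidney = 1), "kidney"),
               class = "ts_data_error")
  expect_error(tissueSpecificityScore(c(liver = 1, lung = 2), "kidney"),
               class = "ts_config_error")
})

test_that("group search matches its spec examples", {
  p1 <- c(kidney = 50, liver = 40, a = 8, b = 7, c = 6, d = 5, e = 4,
          f = 3, g = 2, h = 1)
  expect_identical(findEnrichedGroup(p1, "kidney"),
                   c("kidney", "liver"))  # mean 45 >= 5 * 8

  p2 <- stats::setNames(c(50, rep(49, 9)),
                        c("kidney", paste0("t", 1:9)))
  expect_null(findEnrichedGroup(p2, "kidney"))

  # too few outside tissues for the configured maximum group size
  p3 <- c(kidney = 9, a = 1, b = 1, c = 1)
  expect_error(findEnrichedGroup(p3, "kidney"),
               class = "ts_config_error")
})

test_that("prefix group search agrees with brute-force subset enumeration", {
  set.seed(4711)
  th <- SpecThresholds()
  nAgree <- 0L
  for (i in 1:1000) {
    n <- sample(8:10, 1)
    p <- randomProfile(n)
    target <- sample(names(p), 1)
    got <- findEnrichedGroup(p, target, th)
    want <- bruteForceEnrichedGroups(p, target, th)
    if (is.null(want)) {
      expect_null(got)
    } else {
      # same existence, same minimal size, and the returned group passes
      # the criterion checked directly
      expect_false(is.null(got))
      expect_equal(length(got), length(want[[1]]))
      expect_true(target %in% got)
      expect_true(groupQualifies(p, got, th))
    }
    nAgree <- nAgree + 1L
  }
  expect_identical(nAgree, 1000L)
})

test_that("classification follows the precedence rules on worked examples", {
  t27 <- sprintf("t%02d", 1:26)
  p <- stats::setNames(c(100, 1.9, rep(0.2, 25)), c("kidney", "liver", t27[1:25]))
  expect_identical(classifyGene(p, "kidney")$category, "highly_enriched")

  allFive <- stats::setNames(rep(5, 27), c("kidney", t27))
  expect_identical(classifyGene(allFive, "kidney")$category,
                   "expressed_in_all")

  nd <- stats::setNames(c(0.5, runif(26, 0, 100)), c("kidney", t27))
  expect_identical(classifyGene(nd, "kidney")$category, "not_detected")

  # TS = 3 fails moderate enrichment but {kidney, partner} forms a group
  pg <- stats::setNames(c(30, 10, rep(0.2, 25)),
                        c("kidney", "liver", t27[1:25]))
  r <- classifyGene(pg, "kidney")
  expect_identical(r$category, "group_enriched")
  expect_identical(r$enriched_group, c("kidney", "liver"))
  expect_equal(r$ts_score, 3)

  # enhanced: well above the all-tissue mean but no enrichment or group
  pe <- stats::setNames(
    50 * c(1, 0.4, 0.28, 0.224, 0.19, 0.167, 0.151, 0.138, rep(0.002, 19)),
    c("kidney", t27))
  re <- classifyGene(pe, "kidney")
  expect_identical(re$category, "enhanced")
  expect_true(re$ts_score < 5)

  # detected in some tissues, nothing elevated
  pm <- stats::setNames(c(rep(10, 14), rep(0.05, 13)), c("kidney", t27))
  expect_identical(classifyGene(pm, "kidney")$category, "mixed")
})

test_that("every gene gets exactly one category and tallies are consistent", {
  study <- generateSyntheticStudy(tinySim(10, seed = 5))
  sc <- classifyProfile(TissueProfile(study$means), "kidney")
  tab <- specTable(sc)
  expect_identical(nrow(tab), 70L)
  expect_true(all(tab$category %in% specCategories()))
  tl <- categoryTally(sc)
  expect_identical(sum(tallyCounts(tl)), tallyTotal(tl))
  expect_identical(sum(tallyCounts(tl)[elevatedCategories()]),
                   tallyElevated(tl))
  expect_identical(unname(tallyCounts(tl)), rep(10L, 7))

  # permuting gene order leaves the tally unchanged and preserves order
  perm <- sample(nrow(study$means))
  sc2 <- classifyProfile(TissueProfile(study$means[perm, ]), "kidney")
  expect_identical(tallyCounts(categoryTally(sc2)), tallyCounts(tl))
  expect_identical(specTable(sc2)$gene_id, rownames(study$means)[perm])

  # empty profile: empty table, all-zero tally
  empty <- classifyProfile(
    matrix(numeric(), 0, 27,
           dimnames = list(NULL, colnames(study$means))), "kidney")
  expect_identical(nrow(specTable(empty)), 0L)
  expect_identical(sum(tallyCounts(categoryTally(empty))), 0L)
})

test_that("TS score and categories are scale invariant", {
  set.seed(77)
  study <- generateSyntheticStudy(tinySim(5, seed = 8))
  m <- study$means
  sc1 <- classifyProfile(TissueProfile(m), "kidney")
  for (cmul in c(0.001, 1000)) {
    sc2 <- classifyProfile(TissueProfile(m * cmul), "kidney")
    expect_equal(specTable(sc2)$ts_score, specTable(sc1)$ts_score)
    # detection status changes under scaling, but for genes whose
    # detection pattern is unchanged the category must be identical
    same <- rowSums(m >= 1) == rowSums(m * cmul >= 1) &
      (m[, "kidney"] >= 1) == (m[, "kidney"] * cmul >= 1)
    expect_identical(specTable(sc2)$category[same],
                     specTable(sc1)$category[same])
  }
})

test_that("raising the target FPKM never demotes a gene", {
  # specificity order from least to most specific for the target
  specOrder <- c(not_detected = 0, mixed = 1, expressed_in_all = 1,
                 enhanced = 2, group_enriched = 3, moderately_enriched = 4,
                 highly_enriched = 5)
  set.seed(31)
  for (i in 1:50) {
    p <- randomProfile(10)
    target <- names(p)[1]
    r1 <- classifyGene(p, target)
    p2 <- p
    p2[target] <- p[target] * 10^runif(1, 0, 2)
    r2 <- classifyGene(p2, target)
    expect_gte(r2$ts_score, r1$ts_score)
    expect_gte(specOrder[[r2$category]], specOrder[[r1$category]])
  }
})

test_that("mRNA pool fractions sum to one and follow target FPKM mass", {
  # two genes: 80 FPKM expressed-in-all, 20 FPKM highly enriched
  m <- rbind(hk = rep(80, 27), enr = c(20, rep(0.2, 26)))
  colnames(m) <- c("kidney", sprintf("t%02d", 1:26))
  sc <- classifyProfile(TissueProfile(m), "kidney")
  pf <- mrnaPoolFractions(sc)
  expect_equal(sum(pf), 1)
  expect_equal(unname(pf["expressed_in_all"]), 0.8)
  expect_equal(unname(pf["elevated"]), 0.2)

  onecat <- classifyProfile(TissueProfile(m[1, , drop = FALSE]), "kidney")
  pf1 <- mrnaPoolFractions(onecat)
  expect_equal(unname(pf1["expressed_in_all"]), 1)
  expect_equal(sum(pf1), 1)
})

test_that("top-expressed ranking is FPKM-descending with lexicographic ties", {
  m <- rbind(b = c(100, rep(1, 26)), a = c(100, rep(1, 26)),
             c = c(15484, rep(1, 26)), d = c(7, rep(1, 26)))
  colnames(m) <- c("kidney", sprintf("t%02d", 1:26))
  sc <- classifyProfile(TissueProfile(m), "kidney")
  top <- topExpressed(sc, 3)
  expect_identical(top$gene_id, c("c", "a", "b"))
  expect_equal(top$target_fpkm[1], 15484)
  expect_identical(topExpressed(sc, 1)$gene_id, "c")
  # n beyond the gene count returns everything, no error
  expect_identical(nrow(topExpressed(sc, 100)), 4L)
  expect_error(topExpressed(sc, 0), class = "ts_config_error")
})
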