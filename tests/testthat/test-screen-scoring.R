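test_that("guide frequencies follow the pseudocounted CPM contract", {
  cts <- rbind(GENE1_g1 = c(1, 10), GENE1_g2 = c(3, 10))
  colnames(cts) <- c("vector_T1_r1", "vector_T2_r1")
  se <- makeSE(cts)
  f0 <- assay(normalizeGuideCounts(se, pseudocount = 0), "freq")
  expect_equal(unname(f0[, 1]), c(250000, 750000))
  # column-sum closed form: 1e6 * (1 + n * pc / total)
  set.seed(3)
  cts2 <- matrix(rpois(60, 50), 10, 6,
                 dimnames = list(paste0("GENE", 1:10, "_g1"),
                                 paste0("vector_T", rep(0:2, 2), "_r",
                                        rep(1:2, each = 3))))
  se2 <- normalizeGuideCounts(makeSE(cts2), pseudocount = 0.5)
  sums <- colSums(assay(se2, "freq"))
  expected <- 1e6 * (1 + 10 * 0.5 / colSums(cts2))
  expect_equal(sums, expected, tolerance = 1e-6)
  # empty column is an error naming the sample
  cts3 <- cts; cts3[, 2] <- 0L
  expect_error(normalizeGuideCounts(makeSE(cts3)), "vector_T2_r1")
})

test_that("depletion metric is the replicate-averaged log2 T2/T1 ratio", {
  cts <- rbind(GENE1_g1 = c(800, 400, 800, 400),
               GENE2_g1 = c(200, 600, 200, 600))
  colnames(cts) <- c("vector_T1_r1", "vector_T2_r1",
                     "vector_T1_r2", "vector_T2_r2")
  se <- normalizeGuideCounts(makeSE(cts), pseudocount = 0)
  dm <- depletionMetric(se, "vector")
  expect_equal(dm$depletion[dm$guide_id == "GENE1_g1"], -1.0)
  expect_equal(dm$depletion[dm$guide_id == "GENE2_g1"], log2(3))
  # identical timepoints give exactly zero
  cts2 <- cts; cts2[, c(2, 4)] <- cts2[, c(1, 3)]
  dm2 <- depletionMetric(normalizeGuideCounts(makeSE(cts2), 0), "vector")
  expect_equal(dm2$depletion, c(0, 0))
  expect_error(depletionMetric(se, "KRAS"), "KRAS")
})

test_that("depletion matches the growth-model expectation in simulation", {
  cfg <- screenSimConfig(nGenes = 60, nRibosomal = 0, nNontargeting = 20,
                         depth = 2e6,
                         fitness = data.frame(gene = "GENE001",
                                              background = "KRAS",
                                              fitness = -1),
                         seed = 19)
  sim <- simulateScreen(cfg)
  exp <- expectedScreenFrequencies(cfg)
  dm <- depletionMetric(normalizeGuideCounts(sim$experiment), "KRAS")
  # oracle: log2 expected frequency ratio (includes renormalization shift)
  oracle <- log2(exp$frequency[, "KRAS_T2_r1"] /
                   exp$frequency[, "KRAS_T1_r1"])
  got <- setNames(dm$depletion, dm$guide_id)
  expect_lt(mean(abs(got - oracle[names(got)])), 0.25)
  g1 <- paste0("GENE001_g", 1:5)
  expect_equal(unname(got[g1]), unname(oracle[g1]), tolerance = 0.35)
})

test_that("enrichment scores subtract the vector reference in log2 space", {
  metrics <- data.frame(guide_id = rep(c("g1", "g2"), 2),
                        background = rep(c("vector", "KRAS"), each = 2),
                        depletion = c(-0.5, 0.2, -2, 0.2))
  sc <- enrichmentScore(metrics)
  expect_equal(sc$score[sc$background == "vector"], c(0, 0))
  expect_equal(sc$score[sc$background == "KRAS" & sc$guide_id == "g1"],
               -1.5)
  expect_equal(sc$score[sc$background == "KRAS" & sc$guide_id == "g2"], 0)
  expect_error(enrichmentScore(metrics[metrics$background != "vector", ]),
               "vector")
})

test_that("non-targeting guides score near zero under the null", {
  cfg <- screenSimConfig(seed = 23)
  sim <- simulateScreen(cfg)
  sc <- enrichmentScore(depletionMetric(normalizeGuideCounts(
    sim$experiment)))
  nt <- sim$library$guide_id[sim$library$class == "nontargeting"]
  for (bg in c("KRAS", "NRAS", "HRAS")) {
    m <- mean(sc$score[sc$background == bg & sc$guide_id %in% nt])
    expect_lt(abs(m), 0.05)
  }
})

test_that("gene collapse takes best-3-of-5 means per direction", {
  lib <- data.frame(guide_id = paste0("G1_g", 1:5), gene = "G1",
                    class = "target")
  sc <- data.frame(guide_id = lib$guide_id, background = "KRAS",
                   score = c(1, 2, 3, 4, 5))
  gs <- collapseGenes(sc, lib)
  expect_equal(gs$pos_score, 4.0)
  expect_equal(gs$neg_score, 2.0)
  # all guides equal: both scores collapse to the common value
  sc$score <- rep(7, 5)
  gs2 <- collapseGenes(sc, lib)
  expect_equal(gs2$pos_score, 7)
  expect_equal(gs2$neg_score, 7)
  # fewer guides than k: collapsed over all and flagged
  gs3 <- collapseGenes(sc[1:2, ], lib[1:2, ])
  expect_true(gs3$flagged)
  expect_equal(gs3$pos_score, 7)
  expect_error(collapseGenes(transform(sc, guide_id = paste0("X", 1:5)),
                             lib), "absent from the library")
})

test_that("collapse equals the exhaustive subset-mean oracle", {
  set.seed(29)
  nGenes <- 300
  lib <- data.frame(guide_id = paste0("G", rep(1:nGenes, each = 5), "_g",
                                      1:5),
                    gene = paste0("G", rep(1:nGenes, each = 5)),
                    class = "target")
  sc <- data.frame(guide_id = lib$guide_id, background = "KRAS",
                   score = rnorm(nrow(lib)))
  gs <- collapseGenes(sc, lib)
  for (g in sample(unique(lib$gene), 50)) {
    oracle <- subsetMeanOracle(sc$score[lib$gene == g], 3)
    expect_equal(gs$pos_score[gs$gene == g], oracle[["pos"]],
                 tolerance = 1e-12)
    expect_equal(gs$neg_score[gs$gene == g], oracle[["neg"]],
                 tolerance = 1e-12)
  }
  expect_true(all(gs$pos_score >= gs$neg_score))
})

test_that("classification partitions genes and honors the benchmark", {
  gs <- data.frame(gene = c("A", "B", "C", "BRAF"), class = "target",
                   background = "KRAS", n_guides = 5L,
                   pos_score = c(0.5, 0.5, 0.1, 0.0),
                   neg_score = c(-0.1, -0.5, -0.2, -0.6), flagged = FALSE)
  cl <- classifyGenes(gs, tau = 0.4)
  expect_equal(cl$scores$class_call, c("positive", "both", "unaltered",
                                       "negative"))
  expect_equal(sum(cl$fractions$fraction), 1)
  # benchmark recalibration: tau = |neg_score(BRAF)| = 0.6
  cl2 <- classifyGenes(gs, benchmark = "BRAF")
  expect_equal(unique(cl2$scores$tau), 0.6)
  expect_equal(cl2$scores$class_call[2], "unaltered")  # -0.5 > -0.6
  expect_error(classifyGenes(gs, benchmark = "NOPE"), "NOPE")
})

test_that("classification is monotone in the guide scores", {
  set.seed(41)
  lib <- data.frame(guide_id = paste0("G", rep(1:40, each = 5), "_g", 1:5),
                    gene = paste0("G", rep(1:40, each = 5)),
                    class = "target")
  sc <- data.frame(guide_id = lib$guide_id, background = "KRAS",
                   score = rnorm(200, 0, 0.5))
  before <- classifyGenes(collapseGenes(sc, lib))$scores
  scUp <- transform(sc, score = score + 0.3)
  after <- classifyGenes(collapseGenes(scUp, lib))$scores
  wasPositive <- before$gene[before$class_call %in% c("positive", "both")]
  expect_true(all(after$class_call[after$gene %in% wasPositive] %in%
                    c("positive", "both")))
})

test_that("top-percentile flags follow the ceiling rule", {
  set.seed(43)
  gs <- data.frame(gene = sprintf("G%03d", 1:500), class = "target",
                   background = "KRAS", n_guides = 5L,
                   pos_score = rnorm(500), neg_score = rnorm(500) - 1,
                   flagged = FALSE)
  rk <- rankPercentiles(gs, top = 0.01)
  expect_equal(sum(rk$top_pos), 5L)
  expect_equal(sum(rk$top_neg), 5L)
  expect_true(rk$top_neg[which.min(rk$neg_score)])
  expect_true(rk$top_pos[1])  # waterfall order: most positive first
  expect_equal(rk$gene[1], gs$gene[which.max(gs$pos_score)])
})

test_that("scores are invariant to uniform depth rescaling of a column", {
  # neutral library: pseudocount effects stay below 1e-3 only while counts
  # remain comfortably above it, i.e. without strongly depleted guides
  cfg <- screenSimConfig(nGenes = 50, nRibosomal = 0, nNontargeting = 20,
                         depth = 1e6, seed = 37)
  sim <- simulateScreen(cfg)
  se <- sim$experiment
  cts <- assay(se, "counts")
  cts2 <- cts
  cts2[, "KRAS_T2_r1"] <- cts2[, "KRAS_T2_r1"] * 3L
  se2 <- ScreenExperiment(cts2, sim$library, sampleInfo(se))
  s1 <- enrichmentScore(depletionMetric(normalizeGuideCounts(se)))
  s2 <- enrichmentScore(depletionMetric(normalizeGuideCounts(se2)))
  expect_lt(max(abs(s1$score - s2$score)), 1e-3)
})

test_that("screen QC reports totals, dropouts and Gini evenness", {
  cts <- rbind(GENE1_g1 = c(100L, 0L), GENE2_g1 = c(100L, 200L))
  colnames(cts) <- c("vector_T0_r1", "vector_T1_r1")
  qc <- screenQC(makeSE(cts))
  expect_equal(qc$total_reads, c(200, 200))
  expect_equal(qc$zero_guides, c(0, 1))
  expect_equal(qc$gini, c(0, 0.5))  # equal counts 0; (0,200) gives 1/2
})
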