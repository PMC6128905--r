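makeJoined <- function() {
  data.frame(entity_id = c("REF", "A", "B"),
             protein_id = c("REF", "A", "B"),
             labeling_KRAS = c(8, 4, 4),
             passes_KRAS = c(TRUE, TRUE, TRUE),
             neg_KRAS = c(-1.2, -0.6, -0.5),
             pos_KRAS = c(0, 0, 0), stringsAsFactors = FALSE)
}

test_that("assay join keeps mappable entities and reports the rest", {
  rec <- data.frame(protein_id = c("P1", "P2", "P3"), bait = "KRAS",
                    fold_change = c(4, 3, 2), p_value = 0.01,
                    n_peptides = 3L, passes = c(TRUE, TRUE, FALSE))
  gs <- data.frame(gene = c("G1", "G2", "G4"), class = "target",
                   background = "KRAS", n_guides = 5L,
                   pos_score = c(0.1, 0.2, 0.3),
                   neg_score = c(-1, -2, -3), flagged = FALSE)
  map <- data.frame(protein_id = c("P1", "P2", "P3"),
                    gene = c("G1", "G2", "G3"))
  j <- joinAssays(rec, gs, map)
  expect_setequal(j$records$entity_id, c("G1", "G2"))
  expect_equal(j$records$labeling_KRAS[j$records$entity_id == "G1"], 4)
  expect_equal(j$records$neg_KRAS[j$records$entity_id == "G2"], -2)
  expect_equal(j$sidecar$unmapped_proteins, "P3")
  expect_equal(j$sidecar$unmapped_genes, "G4")
  badMap <- rbind(map, data.frame(protein_id = "P1", gene = "G9"))
  expect_error(joinAssays(rec, gs, badMap), "ambiguous")
})

test_that("a synthetic 100-entity join matches a dictionary-merge oracle", {
  set.seed(51)
  prot <- sprintf("P%03d", 1:100)
  rec <- data.frame(protein_id = rep(prot, 2),
                    bait = rep(c("KRAS", "NRAS"), each = 100),
                    fold_change = rlnorm(200), p_value = runif(200),
                    n_peptides = 3L, passes = runif(200) > 0.5)
  gs <- data.frame(gene = rep(prot[11:100], 2),
                   class = "target",
                   background = rep(c("KRAS", "NRAS"), each = 90),
                   n_guides = 5L, pos_score = rnorm(180),
                   neg_score = rnorm(180) - 1, flagged = FALSE)
  j <- joinAssays(rec, gs)
  expect_setequal(j$records$entity_id, prot[11:100])
  for (e in sample(prot[11:100], 20)) {
    r <- j$records[j$records$entity_id == e, ]
    expect_equal(r$labeling_KRAS,
                 rec$fold_change[rec$protein_id == e & rec$bait == "KRAS"])
    expect_equal(r$neg_NRAS,
                 gs$neg_score[gs$gene == e & gs$background == "NRAS"])
  }
  expect_setequal(j$sidecar$unmapped_proteins, prot[1:10])
})

test_that("dual-hit rule flags entities at half the reference in both assays", {
  j <- makeJoined()
  out <- dualHitCall(j, "REF", "KRAS")
  # A sits exactly on the boundary (labeling 4 = 8/2, neg -0.6 = -1.2/2)
  expect_equal(out$dual_hit_KRAS, c(TRUE, TRUE, FALSE))
  expect_equal(attr(out, "benchmark")[["labeling"]], 8)
  # the reference always flags itself
  expect_true(out$dual_hit_KRAS[out$entity_id == "REF"])
})

test_that("dual-hit calls are invariant to positive rescaling of either assay", {
  set.seed(53)
  j <- data.frame(entity_id = sprintf("E%02d", 1:40),
                  protein_id = sprintf("E%02d", 1:40),
                  labeling_KRAS = rlnorm(40, 1),
                  neg_KRAS = -rlnorm(40, 0), stringsAsFactors = FALSE)
  j$labeling_KRAS[1] <- 5; j$neg_KRAS[1] <- -2
  base <- dualHitCall(j, "E01", "KRAS", requirePass = FALSE)
  scaledLab <- transform(j, labeling_KRAS = labeling_KRAS * 37.5)
  scaledNeg <- transform(j, neg_KRAS = neg_KRAS * 0.04)
  expect_equal(dualHitCall(scaledLab, "E01", "KRAS",
                           requirePass = FALSE)$dual_hit_KRAS,
               base$dual_hit_KRAS)
  expect_equal(dualHitCall(scaledNeg, "E01", "KRAS",
                           requirePass = FALSE)$dual_hit_KRAS,
               base$dual_hit_KRAS)
})

test_that("invalid dual-hit references raise errors", {
  j <- makeJoined()
  expect_error(dualHitCall(j, "MISSING", "KRAS"), "missing")
  j2 <- j; j2$neg_KRAS[1] <- 0.3
  expect_error(dualHitCall(j2, "REF", "KRAS"), "non-negative")
  j3 <- j; j3$passes_KRAS[1] <- FALSE
  expect_error(dualHitCall(j3, "REF", "KRAS"), "interactome")
})

test_that("planted dual-effect genes are recovered against the reference", {
  # 20 entities at 70% of the reference effect in both assays, plus nulls
  set.seed(55)
  cfg <- screenSimConfig(
    nGenes = 120, nRibosomal = 0, nNontargeting = 50,
    fitness = data.frame(
      gene = sprintf("GENE%03d", 1:21), background = "KRAS",
      fitness = c(-0.8, rep(-0.56, 20))),
    seed = 57)
  sim <- simulateScreen(cfg)
  gs <- collapseGenes(enrichmentScore(depletionMetric(
    normalizeGuideCounts(sim$experiment))), sim$library)
  gsK <- gs[gs$background == "KRAS" & gs$class == "target", ]
  lab <- setNames(rep(1, nrow(gsK)), gsK$gene)
  lab[sprintf("GENE%03d", 1:21)] <- c(8, rep(0.7 * 8, 20))
  j <- data.frame(entity_id = gsK$gene, protein_id = gsK$gene,
                  labeling_KRAS = unname(lab[gsK$gene]),
                  neg_KRAS = gsK$neg_score, stringsAsFactors = FALSE)
  out <- dualHitCall(j, "GENE001", "KRAS", requirePass = FALSE)
  planted <- sprintf("GENE%03d", 2:21)
  expect_gte(sum(out$dual_hit_KRAS[out$entity_id %in% planted]), 18)
})

test_that("differential labeling of a matrix against itself is zero", {
  set.seed(59)
  m <- matrix(2^rnorm(30, 10), 10, 3,
              dimnames = list(sprintf("P%02d", 1:10),
                              paste0("control_r", 1:3)))
  pq <- makePQ(m)
  d <- differentialLabeling(pq, pq, reference = "P01")
  expect_true(all(d$records$fold_difference == 0))
  expect_true(all(d$records$direction == "unchanged"))
  expect_equal(unname(d$benchmark), 0)
})

test_that("differential labeling averages knockout lines with equal weight", {
  base <- matrix(100, 4, 3, dimnames = list(c("REF", "A", "B", "C"),
                                            paste0("control_r", 1:3)))
  pqV <- makePQ(base)
  ko <- cbind(base / c(2, 1, 1, 1), base / c(2, 1, 2, 1),
              base / c(8, 0.5, 1, 1))
  colnames(ko) <- paste0("ko_r", 1:9)
  annKO <- data.frame(sample_id = colnames(ko), bait = "control",
                      condition = rep(c("sg1", "sg2", "sg3"), each = 3),
                      replicate = rep(1:3, 3), qc_pool = FALSE)
  pqKO <- ProteinQuant(ko, annKO, rep(2L, 4))
  d <- differentialLabeling(pqV, pqKO, reference = "REF")
  # reference reduced 2-, 2- and 8-fold: benchmark = mean(-1, -1, -3)
  expect_equal(unname(d$benchmark), -5 / 3)
  rec <- d$records
  expect_equal(rec$fold_difference[rec$protein_id == "A"], 1 / 3)
  expect_equal(rec$direction[rec$protein_id == "A"], "enriched")
  expect_equal(rec$fold_difference[rec$protein_id == "B"], -1 / 3)
  expect_equal(rec$fold_difference[rec$protein_id == "C"], 0)
  expect_equal(rec$direction[rec$protein_id == "C"], "unchanged")
  expect_error(differentialLabeling(pqV, pqKO, reference = "NOPE"), "NOPE")
})

test_that("a doubled protein crosses the +0.1 direction threshold", {
  m <- matrix(100, 2, 2, dimnames = list(c("REF", "A"),
                                         paste0("control_r", 1:2)))
  ko <- m * c(0.5, 2)
  colnames(ko) <- paste0("ko_r", 1:2)
  annKO <- data.frame(sample_id = colnames(ko), bait = "control",
                      condition = "sg1", replicate = 1:2, qc_pool = FALSE)
  d <- differentialLabeling(makePQ(m), ProteinQuant(ko, annKO, c(2L, 2L)),
                            reference = "REF")
  expect_equal(d$records$fold_difference[d$records$protein_id == "A"], 1.0)
  expect_equal(d$records$direction[d$records$protein_id == "A"],
               "enriched")
})

test_that("over-representation p-values equal hypergeometric closed forms", {
  bg <- as.character(1:10)
  res <- overrepresentation(hits = as.character(1:5),
                            sets = list(S = as.character(1:5)),
                            background = bg)
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$overlap, 5L, ignore_attr = TRUE)
  # overlap proportional to background composition: fold enrichment 1
  res2 <- overrepresentation(hits = as.character(1:5),
                             sets = list(S = as.character(c(1, 2, 6, 7))),
                             background = bg)
  expect_equal(res2$fold_enrichment, 1.0)
})

test_that("random over-representation tables match brute-force tail sums", {
  set.seed(61)
  for (i in 1:50) {
    N <- sample(30:200, 1)
    bg <- as.character(seq_len(N))
    m <- sample(5:(N - 5), 1)
    q <- sample(5:(N - 5), 1)
    s <- sample(bg, m)
    h <- sample(bg, q)
    res <- overrepresentation(h, list(S = s), bg)
    k <- length(intersect(s, h))
    expect_equal(res$p_value, hyperTailOracle(k, m, N, q),
                 tolerance = 1e-12)
    expect_gt(res$p_value, 0)
    expect_lte(res$p_value, 1)
  }
  expect_error(overrepresentation("x", list(S = "x"), character()),
               "empty")
  expect_error(overrepresentation("zz", list(S = "1"),
                                  as.character(1:5)), "outside")
})

test_that("over-representation p-values are super-uniform under the null", {
  set.seed(63)
  bg <- as.character(1:500)
  s <- sample(bg, 100)
  p <- replicate(1000,
    overrepresentation(sample(bg, 50), list(S = s), bg)$p_value)
  expect_gt(mean(p), 0.45)
  for (t in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    se <- sqrt(t * (1 - t) / 1000)
    expect_lte(mean(p <= t), t + 4 * se)
  }
})

test_that("percent viability implements the plate-reader formula", {
  expect_equal(percentViability(1.1, blank = 0.1, negativeControl = 1.1),
               100)
  expect_equal(percentViability(0.1, blank = 0.1, negativeControl = 1.1),
               0)
  expect_equal(percentViability(0.6, blank = 0.1, negativeControl = 1.1),
               50.0)
  # out-of-range values are reported as-is
  expect_gt(percentViability(1.5, 0.1, 1.1), 100)
  expect_lt(percentViability(0.05, 0.1, 1.1), 0)
  expect_error(percentViability(0.5, blank = 1.1, negativeControl = 1.0),
               "exceed")
})
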