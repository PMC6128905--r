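# Small in-code fixtures and independent oracles shared across test files.

suppressPackageStartupMessages(library(SummarizedExperiment))

# ProteinQuant from a plain matrix; bait inferred from column names like
# "KRAS_r1" unless given.
makePQ <- function(m, baits = sub("_r\\d+$", "", colnames(m)),
                   nPeptides = rep(2L, nrow(m)), qc = grepl("^QC", colnames(m)),
                   normalization = "none") {
  ann <- data.frame(sample_id = colnames(m), bait = ifelse(qc, NA, baits),
                    condition = "vector",
                    replicate = seq_len(ncol(m)), qc_pool = qc)
  ProteinQuant(m, ann, nPeptides, normalization = normalization)
}

# ScreenExperiment from counts with sample names "<bg>_<tp>_r<i>"
makeSE <- function(counts, classes = rep("target", nrow(counts)),
                   genes = sub("_g\\d+$", "", rownames(counts))) {
  parts <- do.call(rbind, strsplit(colnames(counts), "_"))
  ann <- data.frame(sample_id = colnames(counts), background = parts[, 1],
                    timepoint = parts[, 2],
                    replicate = as.integer(sub("^r", "", parts[, 3])))
  lib <- data.frame(guide_id = rownames(counts), gene = genes,
                    class = classes)
  ScreenExperiment(counts, lib, ann)
}

# exhaustive best-k-of-n oracle: extremum over all k-subset means
subsetMeanOracle <- function(scores, k) {
  if (length(scores) <= k) return(c(pos = mean(scores), neg = mean(scores)))
  ms <- combn(scores, k, mean)
  c(pos = max(ms), neg = min(ms))
}

# brute-force hypergeometric upper-tail p: P(overlap >= k)
hyperTailOracle <- function(k, m, N, q) {
  kk <- k:min(m, q)
  sum(choose(m, kk) * choose(N - m, q - kk)) / choose(N, q)
}

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

# pooled-variance two-sample t-test p-value, written out from the textbook
# formula (independent of stats::t.test)
pooledTOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}
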