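# Dropout-screen scoring: guide frequencies, depletion metric, vector-
# referenced enrichment, best-3-of-5 gene collapse, benchmark-calibrated
# classification and percentile ranking.

#' Normalize guide counts to pseudocounted reads-per-million
#'
#' Per sample, `freq = (count + pseudocount) / sum(count) * 1e6`; the
#' denominator is the raw column total, so each column sums to
#' `1e6 * (1 + n_guides * pseudocount / total)` exactly.
#'
#' @param se a [ScreenExperiment-class].
#' @param pseudocount added to every count before scaling (default 0.5;
#'   keeps guides with zero reads finite on the log scale).
#' @return the input with a `freq` assay added and the pseudocount recorded
#'   in `metadata()$pseudocount`.
#' @export
normalizeGuideCounts <- function(se, pseudocount = 0.5) {
  stopifnot(is(se, "ScreenExperiment"))
  cts <- assay(se, "counts")
  tot <- colSums(cts)
  empty <- colnames(cts)[tot == 0]
  if (length(empty))
    stop("sample(s) with zero total counts: ", paste(empty, collapse = ", "))
  assay(se, "freq") <- sweep(cts + pseudocount, 2, tot, "/") * 1e6
  metadata(se)$pseudocount <- pseudocount
  se
}

.freqAssay <- function(se, pseudocount = 0.5) {
  if (!"freq" %in% assayNames(se)) se <- normalizeGuideCounts(se, pseudocount)
  se
}

#' Per-guide depletion metric within one background
#'
#' For each replicate, the log2 ratio of a guide's normalized frequency at
#' the later timepoint over the earlier one; replicates are averaged after
#' the per-replicate log ratio. Negative values mean depletion
#' (`log2(T2/T1)`); T0 is kept for representation QC only.
#'
#' @param se a [ScreenExperiment-class] (a `freq` assay is computed with the
#'   default pseudocount if absent).
#' @param background background to score, or `NULL` for all backgrounds.
#' @param from,to the two timepoints of the metric.
#' @return data.frame `guide_id`, `background`, `depletion` (long over
#'   backgrounds when `background = NULL`).
#' @export
depletionMetric <- function(se, background = NULL, from = "T1", to = "T2") {
  se <- .freqAssay(se)
  ann <- colData(se)
  if (is.null(background)) background <- unique(ann$background)
  freq <- assay(se, "freq")
  out <- lapply(background, function(bg) {
    f1 <- which(ann$background == bg & ann$timepoint == from)
    f2 <- which(ann$background == bg & ann$timepoint == to)
    if (!length(f1) || !length(f2))
      stop("background '", bg, "' is missing timepoint ",
           if (!length(f1)) from else to)
    r1 <- ann$replicate[f1]; r2 <- ann$replicate[f2]
    shared <- intersect(r1, r2)
    if (!length(shared)) stop("no shared replicates between timepoints")
    lr <- vapply(shared, function(r)
      log2(freq[, f2[match(r, r2)]] / freq[, f1[match(r, r1)]]),
      numeric(nrow(freq)))
    data.frame(guide_id = rownames(se), background = bg,
               depletion = rowMeans(lr), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Vector-referenced per-guide enrichment score
#'
#' A guide's enrichment score in a transformed background is its depletion
#' metric there minus its depletion metric in the vector reference; the
#' score of any guide in the reference background is identically 0.
#'
#' @param metrics long data.frame from [depletionMetric()] covering the
#'   reference background.
#' @param reference label of the reference (vector) background.
#' @return data.frame `guide_id`, `background`, `score`.
#' @export
enrichmentScore <- function(metrics, reference = "vector") {
  if (!reference %in% metrics$background)
    stop("reference background '", reference, "' not scored")
  ref <- metrics[metrics$background == reference, ]
  refv <- setNames(ref$depletion, ref$guide_id)
  out <- metrics
  out$score <- metrics$depletion - refv[metrics$guide_id]
  out$depletion <- NULL
  rownames(out) <- NULL
  out
}

# mean of the k most extreme values, ties broken by id for determinism
.topKMean <- function(score, id, k, decreasing) {
  ord <- order(score, id, decreasing = c(decreasing, FALSE),
               method = "radix")
  mean(score[ord[seq_len(min(k, length(score)))]])
}

#' Collapse guide scores to gene scores (best k of n per direction)
#'
#' `pos_score` is the mean of the `k` largest guide enrichment scores of the
#' gene, `neg_score` the mean of the `k` smallest ("three best out of five"
#' applied per direction, the reading under which a gene can be enriched in
#' both directions). Genes with fewer than `k` guides are collapsed over all
#' their guides and flagged. Ties are broken by guide id.
#'
#' @param scores data.frame from [enrichmentScore()].
#' @param library guide library (`guide_id`, `gene`, `class`).
#' @param k number of guides averaged per direction (default 3).
#' @return data.frame `gene`, `class`, `background`, `n_guides`,
#'   `pos_score`, `neg_score`, `flagged`.
#' @export
collapseGenes <- function(scores, library, k = 3) {
  missing <- setdiff(scores$guide_id, library$guide_id)
  if (length(missing))
    stop("guides absent from the library: ",
         paste(head(missing, 5), collapse = ", "))
  scores$gene <- library$gene[match(scores$guide_id, library$guide_id)]
  split <- split(scores, list(scores$gene, scores$background), drop = TRUE)
  out <- do.call(rbind, lapply(split, function(d) {
    data.frame(gene = d$gene[1], background = d$background[1],
               n_guides = nrow(d),
               pos_score = .topKMean(d$score, d$guide_id, k, TRUE),
               neg_score = .topKMean(d$score, d$guide_id, k, FALSE),
               flagged = nrow(d) < k, stringsAsFactors = FALSE)
  }))
  out$class <- library$class[match(out$gene, library$gene)]
  out <- out[order(out$background, out$gene), c("gene", "class",
                                                "background", "n_guides",
                                                "pos_score", "neg_score",
                                                "flagged")]
  rownames(out) <- NULL
  out
}

#' Classify genes by their collapsed enrichment scores
#'
#' With threshold `tau`, a gene is `positive` when `pos_score >= +tau`,
#' `negative` when `neg_score <= -tau`, `both` when both hold, and
#' `unaltered` otherwise. When a benchmark gene is supplied, `tau` is
#' recalibrated per background to the magnitude of the benchmark's negative
#' score there (e.g. BRAF, a pan-RAS effector whose loss impairs all
#' transformed backgrounds).
#'
#' @param geneScores data.frame from [collapseGenes()].
#' @param tau fixed classification threshold (default 0.4).
#' @param benchmark optional benchmark gene id for per-background
#'   recalibration of `tau`.
#' @return list with `scores` (input plus `tau` and `class` columns) and
#'   `fractions` (per background, fractions of the four classes, summing to
#'   1 over classified genes).
#' @export
classifyGenes <- function(geneScores, tau = 0.4, benchmark = NULL) {
  gs <- geneScores
  if (!is.null(benchmark)) {
    bm <- gs[gs$gene == benchmark, ]
    if (!nrow(bm)) stop("benchmark gene '", benchmark, "' missing")
    tauBg <- setNames(abs(bm$neg_score), bm$background)
    gs$tau <- tauBg[gs$background]
  } else gs$tau <- tau
  pos <- gs$pos_score >= gs$tau
  neg <- gs$neg_score <= -gs$tau
  gs$class_call <- ifelse(pos & neg, "both",
                          ifelse(pos, "positive",
                                 ifelse(neg, "negative", "unaltered")))
  fractions <- do.call(rbind, lapply(split(gs, gs$background), function(d) {
    tab <- table(factor(d$class_call,
                        c("positive", "negative", "both", "unaltered")))
    data.frame(background = d$background[1], class = names(tab),
               fraction = as.numeric(tab) / nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(fractions) <- NULL
  list(scores = gs, fractions = fractions)
}

#' Percentile ranks and top-fraction flags per direction
#'
#' Ranks genes within each background and flags the `ceiling(top * n)` most
#' extreme in each direction (by `pos_score` descending for the positive
#' direction, `neg_score` ascending for the negative). Rankings are computed
#' over target-class genes by default, with controls excluded, mirroring a
#' waterfall plot in which control genes are shown only for reference.
#'
#' @param geneScores data.frame from [collapseGenes()].
#' @param top flagged fraction per direction (default 0.01, the top 1%).
#' @param classes gene classes entering the ranking.
#' @return data.frame sorted per background by decreasing `pos_score`
#'   (waterfall order) with columns `pos_percentile`, `neg_percentile`,
#'   `top_pos`, `top_neg`.
#' @export
rankPercentiles <- function(geneScores, top = 0.01, classes = "target") {
  gs <- geneScores[geneScores$class %in% classes, , drop = FALSE]
  out <- do.call(rbind, lapply(split(gs, gs$background), function(d) {
    n <- nrow(d)
    kTop <- ceiling(top * n)
    posOrd <- order(d$pos_score, d$gene, decreasing = c(TRUE, FALSE),
                    method = "radix")
    negOrd <- order(d$neg_score, d$gene, method = "radix")
    d$pos_percentile <- 100 * rank(d$pos_score, ties.method = "average") / n
    d$neg_percentile <- 100 * rank(-d$neg_score, ties.method = "average") / n
    d$top_pos <- seq_len(n) %in% posOrd[seq_len(kTop)]
    d$top_neg <- seq_len(n) %in% negOrd[seq_len(kTop)]
    d[posOrd, ]
  }))
  rownames(out) <- NULL
  out
}

.gini <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n == 0 || sum(x) == 0) return(NA_real_)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

#' Library-representation QC of a screen
#'
#' Per-sample total reads, number of undetected guides, and the Gini
#' coefficient of guide counts (evenness of representation; useful on the
#' T0 samples, which do not enter the depletion metric).
#'
#' @param se a [ScreenExperiment-class].
#' @return data.frame, one row per sample.
#' @export
screenQC <- function(se) {
  stopifnot(is(se, "ScreenExperiment"))
  cts <- assay(se, "counts")
  data.frame(sample_id = colnames(cts),
             as.data.frame(colData(se)),
             total_reads = colSums(cts),
             zero_guides = colSums(cts == 0),
             gini = apply(cts, 2, .gini),
             row.names = NULL, stringsAsFactors = FALSE)
}
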