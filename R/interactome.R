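# Interactome calling: enrichment over the ligase-only control, positive
# control-calibrated stringency, set algebra and z-score clustering.

.pseudoIntensity <- function(intensity) {
  nz <- intensity[intensity > 0]
  if (!length(nz)) stop("matrix has no nonzero intensities")
  min(nz) / 2
}

# Pooled-variance two-sample t on log2 intensities, with the degenerate
# zero-variance contract: p = 1 when both groups are constant and equal,
# p = 0 when constant and unequal.
.log2T <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx + vy == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  t.test(x, y, var.equal = TRUE)$p.value
}

#' Per-protein enrichment of a bait over the ligase-only control
#'
#' Fold change is the ratio of bait to control replicate means of the
#' normalized intensities; significance comes from a two-sample
#' pooled-variance Student t-test on log2 intensities. Zero intensities are
#' replaced, at ratio/log time only, by a pseudo-intensity (default: half
#' the smallest nonzero value in the matrix).
#'
#' @param pq a normalized [ProteinQuant-class].
#' @param bait bait label to test (a value of `colData()$bait`).
#' @param control label of the ligase-only control samples.
#' @param pseudo pseudo-intensity for zeros; `NULL` for the default.
#' @return data.frame with one row per protein: `protein_id`, `bait`,
#'   `fold_change`, `p_value`, `n_peptides`, `all_zero` (fold computed on
#'   pseudo-intensities only). The applied pseudo-intensity is attached as
#'   attribute `"pseudo"`.
#' @export
computeEnrichment <- function(pq, bait, control = "control", pseudo = NULL) {
  stopifnot(is(pq, "ProteinQuant"))
  ann <- colData(pq)
  bcols <- which(!is.na(ann$bait) & ann$bait == bait & !ann$qc_pool)
  ccols <- which(!is.na(ann$bait) & ann$bait == control & !ann$qc_pool)
  if (!length(bcols)) stop("bait '", bait, "' absent from the annotation")
  if (length(bcols) < 2 || length(ccols) < 2)
    stop("need >= 2 replicates for bait and control")
  m <- assay(pq, "intensity")
  if (is.null(pseudo)) pseudo <- .pseudoIntensity(m)
  allZero <- rowSums(m[, c(bcols, ccols), drop = FALSE]) == 0
  m[m == 0] <- pseudo
  bm <- rowMeans(m[, bcols, drop = FALSE])
  cm <- rowMeans(m[, ccols, drop = FALSE])
  lb <- log2(m[, bcols, drop = FALSE])
  lc <- log2(m[, ccols, drop = FALSE])
  p <- vapply(seq_len(nrow(m)), function(i) .log2T(lb[i, ], lc[i, ]),
              numeric(1))
  out <- data.frame(protein_id = rownames(m), bait = bait,
                    fold_change = bm / cm, p_value = p,
                    n_peptides = rowData(pq)$n_peptides,
                    all_zero = allZero, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "pseudo") <- pseudo
  out
}

#' Calibrate the fold-change stringency on positive controls
#'
#' The threshold is the minimum fold change observed among the supplied
#' positive-control proteins across all baits present in `records` (the
#' least recovered control sets the stringency), floored at `floor`:
#' `applied = max(derived, floor)`. Every positive control must itself be
#' significant at `alpha`, otherwise calibration fails naming the protein.
#'
#' @param records enrichment records (possibly several baits,
#'   row-bound) as returned by [computeEnrichment()].
#' @param controls positive-control protein ids (default the three RAF
#'   paralogs).
#' @param alpha significance level the controls must reach.
#' @param floor minimum admissible threshold.
#' @return list with `derived`, `applied`, `floor`, `alpha`, and the
#'   control records used (`controls`).
#' @export
calibrateThreshold <- function(records, controls = c("ARAF", "BRAF", "RAF1"),
                               alpha = 0.05, floor = 2.0) {
  hit <- records[records$protein_id %in% controls, , drop = FALSE]
  missing <- setdiff(controls, hit$protein_id)
  if (length(missing))
    stop("positive controls absent from the records: ",
         paste(missing, collapse = ", "))
  bad <- unique(hit$protein_id[hit$p_value >= alpha])
  if (length(bad))
    stop("positive control(s) not significant at alpha = ", alpha, ": ",
         paste(bad, collapse = ", "))
  derived <- min(hit$fold_change)
  list(derived = derived, applied = max(derived, floor), floor = floor,
       alpha = alpha, controls = hit)
}

#' Disjoint region counts of a list of sets
#'
#' @param sets named list of character vectors.
#' @return named integer vector over the non-empty membership patterns
#'   (names like `"KRAS"`, `"KRAS&NRAS"`), summing to the union size.
#' @export
vennPartition <- function(sets) {
  ids <- unique(unlist(sets))
  if (!length(ids)) return(setNames(integer(), character()))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1,
                                         dimnames = list(NULL, names(sets)))
  pat <- apply(member, 1, function(r)
    paste(names(sets)[r], collapse = "&"))
  counts <- table(pat)
  setNames(as.integer(counts), names(counts))
}

#' Call interactome membership and its Venn partition
#'
#' A protein enters a bait's interactome when `fold_change >= threshold`,
#' `p_value < alpha`, and it was quantified by at least `minPeptides`
#' distinct peptides. A single threshold is shared across baits.
#'
#' @param records row-bound enrichment records for all baits.
#' @param threshold applied fold-change threshold (see
#'   [calibrateThreshold()]).
#' @param alpha significance level.
#' @param minPeptides minimum distinct peptides (default 2).
#' @return list with `records` (input plus a logical `passes` column),
#'   `sets` (bait -> passing protein ids), `venn` (disjoint region counts),
#'   and `union` (all passing ids).
#' @export
callInteractome <- function(records, threshold, alpha = 0.05,
                            minPeptides = 2) {
  records$passes <- records$fold_change >= threshold &
    records$p_value < alpha & records$n_peptides >= minPeptides
  baits <- unique(records$bait)
  sets <- lapply(setNames(baits, baits), function(b)
    records$protein_id[records$bait == b & records$passes])
  venn <- vennPartition(sets)
  list(records = records, sets = sets, venn = venn,
       union = sort(unique(unlist(sets))),
       threshold = threshold, alpha = alpha, min_peptides = minPeptides)
}

#' Row z-scores and hierarchical clustering of samples and proteins
#'
#' Per protein, z = (log2 intensity - row mean) / row sd across the selected
#' samples; rows with zero variance are set to 0 and flagged. Samples and
#' proteins are clustered agglomeratively with correlation distance
#' (1 - Pearson) and average linkage.
#'
#' @param pq a [ProteinQuant-class].
#' @param proteins protein ids to include (e.g. the interactome union);
#'   `NULL` for all.
#' @param samples sample ids to include; `NULL` for all non-QC samples.
#' @param pseudo pseudo-intensity for zeros; `NULL` for the default.
#' @return list with the `z` matrix, `proteinOrder` / `sampleOrder`
#'   (dendrogram leaf orders), the two `hclust` objects, and `zeroVar`
#'   (flagged constant rows).
#' @export
zscoreCluster <- function(pq, proteins = NULL, samples = NULL,
                          pseudo = NULL) {
  stopifnot(is(pq, "ProteinQuant"))
  m <- assay(pq, "intensity")
  if (is.null(samples)) samples <- colnames(pq)[!colData(pq)$qc_pool]
  if (is.null(proteins)) proteins <- rownames(pq)
  m <- m[proteins, samples, drop = FALSE]
  if (ncol(m) < 2) stop("need >= 2 samples")
  if (is.null(pseudo)) pseudo <- .pseudoIntensity(m)
  lm <- log2(pmax(m, pseudo))
  mu <- rowMeans(lm)
  sdv <- apply(lm, 1, sd)
  zeroVar <- sdv == 0
  z <- (lm - mu) / ifelse(zeroVar, 1, sdv)
  z[zeroVar, ] <- 0

  corDist <- function(x) {
    d <- 1 - cor(x)
    d[is.na(d)] <- 1
    as.dist(d)
  }
  keep <- !zeroVar
  sampleH <- hclust(corDist(z[keep, , drop = FALSE]), method = "average")
  proteinH <- if (sum(keep) >= 2) {
    h <- hclust(corDist(t(z[keep, , drop = FALSE])), method = "average")
    h
  } else NULL
  proteinOrder <- if (is.null(proteinH)) rownames(z)
    else c(rownames(z)[keep][proteinH$order], rownames(z)[zeroVar])
  list(z = z, sampleOrder = colnames(z)[sampleH$order],
       proteinOrder = proteinOrder, sampleHclust = sampleH,
       proteinHclust = proteinH, zeroVar = zeroVar)
}
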