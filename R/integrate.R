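# Integration of the labeling and dropout assays: dual-assay records,
# reference-benchmarked hits, knockout-dependent differential labeling,
# over-representation, and viability arithmetic.

#' Join interactome and screen scores into dual-assay records
#'
#' One record per entity mappable between the protein (labeling) and gene
#' (screen) id spaces: the per-bait labeling fold change and pass flag, and
#' the per-background collapsed screen scores. Entities present in only one
#' assay are excluded from the records and listed in a sidecar.
#'
#' @param records interactome enrichment records with a `passes` column
#'   (see [callInteractome()]).
#' @param geneScores collapsed gene scores from [collapseGenes()].
#' @param idMap data.frame `protein_id`, `gene`, a one-to-one mapping;
#'   `NULL` for identity mapping of shared identifiers.
#' @return list with `records` (wide data.frame: `entity_id`, `protein_id`,
#'   `labeling_<bait>`, `passes_<bait>`, `neg_<background>`,
#'   `pos_<background>`) and `sidecar` (unmapped protein and gene ids).
#' @export
joinAssays <- function(records, geneScores, idMap = NULL) {
  prot <- unique(records$protein_id)
  genes <- unique(geneScores$gene)
  if (is.null(idMap))
    idMap <- data.frame(protein_id = intersect(prot, genes),
                        gene = intersect(prot, genes),
                        stringsAsFactors = FALSE)
  dupP <- unique(idMap$protein_id[duplicated(idMap$protein_id)])
  dupG <- unique(idMap$gene[duplicated(idMap$gene)])
  if (length(dupP) || length(dupG))
    stop("ambiguous id mapping for: ",
         paste(unique(c(dupP, dupG)), collapse = ", "))

  map <- idMap[idMap$protein_id %in% prot & idMap$gene %in% genes, ,
               drop = FALSE]
  out <- data.frame(entity_id = map$gene, protein_id = map$protein_id,
                    stringsAsFactors = FALSE)
  for (b in unique(records$bait)) {
    rb <- records[records$bait == b, ]
    i <- match(map$protein_id, rb$protein_id)
    out[[paste0("labeling_", b)]] <- rb$fold_change[i]
    out[[paste0("passes_", b)]] <-
      if ("passes" %in% names(rb)) rb$passes[i] else NA
  }
  for (bg in unique(geneScores$background)) {
    gb <- geneScores[geneScores$background == bg, ]
    i <- match(map$gene, gb$gene)
    out[[paste0("neg_", bg)]] <- gb$neg_score[i]
    out[[paste0("pos_", bg)]] <- gb$pos_score[i]
  }
  list(records = out,
       sidecar = list(unmapped_proteins = setdiff(prot, map$protein_id),
                      unmapped_genes = setdiff(genes, map$gene)))
}

#' Flag dual-assay hits benchmarked to a reference entity
#'
#' An entity is a dual hit in an isoform when it scores at least half as
#' well as the reference in both assays there: labeling fold change at
#' least half the reference's, and (negative) collapsed screen score at
#' most half the reference's (at least half as depleted). With
#' `requirePass = TRUE` (default) the entity must also be a member of that
#' isoform's interactome, which confines dual hits to isoforms where the
#' reference is itself an interactome hit. The reference must be present
#' with positive labeling and negative screen score in the queried isoform,
#' and always flags itself.
#'
#' @param joined dual-assay records from [joinAssays()].
#' @param reference entity id of the benchmark (e.g. the top
#'   isoform-specific vulnerability).
#' @param isoform bait/background label to evaluate.
#' @param requirePass require interactome membership in `isoform`.
#' @return the records with a logical `dual_hit_<isoform>` column appended;
#'   the reference labeling and screen benchmarks are attached as attribute
#'   `"benchmark"`.
#' @export
dualHitCall <- function(joined, reference, isoform, requirePass = TRUE) {
  lab <- joined[[paste0("labeling_", isoform)]]
  neg <- joined[[paste0("neg_", isoform)]]
  if (is.null(lab) || is.null(neg))
    stop("isoform '", isoform, "' not present in the joined records")
  i <- match(reference, joined$entity_id)
  if (is.na(i)) stop("reference '", reference, "' missing from the records")
  p <- joined[[paste0("passes_", isoform)]]
  # membership unknown (no passes column upstream) counts as pass
  pass <- if (is.null(p)) rep(TRUE, nrow(joined)) else ifelse(is.na(p), TRUE, p)
  if (requirePass && !pass[i])
    stop("reference '", reference, "' is not in the ", isoform,
         " interactome")
  if (is.na(lab[i]) || lab[i] <= 0)
    stop("reference '", reference, "' has non-positive labeling in ",
         isoform)
  if (is.na(neg[i]) || neg[i] >= 0)
    stop("reference '", reference, "' has non-negative screen score in ",
         isoform)
  flag <- !is.na(lab) & !is.na(neg) &
    lab >= 0.5 * lab[i] & neg <= 0.5 * neg[i]
  if (requirePass) flag <- flag & pass
  out <- joined
  out[[paste0("dual_hit_", isoform)]] <- flag
  attr(out, "benchmark") <- c(labeling = lab[i], neg_score = neg[i])
  out
}

#' Differential labeling between knockout and vector conditions
#'
#' Per protein, the log2 fold-difference is the mean log2 intensity in the
#' knockout experiment minus that in the vector experiment, averaged with
#' equal weight over knockout lines (the `condition` column of the knockout
#' object). Proteins move direction `enriched` / `depleted` only beyond
#' `delta`; the reference protein's own reduction is reported as the
#' benchmark.
#'
#' @param pqVector,pqKnockout two identically normalized
#'   [ProteinQuant-class] objects (vector control and knockout lines).
#' @param reference protein id whose own fold-difference benchmarks the
#'   comparison.
#' @param delta direction threshold on the log2 fold-difference
#'   (default 0.1).
#' @param pseudo pseudo-intensity for zeros; `NULL` derives it from the
#'   pooled matrices.
#' @return list with `records` (data.frame `protein_id`, per-line
#'   fold-differences, `fold_difference`, `direction`), `benchmark` (the
#'   reference's fold-difference), and `summary` (direction counts).
#' @export
differentialLabeling <- function(pqVector, pqKnockout, reference,
                                 delta = 0.1, pseudo = NULL) {
  stopifnot(is(pqVector, "ProteinQuant"), is(pqKnockout, "ProteinQuant"))
  shared <- intersect(rownames(pqVector), rownames(pqKnockout))
  if (!reference %in% shared)
    stop("reference '", reference, "' absent from the shared proteins")
  mv <- assay(pqVector, "intensity")[shared, !colData(pqVector)$qc_pool,
                                     drop = FALSE]
  mk <- assay(pqKnockout, "intensity")[shared, !colData(pqKnockout)$qc_pool,
                                       drop = FALSE]
  if (is.null(pseudo)) pseudo <- .pseudoIntensity(cbind(mv, mk))
  lv <- log2(pmax(mv, pseudo))
  lk <- log2(pmax(mk, pseudo))
  vecMean <- rowMeans(lv)
  lines <- colData(pqKnockout)$condition[!colData(pqKnockout)$qc_pool]
  lineIds <- unique(lines)
  perLine <- vapply(lineIds, function(l)
    rowMeans(lk[, lines == l, drop = FALSE]) - vecMean,
    numeric(length(shared)))
  fd <- rowMeans(perLine)
  direction <- ifelse(fd >= delta, "enriched",
                      ifelse(fd <= -delta, "depleted", "unchanged"))
  records <- data.frame(protein_id = shared, perLine,
                        fold_difference = fd, direction = direction,
                        row.names = NULL, check.names = FALSE,
                        stringsAsFactors = FALSE)
  names(records)[seq_along(lineIds) + 1] <- paste0("line_", lineIds)
  list(records = records,
       benchmark = fd[match(reference, shared)],
       summary = table(factor(direction,
                              c("enriched", "depleted", "unchanged"))),
       delta = delta)
}

#' Gene-set over-representation of a hit list
#'
#' One-sided Fisher exact (hypergeometric tail) test of each annotation set
#' against the hit list within the background universe; fold enrichment is
#' `(overlap/hits) / (set/background)`.
#'
#' @param hits character vector of hit ids (must lie in `background`).
#' @param sets named list of annotation sets (intersected with the
#'   background).
#' @param background character vector, the test universe.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return data.frame, one row per set: `set_id`, `overlap`, `set_size`,
#'   `n_hits`, `n_background`, `fold_enrichment`, `p_value`.
#' @export
overrepresentation <- function(hits, sets, background,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  background <- unique(background)
  if (!length(background)) stop("background is empty")
  bad <- setdiff(hits, background)
  if (length(bad))
    stop("hit ids outside the background: ",
         paste(head(bad, 5), collapse = ", "))
  hits <- unique(hits)
  N <- length(background); q <- length(hits)
  out <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), background)
    m <- length(s)
    k <- length(intersect(s, hits))
    p <- if (alternative == "greater") {
      phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    } else {
      stats::fisher.test(matrix(c(k, m - k, q - k, N - m - q + k), 2),
                         alternative = "two.sided")$p.value
    }
    data.frame(set_id = nm, overlap = k, set_size = m, n_hits = q,
               n_background = N,
               fold_enrichment = if (q > 0 && m > 0) (k / q) / (m / N)
                                 else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Percent cell viability from plate absorbances
#'
#' `100 * (treated - blank) / (negative_control - blank)`; values may
#' exceed 100 or be negative and are reported as-is.
#'
#' @param treated absorbance of the treated wells (vectorized).
#' @param blank absorbance of the blank control wells.
#' @param negativeControl absorbance of the negative (untreated) control
#'   wells; must exceed `blank`.
#' @return percentage viability.
#' @examples
#' percentViability(0.6, blank = 0.1, negativeControl = 1.1)  # 50
#' @export
percentViability <- function(treated, blank, negativeControl) {
  if (any(negativeControl <= blank))
    stop("negative control absorbance must exceed the blank")
  100 * (treated - blank) / (negativeControl - blank)
}
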