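# Peptide-to-protein quantification and normalization.

#' Aggregate a peptide quantification table to the protein level
#'
#' Each protein's per-sample value is the sum of its peptides' intensities
#' (the standard label-free choice, which preserves peptide-count
#' weighting); `n_peptides` records the number of distinct peptides observed
#' per protein. Missing peptide values are treated as 0 (absence is
#' informative under streptavidin capture), not missing-at-random.
#'
#' @param peptides data.frame with columns `protein_id`, `peptide_id` and
#'   one non-negative intensity column per sample.
#' @param samples sample-annotation data.frame with a `sample_id` column
#'   (one row per intensity column) and a `bait` column.
#' @return a [ProteinQuant-class] with normalization tag `"none"`.
#' @examples
#' pep <- data.frame(protein_id = c("A", "A", "B"),
#'                   peptide_id = c("A_1", "A_2", "B_1"),
#'                   s1 = c(2, 3, 1), s2 = c(1, 1, 4))
#' ann <- data.frame(sample_id = c("s1", "s2"), bait = c("control", "KRAS"))
#' assay(aggregatePeptides(pep, ann))
#' @export
aggregatePeptides <- function(peptides, samples) {
  if (!nrow(peptides)) stop("peptide table is empty")
  if (!all(c("protein_id", "peptide_id") %in% names(peptides)))
    stop("peptide table needs protein_id and peptide_id columns")
  if (anyDuplicated(peptides[, c("protein_id", "peptide_id")]))
    stop("duplicate (protein, peptide) entries in the quantification table")
  samples <- as.data.frame(samples)
  cols <- setdiff(names(peptides), c("protein_id", "peptide_id"))
  if (!setequal(cols, samples$sample_id))
    stop("sample annotation does not match the quant columns")
  m <- as.matrix(peptides[, samples$sample_id, drop = FALSE])
  m[is.na(m)] <- 0
  if (any(m < 0)) stop("peptide intensities must be >= 0")
  agg <- rowsum(m, group = peptides$protein_id, reorder = TRUE)
  np <- as.integer(table(peptides$protein_id)[rownames(agg)])
  ProteinQuant(agg, samples, np, normalization = "none")
}

.sizeFactors <- function(intensity, method, referenceIds = NULL,
                         trim = 0.2) {
  switch(method,
    none = rep(1, ncol(intensity)),
    robust_mean = apply(intensity, 2, function(x) {
      x <- x[x > 0]
      if (!length(x)) stop("a sample has no nonzero intensities")
      exp(mean(log(x), trim = trim))
    }),
    carboxylase = ,
    bira = {
      if (is.null(referenceIds) || !length(referenceIds))
        stop("reference protein ids are required for '", method,
             "' normalization")
      missing <- setdiff(referenceIds, rownames(intensity))
      if (length(missing))
        stop("reference proteins absent from the matrix: ",
             paste(missing, collapse = ", "))
      ref <- intensity[referenceIds, , drop = FALSE]
      sf <- colMeans(ref)
      dead <- colnames(intensity)[sf <= 0]
      if (length(dead))
        stop("reference proteins unobserved in sample(s): ",
             paste(dead, collapse = ", "))
      sf
    },
    stop("unknown normalization method: ", method)
  )
}

#' Normalize a protein quantification matrix
#'
#' Divides each sample column by a scheme-specific size factor, then
#' rescales so the geometric mean of the size factors is 1 (the overall
#' intensity scale is preserved):
#' \describe{
#'   \item{`robust_mean`}{20%-trimmed mean of log nonzero intensities,
#'     re-exponentiated (scaling to the robust mean across samples).}
#'   \item{`carboxylase`}{mean intensity of the endogenously biotinylated
#'     carboxylase reference set per sample (controls for streptavidin
#'     pull-down variability).}
#'   \item{`bira`}{mean intensity of the BirA ligase per sample (controls
#'     for ligase expression / labeling).}
#'   \item{`none`}{identity.}
#' }
#' After `carboxylase`/`bira` normalization the reference-set mean is equal
#' in every sample.
#'
#' @param pq a [ProteinQuant-class].
#' @param method one of `"robust_mean"`, `"carboxylase"`, `"bira"`,
#'   `"none"`.
#' @param referenceIds protein ids of the reference set (required for
#'   `carboxylase` and `bira`).
#' @param trim trim fraction for the robust mean.
#' @return a [ProteinQuant-class] with the normalization tag updated and the
#'   applied size factors in `metadata()$size_factors`.
#' @export
normalizeQuant <- function(pq, method = c("robust_mean", "carboxylase",
                                          "bira", "none"),
                           referenceIds = NULL, trim = 0.2) {
  stopifnot(is(pq, "ProteinQuant"))
  method <- match.arg(method)
  intensity <- assay(pq, "intensity")
  sf <- .sizeFactors(intensity, method, referenceIds, trim)
  sf <- sf / exp(mean(log(sf)))
  out <- pq
  assay(out, "intensity") <- sweep(intensity, 2, sf, "/")
  metadata(out)$normalization <- method
  metadata(out)$size_factors <- setNames(sf, colnames(intensity))
  if (!is.null(referenceIds)) metadata(out)$reference_ids <- referenceIds
  validObject(out)
  out
}

#' Technical %CV across QC-pool injections
#'
#' The QC pool (an equal mixture of all samples injected repeatedly) gauges
#' technical noise: per protein, %CV = 100 * sd/mean across QC columns.
#' Summaries are reported for all proteins and for the higher-confidence
#' subset quantified by two or more peptides.
#'
#' @param pq a [ProteinQuant-class] whose `colData()$qc_pool` flags at least
#'   two QC injections.
#' @return list with `per_protein` (data.frame `protein_id`, `n_peptides`,
#'   `cv_pct`), `mean_cv_all` and `mean_cv_multi_peptide` (mean %CV over
#'   all proteins and over the >= 2-peptide subset).
#' @export
qcCV <- function(pq) {
  stopifnot(is(pq, "ProteinQuant"))
  qc <- colData(pq)$qc_pool
  if (sum(qc) < 2) stop("need at least two QC-pool samples")
  m <- assay(pq, "intensity")[, qc, drop = FALSE]
  mu <- rowMeans(m)
  cv <- ifelse(mu > 0, 100 * apply(m, 1, sd) / mu, NA_real_)
  np <- rowData(pq)$n_peptides
  list(
    per_protein = data.frame(protein_id = rownames(pq), n_peptides = np,
                             cv_pct = cv, row.names = NULL),
    mean_cv_all = mean(cv, na.rm = TRUE),
    mean_cv_multi_peptide = mean(cv[np >= 2], na.rm = TRUE)
  )
}
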