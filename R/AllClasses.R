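#' Configuration for the BioID proximity-labeling simulator
#'
#' Describes the experimental design emulated by [simulateBioid()]: a
#' ligase-only (BirA*) control plus one bait per RAS isoform, each profiled
#' in replicate, with log-normal peptide intensities, spiked bait-specific
#' interactors, and endogenous carboxylase / BirA / RAF reference proteins.
#'
#' @slot nProteins number of simulated background proteins.
#' @slot nTruePerBait named integer vector, true interactors per bait.
#' @slot sharedFraction fraction of each bait's interactors shared by all
#'   baits (the remainder are bait-specific). The default 0.9 makes roughly
#'   three quarters of the union of called interactomes multi-bait, matching
#'   the overlap structure typical of RAS-isoform labeling.
#' @slot trueFold multiplicative labeling enrichment of a true interactor in
#'   its bait's samples.
#' @slot replicateCV coefficient of variation of the log-normal replicate
#'   noise (fraction, e.g. 0.10 for 10%).
#' @slot peptideCountProbs probabilities of a protein being quantified by
#'   1, 2, ... peptides (must allow 1-peptide proteins).
#' @slot minPeptidesInteractor minimum peptide count forced for spiked
#'   interactors and reference proteins (detectable-interactor contract).
#' @slot baits ordered bait labels; the first is the ligase-only control.
#' @slot replicatesPerBait replicates per bait (>= 2).
#' @slot qcPools number of QC-pool injections (equal mixture of all samples).
#' @slot referenceProteins data.frame with columns `id`, `role`
#'   (`carboxylase`, `bira`, or `raf_positive`) and `fold` (labeling fold of
#'   the reference in every non-control bait).
#' @slot baselineMeanlog,baselineSdlog log-normal parameters of baseline
#'   protein abundance.
#' @slot sampleOffsets optional named multiplicative per-sample offsets
#'   (size-factor injection for normalization tests); empty for none.
#' @slot dropoutRate probability that a non-reference protein is unobserved
#'   (intensity 0) in a given sample; 0 by default.
#' @slot seed integer seed keying all random streams.
#' @export
setClass("BioidSimConfig", representation(
  nProteins = "numeric",
  nTruePerBait = "numeric",
  sharedFraction = "numeric",
  trueFold = "numeric",
  replicateCV = "numeric",
  peptideCountProbs = "numeric",
  minPeptidesInteractor = "numeric",
  baits = "character",
  replicatesPerBait = "numeric",
  qcPools = "numeric",
  referenceProteins = "data.frame",
  baselineMeanlog = "numeric",
  baselineSdlog = "numeric",
  sampleOffsets = "numeric",
  dropoutRate = "numeric",
  seed = "numeric"
))

setValidity("BioidSimConfig", function(object) {
  msg <- character()
  if (object@nProteins < 1) msg <- c(msg, "nProteins must be >= 1")
  if (object@trueFold <= 0) msg <- c(msg, "trueFold must be > 0")
  if (object@replicateCV < 0) msg <- c(msg, "replicateCV must be >= 0")
  if (object@replicatesPerBait < 2)
    msg <- c(msg, "replicatesPerBait must be >= 2")
  if (length(object@baits) < 2)
    msg <- c(msg, "need a control bait plus at least one labeling bait")
  if (anyDuplicated(object@baits)) msg <- c(msg, "baits must be unique")
  if (abs(sum(object@peptideCountProbs) - 1) > 1e-8 ||
      any(object@peptideCountProbs < 0))
    msg <- c(msg, "peptideCountProbs must be non-negative and sum to 1")
  if (object@sharedFraction < 0 || object@sharedFraction > 1)
    msg <- c(msg, "sharedFraction must lie in [0, 1]")
  rp <- object@referenceProteins
  if (nrow(rp)) {
    if (!all(c("id", "role", "fold") %in% names(rp)))
      msg <- c(msg, "referenceProteins needs columns id, role, fold")
    else {
      if (anyDuplicated(rp$id)) msg <- c(msg, "reference ids must be unique")
      if (any(rp$fold <= 0)) msg <- c(msg, "reference folds must be > 0")
      if (!all(rp$role %in% c("carboxylase", "bira", "raf_positive")))
        msg <- c(msg, "reference roles must be carboxylase/bira/raf_positive")
    }
  }
  bad <- names(object@nTruePerBait)[!names(object@nTruePerBait) %in%
                                      object@baits[-1]]
  if (length(bad))
    msg <- c(msg, paste("nTruePerBait names not among baits:",
                        paste(bad, collapse = ", ")))
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Build a BioID simulator configuration
#'
#' Defaults emulate the profiled study design: triplicate transfections of a
#' BirA*-only control and BirA*-KRAS/NRAS/HRAS baits, replicate CV of 10%
#' (the QC-pool range of the emulated data is roughly 8--14%), a 4-fold
#' labeling effect for spiked interactors, an interactor overlap structure in
#' which most of the called union is shared between isoforms, endogenously biotinylated carboxylases and the BirA ligase
#' as normalization references, and ARAF/BRAF/RAF1-like positive controls at
#' folds 4.5/3.5/2.5 used for stringency calibration.
#'
#' @param nProteins,nTruePerBait,sharedFraction,trueFold,replicateCV,peptideCountProbs,minPeptidesInteractor,baits,replicatesPerBait,qcPools,referenceProteins,baselineMeanlog,baselineSdlog,sampleOffsets,dropoutRate,seed
#'   see the slot documentation of [BioidSimConfig-class].
#' @return a validated [BioidSimConfig-class] object.
#' @examples
#' cfg <- bioidSimConfig(nProteins = 50, seed = 1)
#' sim <- simulateBioid(cfg)
#' head(sim$truth)
#' @export
bioidSimConfig <- function(nProteins = 2000,
                           nTruePerBait = c(KRAS = 100, NRAS = 100,
                                            HRAS = 100),
                           sharedFraction = 0.9,
                           trueFold = 4,
                           replicateCV = 0.10,
                           peptideCountProbs = c(0.25, 0.30, 0.20, 0.15,
                                                 0.10),
                           minPeptidesInteractor = 2,
                           baits = c("control", "KRAS", "NRAS", "HRAS"),
                           replicatesPerBait = 3,
                           qcPools = 4,
                           referenceProteins = defaultReferenceProteins(),
                           baselineMeanlog = log(1e6),
                           baselineSdlog = 1.5,
                           sampleOffsets = numeric(),
                           dropoutRate = 0,
                           seed = 1) {
  nTruePerBait <- nTruePerBait[nTruePerBait > 0]
  new("BioidSimConfig", nProteins = nProteins, nTruePerBait = nTruePerBait,
      sharedFraction = sharedFraction, trueFold = trueFold,
      replicateCV = replicateCV, peptideCountProbs = peptideCountProbs,
      minPeptidesInteractor = minPeptidesInteractor, baits = baits,
      replicatesPerBait = replicatesPerBait, qcPools = qcPools,
      referenceProteins = referenceProteins,
      baselineMeanlog = baselineMeanlog, baselineSdlog = baselineSdlog,
      sampleOffsets = sampleOffsets, dropoutRate = dropoutRate, seed = seed)
}

#' Default reference-protein table for the BioID simulator
#'
#' Three endogenously biotinylated carboxylases (streptavidin-capture
#' references, fold 1 in every bait), the BirA ligase itself (fold 1), and
#' the three RAF positive controls. RAF1 carries the smallest fold (2.5) and
#' therefore sets the calibrated stringency, mirroring its role as the least
#' recovered RAF isoform.
#'
#' @return data.frame with columns `id`, `role`, `fold`.
#' @export
defaultReferenceProteins <- function() {
  data.frame(
    id = c("PC", "PCCA", "MCCC1", "BirA", "ARAF", "BRAF", "RAF1"),
    role = c("carboxylase", "carboxylase", "carboxylase", "bira",
             "raf_positive", "raf_positive", "raf_positive"),
    fold = c(1, 1, 1, 1, 4.5, 3.5, 2.5),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the pooled CRISPR dropout-screen simulator
#'
#' Describes the screen emulated by [simulateScreen()]: a guide library with
#' a configurable number of guides per target gene plus essential ribosomal
#' and non-targeting controls, infected into four genetic backgrounds and
#' sequenced at three timepoints in replicate. Counts follow a gamma-Poisson
#' (negative binomial) model around expected guide frequencies that evolve as
#' `freq_T0 * 2^(fitness * efficacy * generations)`.
#'
#' @slot nGenes number of target genes (ignored when `genes` is supplied).
#' @slot genes optional explicit target-gene identifiers.
#' @slot guidesPerGene guides per target/ribosomal gene.
#' @slot nRibosomal number of essential ribosomal control genes.
#' @slot nNontargeting number of non-targeting control guides.
#' @slot ntGroupSize non-targeting guides grouped into pseudo-genes of this
#'   size so they flow through gene-level collapse.
#' @slot backgrounds genetic backgrounds; the first is the untransformed
#'   vector reference.
#' @slot timepoints ordered sequencing timepoints.
#' @slot replicates infection replicates per background.
#' @slot depth expected reads per sample.
#' @slot depthJitterCV log-normal CV of per-sample depth.
#' @slot dispersion negative-binomial dispersion (gamma-Poisson).
#' @slot fitness data.frame (`gene`, `background`, `fitness`) of
#'   per-generation fitness effects for specific genes; genes not listed
#'   default to 0 (targets, non-targeting) or `essentialFitness`
#'   (ribosomal controls).
#' @slot essentialFitness per-generation fitness of ribosomal controls in
#'   every background (must be < 0).
#' @slot generations named list (one element per background) of cumulative
#'   population doublings reached at each timepoint.
#' @slot efficacyShape1,efficacyShape2 Beta parameters of per-guide cutting
#'   efficacy.
#' @slot baselineSdlog log-normal spread of library representation at T0.
#' @slot seed integer seed keying all random streams.
#' @export
setClass("ScreenSimConfig", representation(
  nGenes = "numeric",
  genes = "character",
  guidesPerGene = "numeric",
  nRibosomal = "numeric",
  nNontargeting = "numeric",
  ntGroupSize = "numeric",
  backgrounds = "character",
  timepoints = "character",
  replicates = "numeric",
  depth = "numeric",
  depthJitterCV = "numeric",
  dispersion = "numeric",
  fitness = "data.frame",
  essentialFitness = "numeric",
  generations = "list",
  efficacyShape1 = "numeric",
  efficacyShape2 = "numeric",
  baselineSdlog = "numeric",
  seed = "numeric"
))

setValidity("ScreenSimConfig", function(object) {
  msg <- character()
  if (object@depth <= 0) msg <- c(msg, "depth must be > 0")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (object@replicates < 1) msg <- c(msg, "replicates must be >= 1")
  if (object@essentialFitness >= 0)
    msg <- c(msg, "essentialFitness must be < 0 in every background")
  if (length(object@backgrounds) < 2)
    msg <- c(msg, "need the vector reference plus at least one background")
  if (!all(object@backgrounds %in% names(object@generations)))
    msg <- c(msg, "generations must name every background")
  else {
    ok <- vapply(object@backgrounds, function(b) {
      g <- object@generations[[b]]
      all(object@timepoints %in% names(g)) &&
        !is.unsorted(g[object@timepoints])
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "generations must be cumulative over the timepoints")
  }
  ft <- object@fitness
  if (nrow(ft) && !all(c("gene", "background", "fitness") %in% names(ft)))
    msg <- c(msg, "fitness needs columns gene, background, fitness")
  if (object@efficacyShape1 <= 0 || object@efficacyShape2 <= 0)
    msg <- c(msg, "efficacy Beta shapes must be > 0")
  if (length(msg)) msg else TRUE
})

#' Build a dropout-screen simulator configuration
#'
#' Defaults emulate the profiled screen design: 500 target genes with 5
#' guides each, 50 essential ribosomal control genes, non-targeting guides,
#' four backgrounds (vector reference plus KRAS/NRAS/HRAS-transformed) over
#' three timepoints in triplicate, sequencing depth of one million reads,
#' and NB dispersion 0.05. Transformed backgrounds accumulate more
#' population doublings than the vector reference in low serum (cumulative
#' generations 0/3/9 vs 0/2/6), which is what renders essential-gene dropout
#' visible relative to vector.
#'
#' @param nGenes,genes,guidesPerGene,nRibosomal,nNontargeting,ntGroupSize,backgrounds,timepoints,replicates,depth,depthJitterCV,dispersion,fitness,essentialFitness,generations,efficacyShape1,efficacyShape2,baselineSdlog,seed
#'   see the slot documentation of [ScreenSimConfig-class].
#' @return a validated [ScreenSimConfig-class] object.
#' @examples
#' cfg <- screenSimConfig(nGenes = 20, nRibosomal = 5, nNontargeting = 10,
#'                        seed = 1)
#' sim <- simulateScreen(cfg)
#' sim$experiment
#' @export
screenSimConfig <- function(nGenes = 500,
                            genes = character(),
                            guidesPerGene = 5,
                            nRibosomal = 50,
                            nNontargeting = 500,
                            ntGroupSize = 5,
                            backgrounds = c("vector", "KRAS", "NRAS",
                                            "HRAS"),
                            timepoints = c("T0", "T1", "T2"),
                            replicates = 3,
                            depth = 1e6,
                            depthJitterCV = 0.1,
                            dispersion = 0.05,
                            fitness = data.frame(gene = character(),
                                                 background = character(),
                                                 fitness = numeric()),
                            essentialFitness = -1,
                            generations = NULL,
                            efficacyShape1 = 5,
                            efficacyShape2 = 2,
                            baselineSdlog = 0.3,
                            seed = 1) {
  if (is.null(generations)) {
    generations <- lapply(backgrounds, function(b) {
      g <- if (b == backgrounds[1]) c(0, 2, 6) else c(0, 3, 9)
      setNames(g[seq_along(timepoints)], timepoints)
    })
    names(generations) <- backgrounds
  }
  new("ScreenSimConfig", nGenes = nGenes, genes = genes,
      guidesPerGene = guidesPerGene, nRibosomal = nRibosomal,
      nNontargeting = nNontargeting, ntGroupSize = ntGroupSize,
      backgrounds = backgrounds, timepoints = timepoints,
      replicates = replicates, depth = depth,
      depthJitterCV = depthJitterCV, dispersion = dispersion,
      fitness = fitness, essentialFitness = essentialFitness,
      generations = generations, efficacyShape1 = efficacyShape1,
      efficacyShape2 = efficacyShape2, baselineSdlog = baselineSdlog,
      seed = seed)
}

#' Protein-by-sample quantification matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] holding one
#' `intensity` assay (protein x sample, arbitrary label-free units), the
#' per-protein distinct-peptide count in `rowData()$n_peptides`, the sample
#' annotation (bait, condition, replicate, QC-pool flag) in `colData()`, and
#' the applied normalization scheme in `metadata()$normalization`.
#'
#' Build one with [ProteinQuant()] or via [aggregatePeptides()].
#' @export
setClass("ProteinQuant", contains = "SummarizedExperiment")

setValidity("ProteinQuant", function(object) {
  msg <- character()
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "needs an 'intensity' assay")
  else if (any(assay(object, "intensity") < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be >= 0")
  if (!"n_peptides" %in% names(rowData(object)))
    msg <- c(msg, "rowData needs an 'n_peptides' column")
  else if (any(rowData(object)$n_peptides < 1))
    msg <- c(msg, "n_peptides must be >= 1")
  if (!"bait" %in% names(colData(object)))
    msg <- c(msg, "colData needs a 'bait' column")
  if (is.null(metadata(object)$normalization))
    msg <- c(msg, "metadata needs a 'normalization' tag")
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinQuant object
#'
#' @param intensity numeric matrix, proteins x samples, row and column names
#'   set.
#' @param sampleData data.frame of sample annotation; must contain a `bait`
#'   column and one row per intensity column (matched by `sample_id` or row
#'   names).
#' @param nPeptides integer vector of distinct peptides per protein.
#' @param normalization tag recording the applied normalization scheme.
#' @return a [ProteinQuant-class] object.
#' @export
ProteinQuant <- function(intensity, sampleData, nPeptides,
                         normalization = "none") {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity)))
    stop("intensity matrix needs protein row names")
  sampleData <- as.data.frame(sampleData)
  if ("sample_id" %in% names(sampleData))
    rownames(sampleData) <- sampleData$sample_id
  if (is.null(colnames(intensity))) colnames(intensity) <- rownames(sampleData)
  if (!setequal(colnames(intensity), rownames(sampleData)))
    stop("every quant column needs exactly one sample-annotation row")
  sampleData <- sampleData[colnames(intensity), , drop = FALSE]
  if (!"qc_pool" %in% names(sampleData)) sampleData$qc_pool <- FALSE
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = DataFrame(n_peptides = as.integer(nPeptides),
                        row.names = rownames(intensity)),
    colData = DataFrame(sampleData)
  )
  metadata(se)$normalization <- normalization
  out <- new("ProteinQuant", se)
  validObject(out)
  out
}

#' Guide-by-sample screen count container
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] with a `counts`
#' assay of non-negative integer read counts, the guide library (`gene`,
#' `class`, optional `sequence`) in `rowData()`, and the sample annotation
#' (`background`, `timepoint`, `replicate`) in `colData()`. A `freq` assay
#' of pseudocounted reads-per-million is added by [normalizeGuideCounts()].
#'
#' @export
setClass("ScreenExperiment", contains = "SummarizedExperiment")

setValidity("ScreenExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "needs a 'counts' assay")
  else {
    cts <- assay(object, "counts")
    if (any(cts < 0) || any(cts != round(cts)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  need <- c("gene", "class")
  if (!all(need %in% names(rowData(object))))
    msg <- c(msg, "rowData needs 'gene' and 'class' columns")
  else if (!all(rowData(object)$class %in%
                  c("target", "ribosomal_control", "nontargeting")))
    msg <- c(msg, "guide class must be target/ribosomal_control/nontargeting")
  need <- c("background", "timepoint", "replicate")
  if (!all(need %in% names(colData(object))))
    msg <- c(msg, "colData needs background, timepoint, replicate")
  if (length(msg)) msg else TRUE
})

#' Construct a ScreenExperiment object
#'
#' @param counts integer matrix, guides x samples, dimnames set.
#' @param guideLibrary data.frame with columns `guide_id`, `gene`, `class`
#'   (and optionally `sequence`), one row per count row.
#' @param sampleData data.frame with columns `background`, `timepoint`,
#'   `replicate`, one row per count column (matched by `sample_id` or row
#'   names).
#' @return a [ScreenExperiment-class] object.
#' @export
ScreenExperiment <- function(counts, guideLibrary, sampleData) {
  counts <- as.matrix(counts)
  guideLibrary <- as.data.frame(guideLibrary)
  if (anyDuplicated(guideLibrary$guide_id))
    stop("guide ids must be unique")
  if (is.null(rownames(counts))) rownames(counts) <- guideLibrary$guide_id
  guideLibrary <- guideLibrary[match(rownames(counts),
                                     guideLibrary$guide_id), , drop = FALSE]
  sampleData <- as.data.frame(sampleData)
  if ("sample_id" %in% names(sampleData))
    rownames(sampleData) <- sampleData$sample_id
  sampleData <- sampleData[colnames(counts), , drop = FALSE]
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(guideLibrary[setdiff(names(guideLibrary),
                                             "guide_id")],
                        row.names = rownames(counts)),
    colData = DataFrame(sampleData)
  )
  out <- new("ScreenExperiment", se)
  validObject(out)
  out
}

#' @describeIn ProteinQuant-class number of distinct peptides per protein.
#' @param object a `ProteinQuant` or `ScreenExperiment`.
#' @export
nPeptides <- function(object) {
  setNames(rowData(object)$n_peptides, rownames(object))
}

#' @describeIn ProteinQuant-class the applied normalization tag.
#' @export
normalizationMethod <- function(object) metadata(object)$normalization

#' @describeIn ScreenExperiment-class guide library as a data.frame.
#' @export
guideLibrary <- function(object) {
  cbind(data.frame(guide_id = rownames(object)),
        as.data.frame(rowData(object)))
}

#' Sample annotation of a quantification container
#'
#' @param object a [ProteinQuant-class] or [ScreenExperiment-class].
#' @return data.frame of per-sample annotation with a `sample_id` column.
#' @export
sampleInfo <- function(object) {
  cbind(data.frame(sample_id = colnames(object)),
        as.data.frame(colData(object)))
}

#' @export
setMethod("show", "ProteinQuant", function(object) {
  callNextMethod()
  cat("normalization:", metadata(object)$normalization, "\n")
  cat("proteins with >= 2 peptides:",
      sum(rowData(object)$n_peptides >= 2), "\n")
})

#' @export
setMethod("show", "ScreenExperiment", function(object) {
  callNextMethod()
  cls <- table(rowData(object)$class)
  cat("guide classes:",
      paste(names(cls), as.integer(cls), sep = "=", collapse = ", "), "\n")
})
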