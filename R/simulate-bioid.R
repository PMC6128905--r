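# BioID proximity-labeling simulator.
#
# Model: protein p in sample s has intensity
#   baseline(p) * fold(p, bait(s)) * lognormal_noise(cv),
# split over its peptides with fixed per-peptide weights, so that
# peptide-to-protein aggregation by summation recovers the protein value
# exactly. QC-pool injections are an equal mixture of all bait samples with
# their own replicate noise. The noise factor has unit mean, so the ratio of
# replicate means is an unbiased estimate of the true fold.

.lnormSd <- function(cv) sqrt(log(1 + cv^2))

# unit-mean log-normal noise factors
.noiseFactor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- .lnormSd(cv)
  exp(rnorm(n, mean = -s^2 / 2, sd = s))
}

# Deterministic interactor layout: the shared pool occupies the first
# protein indices, followed by one bait-specific block per bait. Appending
# proteins to the configuration never reassigns existing ones.
.interactorLayout <- function(config) {
  nTrue <- config@nTruePerBait
  if (!length(nTrue)) return(list(shared = integer(), specific = list()))
  nShared <- round(config@sharedFraction * min(nTrue))
  shared <- seq_len(min(nShared, config@nProteins))
  specific <- list()
  at <- length(shared)
  for (b in names(nTrue)) {
    k <- max(nTrue[[b]] - length(shared), 0)
    specific[[b]] <- if (k > 0) at + seq_len(k) else integer()
    at <- at + k
  }
  if (at > config@nProteins)
    stop("nProteins too small for the requested interactor layout")
  list(shared = shared, specific = specific)
}

#' Simulate a BioID peptide quantification experiment
#'
#' Generates a peptide-level label-free quantification table, its sample
#' annotation (including QC-pool injections), and a ground-truth table, under
#' the design described in [BioidSimConfig-class]. All randomness is keyed
#' per protein by the configuration seed: the same configuration and seed
#' yield byte-identical tables, and adding proteins does not perturb the
#' draws of existing ones.
#'
#' @param config a [BioidSimConfig-class].
#' @param condition condition label recorded for every non-QC sample (used
#'   to distinguish, e.g., vector from knockout-line experiments).
#' @return list with elements `peptides` (data.frame: `protein_id`,
#'   `peptide_id`, one intensity column per sample), `samples` (data.frame:
#'   `sample_id`, `bait`, `condition`, `replicate`, `qc_pool`) and `truth`
#'   (data.frame: `entity_id`, `kind`, `n_peptides`, `reference_role`, one
#'   `fold_<bait>` column per labeling bait).
#' @examples
#' sim <- simulateBioid(bioidSimConfig(nProteins = 20, seed = 7))
#' sim$peptides[1:3, 1:4]
#' @export
simulateBioid <- function(config, condition = "vector") {
  stopifnot(is(config, "BioidSimConfig"))
  validObject(config)
  cv <- config@replicateCV
  baits <- config@baits
  reps <- config@replicatesPerBait
  refs <- config@referenceProteins
  labelBaits <- baits[-1]

  sampleIds <- as.vector(vapply(baits, function(b)
    paste0(b, "_r", seq_len(reps)), character(reps)))
  sampleBait <- rep(baits, each = reps)
  qcIds <- if (config@qcPools > 0) paste0("QC_p", seq_len(config@qcPools))
           else character()
  samples <- data.frame(
    sample_id = c(sampleIds, qcIds),
    bait = c(sampleBait, rep(NA_character_, length(qcIds))),
    condition = c(rep(condition, length(sampleIds)),
                  rep(NA_character_, length(qcIds))),
    replicate = c(rep(seq_len(reps), times = length(baits)),
                  seq_along(qcIds)),
    qc_pool = c(rep(FALSE, length(sampleIds)), rep(TRUE, length(qcIds))),
    stringsAsFactors = FALSE
  )

  nBg <- config@nProteins
  bgIds <- sprintf("PROT%04d", seq_len(nBg))
  ids <- c(bgIds, refs$id)
  nAll <- length(ids)
  isRef <- c(rep(FALSE, nBg), rep(TRUE, nrow(refs)))

  # fold matrix: proteins x labeling baits (control is the unit reference)
  fold <- matrix(1, nAll, length(labelBaits),
                 dimnames = list(ids, labelBaits))
  lay <- .interactorLayout(config)
  for (b in names(config@nTruePerBait)) {
    idx <- c(lay$shared, lay$specific[[b]])
    fold[idx, b] <- config@trueFold
  }
  if (nrow(refs)) {
    rafOrCtl <- refs$id
    fold[rafOrCtl, ] <- matrix(refs$fold, nrow(refs), length(labelBaits))
  }

  nS <- nrow(samples)
  nQC <- length(qcIds)
  K <- length(config@peptideCountProbs)
  forced <- isRef | rowSums(fold > 1) > 0

  intensity <- matrix(0, nAll, nS, dimnames = list(ids, samples$sample_id))
  npep <- integer(nAll)
  weights <- vector("list", nAll)
  baitIdx <- match(sampleBait, labelBaits)  # NA for control samples

  for (i in seq_len(nAll)) {
    stream <- if (isRef[i]) 3L else 1L
    index <- if (isRef[i]) i - nBg else i
    draws <- .withStream(config@seed, stream, index, {
      k <- sample.int(K, 1, prob = config@peptideCountProbs)
      base <- rlnorm(1, config@baselineMeanlog, config@baselineSdlog)
      w <- rgamma(K, shape = 2)
      noise <- .noiseFactor(length(sampleIds), cv)
      qcNoise <- .noiseFactor(nQC, cv)
      drop <- runif(length(sampleIds))
      list(k = k, base = base, w = w, noise = noise, qcNoise = qcNoise,
           drop = drop)
    })
    k <- max(draws$k, if (forced[i]) config@minPeptidesInteractor else 1L)
    npep[i] <- k
    weights[[i]] <- draws$w[seq_len(k)] / sum(draws$w[seq_len(k)])
    f <- ifelse(is.na(baitIdx), 1, fold[i, baitIdx])
    vals <- draws$base * f * draws$noise
    if (config@dropoutRate > 0 && !isRef[i])
      vals[draws$drop < config@dropoutRate] <- 0
    intensity[i, seq_along(sampleIds)] <- vals
    if (nQC > 0)
      intensity[i, length(sampleIds) + seq_len(nQC)] <-
        mean(vals) * draws$qcNoise
  }

  if (length(config@sampleOffsets)) {
    hit <- intersect(names(config@sampleOffsets), colnames(intensity))
    for (s in hit) intensity[, s] <- intensity[, s] * config@sampleOffsets[s]
  }

  rows <- rep(seq_len(nAll), npep)
  w <- unlist(weights)
  peptides <- data.frame(
    protein_id = ids[rows],
    peptide_id = paste0(ids[rows], "_pep",
                        unlist(lapply(npep, seq_len))),
    intensity[rows, , drop = FALSE] * w,
    check.names = FALSE, row.names = NULL, stringsAsFactors = FALSE
  )

  truth <- data.frame(entity_id = ids, kind = "protein",
                      n_peptides = npep,
                      reference_role = ifelse(isRef,
                                              refs$role[match(ids, refs$id)],
                                              NA_character_),
                      stringsAsFactors = FALSE)
  for (b in labelBaits) truth[[paste0("fold_", b)]] <- fold[, b]

  list(peptides = peptides, samples = samples, truth = truth)
}
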