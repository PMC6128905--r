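# Pooled CRISPR dropout-screen simulator.
#
# Growth model: the relative abundance of guide g in background b at
# timepoint t is
#   a(g,b,t) = baseline(g) * 2^(fitness(gene(g), b) * efficacy(g) * G(b,t)),
# where G(b,t) is the cumulative number of population doublings background b
# has undergone by timepoint t. Expected read counts are depth * a / sum(a)
# per sample; observed counts are negative-binomial (gamma-Poisson) with the
# configured dispersion, or the deterministic rounded expectation when
# dispersion is exactly 0 (the noise-free limit).

.screenLibrary <- function(config) {
  genes <- if (length(config@genes)) config@genes
           else sprintf("GENE%03d", seq_len(config@nGenes))
  gpg <- config@guidesPerGene
  ribo <- if (config@nRibosomal > 0)
    sprintf("RP_CTRL_%02d", seq_len(config@nRibosomal)) else character()
  nNT <- config@nNontargeting
  ntGroups <- if (nNT > 0) ceiling(nNT / config@ntGroupSize) else 0

  block <- function(gn, cls) {
    if (!length(gn)) return(NULL)
    data.frame(gene = rep(gn, each = gpg), class = cls,
               j = rep(seq_len(gpg), times = length(gn)),
               stringsAsFactors = FALSE)
  }
  ntBlock <- if (nNT > 0) {
    grp <- sprintf("NT_CTRL_%02d",
                   rep(seq_len(ntGroups),
                       each = config@ntGroupSize)[seq_len(nNT)])
    data.frame(gene = grp, class = "nontargeting",
               j = as.vector(unlist(lapply(table(factor(grp, unique(grp))),
                                           seq_len))),
               stringsAsFactors = FALSE)
  } else NULL
  lib <- rbind(block(genes, "target"), block(ribo, "ribosomal_control"),
               ntBlock)
  lib$guide_id <- paste0(lib$gene, "_g", lib$j)
  lib$j <- NULL
  lib[, c("guide_id", "gene", "class")]
}

.screenSamples <- function(config) {
  grid <- expand.grid(replicate = seq_len(config@replicates),
                      timepoint = config@timepoints,
                      background = config@backgrounds,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("background", "timepoint", "replicate")]
  grid$sample_id <- with(grid, paste0(background, "_", timepoint, "_r",
                                      replicate))
  grid[, c("sample_id", "background", "timepoint", "replicate")]
}

.fitnessMatrix <- function(config, lib) {
  genes <- unique(lib$gene)
  cls <- lib$class[match(genes, lib$gene)]
  fit <- matrix(0, length(genes), length(config@backgrounds),
                dimnames = list(genes, config@backgrounds))
  fit[cls == "ribosomal_control", ] <- config@essentialFitness
  ft <- config@fitness
  if (nrow(ft)) {
    bad <- setdiff(ft$gene, genes)
    if (length(bad))
      stop("fitness overrides for genes absent from the library: ",
           paste(bad, collapse = ", "))
    fit[cbind(ft$gene, ft$background)] <- ft$fitness
  }
  fit
}

.guideParams <- function(config, lib) {
  n <- nrow(lib)
  baseline <- numeric(n)
  efficacy <- numeric(n)
  for (g in seq_len(n)) {
    draws <- .withStream(config@seed, 11L, g, {
      c(rlnorm(1, 0, config@baselineSdlog),
        rbeta(1, config@efficacyShape1, config@efficacyShape2))
    })
    baseline[g] <- draws[1]
    efficacy[g] <- draws[2]
  }
  list(baseline = baseline, efficacy = efficacy)
}

#' Closed-form expected guide frequencies for a screen configuration
#'
#' Returns the noise-free expectations of the growth model underlying
#' [simulateScreen()]: per-sample guide frequencies (columns sum to 1) and
#' the unnormalized relative abundances, for use as an independent oracle
#' when validating depletion metrics and enrichment scores.
#'
#' @param config a [ScreenSimConfig-class].
#' @return list with `frequency` and `abundance` matrices (guides x
#'   samples), the guide `library`, `samples` annotation, and the per-guide
#'   `efficacy` and `baseline` draws.
#' @export
expectedScreenFrequencies <- function(config) {
  stopifnot(is(config, "ScreenSimConfig"))
  validObject(config)
  lib <- .screenLibrary(config)
  samples <- .screenSamples(config)
  fit <- .fitnessMatrix(config, lib)
  par <- .guideParams(config, lib)
  G <- vapply(seq_len(nrow(samples)), function(s)
    config@generations[[samples$background[s]]][[samples$timepoint[s]]],
    numeric(1))
  ab <- matrix(0, nrow(lib), nrow(samples),
               dimnames = list(lib$guide_id, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    fs <- fit[match(lib$gene, rownames(fit)), samples$background[s]]
    ab[, s] <- par$baseline * 2^(fs * par$efficacy * G[s])
  }
  freq <- sweep(ab, 2, colSums(ab), "/")
  list(frequency = freq, abundance = ab, library = lib, samples = samples,
       efficacy = setNames(par$efficacy, lib$guide_id),
       baseline = setNames(par$baseline, lib$guide_id))
}

#' Simulate a pooled CRISPR dropout screen
#'
#' Draws guide-level read counts over backgrounds, timepoints and replicates
#' under the gamma-Poisson model described in [ScreenSimConfig-class], with
#' per-guide random streams keyed by the configuration seed (identical
#' config and seed give identical counts; guide baselines and efficacies are
#' unchanged when genes are appended).
#'
#' @param config a [ScreenSimConfig-class].
#' @return list with elements `experiment` (a [ScreenExperiment-class]),
#'   `library` (data.frame `guide_id`, `gene`, `class`) and `truth`
#'   (data.frame of gene rows with per-background fitness and guide rows
#'   with efficacy).
#' @examples
#' sim <- simulateScreen(screenSimConfig(nGenes = 10, nRibosomal = 2,
#'                                       nNontargeting = 5, seed = 3))
#' head(sim$truth)
#' @export
simulateScreen <- function(config) {
  stopifnot(is(config, "ScreenSimConfig"))
  validObject(config)
  exp <- expectedScreenFrequencies(config)
  lib <- exp$library
  samples <- exp$samples
  nS <- nrow(samples)

  depths <- vapply(seq_len(nS), function(s) .withStream(config@seed, 12L, s, {
    config@depth * .noiseFactor(1, config@depthJitterCV)
  }), numeric(1))

  mu <- sweep(exp$frequency, 2, depths, "*")
  counts <- matrix(0L, nrow(lib), nS,
                   dimnames = dimnames(exp$frequency))
  if (config@dispersion == 0) {
    counts[] <- round(mu)
  } else {
    size <- 1 / config@dispersion
    for (g in seq_len(nrow(lib))) {
      counts[g, ] <- .withStream(config@seed, 13L, g,
                                 rnbinom(nS, mu = mu[g, ], size = size))
    }
  }
  storage.mode(counts) <- "integer"

  se <- ScreenExperiment(counts, lib, samples)

  fit <- .fitnessMatrix(config, lib)
  geneTruth <- data.frame(entity_id = rownames(fit), kind = "gene",
                          class = lib$class[match(rownames(fit), lib$gene)],
                          efficacy = NA_real_, stringsAsFactors = FALSE)
  for (b in config@backgrounds)
    geneTruth[[paste0("fitness_", b)]] <- fit[, b]
  guideTruth <- data.frame(entity_id = lib$guide_id, kind = "guide",
                           class = lib$class, efficacy = exp$efficacy,
                           stringsAsFactors = FALSE)
  for (b in config@backgrounds)
    guideTruth[[paste0("fitness_", b)]] <- fit[match(lib$gene,
                                                     rownames(fit)), b]
  truth <- rbind(geneTruth, guideTruth)
  rownames(truth) <- NULL

  list(experiment = se, library = lib, truth = truth)
}
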