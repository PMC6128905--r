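# Plain-text interfaces: TSV readers/writers for peptide tables, sample
# annotation, guide libraries and count matrices; YAML simulator configs;
# JSON for Venn partitions and run metadata.

#' Read a peptide-level quantification TSV
#'
#' Expected columns: `protein_id`, `peptide_id`, then one intensity column
#' per sample.
#' @param path file path.
#' @return data.frame.
#' @export
readPeptideTable <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a sample-annotation TSV
#'
#' Expected columns include `sample_id` and `bait` (proteomics) or
#' `background`, `timepoint`, `replicate` (screen).
#' @param path file path.
#' @return data.frame; a missing `qc_pool` column is filled with `FALSE`.
#' @export
readSampleAnnotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(ann$sample_id)) stop("sample ids must be unique")
  if (!"qc_pool" %in% names(ann)) ann$qc_pool <- FALSE
  ann$qc_pool <- as.logical(ann$qc_pool)
  ann
}

#' Read a guide-library TSV (`guide_id`, `gene`, `class`, optional
#' `sequence`)
#' @param path file path.
#' @return data.frame.
#' @export
readGuideLibrary <- function(path) {
  lib <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("guide_id", "gene", "class")
  if (!all(need %in% names(lib)))
    stop("guide library needs columns: ", paste(need, collapse = ", "))
  lib
}

#' Read a guide-count TSV into a ScreenExperiment
#'
#' @param countsPath TSV with a `guide_id` column then one count column per
#'   sample.
#' @param libraryPath guide-library TSV (see [readGuideLibrary()]).
#' @param samplesPath sample-annotation TSV with `sample_id`, `background`,
#'   `timepoint`, `replicate`.
#' @return a [ScreenExperiment-class].
#' @export
readScreenCounts <- function(countsPath, libraryPath, samplesPath) {
  cts <- read.delim(countsPath, check.names = FALSE,
                    stringsAsFactors = FALSE)
  lib <- readGuideLibrary(libraryPath)
  ann <- readSampleAnnotation(samplesPath)
  m <- as.matrix(cts[, setdiff(names(cts), "guide_id"), drop = FALSE])
  rownames(m) <- cts$guide_id
  ScreenExperiment(m, lib, ann)
}

#' Write a ProteinQuant matrix as TSV
#'
#' The applied normalization scheme is recorded in a `#`-prefixed header
#' comment line; columns are `protein_id`, `n_peptides`, then one intensity
#' column per sample.
#' @param pq a [ProteinQuant-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProteinQuant <- function(pq, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# normalization: ", normalizationMethod(pq)), con)
  df <- data.frame(protein_id = rownames(pq),
                   n_peptides = rowData(pq)$n_peptides,
                   assay(pq, "intensity"), check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ProteinQuant TSV written by [writeProteinQuant()]
#' @param path matrix TSV path.
#' @param samples sample-annotation data.frame or TSV path.
#' @return a [ProteinQuant-class].
#' @export
readProteinQuant <- function(path, samples) {
  first <- readLines(path, n = 1)
  norm <- if (startsWith(first, "# normalization:"))
    trimws(sub("# normalization:", "", first)) else "none"
  df <- read.delim(path, check.names = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (is.character(samples)) samples <- readSampleAnnotation(samples)
  m <- as.matrix(df[, setdiff(names(df), c("protein_id", "n_peptides")),
                    drop = FALSE])
  rownames(m) <- df$protein_id
  ProteinQuant(m, samples, df$n_peptides, normalization = norm)
}

#' Write a data.frame as a plain TSV
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a Venn partition (or any named vector/list) as JSON
#' @param x named vector or list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeJsonReport <- function(x, path) {
  jsonlite::write_json(as.list(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read gene sets in GMT format
#' @param path GMT file (set id, description, then member ids, tab-separated).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  sets <- lapply(lines, function(x) x[-(1:2)])
  names(sets) <- vapply(lines, `[`, character(1), 1)
  sets
}

#' Build simulator configurations from a YAML file
#'
#' The file may contain top-level `bioid:` and/or `screen:` blocks whose
#' keys are the arguments of [bioidSimConfig()] / [screenSimConfig()];
#' unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return list with elements `bioid` ([BioidSimConfig-class] or `NULL`)
#'   and `screen` ([ScreenSimConfig-class] or `NULL`).
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(block, fun) {
    if (is.null(block)) return(NULL)
    known <- names(formals(fun))
    bad <- setdiff(names(block), known)
    if (length(bad))
      stop("unknown config keys: ", paste(bad, collapse = ", "))
    if (!is.null(block$nTruePerBait))
      block$nTruePerBait <- unlist(block$nTruePerBait)
    if (!is.null(block$referenceProteins))
      block$referenceProteins <- as.data.frame(block$referenceProteins)
    if (!is.null(block$fitness))
      block$fitness <- as.data.frame(block$fitness)
    if (!is.null(block$generations))
      block$generations <- lapply(block$generations, unlist)
    do.call(fun, block)
  }
  list(bioid = build(y$bioid, bioidSimConfig),
       screen = build(y$screen, screenSimConfig))
}
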