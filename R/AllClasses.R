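#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom Biostrings DNAStringSet width
NULL

.AMINO_ACIDS <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                  "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                  "Thr", "Trp", "Tyr", "Val", "Sec")

#' Set of tRNA genes with mature (CCA-ended) transcript sequences
#'
#' Holds the genomic sequence of each tRNA gene together with its mature
#' transcript form, which always terminates in the universal 3' CCA
#' trinucleotide, plus per-gene annotation (isotype, anticodon, pseudogene
#' flag). Sequences are stored in the DNA alphabet; RNA input is normalized
#' U to T on construction.
#'
#' @slot genomic [Biostrings::DNAStringSet] genomic gene sequences, named by
#'   gene id; a genomically encoded 3' CCA is permitted but not required.
#' @slot mature [Biostrings::DNAStringSet] mature transcript sequences, named
#'   by gene id, every one ending in "CCA".
#' @slot info [S4Vectors::DataFrame] columns `gene_id`, `amino_acid` (one of
#'   the 20 standard isotypes plus Sec), `anticodon`, `is_pseudogene`.
#'
#' @exportClass TrnaGeneSet
setClass("TrnaGeneSet",
  representation(genomic = "DNAStringSet",
                 mature = "DNAStringSet",
                 info = "DataFrame"))

setValidity("TrnaGeneSet", function(object) {
  info <- object@info
  msgs <- character()
  needed <- c("gene_id", "amino_acid", "anticodon", "is_pseudogene")
  if (!all(needed %in% colnames(info)))
    return(paste("info must have columns:", paste(needed, collapse = ", ")))
  n <- nrow(info)
  if (length(object@genomic) != n || length(object@mature) != n)
    msgs <- c(msgs, "genomic, mature and info must have equal length")
  if (anyDuplicated(info$gene_id))
    msgs <- c(msgs, "duplicate gene_id values")
  if (n > 0) {
    mat <- as.character(object@mature)
    if (!all(substring(mat, nchar(mat) - 2L) == "CCA"))
      msgs <- c(msgs, "every mature sequence must end in CCA")
    w <- nchar(mat)
    if (any(w < 60L | w > 120L))
      msgs <- c(msgs, "mature lengths must lie in [60, 120]")
    if (any(grepl("[^ACGT]", mat)))
      msgs <- c(msgs, "mature sequences must use the ACGT alphabet")
    if (!all(info$amino_acid %in% .AMINO_ACIDS))
      msgs <- c(msgs, "unknown amino-acid isotype label")
    if (!all(grepl("^[ACGT]{3}$", info$anticodon)))
      msgs <- c(msgs, "anticodons must be 3-letter DNA triplets")
  }
  if (length(msgs)) msgs else TRUE
})

#' Truncation-aware tRNA reference
#'
#' For every gene the reference enumerates the mature transcript and all its
#' 3'-truncated variants missing 1..`maxMissing` terminal nucleotides, so a
#' read can be assigned simultaneously to a gene and to the number of 3'
#' nucleotides it lacks. Entry names follow the `gene_id::missK` convention.
#' Optional decoy sequences (e.g. other ncRNAs) absorb reads that would
#' otherwise be forced onto tRNAs.
#'
#' @slot sequences [Biostrings::DNAStringSet] all `(gene, k)` entries, named
#'   `gene_id::missK`, ordered by gene id then k ascending.
#' @slot manifest [S4Vectors::DataFrame] columns `entry_id`, `gene_id`,
#'   `missing_3p`, `length`, parallel to `sequences`.
#' @slot genes [TrnaGeneSet] the gene set the reference was built from.
#' @slot maxMissing single integer, deepest truncation enumerated (default
#'   13 in [buildTruncationSet()]).
#' @slot decoys [Biostrings::DNAStringSet] decoy sequences (may be empty).
#'
#' @exportClass TruncationReference
setClass("TruncationReference",
  representation(sequences = "DNAStringSet",
                 manifest = "DataFrame",
                 genes = "TrnaGeneSet",
                 maxMissing = "integer",
                 decoys = "DNAStringSet"))

setValidity("TruncationReference", function(object) {
  m <- object@manifest
  msgs <- character()
  if (nrow(m) != length(object@sequences))
    msgs <- c(msgs, "manifest and sequences must be parallel")
  K <- object@maxMissing
  if (length(K) != 1L || is.na(K) || K < 1L)
    msgs <- c(msgs, "maxMissing must be a single integer >= 1")
  if (nrow(m) > 0) {
    tab <- table(m$gene_id)
    if (!all(tab == K + 1L))
      msgs <- c(msgs, "every gene must contribute exactly maxMissing + 1 entries")
    if (!all(m$missing_3p >= 0L & m$missing_3p <= K))
      msgs <- c(msgs, "missing_3p out of [0, maxMissing]")
    k0 <- as.character(object@sequences[m$missing_3p == 0L])
    if (!all(substring(k0, nchar(k0) - 2L) == "CCA"))
      msgs <- c(msgs, "missing_3p == 0 entries must end in CCA")
  }
  if (length(msgs)) msgs else TRUE
})

#' Per-variant tRNA count matrix across fractionated samples
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose rows are
#' `(gene_id, missing_3p)` truncation variants and whose columns are
#' sequencing samples from a nucleus/cytosol x control/treated design.
#' The single assay `"counts"` holds non-negative integer counts of
#' uniquely assigned reads.
#'
#' Row metadata carries `gene_id`, `missing_3p`, `amino_acid` and
#' `anticodon`; column metadata carries `sample_id`, `fraction`
#' (`"nucleus"` or `"cytosol"`), `condition` (`"control"` or `"treated"`)
#' and `replicate`.
#'
#' @exportClass VariantCounts
setClass("VariantCounts", contains = "SummarizedExperiment")

setValidity("VariantCounts", function(object) {
  msgs <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    msgs <- c(msgs, "counts must be non-negative integers")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("gene_id", "missing_3p") %in% colnames(rd)))
    msgs <- c(msgs, "rowData needs gene_id and missing_3p")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample_id", "fraction", "condition", "replicate") %in%
             colnames(cd)))
    msgs <- c(msgs, "colData needs sample_id, fraction, condition, replicate")
  else {
    if (!all(cd$fraction %in% c("nucleus", "cytosol")))
      msgs <- c(msgs, "fraction must be 'nucleus' or 'cytosol'")
    if (!all(cd$condition %in% c("control", "treated")))
      msgs <- c(msgs, "condition must be 'control' or 'treated'")
    if (anyDuplicated(paste(cd$fraction, cd$condition, cd$replicate)))
      msgs <- c(msgs, "(fraction, condition, replicate) triples must be unique")
  }
  if (length(msgs)) msgs else TRUE
})
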