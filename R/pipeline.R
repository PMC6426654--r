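#' Profile a set of samples into a variant count matrix
#'
#' Convenience wrapper: assigns the reads of every sample against the
#' truncation reference and builds the `(gene, missing_3p) x sample`
#' count matrix in one call.
#'
#' @param reads named list of [Biostrings::DNAStringSet] (or FASTQ
#'   paths), one element per sample, names matching `design$sample_id`.
#' @param design design `data.frame` (`sample_id`, `fraction`,
#'   `condition`, `replicate`).
#' @param ref a [TruncationReference-class].
#' @param ... passed to [assignReads()].
#' @return a [VariantCounts-class].
#' @export
profileSamples <- function(reads, design, ref, ...) {
  design <- as.data.frame(design)
  stopifnot(!is.null(names(reads)),
            all(names(reads) %in% design$sample_id))
  asn <- lapply(names(reads), function(sid)
    assignReads(reads[[sid]], ref, sampleId = sid, ...))
  variantCounts(do.call(rbind, asn), design, ref)
}

#' @keywords internal
"_PACKAGE"

#' @importFrom Rsamtools scanBam ScanBamParam asBam
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom IRanges IRanges
#' @importFrom stats median rnbinom rmultinom rnorm runif rlnorm
NULL
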