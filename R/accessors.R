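#' @rdname TrnaGeneSet-class
#' @export
setMethod("geneIds", "TrnaGeneSet", function(x) as.character(x@info$gene_id))

#' @rdname TrnaGeneSet-class
#' @export
setMethod("matureSeqs", "TrnaGeneSet", function(x) x@mature)

#' @rdname TrnaGeneSet-class
#' @export
setMethod("genomicSeqs", "TrnaGeneSet", function(x) x@genomic)

#' @rdname TrnaGeneSet-class
#' @export
setMethod("geneInfo", "TrnaGeneSet", function(x) x@info)

#' @rdname TrnaGeneSet-class
#' @export
setMethod("length", "TrnaGeneSet", function(x) nrow(x@info))

#' @rdname TrnaGeneSet-class
#' @param i index (integer, logical or gene-id character vector).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "TrnaGeneSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, geneIds(x))
  new("TrnaGeneSet", genomic = x@genomic[i], mature = x@mature[i],
      info = x@info[i, , drop = FALSE])
})

setMethod("show", "TrnaGeneSet", function(object) {
  n <- length(object)
  cat("TrnaGeneSet with", n, "genes\n")
  if (n > 0) {
    cat("  isotypes:", paste(sort(unique(object@info$amino_acid)),
                             collapse = " "), "\n")
    cat("  mature lengths:", min(width(object@mature)), "-",
        max(width(object@mature)), "nt (all CCA-ended)\n")
    cat("  pseudogenes:", sum(object@info$is_pseudogene), "\n")
  }
})

#' @rdname TruncationReference-class
#' @export
setMethod("geneIds", "TruncationReference", function(x) geneIds(x@genes))

#' @rdname TruncationReference-class
#' @export
setMethod("refManifest", "TruncationReference", function(x) x@manifest)

#' @rdname TruncationReference-class
#' @export
setMethod("refSequences", "TruncationReference", function(x) x@sequences)

#' @rdname TruncationReference-class
#' @export
setMethod("maxMissing", "TruncationReference", function(x) x@maxMissing)

#' @rdname TruncationReference-class
#' @export
setMethod("refDecoys", "TruncationReference", function(x) x@decoys)

#' @rdname TruncationReference-class
#' @export
setMethod("geneInfo", "TruncationReference", function(x) geneInfo(x@genes))

#' @rdname TruncationReference-class
#' @export
setMethod("matureSeqs", "TruncationReference", function(x) matureSeqs(x@genes))

setMethod("show", "TruncationReference", function(object) {
  cat("TruncationReference:", length(geneIds(object)), "genes x",
      object@maxMissing + 1L, "variants =", length(object@sequences),
      "entries\n")
  if (length(object@decoys))
    cat("  decoys:", length(object@decoys), "\n")
})

setMethod("show", "VariantCounts", function(object) {
  callNextMethod()
  cd <- SummarizedExperiment::colData(object)
  cat("design:", paste(sprintf("%s/%s r%d", cd$fraction, cd$condition,
                               cd$replicate), collapse = ", "), "\n")
})
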