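#' @rdname TrnaGeneSet-class
#' @param x,object a `TrnaGeneSet` or `TruncationReference`.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname TrnaGeneSet-class
#' @export
setGeneric("matureSeqs", function(x) standardGeneric("matureSeqs"))

#' @rdname TrnaGeneSet-class
#' @export
setGeneric("genomicSeqs", function(x) standardGeneric("genomicSeqs"))

#' @rdname TrnaGeneSet-class
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))

#' @rdname TruncationReference-class
#' @export
setGeneric("refManifest", function(x) standardGeneric("refManifest"))

#' @rdname TruncationReference-class
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))

#' @rdname TruncationReference-class
#' @export
setGeneric("maxMissing", function(x) standardGeneric("maxMissing"))

#' @rdname TruncationReference-class
#' @export
setGeneric("refDecoys", function(x) standardGeneric("refDecoys"))
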