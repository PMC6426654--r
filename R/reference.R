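#' Load tRNA genes from a FASTA file
#'
#' Reads a tRNA gene FASTA, parses per-gene annotation out of the headers,
#' normalizes sequences to the DNA alphabet (U to T), derives the mature
#' CCA-ended transcript of each gene and optionally removes pseudogenes,
#' mirroring the usual construction of a tRNA reference from a gtRNAdb
#' download with pseudogenes excluded.
#'
#' Two header dialects are accepted:
#' \describe{
#'   \item{native}{`>gene_id|aa|anticodon|pseudo={0,1}`, e.g.
#'     `>chr19-tr09|Sec|TCA|pseudo=0`.}
#'   \item{gtRNAdb-style}{names containing `tRNA-<Aa>-<Anticodon>-...`, e.g.
#'     `Homo_sapiens_tRNA-Ala-AGC-1-1`; an isotype token of `Pseudo` or
#'     `Und`, or a header containing "pseudogene", flags a pseudogene (the
#'     anticodon of such records may be `NNN` and is kept verbatim only if
#'     it is a valid triplet, otherwise the record must be dropped via
#'     `dropPseudogenes`).}
#' }
#'
#' @param fastaPath path to the gene FASTA (plain or gzipped).
#' @param dropPseudogenes drop genes flagged as pseudogenes (default TRUE).
#' @return a [TrnaGeneSet-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1|Ala|AGC|pseudo=0",
#'              paste0(strrep("ACGT", 18), "CCA"),
#'              ">g2|Lys|TTT|pseudo=1",
#'              strrep("GCAU", 18)), fa)
#' loadTrnaGenes(fa)                         # pseudogene dropped
#' loadTrnaGenes(fa, dropPseudogenes = FALSE)
#' @export
loadTrnaGenes <- function(fastaPath, dropPseudogenes = TRUE) {
  raw <- Biostrings::readBStringSet(fastaPath)
  if (length(raw) == 0L)
    stop("empty FASTA: ", fastaPath)
  headers <- names(raw)
  ann <- lapply(seq_along(headers), function(i) {
    p <- .parseTrnaHeader(headers[i])
    if (is.null(p))
      stop("unparseable tRNA FASTA header (record ", i, "): ", headers[i])
    p
  })
  info <- S4Vectors::DataFrame(
    gene_id = vapply(ann, `[[`, "", "gene_id"),
    amino_acid = vapply(ann, `[[`, "", "amino_acid"),
    anticodon = vapply(ann, `[[`, "", "anticodon"),
    is_pseudogene = vapply(ann, `[[`, NA, "is_pseudogene"))
  if (anyDuplicated(info$gene_id))
    stop("duplicate gene ids in FASTA: ",
         paste(unique(info$gene_id[duplicated(info$gene_id)]), collapse = ", "))
  seqs <- toupper(chartr("Uu", "Tt", as.character(raw)))
  if (any(grepl("[^ACGT]", seqs)))
    stop("non-ACGT/U characters in sequences of: ",
         paste(info$gene_id[grepl("[^ACGT]", seqs)], collapse = ", "))
  if (dropPseudogenes) {
    keep <- !info$is_pseudogene
    info <- info[keep, , drop = FALSE]
    seqs <- seqs[keep]
    if (nrow(info) == 0L)
      stop("no genes left after removing pseudogenes")
  }
  genomic <- Biostrings::DNAStringSet(seqs)
  names(genomic) <- info$gene_id
  mature <- Biostrings::DNAStringSet(matureSequence(seqs))
  names(mature) <- info$gene_id
  new("TrnaGeneSet", genomic = genomic, mature = mature, info = info)
}

.parseTrnaHeader <- function(h) {
  h <- sub("\\s+$", "", h)
  # native dialect: gene_id|aa|anticodon|pseudo={0,1}
  f <- strsplit(h, "|", fixed = TRUE)[[1]]
  if (length(f) == 4L && grepl("^pseudo=[01]$", f[4])) {
    aa <- .normalizeIsotype(f[2])
    if (is.na(aa)) return(NULL)
    return(list(gene_id = f[1], amino_acid = aa,
                anticodon = toupper(chartr("Uu", "Tt", f[3])),
                is_pseudogene = f[4] == "pseudo=1"))
  }
  # permissive gtRNAdb-style: ...tRNA-<Aa>-<Anticodon>-m-n...
  m <- regmatches(h, regexec("tRNA-([A-Za-z]+)-([A-Za-z]{3})", h))[[1]]
  if (length(m) == 3L) {
    pseudo <- m[2] %in% c("Pseudo", "Und") || grepl("pseudogene", h,
                                                    ignore.case = TRUE)
    aa <- .normalizeIsotype(m[2])
    if (is.na(aa) && !pseudo) return(NULL)
    gid <- strsplit(h, "\\s+")[[1]][1]
    return(list(gene_id = gid,
                amino_acid = if (is.na(aa)) "Ala" else aa,  # placeholder for pseudogenes
                anticodon = toupper(chartr("Uu", "Tt", m[3])),
                is_pseudogene = pseudo))
  }
  NULL
}

.normalizeIsotype <- function(aa) {
  if (aa == "iMet") aa <- "Met"
  if (toupper(aa) == "SEC") aa <- "Sec"
  hit <- match(toupper(aa), toupper(.AMINO_ACIDS))
  if (is.na(hit)) NA_character_ else .AMINO_ACIDS[hit]
}

#' Mature transcript sequence of a tRNA gene
#'
#' The mature tRNA 3' end always carries the CCA trinucleotide, added
#' enzymatically when it is not genomically encoded. A genomically encoded
#' CCA is left untouched, so the operation is idempotent.
#'
#' @param genomicSeq character vector of genomic gene sequences (DNA
#'   alphabet, spliced).
#' @return character vector of mature sequences, each ending in "CCA".
#' @examples
#' matureSequence("ACGTACGTACGTGGT")  # CCA appended
#' matureSequence("ACGTACGTACGTCCA")  # unchanged
#' @export
matureSequence <- function(genomicSeq) {
  genomicSeq <- as.character(genomicSeq)
  if (any(nchar(genomicSeq) < 10L))
    stop("degenerate tRNA gene: sequence shorter than 10 nt")
  hasCCA <- substring(genomicSeq, nchar(genomicSeq) - 2L) == "CCA"
  ifelse(hasCCA, genomicSeq, paste0(genomicSeq, "CCA"))
}

#' Build the truncation-aware reference
#'
#' Enumerates, for every gene, the mature transcript (`missing_3p = 0`) and
#' all variants missing 1..`maxMissing` 3'-terminal nucleotides. Variant
#' `k = 1` lacks the terminal A, `k = 3` the whole CCA, and so on; reads
#' mapped against these entries identify both the gene and the integrity of
#' its 3' end at single-nucleotide resolution. Entries are ordered by gene
#' id, then k ascending, so the build is deterministic.
#'
#' @param genes a [TrnaGeneSet-class].
#' @param maxMissing deepest truncation to enumerate (default 13).
#' @param decoys optional [Biostrings::DNAStringSet] of decoy sequences
#'   (e.g. other ncRNAs); a decoy identical to any tRNA entry is dropped
#'   with a warning.
#' @return a [TruncationReference-class].
#' @export
buildTruncationSet <- function(genes, maxMissing = 13L, decoys = NULL) {
  stopifnot(is(genes, "TrnaGeneSet"), length(genes) > 0)
  maxMissing <- as.integer(maxMissing)
  if (maxMissing < 1L)
    stop("maxMissing must be >= 1")
  w <- width(matureSeqs(genes))
  bad <- w - 20L <= maxMissing
  if (any(bad))
    stop("maxMissing = ", maxMissing, " too deep for genes: ",
         paste(geneIds(genes)[bad], collapse = ", "))
  ord <- order(geneIds(genes))
  gid <- geneIds(genes)[ord]
  mat <- unname(as.character(matureSeqs(genes))[ord])
  ks <- 0:maxMissing
  gene_rep <- rep(gid, each = length(ks))
  k_rep <- rep(ks, times = length(gid))
  seq_rep <- substring(rep(mat, each = length(ks)),
                       1L, nchar(rep(mat, each = length(ks))) - k_rep)
  entry_id <- sprintf("%s::miss%d", gene_rep, k_rep)
  sequences <- Biostrings::DNAStringSet(seq_rep)
  names(sequences) <- entry_id
  manifest <- S4Vectors::DataFrame(entry_id = entry_id, gene_id = gene_rep,
                                   missing_3p = k_rep,
                                   length = nchar(seq_rep))
  dec <- Biostrings::DNAStringSet()
  if (!is.null(decoys) && length(decoys) > 0) {
    dchr <- toupper(chartr("Uu", "Tt", as.character(decoys)))
    clash <- dchr %in% seq_rep
    if (any(clash)) {
      warning(sum(clash), " decoy sequence(s) identical to a tRNA entry; dropped")
      dchr <- dchr[!clash]
    }
    dec <- Biostrings::DNAStringSet(dchr)
    names(dec) <- if (is.null(names(decoys))) {
      sprintf("decoy%04d", seq_along(decoys))[!clash]
    } else names(decoys)[!clash]
  }
  new("TruncationReference", sequences = sequences, manifest = manifest,
      genes = genes[match(gid, geneIds(genes))], maxMissing = maxMissing,
      decoys = dec)
}

#' Write a truncation reference to disk
#'
#' Emits a reference FASTA of all `gene_id::missK` entries (plus decoys)
#' and a tab-separated manifest (`gene_id`, `missing_3p`, `length`).
#' Output is byte-deterministic for identical input.
#'
#' @param ref a [TruncationReference-class].
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written (`fasta`, `manifest`).
#' @export
writeReference <- function(ref, dir) {
  stopifnot(is(ref, "TruncationReference"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "reference.fa")
  all <- c(refSequences(ref), refDecoys(ref))
  Biostrings::writeXStringSet(all, fa)
  mfPath <- file.path(dir, "manifest.tsv")
  utils::write.table(as.data.frame(refManifest(ref)), mfPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fa, manifest = mfPath))
}
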