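#' Assign reads to tRNA truncation variants
#'
#' Matches each read against the truncation reference and reports, per
#' read, the assigned gene, the inferred number of missing 3' nucleotides
#' and whether the assignment is unique. A read matches an entry when it is
#' identical to the entry sequence, or is a 3'-anchored suffix of it (a
#' read whose reverse transcription stalled before the 5' end still carries
#' full 3'-end evidence). The match score is the read length; a read is
#' unique only when all its best-scoring matches lie in a single gene —
#' ties across genes are kept but flagged `unique = FALSE` and never
#' counted. Within one gene, an ambiguous k is resolved toward the most
#' intact variant (smallest k). Matching is hash-based, so assignments do
#' not depend on read order.
#'
#' Reads shorter than `minReadLength` (default 15 nt) are discarded.
#' Optionally one substitution is tolerated (`maxMismatch = 1`) for reads
#' spanning a whole entry; mismatch search is only attempted when no exact
#' match exists.
#'
#' @param reads a [Biostrings::DNAStringSet], or path to a FASTQ file
#'   (plain or gzipped).
#' @param ref a [TruncationReference-class].
#' @param sampleId optional sample label attached to the output.
#' @param maxMismatch 0 (default) or 1 tolerated substitutions.
#' @param minReadLength minimum read length retained (default 15).
#' @return a `data.frame` with columns `read_id`, `gene_id`, `missing_3p`,
#'   `unique`, `start` (1-based 5' position of the read on the mature
#'   transcript, NA when unassigned) and `sample_id`. Unassigned reads have
#'   `gene_id = NA`.
#' @export
assignReads <- function(reads, ref, sampleId = NA_character_,
                        maxMismatch = 0L, minReadLength = 15L) {
  stopifnot(is(ref, "TruncationReference"))
  if (is.character(reads) && length(reads) == 1L)
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  if (length(reads) == 0L) {
    warning("no reads supplied")
    return(.emptyAssignment(sampleId))
  }
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  rs <- as.character(reads)
  keep <- nchar(rs) >= minReadLength
  rs <- rs[keep]; ids <- ids[keep]
  if (length(rs) == 0L) {
    warning("all reads shorter than ", minReadLength, " nt")
    return(.emptyAssignment(sampleId))
  }
  mf <- refManifest(ref)
  entrySeq <- as.character(refSequences(ref))
  entryLen <- mf$length
  # Exact full-entry matches first; a read can equal several entries, so
  # enumerate all candidates per distinct read sequence.
  uniqReads <- unique(rs)
  cand <- split(seq_along(entrySeq), entrySeq)
  exact <- cand[uniqReads]
  names(exact) <- uniqReads

  # Suffix matches, grouped by read length: the length-m suffix of every
  # entry at least m long, hashed once per distinct read length.
  lens <- sort(unique(nchar(uniqReads)))
  sufTab <- list()
  for (m in lens) {
    ok <- which(entryLen >= m)
    sfx <- substring(entrySeq[ok], entryLen[ok] - m + 1L, entryLen[ok])
    sufTab[[as.character(m)]] <- split(ok, sfx)
  }

  resolve <- function(idx) {
    # idx: candidate entry rows; collapse to (gene, k, entry, unique)
    idx <- unname(idx)
    g <- mf$gene_id[idx]
    if (length(unique(g)) > 1L) {
      # ambiguous across genes: report a stable representative, flagged
      o <- order(g, mf$missing_3p[idx])[1]
      return(list(gene = g[o], k = mf$missing_3p[idx[o]], unique = FALSE,
                  entry = idx[o]))
    }
    o <- order(mf$missing_3p[idx])[1]  # most intact variant
    list(gene = g[o], k = mf$missing_3p[idx[o]], unique = TRUE,
         entry = idx[o])
  }

  # resolve each distinct read sequence once, then join per read
  nu <- length(uniqReads)
  uGene <- rep(NA_character_, nu)
  uK <- rep(NA_integer_, nu)
  uUnique <- rep(FALSE, nu)
  uEntry <- rep(NA_integer_, nu)
  for (j in seq_len(nu)) {
    r <- uniqReads[j]
    idx <- exact[[r]]
    if (is.null(idx)) {
      tab <- sufTab[[as.character(nchar(r))]]
      idx <- tab[[r]]
    }
    if (is.null(idx) && maxMismatch >= 1L) {
      same <- which(entryLen == nchar(r))
      if (length(same)) {
        rc <- charToRaw(r)
        nm <- vapply(entrySeq[same],
                     function(s) sum(charToRaw(s) != rc), 0L)
        idx <- same[nm <= maxMismatch]
        if (length(idx) == 0L) idx <- NULL
      }
    }
    if (!is.null(idx)) {
      res <- resolve(idx)
      uGene[j] <- res$gene
      uK[j] <- as.integer(res$k)
      uUnique[j] <- res$unique
      uEntry[j] <- res$entry
    }
  }
  ri <- match(rs, uniqReads)
  outGene <- uGene[ri]
  outK <- uK[ri]
  outUnique <- uUnique[ri]
  outStart <- ifelse(is.na(uEntry[ri]), NA_integer_,
                     entryLen[uEntry[ri]] - nchar(rs) + 1L)
  data.frame(read_id = ids, gene_id = outGene, missing_3p = outK,
             unique = outUnique, start = as.integer(outStart),
             sample_id = sampleId, stringsAsFactors = FALSE)
}

.emptyAssignment <- function(sampleId) {
  data.frame(read_id = character(), gene_id = character(),
             missing_3p = integer(), unique = logical(), start = integer(),
             sample_id = character(), stringsAsFactors = FALSE)
}

#' Import read assignments from SAM/BAM alignments
#'
#' Accepts alignments produced by any aligner against either the
#' truncation reference (`gene_id::missK` reference names) or the mature
#' transcripts (`gene_id` names). The number of missing 3' nucleotides is
#' inferred from the rightmost aligned reference position; 3' soft-clipped
#' bases are treated as absence of evidence and do not extend the
#' alignment end. Reads with more than one alignment record are flagged
#' non-unique.
#'
#' @param path SAM or BAM file path.
#' @param ref a [TruncationReference-class].
#' @inheritParams assignReads
#' @return as [assignReads()].
#' @export
samAssignments <- function(path, ref, sampleId = NA_character_) {
  stopifnot(is(ref, "TruncationReference"))
  isSam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bamPath <- if (isSam) Rsamtools::asBam(path, tempfile(), overwrite = TRUE)
             else path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "flag"))
  b <- Rsamtools::scanBam(bamPath, param = p)[[1]]
  mapped <- !bitwAnd(b$flag, 4L)
  qname <- b$qname[mapped]; rname <- as.character(b$rname[mapped])
  pos <- b$pos[mapped]; cigar <- b$cigar[mapped]
  if (length(qname) == 0L) {
    warning("no mapped reads in ", path)
    return(.emptyAssignment(sampleId))
  }
  mf <- refManifest(ref)
  K <- maxMissing(ref)
  matInfo <- geneInfo(ref)
  matLen <- stats::setNames(width(matureSeqs(ref)), geneIds(ref))

  refSpan <- vapply(cigar, .cigarRefSpan, 0L, USE.NAMES = FALSE)
  alnEnd <- pos + refSpan - 1L

  isEntry <- grepl("::miss[0-9]+$", rname)
  gene <- ifelse(isEntry, sub("::miss[0-9]+$", "", rname), rname)
  known <- gene %in% geneIds(ref)
  if (!all(known))
    stop("alignment reference names not in the reference manifest: ",
         paste(unique(gene[!known]), collapse = ", "))
  kEntry <- ifelse(isEntry, as.integer(sub("^.*::miss", "", rname)), 0L)
  entryLen <- matLen[gene] - kEntry
  if (any(alnEnd > entryLen))
    stop("alignment end beyond reference entry length for reads: ",
         paste(utils::head(qname[alnEnd > entryLen], 5), collapse = ", "))
  missing3p <- pmin(kEntry + (entryLen - alnEnd), K)

  multi <- qname %in% qname[duplicated(qname)]
  # truncation entries are prefixes of the mature transcript, so entry and
  # mature coordinates coincide
  out <- data.frame(read_id = qname, gene_id = gene,
                    missing_3p = as.integer(missing3p), unique = !multi,
                    start = as.integer(pos),
                    sample_id = sampleId, stringsAsFactors = FALSE)
  out[!duplicated(out$read_id), , drop = FALSE]
}

# reference-space span of a CIGAR string (M/D/N/=/X consume reference)
.cigarRefSpan <- function(cig) {
  ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1]]
  n <- as.integer(sub("[MIDNSHP=X]", "", ops))
  op <- sub("[0-9]+", "", ops)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

#' Infer missing 3' nucleotides from an alignment end
#'
#' @param alignmentEnd 1-based inclusive rightmost aligned position on the
#'   mature transcript.
#' @param matureLength mature transcript length.
#' @param maxMissing clamp depth: reads ending more than `maxMissing` nt
#'   short are binned at `maxMissing` (default 13).
#' @return integer number of missing 3' nucleotides in `[0, maxMissing]`.
#' @examples
#' inferMissing3p(76, 76)        # intact
#' inferMissing3p(71, 76)        # 5 nt missing
#' inferMissing3p(50, 76)        # clamped at 13
#' @export
inferMissing3p <- function(alignmentEnd, matureLength, maxMissing = 13L) {
  if (any(alignmentEnd <= 0L))
    stop("alignmentEnd must be positive (1-based inclusive)")
  if (any(alignmentEnd > matureLength))
    stop("alignment end beyond mature transcript length")
  pmin(as.integer(matureLength - alignmentEnd), as.integer(maxMissing))
}

#' Build the per-variant count matrix
#'
#' Counts uniquely assigned reads into a `(gene, missing_3p) x sample`
#' matrix. Non-unique and unassigned reads are excluded; genes or variants
#' with zero reads are retained as zero rows so the matrix shape is fully
#' determined by the reference and the design.
#'
#' @param assignments `data.frame` from [assignReads()] / [samAssignments()]
#'   (rows from several samples may be concatenated), with a valid
#'   `sample_id` column.
#' @param design `data.frame` with columns `sample_id`, `fraction`
#'   (`nucleus`/`cytosol`), `condition` (`control`/`treated`), `replicate`.
#' @param ref a [TruncationReference-class].
#' @return a [VariantCounts-class].
#' @export
variantCounts <- function(assignments, design, ref) {
  stopifnot(is(ref, "TruncationReference"))
  design <- as.data.frame(design)
  req <- c("sample_id", "fraction", "condition", "replicate")
  stopifnot(all(req %in% colnames(design)))
  a <- assignments[assignments$unique & !is.na(assignments$gene_id), ,
                   drop = FALSE]
  if (nrow(a) && !all(a$sample_id %in% design$sample_id))
    stop("assignment sample labels missing from design: ",
         paste(setdiff(unique(a$sample_id), design$sample_id), collapse = ", "))
  mf <- refManifest(ref)
  rowKey <- paste(mf$gene_id, mf$missing_3p, sep = "::")
  cnt <- matrix(0L, nrow = nrow(mf), ncol = nrow(design),
                dimnames = list(mf$entry_id, design$sample_id))
  if (nrow(a)) {
    ri <- match(paste(a$gene_id, a$missing_3p, sep = "::"), rowKey)
    if (anyNA(ri))
      stop("assignments refer to (gene, k) pairs outside the reference")
    ci <- match(a$sample_id, design$sample_id)
    tab <- table(factor(ri, levels = seq_len(nrow(mf))),
                 factor(ci, levels = seq_len(nrow(design))))
    cnt[] <- as.integer(tab)
  }
  gi <- geneInfo(ref)
  rd <- S4Vectors::DataFrame(
    gene_id = mf$gene_id, missing_3p = mf$missing_3p,
    amino_acid = gi$amino_acid[match(mf$gene_id, gi$gene_id)],
    anticodon = gi$anticodon[match(mf$gene_id, gi$gene_id)])
  cd <- S4Vectors::DataFrame(design)
  rownames(cd) <- design$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt), rowData = rd, colData = cd)
  new("VariantCounts", se)
}

#' Collapse variant counts to gene level
#'
#' @param vc a [VariantCounts-class].
#' @return integer matrix, genes x samples (all truncation variants of a
#'   gene pooled).
#' @export
geneCounts <- function(vc) {
  stopifnot(is(vc, "VariantCounts"))
  cnt <- SummarizedExperiment::assay(vc, "counts")
  g <- SummarizedExperiment::rowData(vc)$gene_id
  rowsum(cnt, group = g, reorder = TRUE)
}

#' Intact / defective class counts
#'
#' Intact reads end at the mature CCA terminus (`missing_3p == 0`);
#' defective reads lack at least one 3' nucleotide (all `missing_3p >= 1`
#' variants pooled).
#'
#' @param vc a [VariantCounts-class].
#' @return list of two genes x samples integer matrices, `intact` and
#'   `defective`, with identical row order.
#' @export
classCounts <- function(vc) {
  cnt <- SummarizedExperiment::assay(vc, "counts")
  rd <- SummarizedExperiment::rowData(vc)
  gl <- sort(unique(rd$gene_id))
  intact <- rowsum(cnt[rd$missing_3p == 0L, , drop = FALSE],
                   group = rd$gene_id[rd$missing_3p == 0L], reorder = TRUE)
  defective <- rowsum(cnt[rd$missing_3p >= 1L, , drop = FALSE],
                      group = rd$gene_id[rd$missing_3p >= 1L], reorder = TRUE)
  list(intact = intact[gl, , drop = FALSE],
       defective = defective[gl, , drop = FALSE])
}

#' 3'-end truncation spectrum
#'
#' Relative amount of tRNA mass at each number of missing 3' nucleotides,
#' either pooled over all genes or per gene, within a chosen group of
#' samples.
#'
#' @param vc a [VariantCounts-class].
#' @param samples character vector of sample ids (default: all).
#' @param perGene if TRUE return a genes x (K+1) matrix of per-gene
#'   spectra (genes with zero reads get NA rows); otherwise a single
#'   length-(K+1) vector.
#' @return named numeric vector (or matrix) of fractions summing to 1.
#' @export
truncationSpectrum <- function(vc, samples = NULL, perGene = FALSE) {
  stopifnot(is(vc, "VariantCounts"))
  cnt <- SummarizedExperiment::assay(vc, "counts")
  if (!is.null(samples)) {
    if (!all(samples %in% colnames(cnt)))
      stop("unknown sample ids: ",
           paste(setdiff(samples, colnames(cnt)), collapse = ", "))
    cnt <- cnt[, samples, drop = FALSE]
  }
  rd <- SummarizedExperiment::rowData(vc)
  ks <- sort(unique(rd$missing_3p))
  tot <- rowSums(cnt)
  if (perGene) {
    genes <- sort(unique(rd$gene_id))
    out <- matrix(NA_real_, length(genes), length(ks),
                  dimnames = list(genes, paste0("miss", ks)))
    byGene <- rowsum(tot, group = paste(rd$gene_id, rd$missing_3p, sep = "::"))
    key <- do.call(rbind, strsplit(rownames(byGene), "::"))
    idx <- cbind(match(key[, 1], genes), match(as.integer(key[, 2]), ks))
    out[idx] <- byGene[, 1]
    gs <- rowSums(out, na.rm = TRUE)
    out <- out / gs
    out[gs == 0, ] <- NA_real_
    return(out)
  }
  if (sum(tot) == 0)
    stop("no reads in the selected samples")
  byK <- rowsum(tot, group = rd$missing_3p, reorder = TRUE)[, 1]
  stats::setNames(byK / sum(byK), paste0("miss", ks))
}

#' Per-position read coverage on a mature transcript
#'
#' Number of unique reads covering each 1-based position of the mature
#' transcript, computed from the assigned 5' start and the 3' end implied
#' by `missing_3p`.
#'
#' @param assignments `data.frame` from [assignReads()].
#' @param geneId single gene id.
#' @param ref a [TruncationReference-class].
#' @return integer vector of length equal to the gene's mature length.
#' @export
positionalCoverage <- function(assignments, geneId, ref) {
  stopifnot(is(ref, "TruncationReference"))
  gi <- match(geneId, geneIds(ref))
  if (is.na(gi))
    stop("unknown gene: ", geneId)
  L <- width(matureSeqs(ref))[gi]
  a <- assignments[assignments$unique & !is.na(assignments$gene_id) &
                     assignments$gene_id == geneId, , drop = FALSE]
  cov <- integer(L)
  if (nrow(a)) {
    from <- a$start
    to <- L - a$missing_3p
    # difference-array accumulation of [from, to] intervals
    d <- integer(L + 1L)
    for (i in seq_len(nrow(a))) {
      d[from[i]] <- d[from[i]] + 1L
      d[to[i] + 1L] <- d[to[i] + 1L] - 1L
    }
    cov <- cumsum(d[seq_len(L)])
  }
  cov
}
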