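## Synthetic-data generators: tRNA genes, fractionated read sets with known
## truncation spectra and fold changes, and two-channel cell images with
## known N/C truth. Every generator is deterministic given its seed and
## emits a machine-readable truth table so downstream checks never rely on
## hard-coded expectations.

# 3-letter isotype for each 1-letter code used by the genetic code table
.AA1TO3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
             Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
             L = "Leu", K = "Lys", M = "Met", `F` = "Phe", P = "Pro",
             S = "Ser", `T` = "Thr", W = "Trp", Y = "Tyr", V = "Val")

# anticodons per isotype, derived from the standard genetic code
# (anticodon = reverse complement of the codon); Sec decodes UGA
.isotypeAnticodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc %in% names(.AA1TO3)]
  aa3 <- .AA1TO3[gc[codons]]
  anti <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(codons)))
  out <- split(anti, aa3)
  out$Sec <- "TCA"
  out
}

#' Simulate a set of tRNA genes
#'
#' Generates `n` tRNA genes with random bodies of 62-90 nt followed by a
#' genomically encoded CCA, unique `chrN-trNN`-style identifiers, and
#' isotypes drawn from `isotypeWeights` with anticodons consistent with
#' the standard genetic code. Mature sequences are guaranteed distinct so
#' that exact read assignment is unambiguous. Deterministic per seed.
#'
#' @param n number of genes (default 323).
#' @param seed RNG seed.
#' @param isotypeWeights named numeric vector over the 21 isotypes;
#'   default is proportional to each isotype's codon multiplicity (Sec
#'   weighted as a single codon).
#' @param pseudogeneFraction fraction of genes flagged as pseudogenes
#'   (default 0).
#' @param dir optional output directory; writes `genes.fa` (native
#'   `>gene_id|aa|anticodon|pseudo=` headers) and `genes.tsv`.
#' @return a [TrnaGeneSet-class].
#' @export
simulateTrnaGenes <- function(n = 323L, seed = 1L, isotypeWeights = NULL,
                              pseudogeneFraction = 0, dir = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  anti <- .isotypeAnticodons()
  if (is.null(isotypeWeights)) {
    isotypeWeights <- vapply(anti, length, 0L)[.AMINO_ACIDS]
    names(isotypeWeights) <- .AMINO_ACIDS
  }
  stopifnot(all(names(isotypeWeights) %in% .AMINO_ACIDS))
  aa <- sample(names(isotypeWeights), n, replace = TRUE,
               prob = isotypeWeights)
  ac <- vapply(aa, function(a) sample(anti[[a]], 1L), "")
  chr <- sample(c(1:22, "X"), n, replace = TRUE)
  gid <- sprintf("chr%s-tr%02d", chr, seq_len(n))
  repeat {
    lens <- sample(62:90, n, replace = TRUE)
    body <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      "")
    mature <- paste0(body, "CCA")
    if (!anyDuplicated(mature)) break
  }
  pseudo <- rep(FALSE, n)
  if (pseudogeneFraction > 0)
    pseudo[sample(n, max(1L, round(pseudogeneFraction * n)))] <- TRUE
  info <- S4Vectors::DataFrame(gene_id = gid, amino_acid = unname(aa),
                               anticodon = unname(ac),
                               is_pseudogene = pseudo)
  genomic <- Biostrings::DNAStringSet(mature)  # CCA genomically encoded
  names(genomic) <- gid
  matureSet <- Biostrings::DNAStringSet(mature)
  names(matureSet) <- gid
  gs <- new("TrnaGeneSet", genomic = genomic, mature = matureSet,
            info = info)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    hdr <- sprintf("%s|%s|%s|pseudo=%d", gid, aa, ac, as.integer(pseudo))
    out <- genomic
    names(out) <- hdr
    Biostrings::writeXStringSet(out, file.path(dir, "genes.fa"))
    utils::write.table(as.data.frame(info), file.path(dir, "genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  gs
}

#' Default 3'-truncation spectra per compartment and condition
#'
#' Emulates the qualitative structure of fractionated tRNA pools: about
#' half of cytosolic reads intact with the defective mass spread over 1-6
#' missing nucleotides, 60% intact in the untreated nucleus, and 30%
#' intact in the stressed nucleus with defective mass concentrated at 5-8
#' missing nucleotides.
#'
#' @param nGenes number of genes.
#' @param maxMissing deepest truncation (default 13).
#' @return 4-d array `[gene, k+1, fraction, condition]` with fractions
#'   `nucleus`/`cytosol` and conditions `control`/`treated`; every
#'   spectrum sums to 1.
#' @export
defaultSpectra <- function(nGenes, maxMissing = 13L) {
  K <- maxMissing
  mk <- function(intact, kRange, decay = 0.6) {
    s <- numeric(K + 1)
    s[1] <- intact
    w <- decay^(seq_along(kRange) - 1)
    s[kRange + 1] <- (1 - intact) * w / sum(w)
    s
  }
  cyto <- mk(0.50, 1:6)
  nucCtrl <- mk(0.60, 1:6)
  nucTreat <- mk(0.30, 5:8, decay = 0.9)
  arr <- array(NA_real_, dim = c(nGenes, K + 1, 2, 2),
               dimnames = list(NULL, paste0("miss", 0:K),
                               c("nucleus", "cytosol"),
                               c("control", "treated")))
  for (g in seq_len(nGenes)) {
    arr[g, , "cytosol", "control"] <- cyto
    arr[g, , "cytosol", "treated"] <- cyto
    arr[g, , "nucleus", "control"] <- nucCtrl
    arr[g, , "nucleus", "treated"] <- nucTreat
  }
  arr
}

#' Simulation design for fractionated tRNA-seq read sets
#'
#' Bundles everything the read simulator needs: per-gene baseline
#' abundances, NB dispersion, truncation spectra per compartment and
#' condition, treated-vs-control log2 fold changes per compartment,
#' replicate count, per-sample depth and the RNG seed. The default effect
#' palette leaves all genes null except one selenocysteine-like gene with
#' a strong nuclear gain (8.6-fold) and a cytosolic loss (2.7-fold), so
#' smoke tests see one large, known signal.
#'
#' @param genes a [TrnaGeneSet-class].
#' @param replicates biological replicates per fraction x condition
#'   (default 2).
#' @param depth expected reads per sample (default 1e5).
#' @param seed RNG seed for the read simulator.
#' @param baselineMean per-gene relative abundance; default log-normal
#'   (sdlog 1), drawn deterministically from `seed`.
#' @param dispersion NB dispersion, scalar or per-gene (default 0.05).
#' @param spectra `[gene, k+1, fraction, condition]` array; default
#'   [defaultSpectra()].
#' @param lfcNucleus,lfcCytosol per-gene treated-vs-control log2 fold
#'   changes; default all zero except the Sec-like gene.
#' @param maxMissing deepest truncation (default 13).
#' @return a list of class `"SimDesign"`.
#' @export
simDesign <- function(genes, replicates = 2L, depth = 1e5, seed = 1L,
                      baselineMean = NULL, dispersion = 0.05,
                      spectra = NULL, lfcNucleus = NULL, lfcCytosol = NULL,
                      maxMissing = 13L) {
  stopifnot(is(genes, "TrnaGeneSet"))
  n <- length(genes)
  set.seed(seed + 1009L)  # design draws separated from read sampling
  if (is.null(baselineMean))
    baselineMean <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
  if (is.null(spectra))
    spectra <- defaultSpectra(n, maxMissing)
  if (is.null(lfcNucleus)) {
    lfcNucleus <- numeric(n)
    secLike <- which(geneInfo(genes)$amino_acid == "Sec")[1]
    if (is.na(secLike)) secLike <- 1L
    lfcNucleus[secLike] <- log2(8.6)
  }
  if (is.null(lfcCytosol)) {
    lfcCytosol <- numeric(n)
    secLike <- which(geneInfo(genes)$amino_acid == "Sec")[1]
    if (is.na(secLike)) secLike <- 1L
    lfcCytosol[secLike] <- -log2(2.7)
  }
  stopifnot(length(baselineMean) == n, all(baselineMean > 0),
            length(lfcNucleus) == n, length(lfcCytosol) == n,
            all(dispersion > 0),
            dim(spectra)[1] == n, dim(spectra)[2] == maxMissing + 1)
  sums <- apply(spectra, c(1, 3, 4), sum)
  if (any(abs(sums - 1) > 1e-9))
    stop("every truncation spectrum must sum to 1")
  design <- list(genes = genes, nGenes = n,
                 replicates = as.integer(replicates), depth = depth,
                 seed = as.integer(seed), baselineMean = baselineMean,
                 dispersion = rep_len(dispersion, n), spectra = spectra,
                 lfcNucleus = lfcNucleus, lfcCytosol = lfcCytosol,
                 maxMissing = as.integer(maxMissing))
  class(design) <- "SimDesign"
  design
}

# deterministic largest-remainder apportionment of `total` into parts
# proportional to w (ties broken by index)
.apportion <- function(w, total) {
  if (sum(w) == 0) return(integer(length(w)))
  x <- w / sum(w) * total
  base <- floor(x)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(x - base, seq_along(x), decreasing = c(TRUE, FALSE),
                   method = "radix")[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate fractionated tRNA-seq read sets
#'
#' Draws, for every sample of the `fraction x condition x replicate`
#' design, per-gene counts from a negative binomial whose mean encodes
#' the compartment fold change, splits each gene's reads over missing-3'
#' classes by its truncation spectrum, and emits the reads (each read is
#' the mature sequence minus its last k nucleotides) together with a
#' truth table of every `(gene, k, sample)` count. In `noiseFree` mode
#' counts are deterministic largest-remainder apportionments of the
#' expected values, so the profiler must reproduce the truth exactly.
#'
#' @param design a [simDesign()] object.
#' @param noiseFree disable NB and multinomial sampling (default FALSE).
#' @param errorRate per-base uniform substitution probability (default 0;
#'   0.001 is a realistic sequencer floor).
#' @param dir optional directory; writes one FASTQ per sample, a
#'   `truth.tsv` and a `design.tsv`.
#' @return list with `reads` (named list of [Biostrings::DNAStringSet]
#'   per sample), `truth` (`data.frame` sample_id, gene_id, missing_3p,
#'   count), and `samples` (the design table).
#' @export
simulateReads <- function(design, noiseFree = FALSE, errorRate = 0,
                          dir = NULL) {
  stopifnot(inherits(design, "SimDesign"))
  set.seed(design$seed)
  genes <- design$genes
  gid <- geneIds(genes)
  mature <- as.character(matureSeqs(genes))
  K <- design$maxMissing
  samples <- expand.grid(replicate = seq_len(design$replicates),
                         condition = c("control", "treated"),
                         fraction = c("nucleus", "cytosol"),
                         stringsAsFactors = FALSE)
  samples <- samples[, c("fraction", "condition", "replicate")]
  samples$sample_id <- sprintf("%s_%s_%d",
                               ifelse(samples$fraction == "nucleus",
                                      "nuc", "cyt"),
                               ifelse(samples$condition == "control",
                                      "ctrl", "h2o2"),
                               samples$replicate)
  readsOut <- list()
  truthList <- list()
  for (si in seq_len(nrow(samples))) {
    fr <- samples$fraction[si]; cond <- samples$condition[si]
    lfc <- if (fr == "nucleus") design$lfcNucleus else design$lfcCytosol
    mu <- design$baselineMean * 2^(lfc * (cond == "treated"))
    mu <- mu / sum(mu) * design$depth
    geneCount <- if (noiseFree) .apportion(mu, round(design$depth))
                 else stats::rnbinom(design$nGenes, mu = mu,
                                     size = 1 / design$dispersion)
    kc <- matrix(0L, design$nGenes, K + 1)
    for (g in seq_len(design$nGenes)) {
      if (geneCount[g] == 0) next
      sp <- design$spectra[g, , fr, cond]
      kc[g, ] <- if (noiseFree) .apportion(sp, geneCount[g])
                 else as.integer(stats::rmultinom(1, geneCount[g], sp))
    }
    idx <- which(kc > 0, arr.ind = TRUE)
    seqs <- character(sum(kc))
    pos <- 1L
    ord <- order(idx[, 1], idx[, 2])
    for (r in ord) {
      g <- idx[r, 1]; k <- idx[r, 2] - 1L; cnt <- kc[idx[r, 1], idx[r, 2]]
      s <- substr(mature[g], 1L, nchar(mature[g]) - k)
      seqs[pos:(pos + cnt - 1L)] <- s
      pos <- pos + cnt
    }
    if (errorRate > 0 && length(seqs)) {
      seqs <- vapply(seqs, .mutate, "", rate = errorRate, USE.NAMES = FALSE)
    }
    rd <- Biostrings::DNAStringSet(seqs)
    if (length(rd))
      names(rd) <- sprintf("%s_read%07d", samples$sample_id[si],
                           seq_along(rd))
    readsOut[[samples$sample_id[si]]] <- rd
    truthList[[si]] <- data.frame(
      sample_id = samples$sample_id[si],
      gene_id = rep(gid, each = K + 1),
      missing_3p = rep(0:K, times = design$nGenes),
      count = as.integer(t(kc)), stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truthList)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (sid in names(readsOut)) {
      rd <- readsOut[[sid]]
      q <- Biostrings::PhredQuality(
        vapply(width(rd), function(w) strrep("I", w), ""))
      qrd <- Biostrings::QualityScaledDNAStringSet(rd, q)
      Biostrings::writeQualityScaledXStringSet(
        qrd, file.path(dir, paste0(sid, ".fastq")))
    }
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(samples, file.path(dir, "design.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(reads = readsOut, truth = truth,
       samples = samples[, c("sample_id", "fraction", "condition",
                             "replicate")])
}

.mutate <- function(s, rate) {
  n <- nchar(s)
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(s)
  ch <- strsplit(s, "")[[1]]
  for (i in hit)
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Simulate two-channel tFISH cell images
#'
#' Places non-overlapping cells (elliptical nucleus inside an elliptical
#' cytoplasm) in a frame by rejection sampling, paints a DAPI channel
#' (bright nuclei) and a probe channel in which each cell's nuclear mean
#' intensity is `ratio` times its cytoplasmic mean, adds Gaussian noise,
#' and returns both images plus a truth table. The signal-to-noise ratio
#' is `(cytMean - background) / noiseSd`.
#'
#' The DAPI chromatin signal is painted one pixel inside the nuclear
#' domain seen by the probe, emulating the envelope-to-chromatin offset
#' of real stains; a DAPI mask grown by the standard one-pixel dilation
#' therefore lands on the true nuclear domain.
#'
#' @param nCells number of cells.
#' @param ratio true N/C ratio, scalar or per-cell vector.
#' @param noiseSd Gaussian noise SD (default 0.02).
#' @param seed RNG seed.
#' @param frame image size `c(rows, cols)` (default 420 x 420).
#' @param nucAxes range of nucleus semi-axes in px (default 14-19, giving
#'   areas comfortably above the 500 px particle filter).
#' @param cytExtra range of cytoplasm semi-axis excess over the nucleus
#'   (default 10-16 px).
#' @param background background intensity (default 0.05).
#' @param cytMean cytoplasmic probe intensity (default 0.15).
#' @param dapiLevel nuclear DAPI intensity (default 0.8).
#' @param maxTries placement attempts per cell before giving up.
#' @return list with matrices `dapi` and `probe`, and `truth`
#'   (`data.frame`: cell_id, cx, cy, nucleus/cytoplasm semi-axes, true
#'   ratio, true areas, background, noise_sd).
#' @export
simulateImages <- function(nCells = 20L, ratio = 2, noiseSd = 0.02,
                           seed = 1L, frame = c(420L, 420L),
                           nucAxes = c(14, 19), cytExtra = c(10, 16),
                           background = 0.05, cytMean = 0.15,
                           dapiLevel = 0.8, maxTries = 5000L) {
  set.seed(seed)
  ratio <- rep_len(ratio, nCells)
  nr <- frame[1]; nc <- frame[2]
  placed <- data.frame()
  for (i in seq_len(nCells)) {
    an <- stats::runif(1, nucAxes[1], nucAxes[2])
    bn <- stats::runif(1, nucAxes[1], nucAxes[2])
    ex <- stats::runif(1, cytExtra[1], cytExtra[2])
    ac <- an + ex; bc <- bn + ex
    margin <- max(ac, bc) + 6
    ok <- FALSE
    for (t in seq_len(maxTries)) {
      cx <- stats::runif(1, margin, nr - margin)
      cy <- stats::runif(1, margin, nc - margin)
      if (nrow(placed) == 0 ||
          all(sqrt((placed$cx - cx)^2 + (placed$cy - cy)^2) >
                (pmax(placed$a_cyt, placed$b_cyt) + max(ac, bc) + 5))) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place ", nCells, " cells in a ", nr, "x", nc,
           " frame; enlarge the frame or reduce nCells")
    placed <- rbind(placed,
                    data.frame(cell_id = i, cx = cx, cy = cy, a_nuc = an,
                               b_nuc = bn, a_cyt = ac, b_cyt = bc,
                               ratio = ratio[i]))
  }
  dapi <- matrix(background, nr, nc)
  probe <- matrix(background, nr, nc)
  rowIdx <- matrix(seq_len(nr), nr, nc)
  colIdx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  placed$nuc_area <- NA_integer_
  placed$cyt_area <- NA_integer_
  for (i in seq_len(nCells)) {
    p <- placed[i, ]
    inNuc <- ((rowIdx - p$cx) / p$a_nuc)^2 +
      ((colIdx - p$cy) / p$b_nuc)^2 <= 1
    inChromatin <- ((rowIdx - p$cx) / (p$a_nuc - 1))^2 +
      ((colIdx - p$cy) / (p$b_nuc - 1))^2 <= 1
    inCyt <- ((rowIdx - p$cx) / p$a_cyt)^2 +
      ((colIdx - p$cy) / p$b_cyt)^2 <= 1
    ring <- inCyt & !inNuc
    probe[ring] <- cytMean
    probe[inNuc] <- p$ratio * cytMean
    dapi[inChromatin] <- dapiLevel
    placed$nuc_area[i] <- sum(inNuc)
    placed$cyt_area[i] <- sum(ring)
  }
  if (noiseSd > 0) {
    dapi <- dapi + matrix(stats::rnorm(nr * nc, 0, noiseSd), nr, nc)
    probe <- probe + matrix(stats::rnorm(nr * nc, 0, noiseSd), nr, nc)
    dapi <- pmin(pmax(dapi, 0), 1)
    probe <- pmin(pmax(probe, 0), 1)
  }
  placed$background <- background
  placed$noise_sd <- noiseSd
  list(dapi = dapi, probe = probe, truth = placed)
}
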