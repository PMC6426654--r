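#' Median-of-ratios size factors
#'
#' Per-sample normalization constants computed as the median, over genes,
#' of the ratio of a sample's count to the per-gene geometric mean across
#' samples. Genes with a zero count in any sample are excluded from the
#' median, as in the standard median-of-ratios estimator used for bulk
#' RNA-seq.
#'
#' @param mat genes x samples numeric count matrix.
#' @return positive numeric vector, one factor per sample (named when the
#'   matrix has column names).
#' @examples
#' estimateSizeFactorsMoR(matrix(c(2, 4, 4, 8), nrow = 2))
#' @export
estimateSizeFactorsMoR <- function(mat) {
  mat <- as.matrix(mat)
  ok <- rowSums(mat <= 0) == 0
  if (!any(ok))
    stop("no gene has nonzero counts in every sample; supply deeper data ",
         "or use a pseudo-reference")
  logm <- log(mat[ok, , drop = FALSE])
  logGeo <- rowMeans(logm)
  # median taken in log space (ties averaged on the log scale)
  sf <- exp(apply(logm - logGeo, 2, stats::median))
  if (any(!is.finite(sf) | sf <= 0))
    stop("non-positive size factor")
  sf
}

#' Base mean of normalized counts
#'
#' Mean of the size-factor-normalized counts of each gene across all
#' samples; the quantity the depth filter "base mean of more than 20
#' reads across all samples" is applied to.
#'
#' @param mat genes x samples count matrix.
#' @param sizeFactors per-sample factors from [estimateSizeFactorsMoR()].
#' @return numeric vector, one value per gene.
#' @export
baseMeans <- function(mat, sizeFactors) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == length(sizeFactors))
  rowMeans(sweep(mat, 2, sizeFactors, "/"))
}

#' Sequencing-depth filters
#'
#' Two published filtering rules are exposed:
#' \describe{
#'   \item{`base_mean_gt`}{keep genes whose base mean of normalized counts
#'     is strictly greater than `threshold` (default 20) across all
#'     samples.}
#'   \item{`cyto_control_ge`}{keep genes with at least `threshold` raw
#'     reads in the cytosolic control samples. `scope = "each"` (default)
#'     demands the threshold in every cytosolic control sample;
#'     `scope = "mean"` applies it to their mean.}
#' }
#'
#' @param mat genes x samples raw count matrix; columns are matched to the
#'   design by name, or taken in design order when unnamed.
#' @param design design `data.frame` (needed for `cyto_control_ge`).
#' @param mode `"base_mean_gt"` or `"cyto_control_ge"`.
#' @param threshold read threshold (default 20).
#' @param sizeFactors factors for `base_mean_gt` (computed from `mat` when
#'   omitted).
#' @param scope `"each"` or `"mean"`, for `cyto_control_ge`.
#' @return named logical vector over genes.
#' @export
depthFilter <- function(mat, design = NULL,
                        mode = c("cyto_control_ge", "base_mean_gt"),
                        threshold = 20, sizeFactors = NULL,
                        scope = c("each", "mean")) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  mat <- as.matrix(mat)
  if (mode == "base_mean_gt") {
    if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactorsMoR(mat)
    return(baseMeans(mat, sizeFactors) > threshold)
  }
  if (is.null(design))
    stop("cyto_control_ge requires the sample design")
  cc <- design$sample_id[design$fraction == "cytosol" &
                           design$condition == "control"]
  if (length(cc) == 0L)
    stop("no cytosol/control samples in the design")
  ci <- if (is.null(colnames(mat))) match(cc, design$sample_id)
        else match(cc, colnames(mat))
  if (anyNA(ci))
    stop("cytosol/control samples not found among matrix columns")
  sub <- mat[, ci, drop = FALSE]
  if (scope == "each") {
    apply(sub >= threshold, 1, all)
  } else {
    rowMeans(sub) >= threshold
  }
}

#' Log2 fold change of normalized counts, treated vs control
#'
#' `log2((mean normalized treated + c) / (mean normalized control + c))`
#' with pseudocount `c` (default 0.5) guarding zero counts. Per-replicate
#' fold changes pair replicate i of the treated condition with replicate i
#' of the control condition.
#'
#' @param mat genes x samples count matrix (one compartment, or any sample
#'   subset containing both conditions).
#' @param sizeFactors per-sample factors aligned with `mat` columns.
#' @param condition character/factor per sample, `"control"` or
#'   `"treated"`.
#' @param replicate integer per sample (needed for `perReplicate`).
#' @param pseudocount numeric, default 0.5.
#' @param perReplicate also return a genes x replicates matrix of paired
#'   per-replicate fold changes.
#' @return numeric vector of per-gene Log2FC, or (with `perReplicate`)
#'   a list with elements `lfc` and `perReplicate`.
#' @export
log2FoldChange <- function(mat, sizeFactors, condition, replicate = NULL,
                           pseudocount = 0.5, perReplicate = FALSE) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == length(sizeFactors),
            ncol(mat) == length(condition))
  if (!any(condition == "treated") || !any(condition == "control"))
    stop("need at least one treated and one control sample")
  norm <- sweep(mat, 2, sizeFactors, "/")
  mt <- rowMeans(norm[, condition == "treated", drop = FALSE])
  mc <- rowMeans(norm[, condition == "control", drop = FALSE])
  lfc <- log2((mt + pseudocount) / (mc + pseudocount))
  if (!perReplicate)
    return(lfc)
  if (is.null(replicate))
    stop("perReplicate requires replicate labels")
  reps <- sort(intersect(replicate[condition == "treated"],
                         replicate[condition == "control"]))
  pr <- sapply(reps, function(r) {
    t1 <- norm[, condition == "treated" & replicate == r, drop = FALSE]
    c1 <- norm[, condition == "control" & replicate == r, drop = FALSE]
    log2((rowMeans(t1) + pseudocount) / (rowMeans(c1) + pseudocount))
  })
  colnames(pr) <- paste0("rep", reps)
  list(lfc = lfc, perReplicate = pr)
}

#' Negative-binomial Wald test for differential localization
#'
#' Per-gene two-group test of treated vs control within one compartment,
#' on counts modeled as NB with mean `s_j * q_c` and dispersion estimated
#' by method of moments, floored at `dispFloor`. Because per-gene moment
#' estimates are extremely noisy in small designs, dispersion information
#' is shared across genes by default: the excess variances and squared
#' means of all genes are pooled into a single ratio-of-sums estimate, a
#' moments analogue of the dispersion sharing that standard NB
#' differential tests rely on (`dispersionMode = "per-gene"` keeps the
#' raw per-gene estimates instead). The Wald statistic contrasts
#' `log(q_treated / q_control)` against its delta-method standard error
#' and is referred to the standard normal; with a single sample per
#' condition the dispersion cannot be estimated and the test falls back
#' to Poisson (flagged in the output).
#'
#' A permutation option (`method = "permutation"`) exchanges condition
#' labels across samples and is exact for very small designs, at the price
#' of a coarse p-value grid.
#'
#' @param mat genes x samples count matrix (one compartment).
#' @param sizeFactors per-sample factors aligned with `mat` columns.
#' @param condition `"control"`/`"treated"` per sample.
#' @param dispFloor lower bound for the dispersion (default 1e-8).
#' @param method `"wald"` (default) or `"permutation"`.
#' @param dispersionMode `"pooled"` (default) shares one moments-based
#'   dispersion across genes; `"per-gene"` uses each gene's own estimate.
#' @param pseudocount added to group means inside the log ratio (default
#'   0.5).
#' @return `data.frame` with columns `stat`, `p_value`, `dispersion`,
#'   `poisson_fallback`.
#' @export
nbWaldTest <- function(mat, sizeFactors, condition, dispFloor = 1e-8,
                       method = c("wald", "permutation"),
                       dispersionMode = c("pooled", "per-gene"),
                       pseudocount = 0.5) {
  method <- match.arg(method)
  dispersionMode <- match.arg(dispersionMode)
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == length(sizeFactors),
            ncol(mat) == length(condition))
  it <- condition == "treated"; ic <- condition == "control"
  if (!any(it) || !any(ic))
    stop("degenerate design: need both treated and control samples")
  if (method == "permutation")
    return(.nbPermutationTest(mat, sizeFactors, condition, pseudocount))
  nt <- sum(it); nc <- sum(ic)
  norm <- sweep(mat, 2, sizeFactors, "/")
  qt <- rowMeans(norm[, it, drop = FALSE])
  qc <- rowMeans(norm[, ic, drop = FALSE])
  fallback <- (nt < 2L || nc < 2L)
  if (fallback) {
    alpha <- rep(dispFloor, nrow(mat))
  } else {
    # method-of-moments on normalized counts: Var(K/s) = q/s + alpha q^2;
    # per-gene excess variance over squared mean, within-group pooled
    vt <- apply(norm[, it, drop = FALSE], 1, stats::var)
    vc <- apply(norm[, ic, drop = FALSE], 1, stats::var)
    invS_t <- mean(1 / sizeFactors[it]); invS_c <- mean(1 / sizeFactors[ic])
    num <- (nt - 1) * (vt - qt * invS_t) + (nc - 1) * (vc - qc * invS_c)
    den <- (nt - 1) * qt^2 + (nc - 1) * qc^2
    if (dispersionMode == "pooled") {
      # ratio-of-sums moments estimate of a common dispersion, with the
      # small-sample bias of q^2 as an estimate of mu^2 removed and each
      # gene self-normalized by its squared mean so that highly expressed
      # genes do not dominate the pool; near-unbiased where the per-gene
      # ratio is hopelessly noisy at n = 2
      den2 <- (nt - 1) * pmax(qt^2 - vt / nt, 0) +
        (nc - 1) * pmax(qc^2 - vc / nc, 0)
      qref <- (qt + qc) / 2
      keep <- qref >= 10 & den2 > 0
      if (!any(keep)) keep <- qref > 0 & den2 > 0
      w <- 1 / qref[keep]^2
      pooled <- if (any(keep)) sum(num[keep] * w) / sum(den2[keep] * w)
                else dispFloor
      alpha <- rep(max(pooled, dispFloor), nrow(mat))
    } else {
      alpha <- pmax(ifelse(den > 0, num / den, dispFloor), dispFloor)
    }
  }
  beta <- log((qt + pseudocount) / (qc + pseudocount))
  # Var(log q_c) ~ (1/n^2) sum_j [ 1/(s_j q) + alpha ]
  vlt <- (1 / nt^2) * (sum(1 / sizeFactors[it]) / pmax(qt, pseudocount) +
                         nt * alpha)
  vlc <- (1 / nc^2) * (sum(1 / sizeFactors[ic]) / pmax(qc, pseudocount) +
                         nc * alpha)
  se <- sqrt(vlt + vlc)
  stat <- ifelse(se > 0, beta / se, 0)
  p <- 2 * stats::pnorm(-abs(stat))
  p[qt == 0 & qc == 0] <- 1
  data.frame(stat = stat, p_value = pmin(pmax(p, .Machine$double.xmin), 1),
             dispersion = alpha, poisson_fallback = fallback)
}

.nbPermutationTest <- function(mat, sizeFactors, condition, pseudocount) {
  norm <- sweep(mat, 2, sizeFactors, "/")
  it <- condition == "treated"
  obs <- abs(.permStat(norm, it, pseudocount))
  labs <- utils::combn(ncol(mat), sum(it))
  perms <- apply(labs, 2, function(ix) {
    sel <- rep(FALSE, ncol(mat)); sel[ix] <- TRUE
    abs(.permStat(norm, sel, pseudocount))
  })
  p <- (rowSums(perms >= obs - 1e-12)) / ncol(labs)
  data.frame(stat = obs, p_value = p, dispersion = NA_real_,
             poisson_fallback = FALSE)
}

.permStat <- function(norm, sel, pseudocount) {
  log((rowMeans(norm[, sel, drop = FALSE]) + pseudocount) /
        (rowMeans(norm[, !sel, drop = FALSE]) + pseudocount))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; the adjusted value is always
#' at least the raw p-value and monotone in rank.
#'
#' @param p numeric vector of p-values in `[0, 1]`; NA is an error.
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  if (anyNA(p))
    stop("NA p-values")
  if (any(p < 0 | p > 1))
    stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Replicate-consistency fold-change call
#'
#' A gene is called `"up"` when every biological replicate shows a Log2FC
#' strictly above `threshold` (default 0.75), `"down"` when every
#' replicate is below `-threshold`, and `"none"` otherwise (including sign
#' conflicts).
#'
#' @param perReplicateLfc genes x replicates numeric matrix (>= 2
#'   columns), or a numeric vector for a single gene.
#' @param threshold positive Log2FC cutoff (default 0.75).
#' @return character vector of `"up"`, `"down"`, `"none"` per gene.
#' @export
consistencyCall <- function(perReplicateLfc, threshold = 0.75) {
  m <- if (is.matrix(perReplicateLfc)) perReplicateLfc
       else matrix(perReplicateLfc, nrow = 1)
  if (ncol(m) < 2L)
    stop("need >= 2 replicate fold changes")
  up <- rowSums(m > threshold) == ncol(m)
  down <- rowSums(m < -threshold) == ncol(m)
  out <- rep("none", nrow(m))
  out[up] <- "up"; out[down] <- "down"
  stats::setNames(out, rownames(m))
}

#' Amino-acid (isotype) read distribution
#'
#' Pools reads per isotype and normalizes within each sample, giving the
#' relative representation of each amino-acid family in the tRNA pool of
#' that sample.
#'
#' @param mat genes x samples count matrix.
#' @param isotypes amino-acid label per gene (aligned with rows).
#' @return isotypes x samples matrix of fractions; each column sums to 1.
#' @export
aaDistribution <- function(mat, isotypes) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == length(isotypes))
  if (!all(isotypes %in% .AMINO_ACIDS))
    stop("unknown isotype label(s): ",
         paste(setdiff(isotypes, .AMINO_ACIDS), collapse = ", "))
  pooled <- rowsum(mat, group = isotypes, reorder = TRUE)
  tot <- colSums(pooled)
  if (any(tot == 0))
    stop("sample(s) with zero tRNA-mapped reads")
  sweep(pooled, 2, tot, "/")
}

#' Deterministic hierarchical row ordering
#'
#' Leaf order of complete-linkage hierarchical clustering on Euclidean
#' distances, as used to order genes in localization heatmaps.
#'
#' @param mat numeric matrix with >= 2 rows and finite values.
#' @return integer permutation of row indices.
#' @export
clusterRowOrder <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L)
    stop("need >= 2 rows")
  if (!all(is.finite(mat)))
    stop("non-finite values")
  stats::hclust(stats::dist(mat, method = "euclidean"),
                method = "complete")$order
}

#' Full differential-localization table
#'
#' Runs the whole localization analysis on a [VariantCounts-class] object:
#' gene-level size factors (median-of-ratios over pooled per-gene counts),
#' base means, intact/defective class counts, per-compartment Log2FC with
#' per-replicate values, NB Wald tests within each compartment, BH
#' adjustment, both depth filters and the replicate-consistency call.
#'
#' @param vc a [VariantCounts-class].
#' @param lfcThreshold consistency-call cutoff (default 0.75).
#' @param depthThreshold read threshold for both filters (default 20).
#' @param pseudocount fold-change pseudocount (default 0.5).
#' @param testMethod passed to [nbWaldTest()].
#' @return `data.frame`, one row per (gene, class in intact/defective):
#'   `gene_id`, `variant_class`, `base_mean`, `lfc_nucleus`,
#'   `lfc_cytosol`, per-replicate nuclear/cytosolic LFC columns,
#'   `p_nucleus`, `adj_p_nucleus`, `p_cytosol`, `adj_p_cytosol`,
#'   `passes_base_mean`, `passes_cyto_control`, `call_nucleus`,
#'   `call_cytosol`.
#' @export
localizationTable <- function(vc, lfcThreshold = 0.75, depthThreshold = 20,
                              pseudocount = 0.5,
                              testMethod = c("wald", "permutation")) {
  stopifnot(is(vc, "VariantCounts"))
  testMethod <- match.arg(testMethod)
  cd <- as.data.frame(SummarizedExperiment::colData(vc))
  gc <- geneCounts(vc)
  sf <- estimateSizeFactorsMoR(gc)
  cls <- classCounts(vc)
  genes <- rownames(cls$intact)

  perClass <- lapply(c(intact = "intact", defective = "defective"),
                     function(cl) {
    m <- cls[[cl]]
    bm <- baseMeans(m, sf)
    res <- list(gene_id = genes, variant_class = cl, base_mean = bm)
    for (fr in c("nucleus", "cytosol")) {
      sel <- cd$fraction == fr
      sub <- m[, sel, drop = FALSE]
      l <- log2FoldChange(sub, sf[sel], cd$condition[sel],
                          cd$replicate[sel], pseudocount,
                          perReplicate = TRUE)
      tst <- nbWaldTest(sub, sf[sel], cd$condition[sel],
                        method = testMethod, pseudocount = pseudocount)
      tag <- if (fr == "nucleus") "nucleus" else "cytosol"
      res[[paste0("lfc_", tag)]] <- l$lfc
      for (j in seq_len(ncol(l$perReplicate)))
        res[[paste0("lfc_", tag, "_", colnames(l$perReplicate)[j])]] <-
          l$perReplicate[, j]
      res[[paste0("p_", tag)]] <- tst$p_value
      res[[paste0("adj_p_", tag)]] <- bhAdjust(tst$p_value)
      res[[paste0("call_", tag)]] <-
        consistencyCall(l$perReplicate, lfcThreshold)
    }
    res$passes_base_mean <- depthFilter(m, mode = "base_mean_gt",
                                        threshold = depthThreshold,
                                        sizeFactors = sf)
    res$passes_cyto_control <- depthFilter(m, cd, mode = "cyto_control_ge",
                                           threshold = depthThreshold)
    data.frame(res, stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- rbind(perClass$intact, perClass$defective)
  out[order(out$gene_id, out$variant_class), , drop = FALSE]
}
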