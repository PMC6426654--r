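#' Segmentation parameters
#'
#' Defaults mirror a standard ImageJ-style workflow for cultured cells:
#' Otsu thresholding with a dark background, a single 3x3 binary dilation
#' of the nuclear mask followed by hole filling, particles of at least
#' 500 px kept, particles touching the image border excluded, a median
#' filter of radius 2 on the cytoplasm mask, and two iterations of
#' non-merging dilation when growing cytoplasm components.
#'
#' @param minParticleArea minimum component area in pixels (default 500).
#' @param excludeEdge drop components touching the border (default TRUE).
#' @param dilateIters nuclear-mask dilation iterations (default 1).
#' @param noMergeIters cytoplasm non-merging dilation iterations
#'   (default 2).
#' @param medianRadius cytoplasm median-filter radius in px (default 2).
#' @return named list of parameters.
#' @export
segmentationParams <- function(minParticleArea = 500L, excludeEdge = TRUE,
                               dilateIters = 1L, noMergeIters = 2L,
                               medianRadius = 2L) {
  stopifnot(minParticleArea > 0)
  list(minParticleArea = as.integer(minParticleArea),
       excludeEdge = isTRUE(excludeEdge),
       dilateIters = as.integer(dilateIters),
       noMergeIters = as.integer(noMergeIters),
       medianRadius = as.integer(medianRadius))
}

# scale an 8/16-bit integer or float image to [0, 1] for thresholding
.scale01 <- function(img) {
  img <- as.matrix(img)
  if (!all(is.finite(img)))
    stop("image contains non-finite values")
  mx <- max(img)
  if (mx > 1) {
    denom <- if (mx <= 255) 255 else if (mx <= 65535) 65535 else mx
    img <- img / denom
  }
  img
}

# 8-connected component labeling by iterative minimum-label propagation,
# matching ImageJ's default particle connectivity
.label8 <- function(bw) {
  lab <- matrix(0L, nrow(bw), ncol(bw))
  fg <- which(bw > 0)
  lab[fg] <- fg  # seed with linear pixel index
  repeat {
    nb <- .neighborMin(lab)
    upd <- fg[nb[fg] > 0 & nb[fg] < lab[fg]]
    if (!length(upd)) break
    lab[upd] <- nb[upd]
  }
  # relabel in raster order of first occurrence
  u <- unique(lab[lab > 0])
  first <- vapply(u, function(v) min(which(lab == v)), 0L)
  u <- u[order(first)]
  out <- matrix(0L, nrow(bw), ncol(bw))
  out[lab > 0] <- match(lab[lab > 0], u)
  out
}

# minimum positive label among the 8 neighbors and self, 0 where none
.neighborMin <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  big <- .Machine$integer.max
  acc <- matrix(big, nr, nc)
  l <- lab; l[l == 0L] <- big
  for (di in -1:1) for (dj in -1:1) {
    sh <- matrix(big, nr, nc)
    ri <- max(1, 1 + di):min(nr, nr + di)
    ci <- max(1, 1 + dj):min(nc, nc + dj)
    sh[ri, ci] <- l[ri - di, ci - dj]
    acc <- pmin(acc, sh)
  }
  acc[acc == big] <- 0L
  acc
}

# drop labeled components below a minimum area or touching the border,
# then relabel in raster order
.particleFilter <- function(lab, minArea, excludeEdge) {
  if (max(lab) == 0L) return(lab)
  areas <- tabulate(lab[lab > 0])
  drop <- which(areas < minArea)
  if (excludeEdge) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, border[border > 0])
  }
  lab[lab %in% drop] <- 0L
  u <- unique(lab[lab > 0])
  if (!length(u)) return(matrix(0L, nrow(lab), ncol(lab)))
  first <- vapply(u, function(v) min(which(lab == v)), 0L)
  u <- u[order(first)]
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0] <- match(lab[lab > 0], u)
  out
}

#' Segment nuclei from the DAPI channel
#'
#' Otsu threshold (bright nuclei on dark background), binary dilation with
#' a 3x3 square element, hole filling, 8-connected component labeling,
#' removal of particles under `minParticleArea` pixels and of particles
#' touching the image border. Labels are assigned in raster order, so the
#' result is deterministic.
#'
#' @param dapi single-channel image (matrix or [EBImage::Image]); 8/16-bit
#'   integer or `[0, 1]` float intensities.
#' @param params from [segmentationParams()].
#' @return integer label matrix (0 = background, 1..n = nuclei).
#' @export
segmentNuclei <- function(dapi, params = segmentationParams()) {
  img <- .scale01(dapi)
  if (max(img) == min(img)) {
    warning("constant image: no nuclei found")
    return(matrix(0L, nrow(img), ncol(img)))
  }
  th <- EBImage::otsu(EBImage::Image(img))
  bw <- img > th
  kern <- EBImage::makeBrush(3, shape = "box")
  for (i in seq_len(params$dilateIters))
    bw <- EBImage::dilate(bw, kern) > 0
  bw <- EBImage::fillHull(bw) > 0
  lab <- .label8(bw)
  .particleFilter(lab, params$minParticleArea, params$excludeEdge)
}

#' Non-merging binary dilation on a label image
#'
#' Grows every labeled component by 8-connected dilation, with the
#' constraint that a background pixel is claimed only when exactly one
#' distinct label appears among its neighbors; pixels contested by two or
#' more components stay background, so distinct components can never fuse.
#'
#' @param lab integer label matrix.
#' @param iterations number of dilation rounds (default 2).
#' @param support optional logical matrix; when given, only pixels inside
#'   the support can be claimed, so the dilation re-connects structure
#'   lost to filtering without ever growing into excluded territory.
#' @return label matrix of the same shape; the set of labels is unchanged.
#' @export
dilateNoMerge <- function(lab, iterations = 2L, support = NULL) {
  lab <- as.matrix(lab)
  storage.mode(lab) <- "integer"
  nr <- nrow(lab); nc <- ncol(lab)
  if (!is.null(support)) {
    support <- as.matrix(support) > 0
    stopifnot(all(dim(support) == dim(lab)))
  }
  for (it in seq_len(iterations)) {
    mn <- matrix(0L, nr, nc)      # min positive neighbor label
    mx <- matrix(0L, nr, nc)      # max positive neighbor label
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      sh <- matrix(0L, nr, nc)
      ri <- max(1, 1 + di):min(nr, nr + di)
      ci <- max(1, 1 + dj):min(nc, nc + dj)
      sh[ri, ci] <- lab[ri - di, ci - dj]
      pos <- sh > 0L
      mn[pos] <- ifelse(mn[pos] == 0L, sh[pos], pmin(mn[pos], sh[pos]))
      mx[pos] <- pmax(mx[pos], sh[pos])
    }
    claim <- lab == 0L & mn > 0L & mn == mx  # exactly one claiming label
    if (!is.null(support)) claim <- claim & support
    lab[claim] <- mn[claim]
  }
  lab
}

#' Segment cytoplasm and match cells to nuclei
#'
#' The probe channel with nuclear regions blanked is Otsu-thresholded,
#' median-filtered (radius `medianRadius`), labeled with 8-connectivity
#' and grown by `noMergeIters` rounds of non-merging dilation. The
#' dilation is constrained to the pre-filter threshold support: it
#' re-connects and re-claims above-threshold pixels the median filter
#' removed, but never extends the measurement mask into sub-threshold
#' background, which would otherwise dilute the cytoplasmic mean. Each
#' cytoplasm component is then matched to the nucleus it overlaps most
#' after ring expansion of the nucleus; nuclei with no surrounding signal
#' are dropped with a warning, and the per-cell mask is filtered by the
#' particle-area and border rules. Cell ids follow nucleus labels.
#'
#' @param probe single-channel probe image.
#' @param nucLab nucleus label matrix from [segmentNuclei()].
#' @param params from [segmentationParams()].
#' @return integer label matrix of cytoplasm regions; value i marks the
#'   cytoplasm of the cell whose nucleus has label i (nucleus pixels are
#'   excluded from the cytoplasm mask).
#' @export
segmentCytoplasm <- function(probe, nucLab, params = segmentationParams()) {
  img <- .scale01(probe)
  stopifnot(all(dim(img) == dim(nucLab)))
  blank <- img
  blank[nucLab > 0L] <- 0
  if (max(blank) == min(blank)) {
    warning("constant probe image: no cytoplasm found")
    return(matrix(0L, nrow(img), ncol(img)))
  }
  th <- EBImage::otsu(EBImage::Image(blank))
  support <- blank > th
  bw <- support
  if (params$medianRadius > 0) {
    bw <- EBImage::medianFilter(EBImage::Image(bw * 1),
                                size = params$medianRadius) > 0.5
  }
  cyLab <- .label8(bw)
  cyLab <- dilateNoMerge(cyLab, params$noMergeIters, support = support)

  kern <- EBImage::makeBrush(3, shape = "box")
  out <- matrix(0L, nrow(img), ncol(img))
  taken <- integer(0)
  for (i in sort(unique(nucLab[nucLab > 0L]))) {
    ring <- nucLab == i
    ring <- EBImage::dilate(ring, kern) > 0
    ring <- EBImage::dilate(ring, kern) > 0
    cand <- cyLab[ring & cyLab > 0L]
    cand <- cand[!(cand %in% taken)]
    if (!length(cand)) {
      warning("nucleus ", i, " has no surrounding cytoplasm signal; cell dropped")
      next
    }
    l <- as.integer(names(which.max(table(cand))))
    cellMask <- (cyLab == l) | (nucLab == i)
    area <- sum(cellMask)
    touches <- any(cellMask[1, ]) || any(cellMask[nrow(cellMask), ]) ||
      any(cellMask[, 1]) || any(cellMask[, ncol(cellMask)])
    if (area < params$minParticleArea || (params$excludeEdge && touches)) {
      warning("cell for nucleus ", i, " removed by particle filter")
      next
    }
    taken <- c(taken, l)
    out[cyLab == l & nucLab != i] <- i
  }
  out
}

#' N/C ratio from masks
#'
#' Mean probe intensity over the nucleus divided by the mean over the
#' cytoplasm; invariant to rescaling the whole image.
#'
#' @param probe single-channel probe image.
#' @param nucMask,cytMask disjoint logical masks (or label == id).
#' @return positive numeric ratio.
#' @export
ncRatioMasks <- function(probe, nucMask, cytMask) {
  probe <- as.matrix(probe)
  nucMask <- as.matrix(nucMask) > 0
  cytMask <- as.matrix(cytMask) > 0
  if (!sum(nucMask) || !sum(cytMask))
    stop("empty mask")
  if (any(nucMask & cytMask))
    stop("nucleus and cytoplasm masks overlap")
  mean(probe[nucMask]) / mean(probe[cytMask])
}

#' N/C ratio from raw integrated densities
#'
#' The whole-cell formulation: with RID the summed probe intensity and
#' Area the pixel count, nuclear over total-cell measurements give
#' \deqn{N/C = \frac{RID_{Nuc}/Area_{Nuc}}
#'   {(RID_{Cyt}-RID_{Nuc})/(Area_{Cyt}-Area_{Nuc})}}
#' which equals the mask-based ratio when the measurements are exact sums
#' over nucleus and whole cell.
#'
#' @param ridNuc,areaNuc nuclear integrated density and area.
#' @param ridCyt,areaCyt whole-cell integrated density and area.
#' @return positive numeric ratio.
#' @examples
#' ncRatioFormula(100, 10, 200, 30)  # 10 / 5 = 2
#' @export
ncRatioFormula <- function(ridNuc, areaNuc, ridCyt, areaCyt) {
  if (any(areaNuc <= 0) || any(areaCyt <= areaNuc))
    stop("degenerate cell: need areaCyt > areaNuc > 0")
  if (any(ridNuc < 0) || any(ridCyt <= ridNuc))
    stop("degenerate cell: need ridCyt > ridNuc >= 0")
  (ridNuc / areaNuc) / ((ridCyt - ridNuc) / (areaCyt - areaNuc))
}

#' Per-cell N/C measurements
#'
#' Measures every segmented cell on the probe channel: areas, raw
#' integrated densities, mean intensities and the N/C ratio in the chosen
#' mode. `"masks"` divides nuclear by cytoplasmic mean intensity;
#' `"formula"` uses whole-cell integrated densities through
#' [ncRatioFormula()]. On exact masks both agree to numerical precision.
#'
#' @param probe single-channel probe image.
#' @param nucLab nucleus labels from [segmentNuclei()].
#' @param cytLab cytoplasm labels from [segmentCytoplasm()].
#' @param mode `"masks"` or `"formula"`.
#' @return `data.frame` with one row per cell: `cell_id`, `nuc_area`,
#'   `cyt_area`, `rid_nuc`, `rid_cyt`, `mean_nuc`, `mean_cyt`,
#'   `nc_ratio`. In formula mode `cyt_area`/`rid_cyt` refer to the whole
#'   cell (nucleus + cytoplasm), in masks mode to the cytoplasm only.
#' @export
measureCells <- function(probe, nucLab, cytLab, mode = c("masks", "formula")) {
  mode <- match.arg(mode)
  probe <- as.matrix(probe)
  ids <- sort(intersect(unique(nucLab[nucLab > 0L]),
                        unique(cytLab[cytLab > 0L])))
  rows <- lapply(ids, function(i) {
    nm <- nucLab == i
    cm <- cytLab == i
    ridN <- sum(probe[nm]); areaN <- sum(nm)
    ridC <- sum(probe[cm]); areaC <- sum(cm)
    meanN <- ridN / areaN; meanC <- ridC / areaC
    if (mode == "masks") {
      data.frame(cell_id = i, nuc_area = areaN, cyt_area = areaC,
                 rid_nuc = ridN, rid_cyt = ridC, mean_nuc = meanN,
                 mean_cyt = meanC, nc_ratio = meanN / meanC)
    } else {
      ridW <- ridN + ridC; areaW <- areaN + areaC
      data.frame(cell_id = i, nuc_area = areaN, cyt_area = areaW,
                 rid_nuc = ridN, rid_cyt = ridW, mean_nuc = meanN,
                 mean_cyt = ridC / areaC,
                 nc_ratio = ncRatioFormula(ridN, areaN, ridW, areaW))
    }
  })
  if (!length(rows))
    return(data.frame(cell_id = integer(), nuc_area = integer(),
                      cyt_area = integer(), rid_nuc = numeric(),
                      rid_cyt = numeric(), mean_nuc = numeric(),
                      mean_cyt = numeric(), nc_ratio = numeric()))
  do.call(rbind, rows)
}

#' Group statistics on per-cell N/C ratios
#'
#' `"dunnett"` runs a one-way ANOVA followed by Dunnett's multiple
#' comparisons of every group against the control (multivariate-t
#' adjusted p-values); `"ttest"` runs the classical unpaired two-tailed
#' two-sample Student's t test (pooled variance) on exactly two groups.
#'
#' @param ratiosByGroup named list of numeric vectors (>= 3 observations
#'   per group); the control group is named by `control` (default: first
#'   element).
#' @param test `"dunnett"` or `"ttest"`.
#' @param control control group name, for Dunnett.
#' @return `data.frame` with columns `comparison`, `estimate`, `p_value`.
#' @export
groupStats <- function(ratiosByGroup, test = c("dunnett", "ttest"),
                       control = names(ratiosByGroup)[1]) {
  test <- match.arg(test)
  stopifnot(is.list(ratiosByGroup), !is.null(names(ratiosByGroup)))
  if (any(vapply(ratiosByGroup, length, 0L) < 3L))
    stop("each group needs >= 3 observations")
  if (any(vapply(ratiosByGroup, stats::sd, 0) == 0))
    stop("zero-variance group")
  if (test == "ttest") {
    if (length(ratiosByGroup) != 2L)
      stop("t test needs exactly 2 groups")
    tt <- stats::t.test(ratiosByGroup[[2]], ratiosByGroup[[1]],
                        var.equal = TRUE)
    return(data.frame(
      comparison = paste(names(ratiosByGroup)[2], "-",
                         names(ratiosByGroup)[1]),
      estimate = unname(tt$estimate[1] - tt$estimate[2]),
      p_value = tt$p.value))
  }
  if (length(ratiosByGroup) < 2L)
    stop("Dunnett needs >= 2 groups")
  grp <- factor(rep(names(ratiosByGroup),
                    vapply(ratiosByGroup, length, 0L)),
                levels = c(control,
                           setdiff(names(ratiosByGroup), control)))
  val <- unlist(ratiosByGroup, use.names = FALSE)
  fit <- stats::aov(val ~ grp, data = data.frame(val = val, grp = grp))
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett"))
  sm <- summary(gl)
  data.frame(comparison = names(sm$test$coefficients),
             estimate = as.numeric(sm$test$coefficients),
             p_value = as.numeric(sm$test$pvalues))
}
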