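test_that("median-of-ratios factors match hand computation and symmetry", {
  # hand computation: geometric means (sqrt(8), sqrt(32)); ratios per
  # sample (2/sqrt8, 4/sqrt32) = 1/sqrt2 and (4/sqrt8, 8/sqrt32) = sqrt2
  m <- matrix(c(2, 4, 4, 8), nrow = 2)
  expect_equal(estimateSizeFactorsMoR(m), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # identical columns give unit factors
  m2 <- matrix(c(5, 9, 13, 5, 9, 13), nrow = 3)
  expect_equal(estimateSizeFactorsMoR(m2), c(1, 1))

  # doubling one column doubles that column's factor relative to the
  # others (the shared geometric-mean reference absorbs a 2^(1/m) shift,
  # so factor ratios — not raw factors — carry the scale)
  set.seed(3)
  m3 <- matrix(rpois(40, 50) + 1, nrow = 10)
  f3 <- estimateSizeFactorsMoR(m3)
  m3b <- m3; m3b[, 2] <- 2 * m3[, 2]
  f3b <- estimateSizeFactorsMoR(m3b)
  expect_equal((f3b[2] / f3b[1]) / (f3[2] / f3[1]), 2, tolerance = 1e-12)
  expect_equal(f3b[-2] / f3[-2], rep(2^(-1 / 4), 3), tolerance = 1e-12)

  # zero-containing genes are excluded from the median
  m4 <- rbind(c(0, 100), m3)
  expect_equal(estimateSizeFactorsMoR(m4), estimateSizeFactorsMoR(m3))
  expect_error(estimateSizeFactorsMoR(matrix(c(0, 1, 1, 0), 2)),
               "pseudo-reference")
})

test_that("size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(13)
  m <- matrix(rnbinom(600, mu = 80, size = 10) + 1, ncol = 6)
  ours <- unname(estimateSizeFactorsMoR(m))
  theirs <- unname(DESeq2::estimateSizeFactorsForMatrix(m))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("base means equal brute-force normalized means", {
  set.seed(23)
  m <- matrix(rpois(60, 30) + 1, nrow = 10)
  sf <- estimateSizeFactorsMoR(m)
  bm <- baseMeans(m, sf)
  oracle <- sapply(seq_len(nrow(m)), function(g) mean(m[g, ] / sf))
  expect_equal(unname(bm), oracle)
  expect_equal(unname(baseMeans(matrix(c(10, 30), 1), c(1, 1))), 20)
  expect_equal(unname(baseMeans(matrix(0, 1, 4), rep(1, 4))), 0)
})

test_that("depth filters honor their boundary rules", {
  design <- data.frame(sample_id = c("c1", "c2", "n1"),
                       fraction = c("cytosol", "cytosol", "nucleus"),
                       condition = c("control", "control", "control"),
                       replicate = c(1L, 2L, 1L))
  m <- rbind(gA = c(19, 25, 100),   # one cytosolic control below 20
             gB = c(20, 20, 0),     # exactly at the threshold
             gC = c(21, 40, 5))
  colnames(m) <- design$sample_id
  keep <- depthFilter(m, design, mode = "cyto_control_ge", threshold = 20)
  expect_equal(unname(keep), c(FALSE, TRUE, TRUE))
  keepMean <- depthFilter(m, design, mode = "cyto_control_ge",
                          threshold = 20, scope = "mean")
  expect_equal(unname(keepMean), c(TRUE, TRUE, TRUE))

  # base-mean mode is strictly greater-than
  m2 <- rbind(g1 = c(20, 20), g2 = c(20.5, 20.5))
  keep2 <- depthFilter(m2, mode = "base_mean_gt", threshold = 20,
                       sizeFactors = c(1, 1))
  expect_equal(unname(keep2), c(FALSE, TRUE))

  expect_error(depthFilter(m, design[3, ], mode = "cyto_control_ge"),
               "no cytosol/control")
})

test_that("depth filter matches a brute-force oracle on random matrices", {
  set.seed(33)
  n <- 1000
  design <- data.frame(
    sample_id = c("c1", "c2", "t1", "t2"),
    fraction = "cytosol",
    condition = c("control", "control", "treated", "treated"),
    replicate = c(1L, 2L, 1L, 2L))
  # depths spanning the boundary, with exact-20 values well represented
  m <- matrix(rnbinom(n * 4, mu = 21, size = 3), ncol = 4,
              dimnames = list(sprintf("g%04d", 1:n), design$sample_id))
  got <- depthFilter(m, design, mode = "cyto_control_ge", threshold = 20)
  oracle <- vapply(seq_len(n),
                   function(g) m[g, "c1"] >= 20 && m[g, "c2"] >= 20,
                   logical(1))
  expect_identical(unname(got), oracle)
  expect_gt(sum(m[, c("c1", "c2")] == 20), 0)  # boundary actually exercised
})

test_that("log2 fold changes behave under scaling and recover simulations", {
  # treated 80 vs control 20, equal factors, zero pseudocount: exactly 2
  m <- matrix(c(20, 20, 80, 80), nrow = 1)
  cond <- c("control", "control", "treated", "treated")
  expect_equal(unname(log2FoldChange(m, rep(1, 4), cond, pseudocount = 0)), 2)
  # treated == control: exactly 0
  m0 <- matrix(c(50, 50, 50, 50), nrow = 1)
  expect_equal(unname(log2FoldChange(m0, rep(1, 4), cond)), 0)

  # invariance: rescaling one sample shifts its factor (relative to the
  # rest) by the same amount and leaves every LFC unchanged
  set.seed(43)
  mm <- matrix(rnbinom(400, mu = 100, size = 10) + 1, ncol = 4)
  sf <- estimateSizeFactorsMoR(mm)
  l1 <- log2FoldChange(mm, sf, cond, pseudocount = 0)
  mm2 <- mm; mm2[, 3] <- mm2[, 3] * 5
  sf2 <- estimateSizeFactorsMoR(mm2)
  expect_equal((sf2[3] / sf2[1]) / (sf[3] / sf[1]), 5, tolerance = 1e-12)
  expect_equal(log2FoldChange(mm2, sf2, cond, pseudocount = 0), l1,
               tolerance = 1e-12)

  expect_error(log2FoldChange(mm[, 1:2], sf[1:2], rep("control", 2)),
               "treated")
})

test_that("an 8.6-fold nuclear enrichment is recovered within sampling error", {
  set.seed(53)
  reps <- 60  # replicates to estimate the SE empirically
  lfcHat <- replicate(reps, {
    ctrl <- rnbinom(2, mu = 1e4, size = 1 / 0.05)
    trt <- rnbinom(2, mu = 8.6e4, size = 1 / 0.05)
    log2((mean(trt) + 0.5) / (mean(ctrl) + 0.5))
  })
  se <- sd(lfcHat) / sqrt(1)  # SE of a single estimate
  expect_lt(abs(mean(lfcHat) - log2(8.6)), 3 * se / sqrt(reps) + 0.05)
  # and any single estimate is typically within 3 SE
  expect_gt(mean(abs(lfcHat - log2(8.6)) < 3 * se), 0.95)
})

test_that("NB Wald test is calibrated under the null and powered under effects", {
  set.seed(63)
  n <- 2000
  mu <- rlnorm(n, log(100), 1)
  cnt <- sapply(1:4, function(j) rnbinom(n, mu = mu, size = 1 / 0.05))
  cond <- rep(c("control", "treated"), each = 2)
  res <- nbWaldTest(cnt, rep(1, 4), cond)
  t1 <- mean(res$p_value < 0.05)
  expect_gte(t1, 0.03); expect_lte(t1, 0.07)

  # identical treated/control counts: statistic 0, p 1
  same <- matrix(c(40, 40, 40, 40), nrow = 1)
  r0 <- nbWaldTest(same, rep(1, 4), cond)
  expect_equal(r0$stat, 0)
  expect_equal(r0$p_value, 1)

  # strong effect: LFC 3 at mean 100 detected at p < 1e-3
  c0 <- sapply(1:2, function(j) rnbinom(n, mu = 100, size = 20))
  c1 <- sapply(1:2, function(j) rnbinom(n, mu = 800, size = 20))
  rp <- nbWaldTest(cbind(c0, c1), rep(1, 4), cond)
  expect_gt(mean(rp$p_value < 1e-3), 0.9)

  expect_error(nbWaldTest(cnt, rep(1, 4), rep("control", 4)), "degenerate")
})

test_that("permutation test option gives valid p-values on tiny designs", {
  set.seed(73)
  cnt <- matrix(rnbinom(400, mu = 50, size = 10), ncol = 4)
  cond <- rep(c("control", "treated"), each = 2)
  res <- nbWaldTest(cnt, rep(1, 4), cond, method = "permutation")
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  # the observed labeling is always included: minimum attainable p = 1/6
  expect_gte(min(res$p_value), 1 / 6 - 1e-12)
})

test_that("BH adjustment equals brute-force step-up exactly", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  set.seed(83)
  for (i in 1:5) {
    p <- runif(sample(3:200, 1))
    expect_equal(bhAdjust(p), bruteBH(p), tolerance = 1e-15)
  }
  p <- runif(50)
  expect_true(all(bhAdjust(p) >= p))
  expect_error(bhAdjust(c(0.1, NA)), "NA")
})

test_that("consistency calls require threshold and sign in every replicate", {
  expect_equal(unname(consistencyCall(cbind(0.8, 0.9))), "up")
  expect_equal(unname(consistencyCall(cbind(0.8, -0.9))), "none")
  expect_equal(unname(consistencyCall(cbind(0.8, 0.7))), "none")
  expect_equal(unname(consistencyCall(cbind(-0.76, -2))), "down")
  # boundary: exactly 0.75 is not strictly greater
  expect_equal(unname(consistencyCall(cbind(0.75, 2))), "none")
  expect_error(consistencyCall(matrix(1, 1, 1)), "replicate")

  # brute-force oracle over random replicate pairs incl. boundary values
  set.seed(93)
  lfc <- matrix(sample(c(-2, -0.76, -0.75, 0, 0.75, 0.76, 2), 2000,
                       replace = TRUE), ncol = 2)
  got <- consistencyCall(lfc)
  oracle <- apply(lfc, 1, function(x)
    if (all(x > 0.75)) "up" else if (all(x < -0.75)) "down" else "none")
  expect_identical(unname(got), oracle)
})

test_that("amino-acid distributions are per-sample fractions", {
  m <- rbind(c(30, 10), c(45, 10), c(25, 80))
  iso <- c("Lys", "Lys", "Ala")
  d <- aaDistribution(m, iso)
  expect_equal(colSums(d), c(1, 1))
  expect_equal(unname(d["Lys", 1]), 0.75)
  expect_equal(unname(d["Ala", 2]), 0.8)
  # single-isotype degenerate case
  expect_equal(unname(aaDistribution(m[1:2, , drop = FALSE],
                                     c("Lys", "Lys"))[1, ]), c(1, 1))
  expect_error(aaDistribution(m, c("Lys", "Xyz", "Ala")), "unknown isotype")

  # brute-force group-by oracle
  set.seed(103)
  mm <- matrix(rpois(210, 40), nrow = 30)
  iso2 <- sample(c("Ala", "Gly", "Sec"), 30, replace = TRUE)
  d2 <- aaDistribution(mm, iso2)
  for (a in unique(iso2))
    expect_equal(unname(d2[a, ]),
                 unname(colSums(mm[iso2 == a, , drop = FALSE]) / colSums(mm)))
})

test_that("row clustering is deterministic and permutation-invariant", {
  m <- rbind(a = c(0, 0), b = c(0.1, 0), c = c(5, 5))
  ord <- clusterRowOrder(m)
  # the outlier joins last: it sits alone at one end of the leaf order
  expect_true(ord[1] == 3 || ord[length(ord)] == 3)

  set.seed(113)
  mm <- matrix(rnorm(40), nrow = 8,
               dimnames = list(letters[1:8], NULL))
  o1 <- clusterRowOrder(mm)
  perm <- sample(8)
  o2 <- clusterRowOrder(mm[perm, ])
  # same dendrogram topology: merge heights identical
  h1 <- stats::hclust(stats::dist(mm), "complete")$height
  h2 <- stats::hclust(stats::dist(mm[perm, ]), "complete")$height
  expect_equal(h1, h2)
  expect_setequal(rownames(mm)[o1], rownames(mm[perm, ])[o2])

  expect_error(clusterRowOrder(rbind(c(1, NA), c(0, 1))), "non-finite")
  # identical rows end up adjacent
  m3 <- rbind(x = c(1, 1), y = c(9, 9), z = c(1, 1))
  o3 <- clusterRowOrder(m3)
  expect_equal(abs(diff(match(c(1, 3), o3))), 1)
})

test_that("localization table integrates filters, tests and calls", {
  genes <- simulateTrnaGenes(n = 40, seed = 123)
  lfcN <- numeric(40); lfcN[5] <- 3
  d <- simDesign(genes, depth = 3e4, seed = 5, lfcNucleus = lfcN,
                 lfcCytosol = numeric(40))
  sim <- simulateReads(d)
  ref <- buildTruncationSet(genes, 13)
  vc <- profileSamples(sim$reads, sim$samples, ref)
  tab <- localizationTable(vc)
  expect_equal(nrow(tab), 40 * 2)
  expect_true(all(tab$variant_class %in% c("intact", "defective")))
  expect_true(all(tab$adj_p_nucleus >= tab$p_nucleus - 1e-15))
  expect_true(all(tab$p_nucleus > 0 & tab$p_nucleus <= 1))
  # the planted gene is detected in the nucleus
  hot <- tab[tab$gene_id == geneIds(genes)[5], ]
  expect_true(any(hot$call_nucleus == "up"))
  expect_true(all(tab$call_cytosol[tab$gene_id != geneIds(genes)[5]] %in%
                    c("none", "up", "down")))
})
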