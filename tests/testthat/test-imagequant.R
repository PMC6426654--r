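test_that("nuclei segmentation applies threshold, dilation and particle filter", {
  img <- matrix(0.05, 200, 200)
  img <- paintDisk(img, 60, 60, 26, 0.9)    # area ~2124 px
  nuc <- segmentNuclei(img)
  expect_equal(max(nuc), 1L)

  # a 300 px particle falls below the 500 px filter
  small <- paintDisk(matrix(0.05, 200, 200), 100, 100, 9.7, 0.9)  # ~295 px
  expect_equal(max(segmentNuclei(small)), 0L)

  # two separated disks: both found, areas match the morphological oracle
  two <- matrix(0.05, 300, 300)
  two <- paintDisk(two, 80, 80, 30, 0.9)
  two <- paintDisk(two, 205, 205, 30, 0.9)
  lab <- segmentNuclei(two)
  expect_equal(max(lab), 2L)
  truthMask <- paintDisk(matrix(0L, 300, 300), 80, 80, 30, 1L)
  oracle <- EBImage::fillHull(
    EBImage::dilate(truthMask, EBImage::makeBrush(3, "box"))) > 0
  expect_equal(sum(lab == 1), sum(oracle))
  expect_lt(abs(sum(lab == 1) / sum(truthMask) - 1), 0.10)

  # border-touching particles are excluded
  edge <- paintDisk(matrix(0.05, 200, 200), 5, 100, 26, 0.9)
  expect_equal(max(segmentNuclei(edge)), 0L)

  # constant image: zero nuclei with a warning
  expect_warning(z <- segmentNuclei(matrix(0.3, 50, 50)), "constant")
  expect_equal(max(z), 0L)
})

test_that("particles under 500 px never survive on random blob images", {
  set.seed(17)
  for (rep in 1:3) {
    img <- matrix(0.05, 250, 250)
    rads <- sample(6:24, 6)
    cx <- sample(40:210, 6); cy <- sample(40:210, 6)
    for (i in 1:6) img <- paintDisk(img, cx[i], cy[i], rads[i], 0.9)
    lab <- segmentNuclei(img)
    if (max(lab) > 0) {
      areas <- tabulate(lab[lab > 0])
      expect_true(all(areas >= 500))
    }
    # oracle: labeling the dilated/filled truth by brute force
    bw <- img > 0.5
    oracleLab <- EBImage::bwlabel(EBImage::fillHull(
      EBImage::dilate(bw, EBImage::makeBrush(3, "box"))))
    oracleAreas <- tabulate(oracleLab[oracleLab > 0])
    touching <- unique(c(oracleLab[1, ], oracleLab[250, ],
                         oracleLab[, 1], oracleLab[, 250]))
    okComponents <- setdiff(which(oracleAreas >= 500), touching)
    expect_equal(max(lab), length(okComponents))
  }
})

test_that("non-merging dilation grows components without fusing them", {
  # two bars 3 px apart stay separate through 2 iterations
  lab <- matrix(0L, 30, 30)
  lab[10:20, 10] <- 1L
  lab[10:20, 14] <- 2L
  out <- dilateNoMerge(lab, 2)
  expect_equal(sort(unique(out[out > 0])), c(1L, 2L))
  # grown masks remain disjoint and strictly larger
  expect_gt(sum(out == 1), sum(lab == 1))
  expect_gt(sum(out == 2), sum(lab == 2))

  # property: component count preserved on random label images
  set.seed(27)
  for (rep in 1:5) {
    img <- matrix(0.05, 120, 120)
    for (i in 1:4)
      img <- paintDisk(img, sample(20:100, 1), sample(20:100, 1),
                       sample(4:9, 1), 0.9)
    lab2 <- EBImage::bwlabel(img > 0.5)
    before <- max(lab2)
    after <- dilateNoMerge(lab2, 2)
    expect_equal(length(unique(after[after > 0])), before)
    # every original pixel keeps its label
    expect_true(all(after[lab2 > 0] == lab2[lab2 > 0]))
  }

  # support constraint: claims never leave the support
  sup <- matrix(FALSE, 30, 30); sup[, 1:12] <- TRUE
  constrained <- dilateNoMerge(lab, 2, support = sup)
  expect_true(all(constrained[lab == 0 & !sup] == 0))  # no growth off-support
  expect_true(all(constrained[lab > 0] == lab[lab > 0]))
})

test_that("cytoplasm segmentation matches cells to nuclei and drops orphans", {
  img <- simulateImages(nCells = 3, ratio = 2, noiseSd = 0, seed = 33)
  nuc <- segmentNuclei(img$dapi)
  expect_equal(max(nuc), 3L)
  cyt <- segmentCytoplasm(img$probe, nuc)
  expect_setequal(unique(cyt[cyt > 0]), 1:3)
  # cytoplasm excludes nucleus pixels
  expect_equal(sum(cyt > 0 & nuc > 0), 0L)

  # a nucleus with no surrounding probe signal is dropped
  dapi <- paintDisk(matrix(0.05, 220, 220), 60, 60, 16, 0.9)
  dapi <- paintDisk(dapi, 150, 150, 16, 0.9)
  probe <- matrix(0.02, 220, 220)
  ri <- matrix(seq_len(220), 220, 220)
  ci <- t(ri)
  ring <- (ri - 60)^2 + (ci - 60)^2 <= 30^2 &
    (ri - 60)^2 + (ci - 60)^2 > 17^2
  probe[ring] <- 0.3
  n2 <- segmentNuclei(dapi)
  expect_equal(max(n2), 2L)
  expect_warning(c2 <- segmentCytoplasm(probe, n2), "dropped")
  expect_setequal(unique(c2[c2 > 0]), 1L)
})

test_that("adjacent cells remain separate after non-merge dilation", {
  # two cytoplasm blobs 3 px apart around two nuclei
  dapi <- matrix(0.02, 160, 240)
  probe <- matrix(0.02, 160, 240)
  dapi <- paintDisk(dapi, 80, 70, 14, 0.9)
  dapi <- paintDisk(dapi, 80, 140, 14, 0.9)
  ri <- matrix(seq_len(160), 160, 240)
  ci <- matrix(seq_len(240), 160, 240, byrow = TRUE)
  blob1 <- (ri - 80)^2 + (ci - 70)^2 <= 33^2
  blob2 <- (ri - 80)^2 + (ci - 140)^2 <= 33^2
  probe[blob1 | blob2] <- 0.3
  nuc <- segmentNuclei(dapi)
  cyt <- segmentCytoplasm(probe, nuc)
  expect_equal(max(nuc), 2L)
  expect_setequal(unique(cyt[cyt > 0]), 1:2)
  # the two cytoplasms never touch 8-connectedly
  both <- matrix(0L, 160, 240)
  both[cyt == 1] <- 1L; both[cyt == 2] <- 2L
  grown1 <- dilateNoMerge(matrix(as.integer(cyt == 1), 160, 240), 1)
  expect_equal(sum(grown1 > 0 & cyt == 2), 0L)
})

test_that("mask-based N/C ratio is a ratio of means with scale invariance", {
  probe <- matrix(2, 40, 40)
  nm <- matrix(FALSE, 40, 40); nm[10:15, 10:15] <- TRUE
  cm <- matrix(FALSE, 40, 40); cm[25:35, 25:35] <- TRUE
  expect_equal(ncRatioMasks(probe, nm, cm), 1)

  probe[nm] <- 20; probe[cm] <- 5
  expect_equal(ncRatioMasks(probe, nm, cm), 4)
  expect_equal(ncRatioMasks(probe * 7.3, nm, cm), 4)

  expect_error(ncRatioMasks(probe, nm, matrix(FALSE, 40, 40)), "empty")
  expect_error(ncRatioMasks(probe, nm, nm), "overlap")
})

test_that("formula-mode N/C follows the printed equation and equals mask mode", {
  expect_equal(ncRatioFormula(500, 50, 1500, 150), 1)
  expect_equal(ncRatioFormula(100, 10, 200, 30), 2)
  expect_error(ncRatioFormula(100, 10, 200, 10), "areaCyt")
  expect_error(ncRatioFormula(300, 10, 200, 30), "ridCyt")

  # algebraic identity on exact synthetic cells
  img <- simulateImages(nCells = 6, ratio = 3, noiseSd = 0, seed = 44)
  nuc <- segmentNuclei(img$dapi)
  cyt <- segmentCytoplasm(img$probe, nuc)
  mMask <- measureCells(img$probe, nuc, cyt, mode = "masks")
  mForm <- measureCells(img$probe, nuc, cyt, mode = "formula")
  expect_equal(mForm$nc_ratio, mMask$nc_ratio, tolerance = 1e-12)
  # direct check against hand-evaluated formula inputs
  i <- 1
  expect_equal(mForm$nc_ratio[i],
               ncRatioFormula(mForm$rid_nuc[i], mForm$nuc_area[i],
                              mForm$rid_cyt[i], mForm$cyt_area[i]))
})

test_that("end-to-end N/C recovery hits truth across ratios and SNR", {
  for (r in c(1, 2, 4)) {
    img <- simulateImages(nCells = 10, ratio = r, noiseSd = 0.02, seed = 55)
    nuc <- segmentNuclei(img$dapi)
    cyt <- segmentCytoplasm(img$probe, nuc)
    m <- measureCells(img$probe, nuc, cyt)
    expect_equal(nrow(m), 10)
    expect_lt(abs(median(m$nc_ratio) / r - 1), 0.10)
  }
  # exact recovery at ratio 1 without noise
  img0 <- simulateImages(nCells = 2, ratio = 1, noiseSd = 0, seed = 66)
  n0 <- segmentNuclei(img0$dapi)
  c0 <- segmentCytoplasm(img0$probe, n0)
  expect_equal(measureCells(img0$probe, n0, c0)$nc_ratio, c(1, 1),
               tolerance = 1e-6)
})

test_that("group statistics: t test and Dunnett behave canonically", {
  g1 <- c(1.0, 1.1, 0.9, 1.05, 0.95)
  # identical groups: statistic 0, p = 1
  same <- groupStats(list(ctrl = g1, trt = g1), test = "ttest")
  expect_equal(same$p_value, 1)
  expect_equal(same$estimate, 0)

  set.seed(77)
  a <- rnorm(10, 1, 0.1); b <- rnorm(10, 2, 0.1)
  tt <- groupStats(list(ctrl = a, trt = b), test = "ttest")
  expect_equal(tt$p_value, stats::t.test(b, a, var.equal = TRUE)$p.value)

  # Dunnett with a single comparison reduces to the two-sample t test
  dn <- groupStats(list(ctrl = a, trt = b), test = "dunnett")
  expect_equal(dn$p_value, tt$p_value, tolerance = 1e-6)

  # three groups: one clear shift flagged, null group not
  cc <- rnorm(12, 1, 0.1); t1 <- rnorm(12, 1, 0.1); t2 <- rnorm(12, 1.8, 0.1)
  d3 <- groupStats(list(ctrl = cc, lo = t1, hi = t2), test = "dunnett")
  expect_equal(nrow(d3), 2)
  expect_gt(d3$p_value[d3$comparison == "lo - ctrl"], 0.05)
  expect_lt(d3$p_value[d3$comparison == "hi - ctrl"], 1e-6)

  expect_error(groupStats(list(a = 1:2, b = 3:4), "ttest"), ">= 3")
  expect_error(groupStats(list(a = rep(1, 5), b = c(1, 2, 3, 4, 5)), "ttest"),
               "zero-variance")
})

test_that("Dunnett family-wise error is controlled on null simulations", {
  set.seed(87)
  nrep <- 400
  hits <- replicate(nrep, {
    g <- list(ctrl = rnorm(8), a = rnorm(8), b = rnorm(8))
    any(groupStats(g, test = "dunnett")$p_value < 0.05)
  })
  fwer <- mean(hits)
  expect_gte(fwer, 0.03); expect_lte(fwer, 0.07)
})
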