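panel <- defaultLipidPanel()
prof <- lipidomeProfiles()

processSection <- function(condition = "GBM", treatment = "vehicle",
                           grid = c(30, 30), sigma = 0.3, seed = 21,
                           regionCompositions = NULL, roiFraction = 0.2,
                           backgroundFraction = 0.2) {
  spec <- sectionSpec(condition, treatment, grid = grid, seed = seed,
                      regionCompositions = regionCompositions,
                      roiFraction = roiFraction,
                      backgroundFraction = backgroundFraction)
  sec <- simulateSection(spec, prof, panel, "negative",
                         noiseSigma = sigma, jitterPpm = 3, seed = seed)
  e <- suppressMessages(ticNormalize(annotatePeaks(sec, panel, 9)))
  list(section = sec, experiment = filterBackground(e))
}

test_that("background filtration recovers planted matrix pixels", {
  ps <- processSection(seed = 21)
  cd <- SummarizedExperiment::colData(ps$experiment)
  truth <- sectionMetadata(ps$section)$region_labels
  ## pixels surviving into the experiment, matched by coordinates
  key <- paste(pixelCoords(ps$section)[, 1], pixelCoords(ps$section)[, 2])
  truthKept <- truth[match(paste(cd$x, cd$y), key)]
  ## planted background is either dropped at normalization or flagged
  nBgTotal <- sum(truth == 0)
  nBgCaught <- (nBgTotal - sum(truthKept == 0)) + sum(cd$background & truthKept == 0)
  expect_gte(nBgCaught / nBgTotal, 0.95)
  ## no tissue pixel is flagged background
  expect_equal(sum(cd$background & truthKept > 0), 0)
  expect_error(filterBackground(ps$experiment, frac = 1), "frac")
})

test_that("uniform-TIC data loses no pixels to background filtration", {
  ## all-tissue, noise-free section: every pixel has identical TIC
  ps <- processSection(seed = 22, sigma = 0, backgroundFraction = 0)
  cd <- SummarizedExperiment::colData(ps$experiment)
  expect_equal(sum(cd$background), 0)
  ## frac = 0 limit removes nothing even on noisy data
  ps2 <- processSection(seed = 22, sigma = 0.3, backgroundFraction = 0)
  e0 <- filterBackground(ps2$experiment, frac = 0)
  expect_equal(sum(SummarizedExperiment::colData(e0)$background), 0)
})

test_that("k-means recovers the planted regions at sigma 0.3", {
  ps <- processSection(seed = 23)
  seg <- segmentPixels(ps$experiment, k = 2, seed = 23)
  truth <- sectionMetadata(ps$section)$region_labels
  key <- paste(pixelCoords(ps$section)[, 1], pixelCoords(ps$section)[, 2])
  segKey <- paste(pixelCoords(seg)[, 1], pixelCoords(seg)[, 2])
  truthSeg <- truth[match(segKey, key)]
  ari <- mclust::adjustedRandIndex(truthSeg, segmentLabels(seg))
  expect_gte(ari, 0.9)
  ## reproducible from seed
  seg2 <- segmentPixels(ps$experiment, k = 2, seed = 23)
  expect_identical(segmentLabels(seg), segmentLabels(seg2))
  ## permutation-invariance to feature order
  segP <- segmentPixels(ps$experiment[sample(nrow(ps$experiment)), ],
                        k = 2, seed = 23)
  expect_equal(mclust::adjustedRandIndex(segmentLabels(seg),
                                         segmentLabels(segP)), 1)
})

test_that("silhouette model selection finds a planted 3-region section", {
  ps <- processSection(seed = 24, grid = c(36, 36), sigma = 0.1,
                       roiFraction = 0.3,
                       regionCompositions = c("gbm_vehicle", "healthy_tmz",
                                              "bulk_parenchyma"))
  seg <- segmentPixels(ps$experiment, k = NULL, kRange = 2:6, seed = 24)
  expect_equal(seg@k, 3L)
})

test_that("recovery degrades monotonically with noise", {
  ari_at <- function(sigma) {
    mean(vapply(1:3, function(s) {
      ps <- processSection(seed = 30 + s, sigma = sigma, grid = c(24, 24))
      seg <- segmentPixels(ps$experiment, k = 2, seed = 30 + s)
      truth <- sectionMetadata(ps$section)$region_labels
      key <- paste(pixelCoords(ps$section)[, 1], pixelCoords(ps$section)[, 2])
      segKey <- paste(pixelCoords(seg)[, 1], pixelCoords(seg)[, 2])
      mclust::adjustedRandIndex(truth[match(segKey, key)], segmentLabels(seg))
    }, numeric(1)))
  }
  a0 <- ari_at(0); a3 <- ari_at(0.3); a9 <- ari_at(0.9)
  expect_gte(a0 + 1e-9, a3)
  expect_gte(a3, a9)
})

test_that("Dice coefficient and ROI matching behave on edge cases", {
  expect_equal(diceCoefficient(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE)), 1)
  expect_equal(diceCoefficient(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  ps <- processSection(seed = 25, sigma = 0)
  seg <- segmentPixels(ps$experiment, k = 2, seed = 25)
  seg <- matchROI(seg, roiMask(ps$section), pixelCoords(ps$section))
  truth <- sectionMetadata(ps$section)$region_labels
  key <- paste(pixelCoords(ps$section)[, 1], pixelCoords(ps$section)[, 2])
  segKey <- paste(pixelCoords(seg)[, 1], pixelCoords(seg)[, 2])
  truthSeg <- truth[match(segKey, key)]
  ## the selected cluster is exactly the planted proliferative region
  sel <- segmentLabels(seg) == selectedCluster(seg)
  expect_equal(sel, truthSeg == 1L)
  expect_equal(max(diceTable(seg)$dice), 1)
  expect_error(matchROI(seg, rep(FALSE, 900), pixelCoords(ps$section)),
               "empty")
})
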