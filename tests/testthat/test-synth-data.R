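panel <- defaultLipidPanel()
prof <- lipidomeProfiles()

test_that("packaged composition profiles encode the reported fold changes", {
  sh <- function(arm, pol = "negative")
    unlist(prof$arms[[arm]]$class_shares[[pol]])
  h <- sh("healthy_vehicle"); g <- sh("gbm_vehicle"); t <- sh("healthy_tmz")
  expect_equal(unname(g["PI"] / h["PI"]), 3.6, tolerance = 1e-6)
  expect_equal(unname(g["PE"] / h["PE"]), 1.5, tolerance = 1e-6)
  expect_equal(unname(h["Sulf"] / g["Sulf"]), 2.9, tolerance = 1e-5)
  expect_equal(unname(t["PI"] / h["PI"]), 2.2, tolerance = 1e-6)
  expect_equal(unname(h["Sulf"] / t["Sulf"]), 1.6, tolerance = 1e-5)
  hp <- sh("healthy_vehicle", "positive"); gp <- sh("gbm_vehicle", "positive")
  tp <- sh("healthy_tmz", "positive")
  expect_equal(unname(gp["SM"] / hp["SM"]), 1.8, tolerance = 1e-6)
  expect_equal(unname(hp["HexCer"] / tp["HexCer"]), 1.8, tolerance = 1e-4)
  ## reported species mole fractions
  expect_equal(prof$arms$healthy_vehicle$species_molpct$PE[["36:1"]], 35.6)
  expect_equal(prof$arms$gbm_vehicle$species_molpct$PI[["38:4"]], 75.7)
  expect_equal(prof$arms$healthy_vehicle$species_molpct$PE_P[["36:2"]], 20.8)
})

test_that("resolved profiles are proper mole-fraction/weight distributions", {
  for (arm in names(prof$arms)) for (pol in c("negative", "positive")) {
    w <- resolveProfile(prof, arm, panel, pol)
    expect_true(all(w$fraction >= 0), info = arm)
    expect_equal(sum(w$weight), 1, tolerance = 1e-9, info = arm)
    for (cl in unique(w$class))
      expect_equal(sum(w$fraction[w$class == cl]), 1, tolerance = 1e-9,
                   info = paste(arm, cl))
  }
  expect_error(resolveProfile(prof, "no_such_arm", panel), "unknown")
})

test_that("section geometry assigns every pixel and respects the grid bound", {
  spec <- sectionSpec("healthy", "vehicle", grid = c(24, 30), seed = 5)
  geom <- glioLipidIMS:::sectionGeometry(spec)
  expect_equal(nrow(geom$coords), 24 * 30)
  expect_true(all(geom$labels %in% 0:2))
  expect_equal(mean(geom$labels == 0), spec$backgroundFraction,
               tolerance = 0.01)
  ## region 1 (ROI) is a contiguous compact blob of roiFraction tissue pixels
  expect_equal(sum(geom$labels == 1) / sum(geom$labels > 0),
               spec$roiFraction, tolerance = 0.01)
  expect_error(sectionSpec(grid = c(10, 10)), "at least 20")
})

test_that("noise-free sections reproduce the profile exactly and runs are deterministic", {
  spec <- sectionSpec("GBM", "vehicle", grid = c(24, 24), seed = 2)
  sec <- simulateSection(spec, prof, panel, "negative",
                         noiseSigma = 0, jitterPpm = 0, seed = 2)
  w <- resolveProfile(prof, "gbm_vehicle", panel, "negative")
  labels <- sectionMetadata(sec)$region_labels
  i <- which(labels == 1L)[1]
  pk <- peakList(sec)[[i]]
  expect_equal(pk$mz, w$mz)
  expect_equal(pk$intensity / sum(pk$intensity), w$weight, tolerance = 1e-12)
  sec2 <- simulateSection(spec, prof, panel, "negative",
                          noiseSigma = 0, jitterPpm = 0, seed = 2)
  expect_identical(sec@mz, sec2@mz)
  expect_identical(sec@intensity, sec2@intensity)
  ## different seed changes the draw
  sec3 <- simulateSection(spec, prof, panel, "negative", seed = 3)
  expect_false(identical(sec3@intensity, sec@intensity))
})

test_that("noisy within-class fractions concentrate on the generator value", {
  spec <- sectionSpec("GBM", "vehicle", grid = c(40, 40),
                      backgroundFraction = 0, roiFraction = 0.9, seed = 4)
  sec <- simulateSection(spec, prof, panel, "negative",
                         noiseSigma = 0.3, jitterPpm = 0, seed = 4)
  w <- resolveProfile(prof, "gbm_vehicle", panel, "negative")
  pi_idx <- which(w$class == "PI")
  roi <- which(sectionMetadata(sec)$region_labels == 1L)
  fr <- vapply(roi, function(i) {
    v <- sec@intensity[[i]][pi_idx]
    v[w$species[pi_idx] == "PI 38:4"] / sum(v)
  }, numeric(1))
  expect_equal(mean(fr), 0.757,
               tolerance = 3 * stats::sd(fr) / sqrt(length(fr)) / 0.757 + 0.01)
})

test_that("m/z jitter never exceeds its half-width", {
  spec <- sectionSpec("healthy", "vehicle", grid = c(20, 20), seed = 6)
  sec <- simulateSection(spec, prof, panel, "negative",
                         noiseSigma = 0.2, jitterPpm = 3, seed = 6)
  w <- resolveProfile(prof, "healthy_vehicle", panel, "negative")
  tissue <- which(sectionMetadata(sec)$region_labels > 0)
  for (i in tissue[1:20]) {
    ppm <- 1e6 * (sec@mz[[i]] - w$mz) / w$mz
    expect_lte(max(abs(ppm)), 3)
  }
})

test_that("section TSV round trip preserves peaks and metadata", {
  spec <- sectionSpec("healthy", "TMZ", grid = c(20, 20), seed = 7)
  sec <- simulateSection(spec, prof, panel, "positive", seed = 7)
  path <- tempfile(fileext = ".tsv")
  writeIMSDataset(sec, path)
  back <- readIMSDataset(path)
  expect_equal(back@coords[, 1], sec@coords[, 1])
  expect_equal(unlist(back@mz), unlist(sec@mz), tolerance = 1e-12)
  expect_equal(roiMask(back), roiMask(sec))
  expect_equal(sectionMetadata(back)$condition, "healthy")
})

test_that("expression study plants the documented structure", {
  study <- simulateExpressionStudy(expressionStudySpec(), seed = 11)
  expect_s4_class(study, "ExpressionStudy")
  z <- t(scale(t(exprMatrix(study))))
  ## methylation anticorrelated with expression for coupled genes
  meth <- methylationBetas(study)
  for (pr in rownames(meth)) {
    g <- sub("^cg[0-9]+_", "", pr)
    expect_lt(cor(z[g, ], meth[pr, ]), -0.3)
  }
  ## risk genes: high-expression half has worse survival (log-rank direction)
  surv <- survivalRecords(study)
  lr <- logrankTwoGroups(surv$time, surv$event, z["FABP7", ])
  expect_gt(lr$obs[["high"]], lr$exp[["high"]])
  ## planted module genes are elevated in their subtype
  md <- metadata(study)
  m1 <- md$modules$M1
  cl <- subtypeLabels(study) == "Classical"
  expect_gt(mean(exprMatrix(study)[m1, cl]) -
              mean(exprMatrix(study)[m1, !cl]), 1)
  ## determinism
  study2 <- simulateExpressionStudy(expressionStudySpec(), seed = 11)
  expect_identical(exprMatrix(study), exprMatrix(study2))
})

test_that("zero effect size plants no detectable module structure", {
  study <- simulateExpressionStudy(
    expressionStudySpec(nGenes = 300, samplesPerSubtype = 10,
                        moduleSize = 40, effect = 0), seed = 3)
  mods <- detectModules(study, minSize = 20)
  lab_true <- moduleTruthLabels(study)
  lab_hat <- moduleCallLabels(mods, names(lab_true))
  expect_lt(abs(mclust::adjustedRandIndex(lab_true, lab_hat)), 0.05)
})
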