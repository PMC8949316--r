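panel <- defaultLipidPanel()
prof <- lipidomeProfiles()

tinySection <- function(mzList, intList) {
  n <- length(mzList)
  IMSDataset(coords = cbind(x = seq_len(n), y = rep(1L, n)),
             mz = mzList, intensity = intList,
             metadata = list(polarity = "negative"))
}

test_that("peak alignment merges within tolerance and splits outside it", {
  ds <- tinySection(list(885.550, 885.553), list(1, 1))
  expect_equal(nrow(alignPeaks(ds, tolPpm = 9)$bins), 1L)   # 3.4 ppm apart
  expect_equal(nrow(alignPeaks(ds, tolPpm = 1)$bins), 2L)
  ## consensus m/z is the intensity-weighted mean
  ds2 <- tinySection(list(885.550, 885.553), list(3, 1))
  expect_equal(alignPeaks(ds2, 9)$bins$consensus_mz,
               (3 * 885.550 + 885.553) / 4, tolerance = 1e-9)
  expect_error(alignPeaks(tinySection(list(numeric(0)), list(numeric(0)))),
               "no peaks")
})

test_that("alignment on a jittered synthetic section recovers one bin per species", {
  spec <- sectionSpec("healthy", "vehicle", grid = c(24, 24),
                      backgroundFraction = 0, seed = 8)
  sec <- simulateSection(spec, prof, panel, "negative",
                         noiseSigma = 0.3, jitterPpm = 3, seed = 8)
  aligned <- alignPeaks(sec, tolPpm = 9)
  expect_equal(nrow(aligned$bins), sum(panel$ion_mode == "negative"))
  ## no intensity lost or double-counted
  expect_equal(sum(aligned$peaks$intensity),
               sum(vapply(sec@intensity, sum, numeric(1))))
})

test_that("annotatePeaks builds a per-species feature matrix conserving intensity", {
  spec <- sectionSpec("GBM", "vehicle", grid = c(24, 24),
                      backgroundFraction = 0, seed = 9)
  sec <- simulateSection(spec, prof, panel, "negative",
                         noiseSigma = 0.2, jitterPpm = 3, seed = 9)
  e <- annotatePeaks(sec, panel, tolPpm = 9)
  expect_s4_class(e, "LipidImagingExperiment")
  nneg <- sum(panel$ion_mode == "negative")
  expect_equal(nrow(e), nneg)
  expect_false(anyDuplicated(paste(rownames(e),
                                   SummarizedExperiment::rowData(e)$adduct)) > 0)
  ## every peak annotated here, so column sums equal raw TIC
  expect_equal(colSums(SummarizedExperiment::assay(e, "intensity")),
               unname(SummarizedExperiment::colData(e)$raw_tic),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("TIC normalization is idempotent and drops zero pixels", {
  m <- matrix(c(2, 3, 5, 0, 0, 0), nrow = 3)
  rd <- S4Vectors::DataFrame(species = c("a", "b", "c"), class = "PI",
                             adduct = "M-H", theoretical_mz = 1:3,
                             consensus_mz = 1:3, ppm_error = 0, ambiguous = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = m), rowData = rd,
    colData = S4Vectors::DataFrame(x = 1:2, y = c(1L, 1L),
                                   raw_tic = colSums(m)))
  rownames(se) <- rd$species
  e <- methods::new("LipidImagingExperiment", se)
  expect_message(norm <- ticNormalize(e), "1 zero-TIC")
  expect_equal(ncol(norm), 1L)
  expect_equal(unname(SummarizedExperiment::assay(norm)[, 1]),
               c(0.2, 0.3, 0.5))
  norm2 <- ticNormalize(norm)
  expect_equal(SummarizedExperiment::assay(norm2),
               SummarizedExperiment::assay(norm))
})

test_that("presence filter keeps >=80% features with a ceiling rule and is monotone", {
  ## 5 synthetic one-pixel samples; feature B missing from two of them
  mkExp <- function(int, species) {
    rd <- S4Vectors::DataFrame(species = species, class = "PI", adduct = "M-H",
                               theoretical_mz = seq_along(species),
                               consensus_mz = seq_along(species),
                               ppm_error = 0, ambiguous = FALSE)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(intensity = matrix(int, ncol = 1)), rowData = rd,
      colData = S4Vectors::DataFrame(x = 1L, y = 1L, raw_tic = sum(int)))
    rownames(se) <- species
    methods::new("LipidImagingExperiment", se)
  }
  full <- lapply(1:4, function(i) mkExp(c(1, 1), c("A", "B")))
  partial <- list(mkExp(1, "A"))
  exps <- c(full, partial)
  names(exps) <- paste0("s", 1:5)
  pf <- presenceFilter(exps, threshold = 0.8)      # B in 4/5 -> kept
  expect_setequal(pf$kept, c("A", "B"))
  exps2 <- c(full[1:3], partial, partial)
  names(exps2) <- paste0("s", 1:5)
  pf2 <- presenceFilter(exps2, threshold = 0.8)    # B in 3/5 -> dropped
  expect_equal(pf2$kept, "A")
  expect_equal(pf2$dropped$species, "B")
  ## monotone: raising the threshold never adds features
  for (th in c(0.2, 0.4, 0.6, 0.8, 1)) {
    k_lo <- presenceFilter(exps2, threshold = th)$kept
    for (th2 in seq(th, 1, by = 0.2))
      expect_true(all(presenceFilter(exps2, threshold = th2)$kept %in% k_lo))
  }
  expect_error(presenceFilter(exps2[1]), "at least 2")
})

test_that("the noise-free pipeline reproduces the generating profile row-wise", {
  spec <- sectionSpec("healthy", "vehicle", grid = c(24, 24),
                      backgroundFraction = 0, seed = 10)
  sec <- simulateSection(spec, prof, panel, "negative",
                         noiseSigma = 0, jitterPpm = 0, seed = 10)
  e <- ticNormalize(annotatePeaks(sec, panel, 9))
  labels <- sectionMetadata(sec)$region_labels
  wROI <- resolveProfile(prof, "healthy_vehicle", panel, "negative")
  m <- SummarizedExperiment::assay(e, "intensity")
  idx <- match(wROI$species, rownames(e))
  for (i in which(labels == 1L)[1:5])
    expect_equal(unname(m[idx, i]), wROI$weight, tolerance = 1e-9)
  wBulk <- resolveProfile(prof, "bulk_parenchyma", panel, "negative")
  for (i in which(labels == 2L)[1:5])
    expect_equal(unname(m[idx, i]), wBulk$weight[match(wROI$species, wBulk$species)],
                 tolerance = 1e-9)
})
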