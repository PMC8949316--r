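test_that("sum-composition formulas match the backbone-enumeration oracle", {
  ## spot values derived by explicit atom counting
  expect_equal(lipidFormula("PI", 38, 4),
               c(C = 47L, H = 83L, O = 13L, N = 0L, P = 1L, S = 0L))
  expect_equal(lipidFormula("PE", 34, 0),
               c(C = 39L, H = 78L, O = 8L, N = 1L, P = 1L, S = 0L))
  ## whole default panel against the oracle
  panel <- defaultLipidPanel()
  for (i in seq_len(nrow(panel))) {
    f <- lipidFormula(panel$class[i], panel$carbons[i],
                      panel$double_bonds[i], panel$hydroxylation[i])
    o <- formulaOracle(panel$class[i], panel$carbons[i],
                       panel$double_bonds[i], panel$hydroxylation[i])
    expect_equal(as.integer(f[names(o)]), as.integer(o),
                 info = panel$species[i])
  }
})

test_that("degenerate or inconsistent species are rejected", {
  expect_error(lipidFormula("TG", 0, 0), "unsupported species")
  expect_error(lipidFormula("PE", 34, 0, "d"), "unsupported species")
  expect_error(lipidFormula("SM", 36, 1, "none"), "unsupported species")
  expect_error(lipidFormula("PI", 38, 40), "unsupported species")
})

test_that("theoretical m/z reproduces the PI 38:4 reference and adduct symmetry", {
  mz <- theoreticalMz("PI", 38, 4, adduct = "M-H")
  expect_equal(round(mz, 2), 885.55)
  expect_equal(mz, 885.5499, tolerance = 1e-4)
  ## [M+H]+ - [M-H]- = 2 protons, for any species
  panel <- defaultLipidPanel()
  for (i in sample(nrow(panel), 10)) {
    pos <- theoreticalMz(panel$class[i], panel$carbons[i],
                         panel$double_bonds[i], panel$hydroxylation[i],
                         adduct = "M+H", checkPolarity = FALSE)
    neg <- theoreticalMz(panel$class[i], panel$carbons[i],
                         panel$double_bonds[i], panel$hydroxylation[i],
                         adduct = "M-H", checkPolarity = FALSE)
    expect_equal(pos - neg, 2 * 1.007276, tolerance = 1e-6)
  }
  expect_error(theoreticalMz("PI", 38, 4, adduct = "M+H"), "incompatible")
})

test_that("homologue mass ladders are exact", {
  ## each CH2 adds 14.01565 Da at fixed class/DB
  for (cls in c("PE", "PI", "PC")) {
    m1 <- formulaMass(lipidFormula(cls, 36, 1))
    m2 <- formulaMass(lipidFormula(cls, 38, 1))
    expect_equal(m2 - m1, 2 * 14.01565, tolerance = 1e-5)
  }
  ## each double bond removes 2 H
  expect_equal(formulaMass(lipidFormula("PE", 38, 4)) -
                 formulaMass(lipidFormula("PE", 38, 5)),
               2.015650, tolerance = 1e-5)
  expect_equal(formulaMass(lipidFormula("SM", 42, 1, "d")) -
                 formulaMass(lipidFormula("SM", 42, 2, "d")),
               2.015650, tolerance = 1e-5)
})

test_that("the default panel has the expected scale and layout", {
  panel <- defaultLipidPanel()
  expect_equal(nrow(panel), 124L)
  expect_equal(length(unique(panel$class)), 11L)
  expect_false(is.unsorted(panel$mz))
  expect_false(anyDuplicated(paste(panel$species, panel$adduct)) > 0)
  ## same-polarity species are well separated (unambiguous annotation)
  for (mode in c("negative", "positive")) {
    mz <- sort(panel$mz[panel$ion_mode == mode])
    gaps <- 1e6 * diff(mz) / mz[-length(mz)]
    expect_gt(min(gaps), 70)
  }
})

test_that("buildPanel validates its configuration", {
  expect_equal(nrow(buildPanel(data.frame())), 0L)
  cfg <- data.frame(class = "PC", carbons = 34, double_bonds = 1,
                    hydroxylation = "none", ion_mode = "positive",
                    adduct = c("M+H", "M+Na"))
  expect_equal(nrow(buildPanel(cfg)), 2L)
  expect_error(buildPanel(rbind(cfg, cfg[1, ])), "duplicate")
})

test_that("annotation picks the nearest candidate within tolerance", {
  panel <- defaultLipidPanel("negative")
  ann <- annotateMz(885.552, panel, tolPpm = 9)
  expect_equal(ann$species, "PI 38:4")
  expect_lte(abs(ann$ppm_error), 9)
  expect_false(ann$ambiguous)
  ## too-tight tolerance yields no annotation
  expect_true(is.na(annotateMz(885.552, panel, tolPpm = 0.1)$species))
  ## exact theoretical masses round-trip with zero ppm error
  ann0 <- annotateMz(panel$mz, panel, tolPpm = 9)
  expect_equal(ann0$species, panel$species)
  expect_equal(ann0$ppm_error, rep(0, nrow(panel)))
  expect_error(annotateMz(-1, panel), "positive")
})

test_that("jittered panel masses are re-annotated to their generating species", {
  panel <- defaultLipidPanel("negative")
  withr::with_seed(42, {
    for (rep in 1:3) {
      jit <- panel$mz * (1 + runif(nrow(panel), -3, 3) * 1e-6)
      ann <- annotateMz(jit, panel, tolPpm = 9)
      expect_equal(ann$species, panel$species)
      expect_lte(max(abs(ann$ppm_error)), 9)
    }
  })
})

test_that("species shorthand formats and parses round-trip", {
  panel <- defaultLipidPanel()
  parsed <- parseSpeciesShorthand(panel$species)
  expect_equal(parsed$class, panel$class)
  expect_equal(parsed$carbons, panel$carbons)
  expect_equal(parsed$double_bonds, panel$double_bonds)
  expect_equal(parsed$hydroxylation, panel$hydroxylation)
  expect_equal(speciesShorthand("PE_P", 36, 2), "PE P-36:2")
  expect_error(parseSpeciesShorthand("nonsense"), "unparseable")
})
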