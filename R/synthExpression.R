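GBM_SUBTYPES <- c("Classical", "Mesenchymal", "Proneural", "Neural", "Normal")

## Lipid-enzyme genes planted into subtype-associated modules, mirroring the
## module/subtype assignments reported for TCGA-GBM co-expression analysis.
LIPID_ENZYME_MODULES <- list(
  M1 = list(subtype = "Classical",   genes = c("PLA2G5", "FABP7", "ELOVL2")),
  M2 = list(subtype = "Mesenchymal", genes = c("PLA2G2A", "FABP5", "PTGS2",
                                               "ALOX15B", "ALOX5AP")),
  M3 = list(subtype = "Neural",      genes = c("INPP5F", "DGKB")),
  M4 = list(subtype = "Mesenchymal", genes = character()),
  M5 = list(subtype = "Proneural",   genes = character()),
  M6 = list(subtype = "Proneural",   genes = c("UGT8"))
)

## Methylation probes coupled (anticorrelated) to expression.
METHYLATION_PROBES <- c(PLA2G5 = "cg2433549", FABP7 = "cg18555555",
                        ALOX5AP = "cg08529529")

## Genes whose expression raises the simulated death hazard.
SURVIVAL_RISK_GENES <- c("PLA2G5", "FABP7", "ELOVL2", "PLA2G2A", "ALOX5AP")

#' Specify a synthetic expression/methylation/survival study
#'
#' Defines the generator for a TCGA-like glioblastoma study: a genes x
#' samples expression matrix over the four molecular subtypes plus normal
#' samples, with planted co-expression modules aligned to subtypes,
#' methylation beta values anticorrelated with expression for selected
#' genes, and survival times whose hazard increases with the expression of
#' selected risk genes.
#'
#' Planted module genes follow
#' `expr = effect * ((subtype match) - p + factorScale * activity) + noise`
#' where `activity` is a per-sample module latent factor (centered within
#' subtype groups, so subtype contrasts come only from the planted effect)
#' and `noise` is unit Gaussian: the effect parameter controls both the
#' subtype mean shift (in z-units) and the within-module co-expression
#' strength, so at effect 0 modules are statistically invisible and at the
#' default effect 1.5 within-module correlation is ~0.9.
#'
#' @param nGenes Total genes (module genes plus background).
#' @param samplesPerSubtype Samples per subtype label (scalar or named
#'   vector over Classical, Mesenchymal, Proneural, Neural, Normal; >= 3).
#' @param moduleSize Genes per planted module.
#' @param effect Module effect size in z-units.
#' @param factorScale Scale of the shared module latent factor relative to
#'   the effect (co-expression tightness).
#' @param survivalCoef Per-z log-hazard increment of each risk gene.
#' @param baselineMedianDays Median survival at zero covariates.
#' @param horizonDays Administrative censoring horizon.
#' @param methylationSlope Logistic slope linking expression z to beta.
#' @param methylationNoise SD of Gaussian noise on the logit of beta.
#' @return An `expressionStudySpec` list.
#' @export
expressionStudySpec <- function(nGenes = 600L, samplesPerSubtype = 20L,
                                moduleSize = 40L, effect = 1.5,
                                factorScale = 2, survivalCoef = 0.5,
                                baselineMedianDays = 450,
                                horizonDays = 1800,
                                methylationSlope = 1.5,
                                methylationNoise = 0.5) {
  if (length(samplesPerSubtype) == 1L)
    samplesPerSubtype <- stats::setNames(rep(samplesPerSubtype, 5),
                                         GBM_SUBTYPES)
  if (!all(GBM_SUBTYPES %in% names(samplesPerSubtype)))
    stop("samplesPerSubtype must cover all five subtype labels")
  if (any(samplesPerSubtype < 3L))
    stop("at least 3 samples per subtype are required")
  nMod <- length(LIPID_ENZYME_MODULES)
  if (nGenes < nMod * moduleSize)
    stop("nGenes too small for ", nMod, " modules of ", moduleSize)
  structure(list(nGenes = as.integer(nGenes),
                 samplesPerSubtype = samplesPerSubtype,
                 moduleSize = as.integer(moduleSize), effect = effect,
                 factorScale = factorScale, survivalCoef = survivalCoef,
                 baselineMedianDays = baselineMedianDays,
                 horizonDays = horizonDays,
                 methylationSlope = methylationSlope,
                 methylationNoise = methylationNoise),
            class = "expressionStudySpec")
}

#' Simulate an expression/methylation/survival study
#'
#' @param spec An [expressionStudySpec()].
#' @param seed Integer seed for all random draws.
#' @return An [ExpressionStudy-class]; `metadata(study)` carries the planted
#'   module truth (`modules`, `module_subtype`).
#' @export
#' @examples
#' study <- simulateExpressionStudy(expressionStudySpec(), seed = 1)
simulateExpressionStudy <- function(spec = expressionStudySpec(), seed = 1L) {
  nMod <- length(LIPID_ENZYME_MODULES)
  nModGenes <- nMod * spec$moduleSize
  subtype <- factor(rep(GBM_SUBTYPES, spec$samplesPerSubtype[GBM_SUBTYPES]),
                    levels = GBM_SUBTYPES)
  ns <- length(subtype)
  samples <- sprintf("TCGA.S%03d", seq_len(ns))

  ## gene names: planted enzymes keep their symbols, rest are G####
  genes <- sprintf("G%04d", seq_len(spec$nGenes))
  moduleTruth <- list()
  g <- 0L
  for (m in names(LIPID_ENZYME_MODULES)) {
    idx <- g + seq_len(spec$moduleSize)
    sym <- LIPID_ENZYME_MODULES[[m]]$genes
    if (length(sym)) genes[idx[seq_along(sym)]] <- sym
    moduleTruth[[m]] <- idx
    g <- g + spec$moduleSize
  }

  withSeed(seed, {
    expr <- matrix(stats::rnorm(spec$nGenes * ns), spec$nGenes, ns,
                   dimnames = list(genes, samples))
    for (m in names(LIPID_ENZYME_MODULES)) {
      st <- LIPID_ENZYME_MODULES[[m]]$subtype
      p <- mean(subtype == st)
      ## latent module activity, centered within subtype groups so that
      ## subtype contrasts are carried only by the planted effect term
      fac <- stats::rnorm(ns)
      fac <- fac - stats::ave(fac, subtype)
      signal <- spec$effect *
        ((subtype == st) - p + spec$factorScale * fac)
      expr[moduleTruth[[m]], ] <- expr[moduleTruth[[m]], , drop = FALSE] +
        matrix(signal, spec$moduleSize, ns, byrow = TRUE)
    }

    z <- t(scale(t(expr)))

    ## methylation: coupled probes anticorrelated with expression
    coupled <- METHYLATION_PROBES[names(METHYLATION_PROBES) %in% genes]
    meth <- matrix(numeric(0), 0, ns, dimnames = list(NULL, samples))
    if (length(coupled)) {
      rows <- lapply(names(coupled), function(gn)
        stats::plogis(-spec$methylationSlope * z[gn, ] +
                        stats::rnorm(ns, 0, spec$methylationNoise)))
      meth <- do.call(rbind, rows)
      rownames(meth) <- paste0(coupled, "_", names(coupled))
    }

    ## survival: exponential hazard scaled by risk-gene expression
    risk <- intersect(SURVIVAL_RISK_GENES, genes)
    lp <- if (length(risk))
      colSums(z[risk, , drop = FALSE] * spec$survivalCoef) else rep(0, ns)
    rate0 <- log(2) / spec$baselineMedianDays
    t_raw <- stats::rexp(ns, rate = rate0 * exp(lp))
    event <- as.integer(t_raw <= spec$horizonDays)
    time <- pmin(t_raw, spec$horizonDays)
    dss_censor <- stats::runif(ns) < 0.1
    surv <- data.frame(sample = samples, time = time, event = event,
                       event_dss = as.integer(event == 1L & !dss_censor),
                       subtype = as.character(subtype),
                       stringsAsFactors = FALSE)

    geneInfo <- S4Vectors::DataFrame(
      gene = genes,
      lipid_enzyme = genes %in% unlist(lapply(LIPID_ENZYME_MODULES,
                                              `[[`, "genes")),
      row.names = genes)

    methods::new("ExpressionStudy", expr = expr, subtype = subtype,
                 methylation = meth, survival = surv, geneInfo = geneInfo,
                 metadata = list(
                   seed = seed, spec = spec,
                   modules = lapply(moduleTruth, function(i) genes[i]),
                   module_subtype = vapply(LIPID_ENZYME_MODULES, `[[`, "",
                                           "subtype")))
  })
}
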