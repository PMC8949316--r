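#' Default pipeline run configuration
#'
#' Every tunable of the end-to-end run appears exactly once here: simulation
#' design (grid, sections per arm, noise sigma, m/z jitter), processing
#' (ppm tolerance, presence filter), segmentation (background fraction,
#' segment count), comparison (group arms, display threshold), network
#' parameters (beta, dissimilarity cutoff, permutations) and survival genes.
#'
#' @return A named list; pass (optionally modified) to [runPipeline()].
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    grid = c(60L, 60L),
    n_sections = 5L,
    noise_sigma = 0.3,
    mz_jitter_ppm = 3,
    tol_ppm = 9,
    panel = NULL,
    composition = NULL,
    polarity = "negative",
    background_frac = 0.1,
    k = 2L,
    k_range = c(2L, 8L),
    presence_threshold = 0.8,
    presence_pmin = 0.01,
    display_min_pct = 5,
    groups = list(A = c("healthy", "vehicle"), B = c("GBM", "vehicle")),
    network = list(beta = 9, cutoff = 0.8, min_size = 30L, n_perm = 200L),
    expression = list(n_genes = 600L, samples_per_subtype = 20L,
                      effect = 1.5),
    survival_genes = c("PLA2G5", "FABP7", "ELOVL2", "PLA2G2A", "ALOX5AP")
  )
}

#' Validate a run configuration
#'
#' @param config A configuration list (see [defaultRunConfig()]) or the path
#'   to a YAML file with the same fields.
#' @return The validated configuration list (invisibly usable); missing
#'   fields raise an error naming the field.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- names(defaultRunConfig())
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("run config is missing field(s): ", paste(missing, collapse = ", "))
  if (!is.null(config$panel) && !file.exists(config$panel))
    stop("run config field 'panel' points to a missing file: ", config$panel)
  if (!is.null(config$composition) && !file.exists(config$composition))
    stop("run config field 'composition' points to a missing file: ",
         config$composition)
  if (!config$polarity %in% c("negative", "positive"))
    stop("run config field 'polarity' must be 'negative' or 'positive'")
  config
}

## Simulate + process + segment one study arm; returns per-section
## experiments, segmentations and selected-cluster pixel sets.
processArm <- function(arm, config, profiles, panel, armIndex = 1L) {
  lapply(seq_len(config$n_sections), function(i) {
    sseed <- childSeed(config$seed, i + 1000L * armIndex)
    spec <- sectionSpec(condition = arm[1], treatment = arm[2],
                        grid = config$grid, seed = sseed)
    sec <- simulateSection(spec, profiles, panel, polarity = config$polarity,
                           noiseSigma = config$noise_sigma,
                           jitterPpm = config$mz_jitter_ppm, seed = sseed)
    exp <- ticNormalize(annotatePeaks(sec, panel, tolPpm = config$tol_ppm))
    exp <- filterBackground(exp, frac = config$background_frac)
    seg <- segmentPixels(exp,
                         k = config$k,
                         kRange = seq(config$k_range[1], config$k_range[2]),
                         seed = sseed)
    seg <- matchROI(seg, roiMask(sec), pixelCoords(sec))
    tissue <- !SummarizedExperiment::colData(exp)$background
    sel <- logical(ncol(exp))
    sel[which(tissue)[segmentLabels(seg) == selectedCluster(seg)]] <- TRUE
    list(experiment = exp, segmentation = seg, selected = sel,
         section_id = sectionMetadata(sec)$section_id)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate, process, segment, compare, modules and survival as
#' one reproducible run: synthetic sections for the two configured study
#' arms are annotated, TIC-normalized, background-filtered, segmented and
#' ROI-matched; compositions of the selected clusters are presence-filtered
#' and compared between arms; a synthetic expression study is generated and
#' analyzed for co-expression modules, subtype enrichment, survival and
#' methylation. Stage outputs are written as TSV under `outDir` and a
#' machine-readable JSON report is returned (and written). Reruns with the
#' same configuration are identical.
#'
#' @param config Configuration list or YAML path (see [defaultRunConfig()],
#'   [validateRunConfig()]).
#' @param outDir Output directory (created if needed).
#' @return The report, invisibly (a named list, also serialized to
#'   `report.json`).
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = tempfile("run")) {
  config <- validateRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  wHandler <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  cfgFile <- file.path(outDir, "config.json")
  jsonlite::write_json(config, cfgFile, auto_unbox = TRUE, null = "null",
                       digits = NA)
  cfgHash <- unname(tools::md5sum(cfgFile))
  report <- list(package = "glioLipidIMS",
                 version = as.character(utils::packageVersion("glioLipidIMS")),
                 seed = config$seed, config_hash = cfgHash)
  stage <- "init"
  withCallingHandlers(tryCatch({
    stage <- "simulate_process_segment"
    profiles <- lipidomeProfiles(config$composition)
    panel <- if (is.null(config$panel)) defaultLipidPanel()
             else buildPanel(readPanelConfig(config$panel))
    arms <- list(A = processArm(config$groups$A, config, profiles, panel, 1L),
                 B = processArm(config$groups$B, config, profiles, panel, 2L))
    report$simulate <- list(
      arms = lapply(config$groups, paste, collapse = "_"),
      n_sections = config$n_sections, grid = config$grid,
      noise_sigma = config$noise_sigma, mz_jitter_ppm = config$mz_jitter_ppm)
    report$segment <- list(
      k = vapply(unlist(arms, recursive = FALSE),
                 function(a) a$segmentation@k, 0L),
      dice = vapply(unlist(arms, recursive = FALSE),
                    function(a) max(diceTable(a$segmentation)$dice), 0))

    stage <- "presence_filter"
    allExps <- lapply(unlist(arms, recursive = FALSE), `[[`, "experiment")
    names(allExps) <- vapply(unlist(arms, recursive = FALSE), `[[`, "",
                             "section_id")
    allSel <- lapply(unlist(arms, recursive = FALSE), `[[`, "selected")
    pf <- presenceFilter(allExps, threshold = config$presence_threshold,
                         pMin = config$presence_pmin, pixelSets = allSel)
    report$presence <- list(n_kept = length(pf$kept),
                            n_dropped = nrow(pf$dropped))
    utils::write.table(pf$dropped, file.path(outDir, "dropped_features.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    stage <- "compare"
    tables <- lapply(seq_along(allExps), function(i) {
      e <- allExps[[i]][pf$kept[pf$kept %in% rownames(allExps[[i]])], ]
      compositionTable(ticNormalize(e), pixels = allSel[[i]])
    })
    nA <- config$n_sections
    tablesA <- tables[seq_len(nA)]
    tablesB <- tables[nA + seq_len(config$n_sections)]
    cmp <- compareGroups(tablesA, tablesB,
                         displayMinPct = config$display_min_pct)
    utils::write.table(cmp, file.path(outDir, "comparisons.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    classShare <- function(tabs) t(sapply(tabs, function(t) {
      s <- t[!duplicated(t$class), ]
      stats::setNames(s$class_share, s$class)
    }))
    mat <- rbind(classShare(tablesA), classShare(tablesB))
    groupsVec <- rep(c("A", "B"), each = nA)
    pca <- pcaSeparation(mat, groupsVec)
    utils::write.table(
      data.frame(sample = names(allExps), group = groupsVec, pca$scores),
      file.path(outDir, "pca_scores.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    cls <- cmp[cmp$level == "class", ]
    report$compare <- list(
      class_folds = stats::setNames(as.list(cls$fold_change), cls$feature),
      pca_silhouette = pca$silhouette,
      pca_explained_12 = sum(pca$explained[1:2]))

    stage <- "modules"
    espec <- expressionStudySpec(
      nGenes = config$expression$n_genes,
      samplesPerSubtype = config$expression$samples_per_subtype,
      effect = config$expression$effect)
    study <- simulateExpressionStudy(espec, seed = childSeed(config$seed, 101L))
    mods <- detectModules(study, beta = config$network$beta,
                          dissCutoff = config$network$cutoff,
                          minSize = config$network$min_size)
    mods <- moduleSubtypeNES(mods, study, nPerm = config$network$n_perm,
                             seed = childSeed(config$seed, 102L))
    modTab <- data.frame(
      gene = unlist(moduleGenes(mods), use.names = FALSE),
      module = rep(names(moduleGenes(mods)), lengths(moduleGenes(mods))))
    modTab$hub <- mapply(function(g, m) g %in% hubGenes(mods)[[m]],
                         modTab$gene, modTab$module)
    utils::write.table(modTab, file.path(outDir, "modules.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(module = rownames(mods@nes), mods@nes, check.names = FALSE),
      file.path(outDir, "nes.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    report$modules <- list(
      n_modules = length(moduleGenes(mods)),
      sizes = stats::setNames(as.list(lengths(moduleGenes(mods))),
                              names(moduleGenes(mods))),
      top_subtype = stats::setNames(
        as.list(colnames(mods@nes)[apply(mods@nes, 1, which.max)]),
        rownames(mods@nes)))

    stage <- "survival"
    surv <- survivalRecords(study)
    z <- t(scale(t(exprMatrix(study))))
    genes <- intersect(config$survival_genes, rownames(z))
    lr <- lapply(genes, function(g)
      logrankTwoGroups(surv$time, surv$event, z[g, ]))
    lrTab <- data.frame(gene = genes,
                        chisq = vapply(lr, `[[`, 0, "chisq"),
                        p = vapply(lr, `[[`, 0, "p"))
    utils::write.table(lrTab, file.path(outDir, "logrank.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    meth <- methylationBetas(study)
    anova_expr <- lapply(genes, function(g)
      subtypeAnovaTukey(z[g, ], subtypeLabels(study)))
    anovaTab <- data.frame(gene = genes,
                           F = vapply(anova_expr, `[[`, 0, "F"),
                           p = vapply(anova_expr, `[[`, 0, "p"))
    utils::write.table(anovaTab, file.path(outDir, "subtype_stats.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report$survival <- list(
      logrank_p = stats::setNames(as.list(lrTab$p), lrTab$gene),
      anova_p = stats::setNames(as.list(anovaTab$p), anovaTab$gene),
      n_meth_probes = nrow(meth))

    stage <- "report"
    report$warnings <- warnings_log
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(report)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         " (partial outputs preserved under ", outDir, ")", call. = FALSE)
  }), warning = wHandler)
}
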