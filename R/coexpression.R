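#' Detect co-expression gene modules
#'
#' Weighted co-expression network module detection: the adjacency between two
#' genes is `|Pearson correlation|^beta` (unsigned network, soft-threshold
#' power `beta`), the dissimilarity `1 - adjacency` is clustered by
#' average-linkage hierarchical clustering and cut at `dissCutoff`; clusters
#' below `minSize` genes go to a "not-correlated" pool; modules whose
#' eigengenes (first principal component of the module's genes) correlate
#' above `mergeCor` are merged. Hub genes are the genes of highest
#' intramodular connectivity. Detection is deterministic: correlations are
#' invariant to sample order and no random initialization is involved.
#'
#' @param study An [ExpressionStudy-class] (or a genes x samples matrix).
#' @param beta Soft-threshold power (default 9).
#' @param dissCutoff Dissimilarity cut height in (0, 1) (default 0.8).
#' @param minSize Minimum module size.
#' @param mergeCor Eigengene correlation above which modules merge.
#' @param nHubs Hub genes reported per module.
#' @return A [LipidModuleSet-class]; modules are named M1, M2, ... by
#'   decreasing size.
#' @export
detectModules <- function(study, beta = 9, dissCutoff = 0.8, minSize = 30L,
                          mergeCor = 0.9, nHubs = 5L) {
  expr <- if (methods::is(study, "ExpressionStudy")) exprMatrix(study)
          else as.matrix(study)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant gene(s)")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2L * minSize)
    stop("too few genes for module detection")
  adj <- abs(stats::cor(t(expr)))^beta
  diag(adj) <- 0
  hc <- stats::hclust(stats::as.dist(1 - adj), method = "average")
  cl <- stats::cutree(hc, h = dissCutoff)

  sizes <- table(cl)
  keep <- names(sizes)[sizes >= minSize]
  modules <- lapply(keep, function(k) rownames(expr)[cl == as.integer(k)])
  pool <- rownames(expr)[!cl %in% as.integer(keep)]

  ## merge modules with near-identical eigengenes
  if (length(modules) > 1L) {
    eig <- sapply(modules, function(g) moduleEigengene(expr[g, , drop = FALSE]))
    ec <- stats::cor(eig)
    parent <- seq_along(modules)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_along(modules)) for (j in seq_len(i - 1L))
      if (abs(ec[i, j]) > mergeCor) parent[find(i)] <- find(j)
    grp <- vapply(seq_along(modules), find, 0L)
    modules <- lapply(unique(grp), function(g)
      unlist(modules[grp == g], use.names = FALSE))
  }

  modules <- modules[order(-lengths(modules))]
  names(modules) <- if (length(modules))
    paste0("M", seq_along(modules)) else character(0)
  hubs <- lapply(modules, function(g) {
    conn <- rowSums(adj[g, g, drop = FALSE])
    names(sort(conn, decreasing = TRUE))[seq_len(min(nHubs, length(g)))]
  })
  methods::new("LipidModuleSet", modules = modules, notCorrelated = pool,
               hubs = hubs,
               parameters = list(beta = beta, dissCutoff = dissCutoff,
                                 minSize = as.integer(minSize),
                                 mergeCor = mergeCor),
               nes = matrix(numeric(0), 0, 0),
               nesPadj = matrix(numeric(0), 0, 0))
}

## First principal component of a module's expression (genes x samples),
## oriented to correlate positively with the module's mean expression.
moduleEigengene <- function(expr) {
  z <- t(scale(t(expr)))        # per-gene z-scores, genes x samples
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  e <- pc$x[, 1]
  if (stats::cor(e, colMeans(expr)) < 0) e <- -e
  e
}

## Weighted (weight 1) Kolmogorov-Smirnov running-sum enrichment score of a
## gene set against a ranking metric. `metric` must be named by gene.
enrichmentScore <- function(metric, geneSet) {
  o <- order(metric, decreasing = TRUE)
  r <- metric[o]
  hit <- names(r) %in% geneSet
  if (!any(hit) || all(hit)) return(0)
  w <- abs(r)
  inc <- ifelse(hit, w / sum(w[hit]), -1 / sum(!hit))
  running <- cumsum(inc)
  running[which.max(abs(running))]
}

#' Module-subtype normalized enrichment scores
#'
#' For each subtype, genes are ranked by their mean z-scored expression over
#' that subtype's samples and each module's gene set is scored by the
#' weighted Kolmogorov-Smirnov running-sum statistic. The normalized
#' enrichment score is `ES / mean(|ES|)` over `nPerm` size-matched random
#' gene-set permutations; the permutation tail gives the p-value, corrected
#' by Benjamini-Hochberg across all module x subtype cells.
#'
#' @param moduleSet A [LipidModuleSet-class].
#' @param study An [ExpressionStudy-class].
#' @param nPerm Gene-set permutations per module x subtype cell.
#' @param seed Integer seed for the permutations.
#' @return The module set with `nes` and `nesPadj` matrices filled in.
#' @export
moduleSubtypeNES <- function(moduleSet, study, nPerm = 1000L, seed = 1L) {
  expr <- exprMatrix(study)
  subtype <- subtypeLabels(study)
  if (min(table(subtype)) < 3L)
    stop("at least 3 samples per subtype are required")
  z <- t(scale(t(expr)))
  genes <- rownames(expr)
  nG <- length(genes)
  half <- vapply(moduleSet@modules, length, 0L) > nG / 2
  if (any(half))
    warning("module(s) larger than half the genes: ",
            paste(names(moduleSet@modules)[half], collapse = ", "))

  subtypes <- levels(droplevels(subtype))
  nes <- pval <- matrix(NA_real_, length(moduleSet@modules), length(subtypes),
                        dimnames = list(names(moduleSet@modules), subtypes))
  withSeed(seed, {
    for (st in subtypes) {
      metric <- rowMeans(z[, subtype == st, drop = FALSE])
      names(metric) <- genes
      for (m in names(moduleSet@modules)) {
        set <- moduleSet@modules[[m]]
        es <- enrichmentScore(metric, set)
        esPerm <- vapply(seq_len(nPerm), function(i)
          enrichmentScore(metric, sample(genes, length(set))), numeric(1))
        nes[m, st] <- es / mean(abs(esPerm))
        pval[m, st] <- (1 + sum(abs(esPerm) >= abs(es))) / (1 + nPerm)
      }
    }
  })
  moduleSet@nes <- nes
  moduleSet@nesPadj <- matrix(stats::p.adjust(pval, method = "BH"),
                              nrow(pval), ncol(pval),
                              dimnames = dimnames(pval))
  moduleSet
}
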