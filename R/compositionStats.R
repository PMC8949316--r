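#' Per-sample lipid composition of a pixel selection
#'
#' Averages the TIC-normalized pixel feature vectors over the selected pixels
#' (typically the ROI-matched cluster), then derives per-class relative
#' intensities (share of TIC within the section's ion mode) and within-class
#' species percentages. The within-class percentages are conventionally
#' called mole% although they are intensity shares: MALDI intensities are not
#' molar-corrected, so comparisons are only meaningful within a lipid class.
#'
#' @param x A TIC-normalized [LipidImagingExperiment-class].
#' @param pixels Logical or integer selection of columns (default: all
#'   non-background pixels).
#' @return A data.frame with one row per feature: `species`, `class`,
#'   `mean_intensity` (mean normalized intensity over selected pixels),
#'   `class_share` (sum of the class's mean intensities) and `mol_pct`
#'   (100 x species / class total). Classes with zero total are dropped with
#'   a warning.
#' @export
compositionTable <- function(x, pixels = NULL) {
  if (!isTRUE(S4Vectors::metadata(x)$tic_normalized))
    stop("run ticNormalize() before computing compositions")
  if (is.null(pixels)) {
    cd <- SummarizedExperiment::colData(x)
    pixels <- if ("background" %in% colnames(cd)) !cd$background
              else rep(TRUE, ncol(x))
  }
  sub <- x[, pixels]
  if (ncol(sub) == 0L) stop("empty pixel selection")
  mean_int <- rowMeans(SummarizedExperiment::assay(sub, "intensity"))
  rd <- SummarizedExperiment::rowData(sub)
  tab <- data.frame(species = rd$species, class = rd$class,
                    mean_intensity = mean_int, stringsAsFactors = FALSE)
  classTotal <- tapply(tab$mean_intensity, tab$class, sum)
  zero <- names(classTotal)[classTotal == 0]
  if (length(zero)) {
    warning("dropping class(es) with zero total intensity: ",
            paste(zero, collapse = ", "))
    tab <- tab[!tab$class %in% zero, ]
    classTotal <- classTotal[!names(classTotal) %in% zero]
  }
  tab$class_share <- as.numeric(classTotal[tab$class] /
                                  sum(tab$mean_intensity))
  tab$mol_pct <- as.numeric(100 * tab$mean_intensity / classTotal[tab$class])
  rownames(tab) <- NULL
  tab
}

#' Two-group comparison of lipid compositions
#'
#' Compares per-sample composition tables between two study groups at the
#' class level (relative TIC shares) and the species level (within-class
#' mole percentages): group means, SEM, fold change, and a per-feature
#' two-sample two-tailed t-test with significance stars. Species averaging
#' below 5% abundance in both groups are flagged (`displayed = FALSE`),
#' mirroring the convention of omitting minor species from figures; a
#' Benjamini-Hochberg column is reported for transparency but stars follow
#' the raw p-values.
#'
#' @param tablesA,tablesB Lists of per-sample data.frames from
#'   [compositionTable()] (group A is the reference, e.g. healthy/vehicle).
#' @param welch Use Welch's t-test instead of the Student (pooled-variance)
#'   test.
#' @param displayMinPct Species display threshold on the group-mean mole%.
#' @return A data.frame with one row per feature: `feature`, `level`
#'   (`"class"`/`"species"`), `class`, `mean_A`, `mean_B`, `sem_A`, `sem_B`,
#'   `fold_change` (B/A), `fold_display` (B/A when >= 1, else A/B reported as
#'   an "x-fold decrease"), `direction`, `t`, `p`, `p_adj`, `stars`,
#'   `displayed`.
#' @export
compareGroups <- function(tablesA, tablesB, welch = FALSE,
                          displayMinPct = 5) {
  if (length(tablesA) < 3L || length(tablesB) < 3L)
    stop("at least 3 samples per group are required")
  valueMatrix <- function(tables, level) {
    if (level == "class") {
      rows <- lapply(tables, function(t) {
        s <- t[!duplicated(t$class), ]
        stats::setNames(s$class_share, s$class)
      })
      feats <- sort(unique(unlist(lapply(rows, names))))
      out <- vapply(rows, function(r) unname(r[feats]),
                    numeric(length(feats)))
    } else {
      feats <- sort(unique(unlist(lapply(tables, `[[`, "species"))))
      out <- vapply(tables, function(t) t$mol_pct[match(feats, t$species)],
                    numeric(length(feats)))
    }
    out <- matrix(out, nrow = length(feats),
                  dimnames = list(feats, NULL))
    out
  }
  testRow <- function(a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b))))
        return(c(t = 0, p = 1))
      return(c(t = Inf, p = 0))
    }
    ht <- stats::t.test(b, a, var.equal = !welch)
    c(t = unname(ht$statistic), p = ht$p.value)
  }
  one_level <- function(level) {
    A <- valueMatrix(tablesA, level); B <- valueMatrix(tablesB, level)
    feats <- union(rownames(A), rownames(B))
    out <- lapply(feats, function(f) {
      a <- if (f %in% rownames(A)) A[f, ] else rep(NA_real_, ncol(A))
      b <- if (f %in% rownames(B)) B[f, ] else rep(NA_real_, ncol(B))
      tp <- testRow(a, b)
      mA <- mean(a, na.rm = TRUE); mB <- mean(b, na.rm = TRUE)
      fc <- mB / mA
      cls <- if (level == "class") f else {
        v <- tablesA[[1]]$class[match(f, tablesA[[1]]$species)]
        if (is.na(v)) v <- tablesB[[1]]$class[match(f, tablesB[[1]]$species)]
        v
      }
      data.frame(
        feature = f, level = level, class = cls,
        mean_A = mA, mean_B = mB,
        sem_A = stats::sd(a, na.rm = TRUE) / sqrt(sum(!is.na(a))),
        sem_B = stats::sd(b, na.rm = TRUE) / sqrt(sum(!is.na(b))),
        fold_change = fc,
        fold_display = ifelse(fc >= 1, fc, 1 / fc),
        direction = ifelse(fc >= 1, "increase", "decrease"),
        t = tp["t"], p = tp["p"],
        displayed = if (level == "species")
          mA >= displayMinPct || mB >= displayMinPct else TRUE,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  res <- rbind(one_level("class"), one_level("species"))
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$stars <- cut(res$p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  rownames(res) <- NULL
  res
}

#' PCA separation of composition profiles
#'
#' Unsupervised PCA on standardized features (group labels are not used in
#' the fit), plus the silhouette of the groups in the PC1-PC2 plane as a
#' separation score.
#'
#' @param mat Samples x features numeric matrix (e.g. class shares or
#'   species mole percentages per sample).
#' @param groups Group label per sample (factor or character).
#' @return A list with `scores` (samples x 2), `explained` (per-component
#'   explained variance ratio), `silhouette` (mean group silhouette on
#'   PC1-2) and `dropped` (constant features removed before z-scoring).
#' @export
pcaSeparation <- function(mat, groups) {
  mat <- as.matrix(mat)
  if (length(groups) != nrow(mat)) stop("one group label per sample required")
  if (min(table(groups)) < 2L) stop("at least 2 samples per group")
  sds <- apply(mat, 2, stats::sd)
  dropped <- colnames(mat)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
    mat <- mat[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  sil <- if (length(unique(groups)) > 1L)
    mean(cluster::silhouette(as.integer(factor(groups)),
                             stats::dist(scores))[, "sil_width"])
  else NA_real_
  list(scores = scores, explained = explained, silhouette = sil,
       dropped = dropped)
}
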