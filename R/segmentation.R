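#' Flag matrix-only background pixels
#'
#' Pixels whose raw TIC falls below `frac` times the median pixel TIC are
#' labeled background and excluded from clustering. The median is computed
#' over all pixels: matrix-only pixels carry on the order of 1% of a tissue
#' pixel's ion current, so as long as tissue pixels are the majority the
#' median is a robust tissue-TIC estimate.
#'
#' @param x A [LipidImagingExperiment-class] (needs `raw_tic` in colData).
#' @param frac Background threshold as a fraction of the median TIC.
#' @return `x` with a logical `background` column added to `colData`.
#' @export
filterBackground <- function(x, frac = 0.1) {
  if (frac < 0 || frac >= 1) stop("frac must lie in [0, 1)")
  tic <- SummarizedExperiment::colData(x)$raw_tic
  bg <- tic < frac * stats::median(tic)
  if (all(bg)) stop("all pixels classified as background")
  SummarizedExperiment::colData(x)$background <- bg
  x
}

#' Segment tissue pixels by lipid profile
#'
#' k-means clustering of TIC-normalized pixel feature vectors, with `nstart`
#' restarts from the given seed. When `k` is `NULL` the number of segments is
#' chosen over `kRange` by maximum mean silhouette width (computed on a
#' seeded subsample of at most `silhouetteSample` pixels for tractability).
#' Pixels flagged background by [filterBackground()] are excluded.
#'
#' @param x A [LipidImagingExperiment-class], TIC-normalized; run
#'   [filterBackground()] first (otherwise all pixels are treated as tissue).
#' @param k Fixed number of segments, or `NULL` to select from `kRange`.
#' @param kRange Candidate segment counts (2..8 by default).
#' @param seed Integer seed (restart initialization and silhouette
#'   subsampling).
#' @param nstart k-means restarts.
#' @param logTransform Cluster on `log1p` intensities instead of raw
#'   normalized intensities.
#' @param silhouetteSample Maximum pixels used for silhouette scoring.
#' @return A [SegmentationResult-class].
#' @export
segmentPixels <- function(x, k = NULL, kRange = 2:8, seed = 1L, nstart = 10,
                          logTransform = FALSE, silhouetteSample = 500L) {
  cd <- SummarizedExperiment::colData(x)
  tissue <- if ("background" %in% colnames(cd)) !cd$background
            else rep(TRUE, ncol(x))
  m <- t(SummarizedExperiment::assay(x[, tissue], "intensity"))
  if (logTransform) m <- log1p(m)
  coords <- cbind(x = cd$x[tissue], y = cd$y[tissue])
  ks <- if (!is.null(k)) as.integer(k) else as.integer(kRange)
  if (any(ks < 2L | ks > 8L)) stop("number of segments must lie in 2..8")
  if (max(ks) > nrow(m)) stop("more segments requested than tissue pixels")

  sub <- withSeed(childSeed(seed, 7L),
                  sample(nrow(m), min(silhouetteSample, nrow(m))))
  dsub <- stats::dist(m[sub, , drop = FALSE])

  fits <- lapply(ks, function(kk) {
    fit <- withSeed(childSeed(seed, kk),
                    stats::kmeans(m, centers = kk, nstart = nstart,
                                  iter.max = 50))
    sil <- if (length(unique(fit$cluster[sub])) > 1L)
      mean(cluster::silhouette(fit$cluster[sub], dsub)[, "sil_width"])
    else NA_real_
    list(fit = fit, sil = sil)
  })
  best <- if (length(fits) == 1L) 1L else which.max(vapply(fits, `[[`, 0, "sil"))
  sil <- fits[[best]]$sil
  if (!is.na(sil) && sil < 0.1)
    warning("weak cluster structure: mean silhouette ", round(sil, 3))
  methods::new("SegmentationResult",
               labels = as.integer(fits[[best]]$fit$cluster),
               coords = coords, k = ks[best],
               silhouette = if (is.null(sil) || is.na(sil)) NA_real_ else sil,
               diceTable = data.frame(), selectedCluster = NA_integer_)
}

#' Dice overlap coefficient
#'
#' @param a,b Logical vectors of equal length (or index sets over a common
#'   pixel universe).
#' @return `2 |A n B| / (|A| + |B|)`, in \[0, 1\].
#' @export
diceCoefficient <- function(a, b) {
  if (is.logical(a) && is.logical(b)) {
    if (length(a) != length(b)) stop("mask lengths differ")
    denom <- sum(a) + sum(b)
    if (denom == 0) return(0)
    return(2 * sum(a & b) / denom)
  }
  denom <- length(a) + length(b)
  if (denom == 0) return(0)
  2 * length(intersect(a, b)) / denom
}

#' Match segmentation clusters to the ROI mask
#'
#' Computes the Dice coefficient between every cluster and the MKI67+-like
#' region-of-interest mask and selects the cluster with maximum overlap
#' (replacing visual inspection with a reproducible criterion). Ties are
#' broken toward the larger cluster and reported.
#'
#' @param result A [SegmentationResult-class].
#' @param roiMask Logical ROI mask over the section's pixels.
#' @param maskCoords Pixels x 2 coordinate matrix parallel to `roiMask`
#'   (e.g. `pixelCoords(dataset)`).
#' @return The result with `diceTable` and `selectedCluster` filled in.
#' @export
matchROI <- function(result, roiMask, maskCoords) {
  if (is.matrix(roiMask) && missing(maskCoords)) {
    maskCoords <- cbind(x = rep(seq_len(ncol(roiMask)), each = nrow(roiMask)),
                        y = rep(seq_len(nrow(roiMask)), ncol(roiMask)))
    roiMask <- as.vector(roiMask)
  }
  if (!any(roiMask)) stop("ROI mask is empty")
  roiKey <- paste(maskCoords[roiMask, 1], maskCoords[roiMask, 2])
  labKey <- paste(result@coords[, 1], result@coords[, 2])
  ks <- sort(unique(result@labels))
  dice <- vapply(ks, function(cl)
    diceCoefficient(labKey[result@labels == cl], roiKey), numeric(1))
  size <- tabulate(result@labels)[ks]
  tab <- data.frame(cluster = ks, size = size, dice = dice)
  top <- which(dice == max(dice))
  if (length(top) > 1L) {
    message("matchROI: Dice tie between clusters ",
            paste(ks[top], collapse = ", "), "; selecting the largest")
    top <- top[which.max(size[top])]
  }
  result@diceTable <- tab
  result@selectedCluster <- ks[top]
  methods::validObject(result)
  result
}
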