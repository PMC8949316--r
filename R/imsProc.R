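#' Align centroided peaks across pixels
#'
#' Greedy centroid clustering of all pixel peaks along m/z: the global peak
#' list is sorted, a new consensus bin opens when the ppm gap from a peak to
#' the current bin's running intensity-weighted centroid exceeds the
#' tolerance, and the consensus m/z of each bin is its intensity-weighted
#' mean. Each pixel contributes at most one peak per bin downstream (the
#' maximum-intensity peak wins; centroided data should carry at most one
#' true peak per species).
#'
#' @param dataset An [IMSDataset-class].
#' @param tolPpm Bin-opening tolerance in ppm.
#' @return A list with `bins` (data.frame `consensus_mz`, `n_peaks`),
#'   and `peaks` (data.frame `pixel`, `mz`, `intensity`, `bin`).
#' @export
alignPeaks <- function(dataset, tolPpm = 9) {
  if (tolPpm <= 0) stop("tolPpm must be positive")
  npk <- lengths(dataset@mz)
  if (sum(npk) == 0L) stop("dataset has no peaks")
  pixel <- rep.int(seq_along(npk), npk)
  mz <- unlist(dataset@mz, use.names = FALSE)
  intensity <- unlist(dataset@intensity, use.names = FALSE)
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]; pixel <- pixel[o]

  n <- length(mz)
  bin <- integer(n)
  centroid <- numeric(n)   # per-bin consensus m/z (trimmed later)
  b <- 1L
  c_mz <- mz[1]; c_w <- max(intensity[1], .Machine$double.eps)
  bin[1] <- 1L
  for (i in 2:n) {
    if (1e6 * (mz[i] - c_mz) / c_mz > tolPpm) {
      centroid[b] <- c_mz
      b <- b + 1L
      c_mz <- mz[i]; c_w <- max(intensity[i], .Machine$double.eps)
    } else {
      w <- max(intensity[i], .Machine$double.eps)
      c_mz <- (c_mz * c_w + mz[i] * w) / (c_w + w)
      c_w <- c_w + w
    }
    bin[i] <- b
  }
  centroid[b] <- c_mz
  bins <- data.frame(consensus_mz = centroid[seq_len(b)],
                     n_peaks = tabulate(bin, b))
  list(bins = bins,
       peaks = data.frame(pixel = pixel, mz = mz, intensity = intensity,
                          bin = bin))
}

#' Annotate a section into a lipid feature matrix
#'
#' Runs [alignPeaks()], annotates the consensus m/z axis against the panel
#' entries of the section's ion mode at the given ppm tolerance, and builds
#' the pixels x features intensity matrix (one column per pixel, one row per
#' annotated (species, adduct) feature; within a bin each pixel contributes
#' its maximum-intensity peak). Unannotated bins (chemical noise, background)
#' are dropped from the matrix but still count toward each pixel's `raw_tic`.
#'
#' @param dataset An [IMSDataset-class].
#' @param panel Lipid panel; rows are restricted to the dataset polarity.
#' @param tolPpm Annotation (and alignment) tolerance in ppm.
#' @return A [LipidImagingExperiment-class] (raw intensities; apply
#'   [ticNormalize()] before composition analysis).
#' @export
annotatePeaks <- function(dataset, panel = defaultLipidPanel(), tolPpm = 9) {
  pol <- dataset@metadata$polarity %||% "negative"
  sub <- panel[panel$ion_mode == pol, , drop = FALSE]
  aligned <- alignPeaks(dataset, tolPpm)
  ann <- annotateMz(aligned$bins$consensus_mz, sub, tolPpm)
  keep <- which(!is.na(ann$species))
  if (!length(keep)) stop("no aligned bin matched the panel")

  npix <- nrow(dataset@coords)
  rawTIC <- vapply(dataset@intensity, sum, numeric(1))

  ## per (kept bin, pixel): max intensity
  pk <- aligned$peaks[aligned$peaks$bin %in% keep, ]
  binIdx <- match(pk$bin, keep)
  ij <- (binIdx - 1L) * npix + pk$pixel
  mat <- matrix(0, nrow = length(keep), ncol = npix)
  agg <- tapply(pk$intensity, ij, max)
  cell <- as.integer(names(agg))
  mat[cbind((cell - 1L) %/% npix + 1L, (cell - 1L) %% npix + 1L)] <- agg

  rd <- S4Vectors::DataFrame(
    species = ann$species[keep], class = ann$class[keep],
    adduct = ann$adduct[keep], theoretical_mz = ann$theoretical_mz[keep],
    consensus_mz = ann$observed_mz[keep], ppm_error = ann$ppm_error[keep],
    ambiguous = ann$ambiguous[keep], n_bin_peaks = aligned$bins$n_peaks[keep])

  ## enforce one row per (species, adduct): merge duplicate annotations
  fkey <- paste(rd$species, rd$adduct)
  if (anyDuplicated(fkey)) {
    first <- !duplicated(fkey)
    grp <- match(fkey, fkey[first])
    mat <- rowsum(mat, grp)
    rd <- rd[first, ]
  }
  o <- order(rd$theoretical_mz)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = mat[o, , drop = FALSE]),
    rowData = rd[o, ],
    colData = S4Vectors::DataFrame(
      x = dataset@coords[, 1], y = dataset@coords[, 2], raw_tic = rawTIC))
  rownames(se) <- rd$species[o]
  out <- methods::new("LipidImagingExperiment", se)
  md <- dataset@metadata
  md$tol_ppm <- tolPpm
  md$tic_normalized <- FALSE
  S4Vectors::metadata(out) <- md
  out
}

#' TIC-normalize a feature matrix
#'
#' Divides each pixel's feature vector by its sum over kept features, so
#' pixel columns sum to 1. Pixels with zero total intensity are dropped with
#' a message. Normalizing twice is a no-op.
#'
#' @param x A [LipidImagingExperiment-class].
#' @return The normalized experiment (`metadata(x)$tic_normalized = TRUE`).
#' @export
ticNormalize <- function(x) {
  tic <- colSums(SummarizedExperiment::assay(x, "intensity"))
  drop <- tic <= 0
  if (any(drop)) {
    message("ticNormalize: dropping ", sum(drop), " zero-TIC pixel(s)")
    x <- x[, !drop]
    tic <- tic[!drop]
  }
  SummarizedExperiment::assay(x, "intensity") <-
    sweep(SummarizedExperiment::assay(x, "intensity"), 2, tic, "/")
  md <- S4Vectors::metadata(x)
  md$tic_normalized <- TRUE
  S4Vectors::metadata(x) <- md
  x
}

#' Presence filter across samples
#'
#' Keeps only features detected in at least `threshold` of the analyzed
#' samples, where a feature counts as "present" in a sample when it is
#' detected (nonzero) in at least `pMin` of that sample's analyzed pixels.
#' The retained-sample count uses the ceiling (`>= ceiling(threshold * n)`,
#' i.e. "at least 80%" with the default threshold).
#'
#' @param experiments Named list of [LipidImagingExperiment-class] objects,
#'   one per sample (section).
#' @param threshold Minimum fraction of samples a feature must be present in.
#' @param pMin Minimum fraction of a sample's pixels for within-sample
#'   presence.
#' @param pixelSets Optional list (parallel to `experiments`) of pixel
#'   selections (logical or integer column indices, e.g. the ROI-matched
#'   cluster) to which presence is restricted.
#' @return A list with `kept` (feature names), `dropped` (removal log
#'   data.frame with per-sample presence counts), and `presence` (features x
#'   samples logical matrix).
#' @export
presenceFilter <- function(experiments, threshold = 0.8, pMin = 0.01,
                           pixelSets = NULL) {
  if (length(experiments) < 2L)
    stop("presence filtering requires at least 2 samples")
  feats <- sort(unique(unlist(lapply(experiments, rownames))))
  presence <- matrix(FALSE, length(feats), length(experiments),
                     dimnames = list(feats, names(experiments)))
  for (s in seq_along(experiments)) {
    e <- experiments[[s]]
    if (!is.null(pixelSets)) e <- e[, pixelSets[[s]]]
    m <- SummarizedExperiment::assay(e, "intensity")
    det <- rowMeans(m > 0) >= pMin
    presence[rownames(e)[det], s] <- TRUE
  }
  needed <- ceiling(threshold * length(experiments))
  nPresent <- rowSums(presence)
  kept <- feats[nPresent >= needed]
  lost <- nPresent < needed
  dropped <- data.frame(species = feats[lost],
                        n_present = unname(nPresent[lost]),
                        n_samples = rep(length(experiments), sum(lost)),
                        needed = rep(needed, sum(lost)))
  list(kept = kept, dropped = dropped, presence = presence)
}
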