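#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' IMSDataset: a pixel grid of centroided spectra
#'
#' Container for one imaging-MS section in one ion mode: per pixel an
#' ascending centroided m/z array with matching intensities, plus section
#' metadata (condition, treatment, section id, polarity, lateral resolution).
#'
#' @slot coords Integer matrix (pixels x 2) of unique x/y grid coordinates.
#' @slot mz List of numeric vectors, one ascending m/z array per pixel.
#' @slot intensity List of numeric vectors matching `mz`, all non-negative.
#' @slot metadata Named list of section metadata; conventional fields are
#'   `condition`, `treatment`, `section_id`, `polarity`,
#'   `lateral_resolution_um`, and for synthetic sections `roi_mask` (logical
#'   pixel vector marking the planted proliferative region) and
#'   `region_labels` (generator ground truth; 0 = background).
#' @export
setClass("IMSDataset",
  slots = c(coords = "matrix", mz = "list", intensity = "list",
            metadata = "list"))

setValidity("IMSDataset", function(object) {
  n <- nrow(object@coords)
  if (ncol(object@coords) != 2L) return("coords must have two columns (x, y)")
  if (length(object@mz) != n || length(object@intensity) != n)
    return("mz/intensity lists must match the number of pixels")
  if (anyDuplicated(paste(object@coords[, 1], object@coords[, 2])))
    return("pixel coordinates must be unique")
  for (i in seq_len(n)) {
    if (length(object@mz[[i]]) != length(object@intensity[[i]]))
      return("mz and intensity arrays differ in length")
    if (is.unsorted(object@mz[[i]]))
      return("mz arrays must be sorted ascending")
    if (any(object@intensity[[i]] < 0))
      return("intensities must be non-negative")
  }
  TRUE
})

#' Construct an IMSDataset
#'
#' @param coords Pixels x 2 matrix of grid coordinates.
#' @param mz,intensity Per-pixel peak lists (parallel lists of numeric
#'   vectors; m/z ascending).
#' @param metadata Named list of section metadata (see [IMSDataset-class]).
#' @return An [IMSDataset-class] object.
#' @export
IMSDataset <- function(coords, mz, intensity, metadata = list()) {
  new("IMSDataset", coords = as.matrix(coords), mz = mz,
      intensity = intensity, metadata = metadata)
}

setMethod("show", "IMSDataset", function(object) {
  md <- object@metadata
  cat("IMSDataset:", nrow(object@coords), "pixels,",
      sum(lengths(object@mz)), "peaks\n")
  cat("  polarity:", md$polarity %||% "?",
      " condition:", md$condition %||% "?",
      " treatment:", md$treatment %||% "?", "\n")
})

#' LipidImagingExperiment: pixels x annotated lipid features
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' aligned, annotated feature matrix of one section: rows are annotated lipid
#' features (rowData carries `species`, `class`, `adduct`, `theoretical_mz`,
#' `consensus_mz`, `ppm_error`, `ambiguous`), columns are pixels (colData
#' carries `x`, `y`, `raw_tic` computed from all raw peaks before annotation,
#' and after background filtering a logical `background`). The `"intensity"`
#' assay is raw summed bin intensity until [ticNormalize()] is applied, after
#' which columns sum to 1 and `metadata(x)$tic_normalized` is `TRUE`.
#'
#' @export
setClass("LipidImagingExperiment", contains = "SummarizedExperiment")

setValidity("LipidImagingExperiment", function(object) {
  need_row <- c("species", "class", "adduct", "theoretical_mz",
                "consensus_mz", "ppm_error")
  if (!all(need_row %in% colnames(rowData(object))))
    return(paste("rowData must carry:", paste(need_row, collapse = ", ")))
  if (!all(c("x", "y", "raw_tic") %in% colnames(colData(object))))
    return("colData must carry x, y, raw_tic")
  TRUE
})

#' SegmentationResult: pixel clustering with ROI matching
#'
#' @slot labels Integer cluster id per tissue pixel (background pixels are
#'   excluded before clustering; see `coords` for which pixels these are).
#' @slot coords Tissue-pixel coordinates (pixels x 2), parallel to `labels`.
#' @slot k Number of segments used.
#' @slot silhouette Mean silhouette width of the chosen clustering (NA when
#'   k was fixed by the caller and not scored).
#' @slot diceTable data.frame of per-cluster Dice coefficients vs the ROI
#'   mask (empty until [matchROI()] is applied).
#' @slot selectedCluster Cluster id maximizing Dice overlap (NA until
#'   [matchROI()]).
#' @export
setClass("SegmentationResult",
  slots = c(labels = "integer", coords = "matrix", k = "integer",
            silhouette = "numeric", diceTable = "data.frame",
            selectedCluster = "integer"))

setValidity("SegmentationResult", function(object) {
  if (length(object@labels) != nrow(object@coords))
    return("labels and coords disagree in length")
  if (object@k < 2L || object@k > 8L)
    return("number of segments must lie in 2..8")
  if (nrow(object@diceTable) &&
      (any(object@diceTable$dice < 0) || any(object@diceTable$dice > 1)))
    return("Dice coefficients must lie in [0, 1]")
  TRUE
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult: k =", object@k, "on", length(object@labels),
      "tissue pixels\n")
  if (!is.na(object@selectedCluster))
    cat("  ROI-matched cluster:", object@selectedCluster, "(Dice",
        round(max(object@diceTable$dice), 3), ")\n")
})

#' ExpressionStudy: genes x samples with subtype, methylation and survival
#'
#' @slot expr Numeric genes x samples matrix.
#' @slot subtype Factor of per-sample molecular subtype labels (Classical,
#'   Mesenchymal, Proneural, Neural, Normal).
#' @slot methylation Numeric probes x samples matrix of beta values in
#'   \[0, 1\]; row names follow `<probe>_<gene>` so probes map to genes.
#' @slot survival data.frame with columns `sample`, `time` (days), `event`
#'   (1 = death observed, 0 = censored), optionally `event_dss` for
#'   disease-specific survival.
#' @slot geneInfo DataFrame of per-gene annotation (e.g. `lipid_enzyme`).
#' @slot metadata Named list (simulation ground truth lives here).
#' @export
setClass("ExpressionStudy",
  slots = c(expr = "matrix", subtype = "factor", methylation = "matrix",
            survival = "data.frame", geneInfo = "DataFrame",
            metadata = "list"))

setValidity("ExpressionStudy", function(object) {
  if (ncol(object@expr) != length(object@subtype))
    return("subtype labels must match expression columns")
  if (nrow(object@methylation) &&
      ncol(object@methylation) != ncol(object@expr))
    return("methylation columns must match expression columns")
  if (length(object@methylation) &&
      (min(object@methylation) < 0 || max(object@methylation) > 1))
    return("methylation beta values must lie in [0, 1]")
  if (nrow(object@survival) && any(object@survival$time <= 0))
    return("survival times must be positive")
  TRUE
})

setMethod("show", "ExpressionStudy", function(object) {
  cat("ExpressionStudy:", nrow(object@expr), "genes x", ncol(object@expr),
      "samples\n  subtypes:",
      paste(names(table(object@subtype)), table(object@subtype),
            sep = "=", collapse = " "), "\n")
  if (nrow(object@methylation))
    cat("  methylation probes:", nrow(object@methylation), "\n")
  if (nrow(object@survival))
    cat("  survival records:", nrow(object@survival), "\n")
})

#' LipidModuleSet: co-expression modules with subtype enrichment
#'
#' @slot modules Named list of character gene vectors (disjoint).
#' @slot notCorrelated Character vector of genes assigned to no module.
#' @slot hubs Named list of hub genes (top intramodular connectivity).
#' @slot parameters List of network parameters (beta, dissimilarity cutoff,
#'   minimum module size, merge threshold).
#' @slot nes Module x subtype matrix of normalized enrichment scores (empty
#'   until [moduleSubtypeNES()] is run).
#' @slot nesPadj Matching matrix of BH-adjusted permutation p-values.
#' @export
setClass("LipidModuleSet",
  slots = c(modules = "list", notCorrelated = "character", hubs = "list",
            parameters = "list", nes = "matrix", nesPadj = "matrix"))

setValidity("LipidModuleSet", function(object) {
  genes <- unlist(object@modules, use.names = FALSE)
  if (anyDuplicated(genes)) return("modules must be disjoint")
  p <- object@parameters
  if (!is.null(p$beta) && p$beta < 1) return("beta must be >= 1")
  if (!is.null(p$dissCutoff) &&
      (p$dissCutoff <= 0 || p$dissCutoff >= 1))
    return("dissimilarity cutoff must lie in (0, 1)")
  TRUE
})

setMethod("show", "LipidModuleSet", function(object) {
  cat("LipidModuleSet:", length(object@modules), "modules (sizes",
      paste(lengths(object@modules), collapse = ", "), "),",
      length(object@notCorrelated), "not-correlated genes\n")
  if (length(object@nes))
    cat("  NES scored against", ncol(object@nes), "subtypes\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
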