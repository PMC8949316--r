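#' Accessors for package classes
#'
#' `pixelCoords()` returns the pixel coordinate matrix; `peakList()` the
#' per-pixel centroided peaks; `sectionMetadata()` the section metadata list;
#' `roiMask()` the logical region-of-interest mask; `segmentLabels()` the
#' per-pixel cluster labels; `selectedCluster()` the ROI-matched cluster id;
#' `diceTable()` the per-cluster Dice table; `exprMatrix()`, `subtypeLabels()`,
#' `methylationBetas()`, `survivalRecords()` the expression-study components;
#' `moduleGenes()` and `hubGenes()` the module memberships.
#'
#' @param x An object of the corresponding class.
#' @return See each accessor's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))
#' @rdname accessors
#' @export
setGeneric("peakList", function(x) standardGeneric("peakList"))
#' @rdname accessors
#' @export
setGeneric("sectionMetadata", function(x) standardGeneric("sectionMetadata"))
#' @rdname accessors
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))
#' @rdname accessors
#' @export
setGeneric("segmentLabels", function(x) standardGeneric("segmentLabels"))
#' @rdname accessors
#' @export
setGeneric("selectedCluster", function(x) standardGeneric("selectedCluster"))
#' @rdname accessors
#' @export
setGeneric("diceTable", function(x) standardGeneric("diceTable"))
#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))
#' @rdname accessors
#' @export
setGeneric("subtypeLabels", function(x) standardGeneric("subtypeLabels"))
#' @rdname accessors
#' @export
setGeneric("methylationBetas", function(x) standardGeneric("methylationBetas"))
#' @rdname accessors
#' @export
setGeneric("survivalRecords", function(x) standardGeneric("survivalRecords"))
#' @rdname accessors
#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))
#' @rdname accessors
#' @export
setGeneric("hubGenes", function(x) standardGeneric("hubGenes"))

#' @rdname accessors
#' @export
setMethod("pixelCoords", "IMSDataset", function(x) x@coords)
#' @rdname accessors
#' @export
setMethod("peakList", "IMSDataset", function(x)
  lapply(seq_len(nrow(x@coords)), function(i)
    list(mz = x@mz[[i]], intensity = x@intensity[[i]])))
#' @rdname accessors
#' @export
setMethod("sectionMetadata", "IMSDataset", function(x) x@metadata)
#' @rdname accessors
#' @export
setMethod("roiMask", "IMSDataset", function(x) x@metadata$roi_mask)
#' @rdname accessors
#' @export
setMethod("segmentLabels", "SegmentationResult", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("pixelCoords", "SegmentationResult", function(x) x@coords)
#' @rdname accessors
#' @export
setMethod("selectedCluster", "SegmentationResult", function(x)
  x@selectedCluster)
#' @rdname accessors
#' @export
setMethod("diceTable", "SegmentationResult", function(x) x@diceTable)
#' @rdname accessors
#' @export
setMethod("exprMatrix", "ExpressionStudy", function(x) x@expr)
#' @rdname accessors
#' @export
setMethod("subtypeLabels", "ExpressionStudy", function(x) x@subtype)
#' @rdname accessors
#' @export
setMethod("methylationBetas", "ExpressionStudy", function(x) x@methylation)
#' @rdname accessors
#' @export
setMethod("survivalRecords", "ExpressionStudy", function(x) x@survival)
#' @rdname accessors
#' @export
setMethod("moduleGenes", "LipidModuleSet", function(x) x@modules)
#' @rdname accessors
#' @importFrom S4Vectors metadata
#' @export metadata
#' @exportMethod metadata
setMethod("metadata", "ExpressionStudy", function(x, ...) x@metadata)
#' @rdname accessors
#' @export
setMethod("hubGenes", "LipidModuleSet", function(x) x@hubs)
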