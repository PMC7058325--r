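#' Pixel grid of an image-like object
#'
#' @param x a [FundusImage-class], [VesselMask-class] or [HeatMap-class].
#' @return numeric matrix (rows = y, columns = x).
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "FundusImage", function(x) x@pixels)
#' @rdname pixels
#' @export
setMethod("pixels", "VesselMask", function(x) x@pixels)
#' @rdname pixels
#' @export
setMethod("pixels", "HeatMap", function(x) x@values)

#' Class label of a fundus image
#' @param x a [FundusImage-class].
#' @export
setGeneric("imageLabel", function(x) standardGeneric("imageLabel"))
#' @rdname imageLabel
#' @export
setMethod("imageLabel", "FundusImage", function(x) x@label)

#' Provenance stage of a fundus image
#' @param x a [FundusImage-class].
#' @return one of `"raw"`, `"enhanced"`, `"segmented"`.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname provenance
#' @export
setMethod("provenance", "FundusImage", function(x) x@provenance)

#' Bifurcation records of a vascular tree
#' @param x a [VascularTree-class].
#' @return data.frame, one row per bifurcation.
#' @export
setGeneric("bifurcations", function(x) standardGeneric("bifurcations"))
#' @rdname bifurcations
#' @export
setMethod("bifurcations", "VascularTree", function(x) x@bifurcations)

#' Segment table of a vascular tree
#' @param x a [VascularTree-class].
#' @export
setGeneric("treeSegments", function(x) standardGeneric("treeSegments"))
#' @rdname treeSegments
#' @export
setMethod("treeSegments", "VascularTree", function(x) x@segments)

#' Node coordinates of a vascular tree
#' @param x a [VascularTree-class].
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))
#' @rdname treeNodes
#' @export
setMethod("treeNodes", "VascularTree", function(x) x@nodes)

#' Fold assignments of a cross-validation plan
#' @param x a [FoldPlan-class].
#' @return integer vector, test-fold index per record.
#' @export
setGeneric("foldAssignments", function(x) standardGeneric("foldAssignments"))
#' @rdname foldAssignments
#' @export
setMethod("foldAssignments", "FoldPlan", function(x) x@assignments)

#' Fold membership lists of a cross-validation plan
#' @param x a [FoldPlan-class].
#' @param i fold index.
#' @return list with `test`, `development`, `train`, `validation` indices.
#' @export
setGeneric("foldRecords", function(x, i) standardGeneric("foldRecords"))
#' @rdname foldRecords
#' @export
setMethod("foldRecords", "FoldPlan", function(x, i) x@folds[[i]])

#' Metrics report as a one-row data.frame
#' @param x a [MetricsReport-class].
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))
#' @rdname metricsTable
#' @export
setMethod("metricsTable", "MetricsReport", function(x) {
  data.frame(fold = x@fold, accuracy = x@accuracy,
             specificity = x@specificity, precision = x@precision,
             recall = x@recall, auc = x@auc, n = x@nImages,
             stringsAsFactors = FALSE)
})

#' Enrichment ratio of an attribution result
#' @param x an [EnrichmentResult-class].
#' @export
setGeneric("enrichmentRatio", function(x) standardGeneric("enrichmentRatio"))
#' @rdname enrichmentRatio
#' @export
setMethod("enrichmentRatio", "EnrichmentResult", function(x) x@ratio)

setMethod("show", "SimulatorConfig", function(object) {
  cat("SimulatorConfig:", object@imageSize, "x", object@imageSize,
      "px, depth", object@treeDepth, "\n")
  cat(sprintf("  asymmetry %.2f +/- %.2f (class effect %+.2f), angle %.0f +/- %.0f deg (%+.0f)\n",
              object@asymmetryMean, object@asymmetrySd, object@classEffect,
              object@angleMean, object@angleSd, object@classEffectAngle))
  cat(sprintf("  effect mode: %s; Murray exponent %.1f; seed %d\n",
              object@effectMode, object@murrayExponent, object@seed))
})

setMethod("show", "VascularTree", function(object) {
  cat(sprintf("VascularTree: %d nodes, %d segments, %d bifurcations (%d px image)\n",
              nrow(object@nodes), nrow(object@segments),
              nrow(object@bifurcations), object@imageSize))
})

setMethod("show", "FundusImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FundusImage %dx%d [%s, %s, subject %s]\n",
              d[1], d[2], object@provenance, object@label, object@subjectId))
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d folds over %d records (%s)\n", object@k,
              length(object@assignments),
              if (object@grouped) "subject-grouped" else "record-level"))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              object@tp, object@tn, object@fp, object@fn,
              object@tp + object@tn + object@fp + object@fn))
})

setMethod("show", "MetricsReport", function(object) {
  fmt <- function(v) ifelse(is.na(v), "undef", sprintf("%.2f%%", 100 * v))
  cat(sprintf("MetricsReport [fold %s, n=%d]\n", object@fold, object@nImages))
  cat(sprintf("  accuracy %s  specificity %s  precision %s  recall %s  AUC %s\n",
              fmt(object@accuracy), fmt(object@specificity),
              fmt(object@precision), fmt(object@recall),
              ifelse(is.na(object@auc), "undef", sprintf("%.4f", object@auc))))
})

setMethod("show", "EnrichmentResult", function(object) {
  if (object@defined)
    cat(sprintf("EnrichmentResult: ratio %.3f (%d bifurcations, radius %.1f px)\n",
                object@ratio, object@nBifurcations, object@radius))
  else cat("EnrichmentResult: undefined (no bifurcations)\n")
})

setMethod("show", "SegmenterModel", function(object) {
  cat(sprintf("SegmenterModel: depth %d, base filters %d, %d epochs (final loss %.4f)\n",
              object@config$depth, object@config$baseFilters,
              length(object@history), utils::tail(object@history, 1)))
})

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf("ClassifierModel: conv filters %s, input %d px, %d epochs\n",
              paste(object@config$convFilters, collapse = "-"),
              object@config$inputSide, nrow(object@history)))
})
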