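#' @import methods
NULL

.CLASS_LEVELS <- c("non-hypertension", "hypertension")

#' Simulator configuration
#'
#' Parameters of the synthetic vascular-tree world: image geometry, Murray's
#' exponent, bifurcation-angle and asymmetry-ratio distributions, the
#' class-conditional branching effect, and rendering knobs.
#'
#' The asymmetry ratio at a bifurcation is the squared ratio of the two
#' daughter diameters, \eqn{(\min(d_1,d_2)/\max(d_1,d_2))^2 \in (0,1]}.
#' `classEffect` is added to `asymmetryMean` (and `classEffectAngle` to
#' `angleMean`, in degrees) for the "hypertension" class. `effectMode`
#' selects where the class signal is planted: `"bifurcation"` (geometry at
#' branch points, the default) or `"diffuse"` (a uniform relative caliber
#' shift `caliberShift`, the negative control for attribution analyses).
#'
#' @slot imageSize integer, pixels per (square) side, >= 64.
#' @slot treeDepth integer, maximum number of bifurcation generations.
#' @slot rootDiameter numeric, root vessel diameter in pixels.
#' @slot murrayExponent numeric, exponent m in \eqn{d_p^m = d_1^m + d_2^m}.
#' @slot angleMean,angleSd numeric, total bifurcation opening angle (degrees).
#' @slot asymmetryMean,asymmetrySd numeric, asymmetry-ratio distribution.
#' @slot classEffect numeric, additive shift of `asymmetryMean` for the
#'   hypertension class.
#' @slot classEffectAngle numeric, additive shift of `angleMean` (degrees)
#'   for the hypertension class.
#' @slot effectMode character, `"bifurcation"` or `"diffuse"`.
#' @slot caliberShift numeric, relative diameter change for the hypertension
#'   class in diffuse mode (e.g. -0.15 narrows all vessels by 15%).
#' @slot backgroundTextureSd,illuminationGradient,vesselContrast numeric,
#'   rendering knobs (all dimensionless, intensities live in \[0,1\]).
#' @slot darkVessels logical, vessel polarity (dark on bright background).
#' @slot twoEyeProb numeric, probability that a subject contributes two
#'   images (two eyes).
#' @slot seed integer, base seed.
#' @exportClass SimulatorConfig
setClass("SimulatorConfig", representation(
  imageSize = "integer", treeDepth = "integer", rootDiameter = "numeric",
  murrayExponent = "numeric", angleMean = "numeric", angleSd = "numeric",
  asymmetryMean = "numeric", asymmetrySd = "numeric",
  classEffect = "numeric", classEffectAngle = "numeric",
  effectMode = "character", caliberShift = "numeric",
  backgroundTextureSd = "numeric", illuminationGradient = "numeric",
  vesselContrast = "numeric", darkVessels = "logical",
  twoEyeProb = "numeric", seed = "integer"))

setValidity("SimulatorConfig", function(object) {
  msg <- character()
  if (object@imageSize < 64L) msg <- c(msg, "imageSize must be >= 64")
  if (object@murrayExponent <= 0) msg <- c(msg, "murrayExponent must be > 0")
  if (object@angleMean <= 0 || object@angleMean >= 180)
    msg <- c(msg, "angleMean must lie in (0, 180) degrees")
  hi <- object@asymmetryMean + abs(object@classEffect)
  lo <- object@asymmetryMean - abs(object@classEffect)
  if (lo <= 0 || hi > 1)
    msg <- c(msg, "asymmetryMean +/- |classEffect| must lie in (0, 1]")
  if (!object@effectMode %in% c("bifurcation", "diffuse"))
    msg <- c(msg, "effectMode must be 'bifurcation' or 'diffuse'")
  if (object@twoEyeProb < 0 || object@twoEyeProb > 1)
    msg <- c(msg, "twoEyeProb must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic vascular tree
#'
#' Geometric ground truth for one eye: node positions, tapered segments, and
#' per-bifurcation records (parent/daughter diameters, opening angle,
#' asymmetry ratio). Coordinates are 0-based, x = column, y = row, origin at
#' the top-left of the image.
#'
#' @slot nodes numeric matrix, one row per node, columns `x`, `y`.
#' @slot segments data.frame with `parent`, `child` (node indices,
#'   1-based), `diameter` (width at the parent end, pixels) and
#'   `diameterEnd` (width at the child end; segments taper linearly from
#'   the junction-planted width to the carried subtree width).
#' @slot bifurcations data.frame with `node`, `x`, `y`, `d_parent`, `d1`,
#'   `d2`, `angle_deg`, `asymmetry`.
#' @slot imageSize integer side length of the target image.
#' @exportClass VascularTree
setClass("VascularTree", representation(
  nodes = "matrix", segments = "data.frame", bifurcations = "data.frame",
  imageSize = "integer"))

setValidity("VascularTree", function(object) {
  msg <- character()
  seg <- object@segments
  if (nrow(seg)) {
    kids <- table(factor(seg$parent, levels = seq_len(nrow(object@nodes))))
    if (any(!kids %in% c(0L, 1L, 2L)))
      msg <- c(msg, "each node must have 0, 1 or 2 daughter segments")
    if (nrow(object@bifurcations) != sum(kids == 2L))
      msg <- c(msg, "bifurcation records must match nodes with two daughters")
  }
  if (any(object@nodes < 0) || any(object@nodes > object@imageSize - 1L))
    msg <- c(msg, "node coordinates must lie inside the image")
  if (length(msg)) msg else TRUE
})

#' Fundus-style image
#'
#' A single-channel intensity grid in \[0,1\] with its class label, subject
#' identifier (two images may share a subject, mimicking two eyes), and
#' provenance stage (`raw`, `enhanced` or `segmented`).
#'
#' @slot pixels numeric matrix, intensities in \[0,1\]; rows = y, columns = x.
#' @slot label character, `"hypertension"` or `"non-hypertension"`.
#' @slot subjectId character, opaque subject identifier.
#' @slot provenance character, one of `raw`, `enhanced`, `segmented`.
#' @exportClass FundusImage
setClass("FundusImage", representation(
  pixels = "matrix", label = "character", subjectId = "character",
  provenance = "character"))

setValidity("FundusImage", function(object) {
  msg <- character()
  p <- object@pixels
  if (any(p < 0 | p > 1)) msg <- c(msg, "intensities must lie in [0,1]")
  if (!object@label %in% .CLASS_LEVELS)
    msg <- c(msg, sprintf("label must be one of: %s",
                          paste(.CLASS_LEVELS, collapse = ", ")))
  if (!object@provenance %in% c("raw", "enhanced", "segmented"))
    msg <- c(msg, "provenance must be raw, enhanced or segmented")
  if (length(msg)) msg else TRUE
})

#' Binary vessel mask
#'
#' @slot pixels integer/numeric matrix of 0/1, aligned to its image.
#' @exportClass VesselMask
setClass("VesselMask", representation(pixels = "matrix"))

setValidity("VesselMask", function(object) {
  if (!all(object@pixels %in% c(0, 1))) "mask values must be 0 or 1" else TRUE
})

#' Nested cross-validation fold plan
#'
#' Bookkeeping for the five-fold protocol: every record is assigned to one
#' test fold; the remaining records form that fold's development set, which
#' is further split 75/25 into train and validation. With grouping enabled,
#' all records of one subject share a fold (no eye-level leakage).
#'
#' @slot k integer, number of folds.
#' @slot assignments integer vector, test-fold index per record.
#' @slot folds list, per fold: `test`, `development`, `train`, `validation`
#'   (record indices).
#' @slot grouped logical, whether subject grouping was applied.
#' @slot seed integer.
#' @exportClass FoldPlan
setClass("FoldPlan", representation(
  k = "integer", assignments = "integer", folds = "list",
  grouped = "logical", seed = "integer"))

setValidity("FoldPlan", function(object) {
  msg <- character()
  n <- length(object@assignments)
  for (i in seq_len(object@k)) {
    f <- object@folds[[i]]
    if (!setequal(c(f$test, f$development), seq_len(n)))
      msg <- c(msg, "test and development must partition the records")
    if (length(intersect(f$test, f$development)))
      msg <- c(msg, "test and development overlap")
    if (!setequal(c(f$train, f$validation), f$development))
      msg <- c(msg, "train and validation must partition the development set")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' Confusion-matrix counts
#'
#' TP are correctly classified hypertension images, TN correctly classified
#' non-hypertension images, FP non-hypertension images called hypertension,
#' FN hypertension images called non-hypertension.
#'
#' @slot tp,tn,fp,fn non-negative integer counts.
#' @exportClass ConfusionCounts
setClass("ConfusionCounts", representation(
  tp = "integer", tn = "integer", fp = "integer", fn = "integer"))

setValidity("ConfusionCounts", function(object) {
  if (any(c(object@tp, object@tn, object@fp, object@fn) < 0L))
    "counts must be non-negative" else TRUE
})

#' Per-fold or averaged classification metrics
#'
#' Accuracy, specificity, precision, recall and AUC as fractions in \[0,1\].
#' A metric whose denominator is zero is `NA` and listed in `undefined`
#' rather than silently reported as 0.
#'
#' @slot accuracy,specificity,precision,recall,auc numeric (possibly NA).
#' @slot undefined character, names of undefined metrics.
#' @slot fold character, fold label (e.g. "1".."5" or "average").
#' @slot nImages integer, number of evaluated images.
#' @exportClass MetricsReport
setClass("MetricsReport", representation(
  accuracy = "numeric", specificity = "numeric", precision = "numeric",
  recall = "numeric", auc = "numeric", undefined = "character",
  fold = "character", nImages = "integer"))

setValidity("MetricsReport", function(object) {
  v <- c(object@accuracy, object@specificity, object@precision,
         object@recall, object@auc)
  if (any(!is.na(v) & (v < 0 | v > 1)))
    "metrics must lie in [0,1] when defined" else TRUE
})

#' Grad-CAM heat map
#'
#' Non-negative class-activation grid, max-normalized to \[0,1\], spatially
#' aligned to the classifier input after bilinear upsampling.
#'
#' @slot values numeric matrix, all >= 0, max = 1 unless all-zero.
#' @slot sourceId character, id of the image explained.
#' @slot targetClass character, class whose score was attributed.
#' @exportClass HeatMap
setClass("HeatMap", representation(
  values = "matrix", sourceId = "character", targetClass = "character"))

setValidity("HeatMap", function(object) {
  v <- object@values
  if (any(v < 0)) return("heat-map values must be non-negative")
  if (max(v) > 0 && abs(max(v) - 1) > 1e-8)
    return("heat map must be max-normalized")
  TRUE
})

#' Bifurcation-localization enrichment of a heat map
#'
#' Ratio of heat-map mass density inside radius-r disks around bifurcations
#' to the mass density over the whole vessel-adjacent region. 1 means no
#' preference; > 1 means activation concentrates at bifurcations.
#'
#' @slot ratio numeric (NA when undefined).
#' @slot massNear,totalMass numeric, heat-map mass inside disks / overall.
#' @slot areaNear,totalArea numeric, pixel areas of the two regions.
#' @slot radius numeric, disk radius in pixels.
#' @slot nBifurcations integer.
#' @slot defined logical.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult", representation(
  ratio = "numeric", massNear = "numeric", totalMass = "numeric",
  areaNear = "numeric", totalArea = "numeric", radius = "numeric",
  nBifurcations = "integer", defined = "logical"))

setValidity("EnrichmentResult", function(object) {
  if (object@defined && object@massNear > object@totalMass + 1e-9)
    "mass near bifurcations cannot exceed total mass" else TRUE
})

#' Trained U-Net vessel segmenter
#'
#' @slot params list of weight arrays.
#' @slot config list, the `segmenterConfig()` used for training.
#' @slot history numeric, mean training loss per epoch.
#' @exportClass SegmenterModel
setClass("SegmenterModel", representation(
  params = "list", config = "list", history = "numeric"))

#' Trained CNN classifier
#'
#' @slot params list of weight arrays (conv, batch-norm, dense stages).
#' @slot config list, the `classifierConfig()` used for training.
#' @slot history data.frame with `epoch`, `train_loss`, `val_loss`.
#' @slot classes character, class order of the softmax output.
#' @exportClass ClassifierModel
setClass("ClassifierModel", representation(
  params = "list", config = "list", history = "data.frame",
  classes = "character"))
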