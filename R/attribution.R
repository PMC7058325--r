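# Grad-CAM class-activation maps and the bifurcation-localization
# enrichment statistic that turns "activation sits on or around vessel
# bifurcations" into a number.

#' Grad-CAM heat map for one image
#'
#' Channel weights are the spatial means of the target-class score gradient
#' over the final convolution stage's activation maps; the map is the
#' rectified weighted sum of those maps, bilinearly upsampled to the
#' classifier input size and max-normalized. Deterministic at inference.
#'
#' @param model a trained [ClassifierModel-class].
#' @param image a [FundusImage-class] or matrix (resized internally to the
#'   classifier input side).
#' @param targetClass class whose score is attributed.
#' @param sourceId identifier stored in the result.
#' @return a [HeatMap-class].
#' @export
gradCam <- function(model, image, targetClass = "hypertension",
                    sourceId = "img") {
  if (!is(model, "ClassifierModel") || !length(model@params))
    stopModel("not a trained classifier model")
  cfg <- model@config
  S <- cfg$inputSide
  m <- clip01(resizeMatrix(.pixelsOf(image), S))
  x <- array(m, c(S, S, 1L, 1L))
  fw <- cnnForward(model@params, x, cfg, training = FALSE)
  cIdx <- match(targetClass, model@classes)
  if (is.na(cIdx)) stopConfig("unknown target class: ", targetClass)
  dlogits <- matrix(0, 2L, 1L)
  dlogits[cIdx, 1L] <- 1
  bk <- cnnBackward(dlogits, fw$caches, model@params, cfg,
                    stopAtLastConv = TRUE)
  A <- fw$caches$lastConvAct   # (h, w, C, 1)
  dA <- bk$dLastConvAct
  w <- apply(dA[, , , 1L, drop = FALSE], 3, mean)
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_along(w)) cam <- cam + w[k] * A[, , k, 1L]
  cam <- pmax(cam, 0)
  cam <- resizeMatrix(cam, S)
  cam <- pmax(cam, 0)
  if (max(cam) > 0) cam <- cam / max(cam)
  new("HeatMap", values = cam, sourceId = sourceId,
      targetClass = targetClass)
}

#' Detect bifurcations in a binary vessel mask
#'
#' Skeletonizes the mask (Zhang-Suen thinning) and reports branch points:
#' skeleton pixels whose 8-neighbourhood crossing number (0-to-1
#' transitions around the circle of neighbours) is three or more, i.e.
#' pixels where at least three skeleton branches meet. The crossing-number
#' rule is robust to the staircase patterns of rasterized diagonal lines,
#' which carry three raw neighbours without being junctions. Detections
#' closer than `mergeRadius` pixels are merged into their centroid.
#'
#' @param mask a [VesselMask-class] or binary matrix.
#' @param mergeRadius cluster-merge distance, pixels.
#' @return data.frame with columns `x`, `y` (0-based, x = column).
#' @export
detectBifurcations <- function(mask, mergeRadius = 3) {
  m <- if (is(mask, "VesselMask")) mask@pixels else mask
  if (!any(m > 0)) return(data.frame(x = numeric(), y = numeric()))
  skel <- .thin_cpp(matrix(as.integer(m > 0), nrow(m), ncol(m)))
  H <- nrow(skel); W <- ncol(skel)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- skel
  shift <- function(dr, dc) pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  # neighbours in circular order; crossing number = # of 0 -> 1 steps
  ring <- list(shift(-1, 0), shift(-1, 1), shift(0, 1), shift(1, 1),
               shift(1, 0), shift(1, -1), shift(0, -1), shift(-1, -1))
  trans <- matrix(0L, H, W)
  for (i in 1:8) {
    j <- if (i == 8L) 1L else i + 1L
    trans <- trans + (ring[[i]] == 0L & ring[[j]] == 1L)
  }
  bp <- which(skel == 1L & trans >= 3L, arr.ind = TRUE)
  if (nrow(bp) == 0L) return(data.frame(x = numeric(), y = numeric()))
  pts <- data.frame(x = bp[, 2] - 1, y = bp[, 1] - 1)
  if (nrow(pts) > 1L) {
    cl <- stats::cutree(stats::hclust(stats::dist(pts), method = "single"),
                        h = mergeRadius)
    pts <- do.call(rbind, lapply(split(pts, cl), function(g)
      data.frame(x = mean(g$x), y = mean(g$y))))
    rownames(pts) <- NULL
  }
  pts
}

#' Bifurcation-localization enrichment of a heat map
#'
#' Compares heat-map mass density inside radius-`radius` disks around the
#' bifurcation points (intersected with the vessel-adjacent region) against
#' the density over the whole vessel-adjacent region (the mask dilated by
#' the same radius): `ratio = (massNear/areaNear) / (totalMass/totalArea)`.
#' A uniform map over the vessel region scores exactly 1; the ratio is
#' invariant to positive scaling of the heat map.
#'
#' @param heatmap a [HeatMap-class] or non-negative matrix.
#' @param bifurcations data.frame with `x`, `y` columns (0-based), in the
#'   heat map's coordinate system.
#' @param mask a [VesselMask-class] or binary matrix, same dimensions as
#'   the heat map.
#' @param radius disk radius in pixels (>= 1).
#' @return an [EnrichmentResult-class]; undefined (flagged) when there are
#'   no bifurcations or no heat mass on the vessel region.
#' @export
localizationEnrichment <- function(heatmap, bifurcations, mask, radius) {
  h <- if (is(heatmap, "HeatMap")) heatmap@values else heatmap
  m <- if (is(mask, "VesselMask")) mask@pixels else mask
  if (!identical(dim(h), dim(m)))
    stopData("heat map and mask dimensions are misaligned")
  if (radius < 1) stopConfig("radius must be >= 1")
  undef <- function(n) new("EnrichmentResult", ratio = NA_real_,
                           massNear = 0, totalMass = 0, areaNear = 0,
                           totalArea = 0, radius = radius,
                           nBifurcations = n, defined = FALSE)
  nb <- nrow(bifurcations)
  if (nb == 0L) return(undef(0L))
  H <- nrow(h); W <- ncol(h)
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(radius)) + 1L, "disc")
  vadj <- EBImage::imageData(EBImage::dilate(EBImage::Image(m * 1),
                                             brush)) > 0
  near <- matrix(FALSE, H, W)
  for (i in seq_len(nb)) {
    # pixel (r, c) holds coordinate (x = c - 1, y = r - 1)
    r0 <- max(1L, floor(bifurcations$y[i] + 1 - radius))
    r1 <- min(H, ceiling(bifurcations$y[i] + 1 + radius))
    c0 <- max(1L, floor(bifurcations$x[i] + 1 - radius))
    c1 <- min(W, ceiling(bifurcations$x[i] + 1 + radius))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    dd <- outer((rr - 1) - bifurcations$y[i], (cc - 1) - bifurcations$x[i],
                function(a, b) a^2 + b^2)
    near[rr, cc] <- near[rr, cc] | (dd <= radius^2)
  }
  near <- near & vadj
  totalMass <- sum(h[vadj])
  massNear <- sum(h[near])
  areaNear <- sum(near)
  totalArea <- sum(vadj)
  if (totalMass <= 0 || areaNear == 0) return(undef(as.integer(nb)))
  ratio <- (massNear / areaNear) / (totalMass / totalArea)
  new("EnrichmentResult", ratio = ratio, massNear = massNear,
      totalMass = totalMass, areaNear = areaNear, totalArea = totalArea,
      radius = radius, nBifurcations = as.integer(nb), defined = TRUE)
}

# Mean local vessel diameter of a mask, estimated as vessel area over
# skeleton length; used for the default enrichment radius (2x diameter).
meanVesselDiameter <- function(mask) {
  m <- if (is(mask, "VesselMask")) mask@pixels else mask
  if (!any(m > 0)) return(NA_real_)
  skel <- .thin_cpp(matrix(as.integer(m > 0), nrow(m), ncol(m)))
  sl <- sum(skel)
  if (sl == 0) return(NA_real_)
  sum(m > 0) / sl
}

#' Cohort-level attribution report
#'
#' For every correctly classified image (score >= 0.5 matching the true
#' label), computes the Grad-CAM heat map for its true class, upsamples it
#' to the image size, and scores bifurcation enrichment against the
#' image's vessel mask and annotated bifurcations. Heat maps are made only
#' for correctly classified images, mirroring how class-activation
#' evidence is read off a test set.
#'
#' @param model a trained [ClassifierModel-class].
#' @param images list of (segmented) [FundusImage-class] or matrices.
#' @param labels class labels per image.
#' @param masks list of [VesselMask-class] or binary matrices (ground
#'   truth or segmenter output).
#' @param bifurcationTables list of data.frames with `x`, `y` per image
#'   (simulator annotations or [detectBifurcations()] output), in image
#'   coordinates.
#' @param radius disk radius in pixels; `NULL` uses 2x the mean local
#'   vessel diameter per image.
#' @param ids image identifiers.
#' @return list with `table` (per-image data.frame: id, label, score,
#'   correct, target_class, ratio, n_bifurcations, mass_near, total_mass)
#'   and `summary` (per-class mean/median ratio and a two-sided Wilcoxon
#'   comparison of hypertension-class vs non-hypertension-class ratios).
#' @export
cohortAttributionReport <- function(model, images, labels, masks,
                                    bifurcationTables, radius = NULL,
                                    ids = NULL) {
  n <- length(images)
  if (is.null(ids)) ids <- sprintf("img%03d", seq_len(n))
  scores <- predictScores(model, images)
  pos <- .isPositive(labels)
  correct <- (scores >= 0.5) == pos
  rows <- list()
  for (i in seq_len(n)) {
    if (!correct[i]) next
    msk <- if (is(masks[[i]], "VesselMask")) masks[[i]]@pixels else masks[[i]]
    side <- nrow(msk)
    rad <- if (is.null(radius)) {
      d <- meanVesselDiameter(msk)
      if (is.na(d)) next
      max(2, 2 * d)
    } else radius
    cls <- as.character(labels[i])
    hm <- gradCam(model, images[[i]], targetClass = cls, sourceId = ids[i])
    hv <- resizeMatrix(hm@values, side)
    hv <- pmax(hv, 0)
    enr <- localizationEnrichment(hv, bifurcationTables[[i]], msk, rad)
    rows[[length(rows) + 1L]] <- data.frame(
      id = ids[i], label = cls, score = scores[i], correct = TRUE,
      target_class = cls, ratio = enr@ratio,
      n_bifurcations = enr@nBifurcations, mass_near = enr@massNear,
      total_mass = enr@totalMass, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), label = character(), score = numeric(),
               correct = logical(), target_class = character(),
               ratio = numeric(), n_bifurcations = integer(),
               mass_near = numeric(), total_mass = numeric())
  bycls <- split(tab$ratio[!is.na(tab$ratio)],
                 tab$label[!is.na(tab$ratio)])
  summ <- data.frame(
    class = names(bycls),
    n = vapply(bycls, length, 0L),
    mean_ratio = vapply(bycls, mean, 0),
    median_ratio = vapply(bycls, median, 0),
    stringsAsFactors = FALSE)
  pval <- if (length(bycls) == 2L && all(vapply(bycls, length, 0L) > 0L))
    suppressWarnings(wilcox.test(bycls[["hypertension"]],
                                 bycls[["non-hypertension"]])$p.value)
  else NA_real_
  list(table = tab, summary = summ, wilcox_p = pval)
}
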