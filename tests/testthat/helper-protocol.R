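# Reference analysis protocol shared by the acceptance tests (mirrored by
# scripts/acceptance.R): problem sizes, classifier settings and the
# attribution regime. One place to read the study design from.

acceptProtocol <- list(
  # segmenter competence: 40 training / 20 held-out pairs at 128 px
  segTrainPairs = 40L, segTestPairs = 20L, segSide = 128L,
  segEpochs = 5L, segPatches = 18L,
  # parameter recovery: 200 images/class, five folds, enhanced images,
  # 64-px classifier input. The "large planted effect" cohort shifts both
  # bifurcation-geometry knobs (asymmetry ratio and opening angle).
  cvPerClass = 200L, cvEpochs = 10L,
  # attribution: one model per mode at the full attribution protocol
  # (96-px input, final three stages unpooled -> 24x24 class-activation
  # map), evaluated on independently seeded cohorts
  attrPerClass = 100L, attrEpochs = 40L, attrDiffuseEpochs = 40L,
  attrEvalPerClass = 25L, attrEvalSeeds = 5L
)

# classifier for the parameter-recovery experiment (fast, coarse maps)
recoveryClassifierConfig <- function(seed = 1L) {
  classifierConfig(inputSide = 64L, trainResizeSide = 72L,
                   epochs = acceptProtocol$cvEpochs, batchSize = 8L,
                   seed = as.integer(seed))
}

# classifier for attribution: fine-grained final convolution map
attrClassifierConfig <- function(epochs, seed = 1L) {
  classifierConfig(convFilters = c(8L, 16L, 32L, 32L, 32L),
                   poolSizes = c(2L, 2L, 1L, 1L, 1L),
                   inputSide = 96L, trainResizeSide = 108L,
                   epochs = as.integer(epochs), batchSize = 8L,
                   seed = as.integer(seed))
}

# the "large bifurcation-planted effect" condition: asymmetry and angle
largeEffectConfig <- function() simulatorConfig(classEffectAngle = 20)

# Cohort of enhanced images (for classification experiments).
enhancedCohort <- function(simCfg, nPerClass, seed, side = 128L) {
  pre <- preprocessConfig(targetSide = side)
  co <- generateCohort(simCfg, nPerClass, seed = seed)
  list(images = lapply(co$records, function(r) enhanceImage(r$image, pre)),
       labels = co$manifest$label,
       subjects = co$manifest$subject_id)
}

# Vessel-only cohort: the enhancement geometry applied to image and mask,
# the mask standing as the idealized segmented image, bifurcation
# coordinates carried through the same transform.
vesselOnlyCohort <- function(simCfg, nPerClass, seed, side = 128L) {
  pre <- preprocessConfig(targetSide = side)
  co <- generateCohort(simCfg, nPerClass, seed = seed)
  pairs <- lapply(co$records, function(r) enhancePair(r$image, r$mask, pre))
  list(images = lapply(pairs, function(p) p$mask@pixels * 1),
       masks = lapply(pairs, `[[`, "mask"),
       bifs = lapply(seq_along(pairs), function(i) {
         tr <- pairs[[i]]$transform
         bf <- co$records[[i]]$bifurcations
         data.frame(x = (bf$x - tr$x0) * tr$scale,
                    y = (bf$y - tr$y0) * tr$scale)
       }),
       labels = co$manifest$label,
       subjects = co$manifest$subject_id,
       ids = co$manifest$id)
}

# Train the attribution model for one simulator mode on a vessel-only
# cohort (75/25 train/validation split; held-out evaluation happens on
# independently seeded cohorts).
trainAttributionModel <- function(world, epochs, seed) {
  n <- length(world$images)
  set.seed(seed + 7)
  ord <- sample(n)
  nv <- round(0.25 * n)
  model <- trainClassifier(world$images, world$labels,
                           attrClassifierConfig(epochs),
                           trainIdx = ord[-seq_len(nv)],
                           valIdx = ord[seq_len(nv)], seed = seed + 13)
  list(model = model)
}

# Median hypertension-class enrichment on a vessel-only world (or subset).
hypertensionEnrichmentMedian <- function(model, world, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(world$images)
  rep <- cohortAttributionReport(model, world$images[idx],
                                 world$labels[idx], world$masks[idx],
                                 world$bifs[idx], ids = world$ids[idx])
  median(rep$table$ratio[rep$table$label == "hypertension"], na.rm = TRUE)
}
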