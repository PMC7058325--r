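# Small CNN classifier and its training protocol: five conv/batch-norm/
# ReLU/max-pool stages, global max pooling, two dense layers with dropout,
# softmax over the two classes; nested five-fold partition with a 75/25
# development split, augmentation on the training split only, fixed-epoch
# stopping.

#' Create a classifier configuration
#'
#' The architecture has exactly five convolution stages (conv -> batch norm
#' -> ReLU -> max pool), global max pooling after the last stage, and two
#' dense layers (the second sized to the two classes) with dropout.
#' Filter counts are deliberately small to limit learnable parameters.
#' `inputSide`/`trainResizeSide` default to the classical 224/256 protocol
#' (resize to 256, random-crop to 224 during training); desk-scale analyses
#' pass smaller values. Epoch presets of 300 (enhanced) and 500 (segmented)
#' belong to the full-scale protocol; the default here is scaled down.
#'
#' @param convFilters integer vector of 5 filter counts.
#' @param kernelSizes,strides,poolSizes integer vectors of 5 (a pool size
#'   of 1 disables pooling at that stage, trading receptive-field reduction
#'   for attribution resolution).
#' @param denseUnits integer vector of 2; the last entry must be 2.
#' @param dropoutRates numeric vector of 2, each in \[0,1).
#' @param inputSide classifier input side (pixels).
#' @param trainResizeSide resize target before random cropping; must
#'   exceed `inputSide`.
#' @param epochs,batchSize,learningRate training settings (Adam).
#' @param brightnessJitter maximum relative brightness factor deviation.
#' @param seed integer seed.
#' @export
classifierConfig <- function(convFilters = c(8L, 16L, 32L, 32L, 32L),
                             kernelSizes = rep(3L, 5L),
                             strides = rep(1L, 5L),
                             poolSizes = rep(2L, 5L),
                             denseUnits = c(32L, 2L),
                             dropoutRates = c(0.5, 0),
                             inputSide = 224L, trainResizeSide = 256L,
                             epochs = 30L, batchSize = 32L,
                             learningRate = 1e-3, brightnessJitter = 0.2,
                             seed = 1L) {
  if (length(convFilters) != 5L || length(kernelSizes) != 5L ||
      length(strides) != 5L || length(poolSizes) != 5L)
    stopConfig("exactly 5 convolution stages are required")
  if (length(denseUnits) != 2L || length(dropoutRates) != 2L)
    stopConfig("exactly 2 dense stages are required")
  if (denseUnits[2] != 2L)
    stopConfig("the final dense layer must have 2 units (two classes)")
  if (any(dropoutRates < 0 | dropoutRates >= 1))
    stopConfig("dropout rates must lie in [0,1)")
  if (inputSide >= trainResizeSide)
    stopConfig("inputSide must be smaller than trainResizeSide")
  structure(list(convFilters = as.integer(convFilters),
                 kernelSizes = as.integer(kernelSizes),
                 strides = as.integer(strides),
                 poolSizes = as.integer(poolSizes),
                 denseUnits = as.integer(denseUnits),
                 dropoutRates = dropoutRates,
                 inputSide = as.integer(inputSide),
                 trainResizeSide = as.integer(trainResizeSide),
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate,
                 brightnessJitter = brightnessJitter,
                 seed = as.integer(seed)),
            class = "ClassifierConfig")
}

cnnInit <- function(cfg) {
  p <- list()
  cin <- 1L
  for (i in 1:5) {
    ini <- nnConvInit(cfg$kernelSizes[i], cin, cfg$convFilters[i])
    p[[paste0("conv", i, ".W")]] <- ini$W
    p[[paste0("conv", i, ".b")]] <- ini$b
    bn <- nnBnInit(cfg$convFilters[i])
    p[[paste0("bn", i, ".gamma")]] <- bn$gamma
    p[[paste0("bn", i, ".beta")]] <- bn$beta
    p[[paste0("bn", i, ".rm")]] <- bn$rm
    p[[paste0("bn", i, ".rv")]] <- bn$rv
    cin <- cfg$convFilters[i]
  }
  d1 <- nnDenseInit(cfg$convFilters[5], cfg$denseUnits[1])
  p[["fc1.W"]] <- d1$W; p[["fc1.b"]] <- d1$b
  d2 <- nnDenseInit(cfg$denseUnits[1], cfg$denseUnits[2])
  p[["fc2.W"]] <- d2$W; p[["fc2.b"]] <- d2$b
  p
}

#' Build an untrained CNN classifier
#'
#' Initializes weights for the configured architecture (He initialization,
#' drawn from the current RNG state under `config$seed`).
#'
#' @param config a [classifierConfig()].
#' @return an untrained [ClassifierModel-class].
#' @export
buildCnn <- function(config = classifierConfig()) {
  params <- withSeed(config$seed, cnnInit(config))
  new("ClassifierModel", params = params, config = unclass(config),
      history = data.frame(epoch = integer(), train_loss = numeric(),
                           val_loss = numeric()),
      classes = .CLASS_LEVELS)
}

#' Trainable parameter count of a classifier
#'
#' Batch-norm running statistics are bookkeeping, not trainable parameters.
#'
#' @param model a [ClassifierModel-class].
#' @export
parameterCount <- function(model) {
  nm <- names(model@params)
  sum(vapply(model@params[!grepl("\\.(rm|rv)$", nm)], length, 0L))
}

# Forward pass. Returns logits (2 x N), caches for the backward pass, and
# the post-ReLU activation of the fifth convolution stage (the Grad-CAM
# target layer).
cnnForward <- function(params, x, cfg, training) {
  caches <- list()
  h <- x
  for (i in 1:5) {
    cv <- nnConvFwd(h, params[[paste0("conv", i, ".W")]],
                    params[[paste0("conv", i, ".b")]], cfg$kernelSizes[i],
                    stride = cfg$strides[i])
    bnp <- list(gamma = params[[paste0("bn", i, ".gamma")]],
                beta = params[[paste0("bn", i, ".beta")]],
                rm = params[[paste0("bn", i, ".rm")]],
                rv = params[[paste0("bn", i, ".rv")]])
    bn <- nnBnFwd(cv$y, bnp, training)
    rl <- nnReluFwd(bn$y)
    pl <- nnPoolFwd(rl$y, cfg$poolSizes[i])
    caches[[i]] <- list(conv = cv$cache, bn = bn$cache, bnUpd = bn$bn,
                        relu = rl$cache, pool = pl)
    if (i == 5L) caches$lastConvAct <- rl$y
    h <- pl$y
  }
  gmp <- nnGmpFwd(h)
  caches$gmp <- gmp$cache
  f1 <- nnDenseFwd(gmp$y, params[["fc1.W"]], params[["fc1.b"]])
  r1 <- nnReluFwd(f1$y)
  dp1 <- nnDropoutFwd(r1$y, cfg$dropoutRates[1], training)
  f2 <- nnDenseFwd(dp1$y, params[["fc2.W"]], params[["fc2.b"]])
  dp2 <- nnDropoutFwd(f2$y, cfg$dropoutRates[2], training)
  caches$fc1 <- f1$cache; caches$r1 <- r1$cache; caches$dp1 <- dp1$cache
  caches$fc2 <- f2$cache; caches$dp2 <- dp2$cache
  list(logits = dp2$y, caches = caches)
}

# Backward pass from dlogits. With stopAtLastConv the gradient is returned
# at the fifth stage's post-ReLU activation (Grad-CAM) instead of being
# propagated through the remaining stages.
cnnBackward <- function(dlogits, caches, params, cfg,
                        stopAtLastConv = FALSE) {
  g <- list()
  dh <- nnDropoutBwd(dlogits, caches$dp2)
  b2 <- nnDenseBwd(dh, caches$fc2, params[["fc2.W"]])
  g[["fc2.W"]] <- b2$dW; g[["fc2.b"]] <- b2$db
  dh <- nnDropoutBwd(b2$dx, caches$dp1)
  dh <- nnReluBwd(dh, caches$r1)
  b1 <- nnDenseBwd(dh, caches$fc1, params[["fc1.W"]])
  g[["fc1.W"]] <- b1$dW; g[["fc1.b"]] <- b1$db
  dh <- nnGmpBwd(b1$dx, caches$gmp)
  for (i in 5:1) {
    cc <- caches[[i]]
    dh <- nnPoolBwd(dh, cc$pool)
    # the Grad-CAM target is the post-ReLU stage-5 activation: stop here,
    # before the ReLU backward
    if (i == 5L && stopAtLastConv) return(list(dLastConvAct = dh))
    dh <- nnReluBwd(dh, cc$relu)
    bnp <- list(gamma = params[[paste0("bn", i, ".gamma")]])
    bn <- nnBnBwd(dh, cc$bn, bnp)
    g[[paste0("bn", i, ".gamma")]] <- bn$dgamma
    g[[paste0("bn", i, ".beta")]] <- bn$dbeta
    cv <- nnConvBwd(bn$dx, cc$conv, params[[paste0("conv", i, ".W")]])
    g[[paste0("conv", i, ".W")]] <- cv$dW
    g[[paste0("conv", i, ".b")]] <- cv$db
    dh <- cv$dx
  }
  g
}

#' Build a nested cross-validation fold plan
#'
#' Partitions records into `k` test folds; each fold's complement is its
#' development set, split 75/25 into train and validation. With
#' `groupBySubject` (the default) all records of one subject share a fold
#' and a development side, preventing two eyes of one subject from leaking
#' between train and test; fold sizes are then balanced greedily and may
#' differ by up to the largest group size. Without grouping the folds are
#' exactly balanced (sizes differ by at most 1).
#'
#' @param labels character vector of class labels per record.
#' @param subjects character vector of subject ids per record.
#' @param k number of folds.
#' @param groupBySubject logical.
#' @param seed integer seed.
#' @return a [FoldPlan-class].
#' @export
makeFoldPlan <- function(labels, subjects = NULL, k = 5L,
                         groupBySubject = !is.null(subjects), seed = 1L) {
  n <- length(labels)
  if (groupBySubject && is.null(subjects))
    stopConfig("groupBySubject requires subject ids")
  units <- if (groupBySubject) split(seq_len(n), subjects)
  else as.list(seq_len(n))
  if (k > length(units))
    stopData("more folds than ", if (groupBySubject) "subjects" else "records")
  withSeed(seed, {
    units <- units[sample.int(length(units))]
    sizes <- integer(k)
    assign <- integer(n)
    for (u in units) {
      f <- which.min(sizes + runif(k) * 1e-9)
      assign[u] <- f
      sizes[f] <- sizes[f] + length(u)
    }
    folds <- lapply(seq_len(k), function(f) {
      test <- which(assign == f)
      dev <- which(assign != f)
      nVal <- round(0.25 * length(dev))
      devUnits <- if (groupBySubject)
        split(dev, subjects[dev]) else as.list(dev)
      devUnits <- devUnits[sample.int(length(devUnits))]
      val <- integer()
      for (u in devUnits) {
        if (length(val) >= nVal) break
        val <- c(val, u)
      }
      list(test = test, development = dev,
           train = setdiff(dev, val), validation = sort(val))
    })
    new("FoldPlan", k = as.integer(k), assignments = assign, folds = folds,
        grouped = isTRUE(groupBySubject), seed = as.integer(seed))
  })
}

# Augmentation core operating on a pre-resized (trainResizeSide) matrix
# using the current RNG stream: random crop to inputSide, random
# horizontal/vertical flips, random brightness factor, clipped to [0,1].
.augmentCore <- function(m, cfg) {
  S <- cfg$inputSide
  r0 <- sample.int(nrow(m) - S + 1L, 1L)
  c0 <- sample.int(ncol(m) - S + 1L, 1L)
  out <- m[r0:(r0 + S - 1L), c0:(c0 + S - 1L)]
  if (runif(1) < 0.5) out <- out[S:1, ]
  if (runif(1) < 0.5) out <- out[, S:1]
  f <- runif(1, 1 - cfg$brightnessJitter, 1 + cfg$brightnessJitter)
  out <- out * f
  if (f > 1) out[out > 1] <- 1   # inputs are non-negative already
  out
}

#' Random training augmentation
#'
#' Random crop from `trainResizeSide` to `inputSide`, random horizontal and
#' vertical flips, and a random brightness factor in
#' `\[1 - brightnessJitter, 1 + brightnessJitter\]` (clipped to \[0,1\]).
#'
#' @param image a [FundusImage-class] or matrix, already resized to
#'   `config$trainResizeSide`.
#' @param config a [classifierConfig()].
#' @param seed integer seed.
#' @return an `inputSide x inputSide` matrix (or [FundusImage-class]).
#' @export
augmentImage <- function(image, config, seed = 1L) {
  m <- .pixelsOf(image)
  if (nrow(m) != config$trainResizeSide || ncol(m) != config$trainResizeSide)
    stopData("augment input must be resized to trainResizeSide first")
  .rewrap(image, withSeed(seed, .augmentCore(m, config)))
}

.labelIndex <- function(labels) {
  if (is.numeric(labels) || is.logical(labels)) return(as.integer(labels) + 1L)
  idx <- match(as.character(labels), .CLASS_LEVELS)
  if (anyNA(idx)) stopData("labels must be one of: ",
                           paste(.CLASS_LEVELS, collapse = ", "))
  idx
}

#' Train the CNN classifier
#'
#' Trains for exactly `config$epochs` epochs with augmentation applied to
#' the training split only; validation images are evaluated un-augmented at
#' `inputSide` (batch norm in inference statistics, dropout off). If
#' `trainIdx`/`valIdx` are not supplied, a record-level 75/25 split of the
#' input is drawn. The history records train and validation loss per epoch.
#'
#' @param images list of [FundusImage-class] or matrices (native size; the
#'   function resizes internally).
#' @param labels class labels per image.
#' @param config a [classifierConfig()].
#' @param trainIdx,valIdx optional index vectors (e.g. from a
#'   [FoldPlan-class]).
#' @param seed integer seed; defaults to `config$seed`.
#' @param hook optional instrumentation callback, called as
#'   `hook(stage, ids)` with stage `"augment"` for every augmented batch.
#' @return a trained [ClassifierModel-class].
#' @export
trainClassifier <- function(images, labels, config = classifierConfig(),
                            trainIdx = NULL, valIdx = NULL,
                            seed = config$seed, hook = NULL) {
  n <- length(images)
  yIdx <- .labelIndex(labels)
  withSeed(seed, {
    if (is.null(trainIdx)) {
      ord <- sample.int(n)
      nVal <- round(0.25 * n)
      valIdx <- ord[seq_len(nVal)]
      trainIdx <- setdiff(ord, valIdx)
    }
    if (length(unique(yIdx[trainIdx])) < 2L)
      stopData("training split must contain both classes")
    trainImgs <- lapply(images[trainIdx], function(im)
      resizeMatrix(.pixelsOf(im), config$trainResizeSide))
    valImgs <- lapply(images[valIdx], function(im)
      clip01(resizeMatrix(.pixelsOf(im), config$inputSide)))
    yTrain <- yIdx[trainIdx]
    yVal <- yIdx[valIdx]
    params <- cnnInit(config)
    state <- nnAdamInit(params)
    S <- config$inputSide
    hist <- data.frame(epoch = seq_len(config$epochs),
                       train_loss = NA_real_, val_loss = NA_real_)
    xVal <- if (length(valImgs))
      array(unlist(valImgs), c(S, S, 1L, length(valImgs)))
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(trainImgs))
      losses <- c()
      for (b0 in seq(1L, length(ord), config$batchSize)) {
        ids <- ord[b0:min(b0 + config$batchSize - 1L, length(ord))]
        if (!is.null(hook)) hook("augment", trainIdx[ids])
        xb <- array(0, c(S, S, 1L, length(ids)))
        for (j in seq_along(ids))
          xb[, , 1L, j] <- .augmentCore(trainImgs[[ids[j]]], config)
        fw <- cnnForward(params, xb, config, training = TRUE)
        # persist batch-norm running statistics
        for (i in 1:5) {
          params[[paste0("bn", i, ".rm")]] <- fw$caches[[i]]$bnUpd$rm
          params[[paste0("bn", i, ".rv")]] <- fw$caches[[i]]$bnUpd$rv
        }
        ls <- nnSoftmaxCE(fw$logits, yTrain[ids])
        grads <- cnnBackward(ls$dlogits, fw$caches, params, config)
        st <- nnAdamStep(params, grads, state, config$learningRate)
        params <- st$params; state <- st$state
        losses <- c(losses, ls$loss)
      }
      hist$train_loss[ep] <- mean(losses)
      if (length(valImgs)) {
        fwv <- cnnForward(params, xVal, config, training = FALSE)
        hist$val_loss[ep] <- nnSoftmaxCE(fwv$logits, yVal)$loss
      }
    }
    new("ClassifierModel", params = params, config = unclass(config),
        history = hist, classes = .CLASS_LEVELS)
  })
}

#' Hypertension score for images
#'
#' Deterministic inference (dropout off, batch norm using running
#' statistics): images are resized to `inputSide` and the softmax
#' probability of the hypertension class is returned.
#'
#' @param model a trained [ClassifierModel-class].
#' @param images list of [FundusImage-class] or matrices.
#' @return numeric vector of scores in \[0,1\].
#' @export
predictScores <- function(model, images) {
  if (!is(model, "ClassifierModel") || !length(model@params))
    stopModel("not a trained classifier model")
  cfg <- model@config
  S <- cfg$inputSide
  xs <- lapply(images, function(im)
    clip01(resizeMatrix(.pixelsOf(im), S)))
  scores <- numeric(length(xs))
  bs <- 64L
  for (b0 in seq(1L, length(xs), bs)) {
    ids <- b0:min(b0 + bs - 1L, length(xs))
    x <- array(unlist(xs[ids]), c(S, S, 1L, length(ids)))
    fw <- cnnForward(model@params, x, cfg, training = FALSE)
    e <- exp(sweep(fw$logits, 2, apply(fw$logits, 2, max)))
    p <- sweep(e, 2, colSums(e), `/`)
    scores[ids] <- p[2L, ]
  }
  scores
}

#' Five-fold cross-validated training and evaluation
#'
#' Runs the full nested protocol: for each fold, train on that fold's
#' train/validation split and score the untouched test fold; per-fold
#' metrics are computed at threshold 0.5 and averaged.
#'
#' @param images list of images.
#' @param labels class labels per image.
#' @param subjects subject ids (for grouped folds); NULL for record-level
#'   folds.
#' @param config a [classifierConfig()].
#' @param k number of folds.
#' @param groupBySubject logical.
#' @param seed integer seed.
#' @return list with `plan`, `models`, `foldReports`, `average`
#'   ([MetricsReport-class]), and per-record test `scores`.
#' @export
crossValidate <- function(images, labels, subjects = NULL,
                          config = classifierConfig(), k = 5L,
                          groupBySubject = !is.null(subjects),
                          seed = config$seed) {
  plan <- makeFoldPlan(labels, subjects, k = k,
                       groupBySubject = groupBySubject,
                       seed = deriveSeed(seed, "folds"))
  scores <- rep(NA_real_, length(images))
  foldReports <- list()
  models <- list()
  for (f in seq_len(k)) {
    fr <- plan@folds[[f]]
    model <- trainClassifier(images, labels, config,
                             trainIdx = fr$train, valIdx = fr$validation,
                             seed = deriveSeed(seed, "train") + f)
    sc <- predictScores(model, images[fr$test])
    scores[fr$test] <- sc
    cm <- confusionCounts(sc, labels[fr$test])
    # a tiny unstratified fold can hold a single class; its AUC is then
    # undefined and flagged rather than fatal
    auc <- tryCatch(aucScore(sc, labels[fr$test]),
                    retinavasc_data_error = function(e) NA_real_)
    rep_ <- computeMetrics(cm, auc = auc, fold = as.character(f))
    foldReports[[f]] <- rep_
    models[[f]] <- model
  }
  list(plan = plan, models = models, foldReports = foldReports,
       average = aggregateCv(foldReports), scores = scores)
}
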