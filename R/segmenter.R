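# U-Net-derived vessel segmenter: patch-based training on (image, mask)
# pairs, full-image fully-convolutional inference, binarized "segmented"
# dataset construction.

#' Create a segmenter configuration
#'
#' The architecture is a compact U-Net: `depth` encoder levels of two 3x3
#' convolutions + ReLU followed by 2x2 max pooling, a two-convolution
#' bottleneck, and a mirrored decoder with nearest-neighbour upsampling and
#' skip concatenation, closed by a 1x1 convolution with sigmoid output.
#' Training is patch-based (48x48 patches by default) with per-pixel binary
#' cross-entropy; inference is fully convolutional on whole images.
#'
#' @param depth encoder levels (>= 2).
#' @param baseFilters filters at the first level (doubled per level).
#' @param patchSide training patch side, pixels; must be divisible by
#'   `2^depth`.
#' @param epochs,batchSize,learningRate optimizer settings (Adam).
#' @param binarizeThreshold probability cutoff for binary vessel maps,
#'   in (0,1).
#' @param patchesPerImage training patches sampled per pair.
#' @param augmentFlip apply random horizontal/vertical patch flips.
#' @param seed integer seed.
#' @export
segmenterConfig <- function(depth = 2L, baseFilters = 8L, patchSide = 48L,
                            epochs = 12L, batchSize = 32L,
                            learningRate = 1e-3, binarizeThreshold = 0.5,
                            patchesPerImage = 30L, augmentFlip = TRUE,
                            seed = 1L) {
  if (depth < 2L) stopConfig("depth must be >= 2")
  if (patchSide %% 2L^depth != 0L)
    stopConfig("patchSide must be divisible by 2^depth")
  if (binarizeThreshold <= 0 || binarizeThreshold >= 1)
    stopConfig("binarizeThreshold must lie in (0,1)")
  structure(list(depth = as.integer(depth),
                 baseFilters = as.integer(baseFilters),
                 patchSide = as.integer(patchSide),
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate,
                 binarizeThreshold = binarizeThreshold,
                 patchesPerImage = as.integer(patchesPerImage),
                 augmentFlip = isTRUE(augmentFlip),
                 seed = as.integer(seed)),
            class = "SegmenterConfig")
}

unetInit <- function(cfg) {
  D <- cfg$depth; F1 <- cfg$baseFilters
  p <- list()
  addConv <- function(p, nm, k, cin, cout) {
    ini <- nnConvInit(k, cin, cout)
    p[[paste0(nm, ".W")]] <- ini$W
    p[[paste0(nm, ".b")]] <- ini$b
    p
  }
  cin <- 1L
  for (i in seq_len(D)) {
    f <- F1 * 2L^(i - 1L)
    p <- addConv(p, paste0("enc", i, "a"), 3L, cin, f)
    p <- addConv(p, paste0("enc", i, "b"), 3L, f, f)
    cin <- f
  }
  fb <- F1 * 2L^D
  p <- addConv(p, "bota", 3L, cin, fb)
  p <- addConv(p, "botb", 3L, fb, fb)
  above <- fb
  for (i in rev(seq_len(D))) {
    f <- F1 * 2L^(i - 1L)
    p <- addConv(p, paste0("dec", i, "a"), 3L, f + above, f)
    p <- addConv(p, paste0("dec", i, "b"), 3L, f, f)
    above <- f
  }
  p <- addConv(p, "out", 1L, F1, 1L)
  p
}

catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

unetForward <- function(params, x, cfg) {
  D <- cfg$depth
  caches <- list()
  h <- x
  for (i in seq_len(D)) {
    a <- nnConvFwd(h, params[[paste0("enc", i, "a.W")]],
                   params[[paste0("enc", i, "a.b")]], 3L)
    ra <- nnReluFwd(a$y)
    b <- nnConvFwd(ra$y, params[[paste0("enc", i, "b.W")]],
                   params[[paste0("enc", i, "b.b")]], 3L)
    rb <- nnReluFwd(b$y)
    pl <- nnPoolFwd(rb$y, 2L)
    caches[[paste0("enc", i)]] <- list(a = a$cache, ra = ra$cache,
                                       b = b$cache, rb = rb$cache,
                                       pool = pl, skip = rb$y)
    h <- pl$y
  }
  a <- nnConvFwd(h, params[["bota.W"]], params[["bota.b"]], 3L)
  ra <- nnReluFwd(a$y)
  b <- nnConvFwd(ra$y, params[["botb.W"]], params[["botb.b"]], 3L)
  rb <- nnReluFwd(b$y)
  caches$bot <- list(a = a$cache, ra = ra$cache, b = b$cache, rb = rb$cache)
  h <- rb$y
  for (i in rev(seq_len(D))) {
    up <- nnUpFwd(h)
    skip <- caches[[paste0("enc", i)]]$skip
    catd <- catChannels(skip, up)
    a <- nnConvFwd(catd, params[[paste0("dec", i, "a.W")]],
                   params[[paste0("dec", i, "a.b")]], 3L)
    ra <- nnReluFwd(a$y)
    b <- nnConvFwd(ra$y, params[[paste0("dec", i, "b.W")]],
                   params[[paste0("dec", i, "b.b")]], 3L)
    rb <- nnReluFwd(b$y)
    caches[[paste0("dec", i)]] <- list(a = a$cache, ra = ra$cache,
                                       b = b$cache, rb = rb$cache,
                                       nSkip = dim(skip)[3])
    h <- rb$y
  }
  o <- nnConvFwd(h, params[["out.W"]], params[["out.b"]], 1L, pad = 0L)
  caches$out <- o$cache
  list(logits = o$y, caches = caches)
}

unetBackward <- function(dlogits, caches, params, cfg) {
  D <- cfg$depth
  g <- list()
  bk <- nnConvBwd(dlogits, caches$out, params[["out.W"]])
  g[["out.W"]] <- bk$dW; g[["out.b"]] <- bk$db
  dh <- bk$dx
  dskips <- list()
  for (i in seq_len(D)) {   # decoder blocks, shallowest (last applied) first
    cc <- caches[[paste0("dec", i)]]
    dh <- nnReluBwd(dh, cc$rb)
    bb <- nnConvBwd(dh, cc$b, params[[paste0("dec", i, "b.W")]])
    g[[paste0("dec", i, "b.W")]] <- bb$dW
    g[[paste0("dec", i, "b.b")]] <- bb$db
    dh <- nnReluBwd(bb$dx, cc$ra)
    ba <- nnConvBwd(dh, cc$a, params[[paste0("dec", i, "a.W")]])
    g[[paste0("dec", i, "a.W")]] <- ba$dW
    g[[paste0("dec", i, "a.b")]] <- ba$db
    nS <- cc$nSkip
    dcat <- ba$dx
    dskips[[i]] <- dcat[, , seq_len(nS), , drop = FALSE]
    dup <- dcat[, , nS + seq_len(dim(dcat)[3] - nS), , drop = FALSE]
    dh <- nnUpBwd(dup)
  }
  cc <- caches$bot
  dh <- nnReluBwd(dh, cc$rb)
  bb <- nnConvBwd(dh, cc$b, params[["botb.W"]])
  g[["botb.W"]] <- bb$dW; g[["botb.b"]] <- bb$db
  dh <- nnReluBwd(bb$dx, cc$ra)
  ba <- nnConvBwd(dh, cc$a, params[["bota.W"]])
  g[["bota.W"]] <- ba$dW; g[["bota.b"]] <- ba$db
  dh <- ba$dx
  for (i in rev(seq_len(D))) {  # encoder blocks, deepest first
    cc <- caches[[paste0("enc", i)]]
    dpool <- nnPoolBwd(dh, cc$pool)
    dAct <- dpool + dskips[[i]]
    dAct <- nnReluBwd(dAct, cc$rb)
    bb <- nnConvBwd(dAct, cc$b, params[[paste0("enc", i, "b.W")]])
    g[[paste0("enc", i, "b.W")]] <- bb$dW
    g[[paste0("enc", i, "b.b")]] <- bb$db
    dh2 <- nnReluBwd(bb$dx, cc$ra)
    ba <- nnConvBwd(dh2, cc$a, params[[paste0("enc", i, "a.W")]])
    g[[paste0("enc", i, "a.W")]] <- ba$dW
    g[[paste0("enc", i, "a.b")]] <- ba$db
    dh <- ba$dx
  }
  g
}

.pairPixels <- function(pair) {
  img <- .pixelsOf(pair$image)
  msk <- if (is(pair$mask, "VesselMask")) pair$mask@pixels else pair$mask
  if (!identical(dim(img), dim(msk)))
    stopData("image and mask dimensions are misaligned")
  list(img = img, msk = msk)
}

#' Train the vessel segmenter
#'
#' Samples `patchesPerImage` patches per (image, mask) pair -- half centered
#' on random vessel pixels, half uniform, optionally flip-augmented -- and
#' minimizes per-pixel binary cross-entropy with Adam. Reproducible from
#' `config$seed`.
#'
#' @param pairs list of `list(image=, mask=)` pairs ([FundusImage-class] /
#'   [VesselMask-class] or plain matrices of identical dimensions).
#' @param config a [segmenterConfig()].
#' @return a [SegmenterModel-class] with the mean training loss per epoch
#'   in its history.
#' @export
trainSegmenter <- function(pairs, config = segmenterConfig()) {
  if (length(pairs) < 1L) stopData("need at least one training pair")
  px <- lapply(pairs, .pairPixels)
  P <- config$patchSide
  withSeed(config$seed, {
    params <- unetInit(config)
    # pre-sample the patch bank
    xs <- list(); ys <- list()
    for (pp in px) {
      d <- dim(pp$img)
      if (any(d < P)) stopData("image smaller than the training patch")
      vpix <- which(pp$msk > 0, arr.ind = TRUE)
      for (q in seq_len(config$patchesPerImage)) {
        if (q %% 2L == 0L && nrow(vpix) > 0) {
          ctr <- vpix[sample.int(nrow(vpix), 1L), ]
          r0 <- min(max(ctr[1] - P %/% 2L, 1L), d[1] - P + 1L)
          c0 <- min(max(ctr[2] - P %/% 2L, 1L), d[2] - P + 1L)
        } else {
          r0 <- sample.int(d[1] - P + 1L, 1L)
          c0 <- sample.int(d[2] - P + 1L, 1L)
        }
        xp <- pp$img[r0:(r0 + P - 1L), c0:(c0 + P - 1L)]
        yp <- pp$msk[r0:(r0 + P - 1L), c0:(c0 + P - 1L)]
        if (config$augmentFlip) {
          if (runif(1) < 0.5) { xp <- xp[P:1, ]; yp <- yp[P:1, ] }
          if (runif(1) < 0.5) { xp <- xp[, P:1]; yp <- yp[, P:1] }
        }
        xs[[length(xs) + 1L]] <- xp
        ys[[length(ys) + 1L]] <- yp
      }
    }
    n <- length(xs)
    state <- nnAdamInit(params)
    history <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (b0 in seq(1L, n, config$batchSize)) {
        ids <- ord[b0:min(b0 + config$batchSize - 1L, n)]
        nb <- length(ids)
        x <- array(unlist(xs[ids]), c(P, P, 1L, nb))
        y <- array(unlist(ys[ids]), c(P, P, 1L, nb))
        fw <- unetForward(params, x, config)
        ls <- nnBCE(fw$logits, y)
        grads <- unetBackward(ls$dlogits, fw$caches, params, config)
        st <- nnAdamStep(params, grads, state, config$learningRate)
        params <- st$params; state <- st$state
        losses <- c(losses, ls$loss)
      }
      history[ep] <- mean(losses)
    }
    new("SegmenterModel", params = params, config = unclass(config),
        history = history)
  })
}

#' Per-pixel vessel probability map
#'
#' Fully-convolutional forward pass on a whole image; the image is
#' zero-padded to a multiple of \eqn{2^{depth}} and the padding is removed
#' from the output. Values lie in \[0,1\] and have the input's dimensions.
#'
#' @param model a trained [SegmenterModel-class].
#' @param image a [FundusImage-class] or intensity matrix.
#' @export
segmentVessels <- function(model, image) {
  if (!is(model, "SegmenterModel") || !length(model@params))
    stopModel("not a trained segmenter model")
  m <- .pixelsOf(image)
  H <- nrow(m); W <- ncol(m)
  mult <- 2L^model@config$depth
  Hp <- as.integer(ceiling(H / mult) * mult)
  Wp <- as.integer(ceiling(W / mult) * mult)
  mp <- matrix(0, Hp, Wp)
  mp[seq_len(H), seq_len(W)] <- m
  fw <- unetForward(model@params, array(mp, c(Hp, Wp, 1L, 1L)),
                    model@config)
  nnSigmoid(fw$logits[seq_len(H), seq_len(W), 1L, 1L])
}

#' Dice overlap coefficient
#'
#' \eqn{2|A \cap B| / (|A| + |B|)} between two binary masks; 1 when both
#' are empty.
#'
#' @param a,b binary matrices (or [VesselMask-class]) of equal dimensions.
#' @export
diceCoefficient <- function(a, b) {
  if (is(a, "VesselMask")) a <- a@pixels
  if (is(b, "VesselMask")) b <- b@pixels
  sa <- sum(a > 0); sb <- sum(b > 0)
  if (sa + sb == 0) return(1)
  2 * sum(a > 0 & b > 0) / (sa + sb)
}

#' Build the vessel-only ("segmented") dataset
#'
#' Applies the segmenter to every enhanced image and binarizes at
#' `threshold` (set `binarize = FALSE` to keep probability maps for
#' ablation). Labels and subject ids pass through unchanged; outputs carry
#' provenance `"segmented"`.
#'
#' @param model a trained [SegmenterModel-class].
#' @param images list of [FundusImage-class] (typically enhanced).
#' @param threshold probability cutoff; defaults to the model's configured
#'   `binarizeThreshold`.
#' @param binarize logical.
#' @return list of [FundusImage-class] of the same length.
#' @export
makeSegmentedDataset <- function(model, images,
                                 threshold = model@config$binarizeThreshold,
                                 binarize = TRUE) {
  lapply(images, function(img) {
    pr <- segmentVessels(model, img)
    out <- if (binarize) (pr >= threshold) * 1 else pr
    .rewrap(img, out, provenance = "segmented")
  })
}
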