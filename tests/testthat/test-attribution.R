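# A hand-built pass-through network with a known receptive field: channel 1
# is copied through every stage (center-tap convolutions, neutral batch
# norm), the class-2 ("hypertension") logit is the global max of the final
# map. Pool sizes (2,2,1,1,1) leave an 8x8 final conv map for a 32-px input.
toyModel <- function() {
  cfg <- classifierConfig(convFilters = c(2L, 2L, 2L, 2L, 2L),
                          poolSizes = c(2L, 2L, 1L, 1L, 1L),
                          denseUnits = c(2L, 2L), dropoutRates = c(0, 0),
                          inputSide = 32L, trainResizeSide = 36L)
  model <- buildCnn(cfg)
  p <- model@params
  for (i in 1:5) {
    W <- matrix(0, 9 * 2, 2)
    if (i == 1) W[5, 1] <- 1          # center tap, input channel -> ch 1
    else W[5, 1] <- 1                 # center tap, ch 1 -> ch 1
    p[[paste0("conv", i, ".W")]] <- if (i == 1)
      matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0, rep(0, 9)), 9, 2) else W
    p[[paste0("conv", i, ".b")]] <- c(0, 0)
    p[[paste0("bn", i, ".gamma")]] <- c(1, 1)
    p[[paste0("bn", i, ".beta")]] <- c(0, 0)
    p[[paste0("bn", i, ".rm")]] <- c(0, 0)
    p[[paste0("bn", i, ".rv")]] <- c(1, 1)
  }
  p[["fc1.W"]] <- matrix(c(1, 0, 0, 0), 2, 2)  # unit 1 = channel-1 max
  p[["fc1.b"]] <- c(0, 0)
  p[["fc2.W"]] <- matrix(c(0, 0, 1, 0), 2, 2)  # class 2 logit = unit 1
  p[["fc2.b"]] <- c(0, 0)
  methods::initialize(model, params = p)
}

test_that("Grad-CAM localizes the known receptive field of a toy network", {
  model <- toyModel()
  img <- matrix(0.05, 32, 32)
  img[3:10, 3:10] <- 1         # bright blob in the top-left quadrant
  hm <- gradCam(model, img, targetClass = "hypertension")
  expect_s4_class(hm, "HeatMap")
  v <- pixels(hm)
  expect_true(all(v >= 0))
  expect_equal(max(v), 1)
  am <- which(v == max(v), arr.ind = TRUE)[1, ]
  expect_lt(am[1], 17)   # argmax row in the top-left quadrant
  expect_lt(am[2], 17)
})

test_that("heat maps are invariant to positive scaling of the logits", {
  model <- toyModel()
  img <- matrix(runif(32 * 32, 0, 0.5), 32, 32)
  img[20:28, 5:13] <- 1
  h1 <- pixels(gradCam(model, img))
  p <- model@params
  p[["fc2.W"]] <- 10 * p[["fc2.W"]]
  p[["fc2.b"]] <- 10 * p[["fc2.b"]]
  scaled <- methods::initialize(model, params = p)
  h2 <- pixels(gradCam(scaled, img))
  expect_equal(h1, h2, tolerance = 1e-8)
  expect_identical(h1, pixels(gradCam(model, img)))  # deterministic
})

test_that("a straight bar has no bifurcations and a Y has exactly one", {
  bar <- matrix(0L, 40, 40)
  bar[18:22, 5:35] <- 1L
  expect_equal(nrow(detectBifurcations(bar)), 0L)
  segs <- rbind(c(30, 35, 30, 20, 3),    # stem (x0,y0,x1,y1,w)
                c(30, 20, 15, 6, 3),     # left arm
                c(30, 20, 45, 6, 3))     # right arm
  y <- retinavasc:::.render_segments_cpp(segs, 60L)
  bp <- detectBifurcations(y$mask)
  expect_equal(nrow(bp), 1L)
  expect_lt(sqrt((bp$x - 30)^2 + (bp$y - 20)^2), 5)
  expect_equal(nrow(detectBifurcations(matrix(0L, 10, 10))), 0L)
})

test_that("most ground-truth bifurcations are recovered from rendered masks", {
  co <- smallCohort()
  recovered <- 0L; total <- 0L
  for (i in c(1L, 4L, 8L)) {
    rec <- co$records[[i]]
    bp <- detectBifurcations(rec$mask)
    gt <- rec$bifurcations
    total <- total + nrow(gt)
    for (j in seq_len(nrow(gt))) {
      d <- sqrt((bp$x - gt$x[j])^2 + (bp$y - gt$y[j])^2)
      if (length(d) && min(d) <= 5) recovered <- recovered + 1L
    }
  }
  expect_gte(recovered / total, 0.9)
})

test_that("enrichment is exact on constructed heat maps", {
  mask <- matrix(0L, 64, 64)
  mask[32, 10:54] <- 1L
  mask[10:54, 32] <- 1L
  bifs <- data.frame(x = 31, y = 31)
  radius <- 5
  # uniform mass over the vessel-adjacent region -> ratio exactly 1
  brush <- EBImage::makeBrush(2L * radius + 1L, "disc")
  vadj <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1),
                                             brush)) > 0
  uni <- localizationEnrichment(vadj * 1, bifs, mask, radius)
  expect_true(uni@defined)
  expect_equal(enrichmentRatio(uni), 1, tolerance = 1e-12)
  # all mass inside the disks -> ratio = totalArea / areaNear (closed form)
  xs <- matrix(rep(0:63, each = 64), 64, 64)
  ys <- matrix(rep(0:63, 64), 64, 64)
  disk <- ((xs - 31)^2 + (ys - 31)^2 <= radius^2) & vadj
  inDisk <- localizationEnrichment(disk * 1, bifs, mask, radius)
  expect_equal(enrichmentRatio(inDisk), inDisk@totalArea / inDisk@areaNear,
               tolerance = 1e-12)
  # no mass inside the disks -> ratio 0
  out <- localizationEnrichment((vadj & !disk) * 1, bifs, mask, radius)
  expect_equal(enrichmentRatio(out), 0)
  # invariance to positive scaling of the heat map
  set.seed(13)
  h <- matrix(runif(64 * 64), 64, 64) * vadj
  r1 <- enrichmentRatio(localizationEnrichment(h, bifs, mask, radius))
  r2 <- enrichmentRatio(localizationEnrichment(3.7 * h, bifs, mask, radius))
  expect_equal(r1, r2, tolerance = 1e-12)
  # no bifurcations -> flagged undefined
  und <- localizationEnrichment(h, data.frame(x = numeric(), y = numeric()),
                                mask, radius)
  expect_false(und@defined)
  expect_true(is.na(enrichmentRatio(und)))
  expect_error(localizationEnrichment(h, bifs, mask[1:10, 1:10], radius),
               class = "retinavasc_data_error")
})

test_that("the cohort report covers only correctly classified images", {
  # the toy model always predicts "hypertension", so exactly the
  # hypertension-labeled images are correctly classified
  model <- toyModel()
  co <- smallCohort()
  idx <- c(1L, 2L, 7L, 8L)
  imgs <- lapply(co$records[idx], function(r) pixels(r$mask) * 1)
  masks <- lapply(co$records[idx], function(r) r$mask)
  bifs <- lapply(co$records[idx], function(r)
    r$bifurcations[, c("x", "y")])
  labs <- co$manifest$label[idx]
  rep <- cohortAttributionReport(model, imgs, labs, masks, bifs,
                                 ids = co$manifest$id[idx])
  expect_true(all(rep$table$label == "hypertension"))
  expect_true(all(rep$table$correct))
  expect_equal(nrow(rep$table), sum(labs == "hypertension"))
  expect_true(all(rep$table$target_class == rep$table$label))
})
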