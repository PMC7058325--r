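test_that("the built CNN has 5 conv stages, 2 dense stages and softmax output", {
  cfg <- tinyClassifierConfig()
  model <- buildCnn(cfg)
  nm <- names(model@params)
  expect_equal(sum(grepl("^conv[0-9]\\.W$", nm)), 5L)
  expect_equal(sum(grepl("^fc[0-9]\\.W$", nm)), 2L)
  expect_equal(sum(grepl("^bn[0-9]\\.gamma$", nm)), 5L)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  fw <- retinavasc:::cnnForward(model@params, x, model@config,
                                training = FALSE)
  p <- exp(fw$logits); p <- p / sum(p)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_error(classifierConfig(convFilters = c(8L, 8L)),
               class = "retinavasc_config_error")
  expect_error(classifierConfig(denseUnits = c(16L, 3L)),
               class = "retinavasc_config_error")
  expect_error(classifierConfig(inputSide = 64L, trainResizeSide = 64L),
               class = "retinavasc_config_error")
})

test_that("trainable parameter count equals hand-computed shape arithmetic", {
  cfg <- classifierConfig(convFilters = c(2L, 3L, 3L, 3L, 4L),
                          denseUnits = c(5L, 2L),
                          inputSide = 32L, trainResizeSide = 36L)
  model <- buildCnn(cfg)
  # conv: k*k*cin*cout + cout; bn: 2*cout; dense: din*dout + dout
  byHand <- (9 * 1 * 2 + 2) + (9 * 2 * 3 + 3) + (9 * 3 * 3 + 3) +
    (9 * 3 * 3 + 3) + (9 * 3 * 4 + 4) +      # conv stages
    2 * (2 + 3 + 3 + 3 + 4) +                # batch-norm scale/shift
    (4 * 5 + 5) + (5 * 2 + 2)                # dense stages
  expect_equal(parameterCount(model), byHand)
})

test_that("fold plans partition records with balanced sizes and 75/25 splits", {
  labs <- rep(c("hypertension", "non-hypertension"), 10)
  plan <- makeFoldPlan(labs, k = 5L, groupBySubject = FALSE, seed = 3L)
  expect_equal(as.integer(table(foldAssignments(plan))), rep(4L, 5))
  # development of 100 records -> 75 train / 25 validation
  labs125 <- rep(c("hypertension", "non-hypertension"), length.out = 125)
  p125 <- makeFoldPlan(labs125, k = 5L, groupBySubject = FALSE, seed = 4L)
  fr <- foldRecords(p125, 2L)
  expect_equal(length(fr$development), 100L)
  expect_equal(length(fr$validation), 25L)
  expect_equal(length(fr$train), 75L)
  expect_error(makeFoldPlan(labs[1:3], k = 5L, groupBySubject = FALSE),
               class = "retinavasc_data_error")
})

test_that("fold plans are disjoint and cover all records across a seed sweep", {
  labs <- rep(c("hypertension", "non-hypertension"), 15)
  subj <- rep(sprintf("s%02d", 1:15), each = 2)
  for (s in 1:50) {
    plan <- makeFoldPlan(labs, subj, k = 5L, seed = s)
    a <- foldAssignments(plan)
    expect_true(all(a %in% 1:5))
    for (f in 1:5) {
      fr <- foldRecords(plan, f)
      expect_length(intersect(fr$test, fr$development), 0)
      expect_setequal(c(fr$test, fr$development), seq_along(labs))
      expect_setequal(c(fr$train, fr$validation), fr$development)
    }
  }
})

test_that("subject grouping keeps both eyes of a subject in one fold", {
  labs <- rep(c("hypertension", "non-hypertension"), each = 12)
  subj <- c(rep(sprintf("h%02d", 1:6), each = 2),
            rep(sprintf("n%02d", 1:6), each = 2))
  plan <- makeFoldPlan(labs, subj, k = 4L, seed = 9L)
  a <- foldAssignments(plan)
  for (s in unique(subj))
    expect_equal(length(unique(a[subj == s])), 1L)
  # and train/validation also respect subject boundaries
  for (f in 1:4) {
    fr <- foldRecords(plan, f)
    trSubj <- unique(subj[fr$train])
    vaSubj <- unique(subj[fr$validation])
    expect_length(intersect(trSubj, vaSubj), 0)
  }
})

test_that("augmentation crops a contiguous window with flips and brightness", {
  cfg <- classifierConfig(inputSide = 8L, trainResizeSide = 12L,
                          brightnessJitter = 0)
  set.seed(21)
  m <- matrix(runif(12 * 12), 12, 12)
  out <- augmentImage(m, cfg, seed = 5L)
  expect_equal(dim(out), c(8L, 8L))
  expect_identical(out, augmentImage(m, cfg, seed = 5L))
  # exhaustive window-match oracle at zero jitter: the output must equal
  # one of the four flip variants of some contiguous 8x8 window
  found <- FALSE
  for (r0 in 1:5) for (c0 in 1:5) {
    win <- m[r0:(r0 + 7), c0:(c0 + 7)]
    for (fh in c(FALSE, TRUE)) for (fv in c(FALSE, TRUE)) {
      v <- win
      if (fh) v <- v[8:1, ]
      if (fv) v <- v[, 8:1]
      if (isTRUE(all.equal(v, out, tolerance = 1e-12))) found <- TRUE
    }
  }
  expect_true(found)
  # brightness jitter stays within the configured factor band
  cfgJ <- classifierConfig(inputSide = 8L, trainResizeSide = 12L,
                           brightnessJitter = 0.2)
  mc <- matrix(0.5, 12, 12)
  for (s in 1:10) {
    a <- augmentImage(mc, cfgJ, seed = s)
    expect_true(all(a >= 0.5 * 0.8 - 1e-12 & a <= 0.5 * 1.2 + 1e-12))
  }
  expect_error(augmentImage(matrix(0.5, 5, 5), cfg),
               class = "retinavasc_data_error")
})

test_that("a tiny balanced set is overfit and scored consistently", {
  # fit-capacity check: two visually distinct synthetic patterns
  set.seed(8)
  mkimg <- function(cls) {
    m <- matrix(runif(48 * 48, 0, 0.2), 48, 48)
    if (cls == "hypertension") m[20:28, ] <- 0.9 else m[, 20:28] <- 0.9
    m
  }
  labs <- rep(c("hypertension", "non-hypertension"), each = 4)
  imgs <- lapply(labs, mkimg)
  cfg <- tinyClassifierConfig(epochs = 25L)
  hookLog <- new.env(); hookLog$ids <- integer()
  model <- trainClassifier(imgs, labs, cfg, trainIdx = c(1:3, 5:7),
                           valIdx = c(4L, 8L), seed = 2L,
                           hook = function(stage, ids)
                             hookLog$ids <- union(hookLog$ids, ids))
  expect_equal(nrow(model@history), 25L)
  expect_true(all(is.finite(model@history$train_loss)))
  # augmentation touched only the training split, never validation
  expect_length(intersect(hookLog$ids, c(4L, 8L)), 0)
  expect_setequal(hookLog$ids, c(1:3, 5:7))
  sc <- predictScores(model, imgs)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_identical(sc, predictScores(model, imgs))
  acc <- mean((sc[c(1:3, 5:7)] >= 0.5) ==
                (labs[c(1:3, 5:7)] == "hypertension"))
  expect_gte(acc, 0.95)
  expect_true(all(sc[1:3] > 0.5))
  expect_error(trainClassifier(imgs, labs, cfg, trainIdx = 1:3,
                               valIdx = 4L),
               class = "retinavasc_data_error")
})

test_that("training is reproducible from its seed", {
  set.seed(91)
  imgs <- lapply(1:6, function(i) matrix(runif(40 * 40), 40, 40))
  labs <- rep(c("hypertension", "non-hypertension"), 3)
  cfg <- tinyClassifierConfig(epochs = 2L)
  m1 <- trainClassifier(imgs, labs, cfg, trainIdx = 1:4, valIdx = 5:6,
                        seed = 7L)
  m2 <- trainClassifier(imgs, labs, cfg, trainIdx = 1:4, valIdx = 5:6,
                        seed = 7L)
  expect_identical(m1@history, m2@history)
  expect_identical(m1@params[["conv1.W"]], m2@params[["conv1.W"]])
})
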