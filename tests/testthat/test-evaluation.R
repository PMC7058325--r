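# Construct a 20-score instance with known counts at threshold 0.5:
# 12 hypertension images (7 scoring >= 0.5, 5 below) and 8 controls
# (3 scoring >= 0.5, 5 below) -> TP=7, TN=5, FP=3, FN=5 by hand count.
.constructedScores <- function() {
  list(scores = c(seq(0.55, 0.95, length.out = 7),  # TP
                  seq(0.05, 0.45, length.out = 5),  # FN
                  seq(0.55, 0.85, length.out = 3),  # FP
                  seq(0.05, 0.45, length.out = 5)), # TN
       labels = c(rep("hypertension", 12), rep("non-hypertension", 8)))
}

test_that("confusion counts match the hand count on the constructed instance", {
  d <- .constructedScores()
  cm <- confusionCounts(d$scores, d$labels, threshold = 0.5)
  expect_equal(cm@tp, 7L)
  expect_equal(cm@tn, 5L)
  expect_equal(cm@fp, 3L)
  expect_equal(cm@fn, 5L)
})

test_that("counts are conserved and separate perfectly when classes separate", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    sc <- runif(n)
    lb <- sample(c(0, 1), n, replace = TRUE)
    cm <- confusionCounts(sc, lb, threshold = runif(1, 0.2, 0.8))
    expect_equal(cm@tp + cm@tn + cm@fp + cm@fn, n)
  }
  cm <- confusionCounts(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), 0.5)
  expect_equal(cm@fp + cm@fn, 0L)
  expect_error(confusionCounts(c(0.5), c(1, 0)), class = "retinavasc_data_error")
})

test_that("metric formulas reproduce hand arithmetic and flag undefined cases", {
  cm <- new("ConfusionCounts", tp = 7L, tn = 5L, fp = 3L, fn = 5L)
  r <- computeMetrics(cm)
  expect_equal(r@accuracy, 0.60)
  expect_equal(r@specificity, 0.625)
  expect_equal(r@precision, 0.70)
  expect_equal(r@recall, 7 / 12)
  allRight <- computeMetrics(new("ConfusionCounts", tp = 4L, tn = 6L,
                                 fp = 0L, fn = 0L))
  expect_equal(c(allRight@accuracy, allRight@specificity,
                 allRight@precision, allRight@recall), rep(1, 4))
  noNeg <- computeMetrics(new("ConfusionCounts", tp = 3L, tn = 0L,
                              fp = 0L, fn = 1L))
  expect_true(is.na(noNeg@specificity))
  expect_true("specificity" %in% noNeg@undefined)
})

test_that("AUC equals the exhaustive pairwise oracle, with midrank ties", {
  expect_equal(aucScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(aucScore(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  pairwiseAuc <- function(s, y) {
    ps <- s[y == 1]; ns <- s[y == 0]
    tot <- 0
    for (p in ps) for (q in ns) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(ps) * length(ns))
  }
  set.seed(29)
  for (i in 1:100) {
    s <- round(runif(30), 2)   # rounding forces ties
    y <- c(rep(1, 15), rep(0, 15))[sample(30)]
    expect_equal(aucScore(s, y), pairwiseAuc(s, y), tolerance = 1e-12)
  }
  expect_error(aucScore(runif(5), rep(1, 5)), class = "retinavasc_data_error")
})

test_that("AUC of flipped labels is the complement", {
  set.seed(31)
  for (i in 1:20) {
    s <- round(runif(25), 1)
    y <- rbinom(25, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(aucScore(s, y) + aucScore(s, 1 - y), 1, tolerance = 1e-12)
  }
})

test_that("accuracy equals the prevalence-weighted mix of recall and specificity", {
  set.seed(37)
  for (i in 1:20) {
    n <- 40
    s <- runif(n); y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    r <- computeMetrics(confusionCounts(s, y))
    P <- sum(y == 1); N <- sum(y == 0)
    expect_equal(r@accuracy, (r@recall * P + r@specificity * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("cross-validation averaging is an unweighted mean, order-invariant", {
  mk <- function(acc, auc, f) new("MetricsReport", accuracy = acc,
                                  specificity = acc, precision = acc,
                                  recall = acc, auc = auc,
                                  undefined = character(), fold = f,
                                  nImages = 10L)
  reps <- list(mk(0.5, 0.51, "1"), mk(0.6, 0.62, "2"), mk(0.7, 0.73, "3"),
               mk(0.55, 0.58, "4"), mk(0.65, 0.66, "5"))
  a1 <- aggregateCv(reps)
  a2 <- aggregateCv(rev(reps))
  expect_equal(a1@accuracy, mean(c(0.5, 0.6, 0.7, 0.55, 0.65)))
  expect_equal(a1@auc, a2@auc)
  expect_equal(a1@fold, "average")
  same <- aggregateCv(list(mk(0.6, 0.6, "1"), mk(0.6, 0.6, "2")))
  expect_equal(same@accuracy, 0.6)
  expect_equal(same@auc, 0.6)
})

test_that("cvTable lays out per-fold rows plus the average row", {
  d <- .constructedScores()
  cm <- confusionCounts(d$scores, d$labels)
  reps <- lapply(1:5, function(f)
    computeMetrics(cm, auc = aucScore(d$scores, d$labels), fold = f))
  tab <- cvTable(reps)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$fold[6], "average")
  expect_equal(tab$accuracy[6], mean(tab$accuracy[1:5]))
})
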