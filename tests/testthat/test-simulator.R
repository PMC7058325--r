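test_that("Murray's relation holds exactly at every bifurcation", {
  cfg <- testSimConfig()
  for (s in c(1L, 17L, 23L)) {
    for (lab in c("non-hypertension", "hypertension")) {
      tr <- sampleTree(cfg, lab, seed = s)
      bf <- bifurcations(tr)
      expect_gt(nrow(bf), 0)
      relErr <- abs(bf$d_parent^3 - (bf$d1^3 + bf$d2^3)) / bf$d_parent^3
      expect_lt(max(relErr), 1e-9)
      # asymmetry records are (min/max)^2 of the stored daughters
      expect_equal(bf$asymmetry,
                   (pmin(bf$d1, bf$d2) / pmax(bf$d1, bf$d2))^2,
                   tolerance = 1e-12)
    }
  }
})

test_that("a configurable Murray exponent is honoured", {
  cfg <- testSimConfig(murrayExponent = 2.5)
  bf <- bifurcations(sampleTree(cfg, seed = 5))
  relErr <- abs(bf$d_parent^2.5 - (bf$d1^2.5 + bf$d2^2.5)) / bf$d_parent^2.5
  expect_lt(max(relErr), 1e-9)
})

test_that("treeDepth = 0 yields a single root segment and no bifurcations", {
  tr <- sampleTree(testSimConfig(treeDepth = 0L), seed = 9)
  expect_equal(nrow(treeSegments(tr)), 1L)
  expect_equal(nrow(bifurcations(tr)), 0L)
})

test_that("planted class effect moves the mean asymmetry ratio by its size", {
  # Monte-Carlo oracle: the sample mean of stored bifurcation records
  cfg <- testSimConfig(classEffect = -0.2, classEffectAngle = 0)
  meanAsym <- function(lab, seeds) {
    mean(vapply(seeds, function(s)
      mean(bifurcations(sampleTree(cfg, lab, seed = s))$asymmetry), 0))
  }
  seeds <- 1:200
  d <- meanAsym("hypertension", seeds) - meanAsym("non-hypertension", seeds)
  expect_equal(d, -0.2, tolerance = 0.02)
})

test_that("trees are deterministic and confined to the image disc", {
  cfg <- testSimConfig()
  t1 <- sampleTree(cfg, seed = 31)
  t2 <- sampleTree(cfg, seed = 31)
  expect_identical(treeNodes(t1), treeNodes(t2))
  expect_identical(bifurcations(t1), bifurcations(t2))
  ctr <- (cfg@imageSize - 1) / 2
  rr <- sqrt((treeNodes(t1)[, 1] - ctr)^2 + (treeNodes(t1)[, 2] - ctr)^2)
  expect_true(all(rr <= 0.48 * cfg@imageSize))
})

test_that("rendering aligns image and mask and is bit-reproducible", {
  cfg <- testSimConfig()
  tr <- sampleTree(cfg, seed = 3)
  r1 <- renderTree(tr, cfg, seed = 4)
  r2 <- renderTree(tr, cfg, seed = 4)
  expect_identical(pixels(r1$image), pixels(r2$image))
  expect_identical(pixels(r1$mask), pixels(r2$mask))
  expect_identical(dim(pixels(r1$image)), dim(pixels(r1$mask)))
  expect_true(all(pixels(r1$image) >= 0 & pixels(r1$image) <= 1))
  expect_true(all(pixels(r1$mask) %in% c(0L, 1L)))
})

test_that("every segment centerline midpoint falls inside the mask", {
  # independent centerline rasterization: walk each segment's center at
  # sub-pixel steps and require the mask to cover the rounded positions
  cfg <- testSimConfig()
  tr <- sampleTree(cfg, seed = 8)
  msk <- pixels(renderTree(tr, cfg, seed = 8)$mask)
  seg <- treeSegments(tr)
  nod <- treeNodes(tr)
  hits <- 0L; total <- 0L
  for (i in seq_len(nrow(seg))) {
    p0 <- nod[seg$parent[i], ]; p1 <- nod[seg$child[i], ]
    for (t in seq(0.1, 0.9, by = 0.2)) {
      q <- p0 + t * (p1 - p0)
      total <- total + 1L
      hits <- hits + msk[round(q[2]) + 1L, round(q[1]) + 1L]
    }
  }
  expect_equal(hits, total)
})

test_that("an empty tree renders an all-zero mask", {
  cfg <- testSimConfig()
  empty <- new("VascularTree",
               nodes = matrix(c(60, 60), 1, 2,
                              dimnames = list(NULL, c("x", "y"))),
               segments = data.frame(parent = integer(), child = integer(),
                                     diameter = numeric()),
               bifurcations = data.frame(node = integer(), x = numeric(),
                                         y = numeric(), d_parent = numeric(),
                                         d1 = numeric(), d2 = numeric(),
                                         angle_deg = numeric(),
                                         asymmetry = numeric()),
               imageSize = cfg@imageSize)
  r <- renderTree(empty, cfg, seed = 1)
  expect_equal(sum(pixels(r$mask)), 0)
})

test_that("vessel pixels darker than background are covered by the dilated mask", {
  cfg <- testSimConfig()
  tr <- sampleTree(cfg, seed = 12)
  r <- renderTree(tr, cfg, seed = 12)
  img <- pixels(r$image)
  msk <- pixels(r$mask)
  # local background estimate: heavy Gaussian smoothing of the image
  bg <- matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                                 sigma = 6)),
               nrow(img), ncol(img))
  # consider the interior of the field of view only: outside the disc and
  # at its rim, "darker than background" reflects the black surround,
  # not vessels
  S <- nrow(img)
  ctr <- (S - 1) / 2
  xs <- matrix(rep(0:(S - 1), each = S), S, S)
  ys <- matrix(rep(0:(S - 1), S), S, S)
  interior <- ((xs - ctr)^2 + (ys - ctr)^2) <= (0.42 * S)^2
  dark <- interior & ((bg - img) > cfg@vesselContrast / 2)
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(msk * 1),
                                            EBImage::makeBrush(3, "box"))) > 0
  covered <- sum(dark & dil) / max(1, sum(dark))
  expect_gte(covered, 0.99)
})

test_that("generateCohort delivers balanced labeled records reproducibly", {
  co <- smallCohort()
  expect_equal(nrow(co$manifest), 12L)
  expect_equal(unname(table(co$manifest$label)["hypertension"]), 6L)
  expect_equal(unname(table(co$manifest$label)["non-hypertension"]), 6L)
  co2 <- generateCohort(testSimConfig(), 6L, seed = 42L)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(pixels(co$records[[3]]$image), pixels(co2$records[[3]]$image))
  # some subjects contribute two eyes, and both carry the same label
  tab <- table(co$manifest$subject_id)
  for (s in names(tab[tab == 2L])) {
    labs <- co$manifest$label[co$manifest$subject_id == s]
    expect_equal(length(unique(labs)), 1L)
  }
  expect_error(generateCohort(testSimConfig(), 0L), class = "retinavasc_config_error")
})

test_that("a zero class effect produces no spurious asymmetry difference", {
  # null calibration: per-cohort two-sample t-test on per-image mean
  # asymmetry should be non-significant in the large majority of cohorts
  cfg <- testSimConfig(classEffect = 0, classEffectAngle = 0)
  reps <- 15L
  sig <- 0L
  for (r in seq_len(reps)) {
    co <- generateCohort(cfg, 8L, seed = 1000L + r)
    ms <- vapply(co$records, function(x) mean(x$bifurcations$asymmetry), 0)
    lab <- co$manifest$label
    p <- t.test(ms[lab == "hypertension"], ms[lab == "non-hypertension"])$p.value
    sig <- sig + (p < 0.05)
  }
  expect_lte(sig, 3L)  # ~95% non-significant, generous binomial slack
})

test_that("invalid simulator configurations are rejected", {
  expect_error(simulatorConfig(imageSize = 32L), class = "retinavasc_config_error")
  expect_error(simulatorConfig(asymmetryMean = 0.9, classEffect = -0.95),
               class = "retinavasc_config_error")
  expect_error(simulatorConfig(angleMean = 190), class = "retinavasc_config_error")
  expect_error(simulatorConfig(murrayExponent = -1), class = "retinavasc_config_error")
})
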