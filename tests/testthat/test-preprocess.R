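test_that("autocrop matches the exhaustive bounding-box oracle", {
  # bright rectangle at known position inside a black canvas
  canvas <- matrix(0, 100, 120)
  canvas[21:50, 31:90] <- 0.8     # 30 rows x 60 cols
  out <- autocropSquare(canvas, borderThreshold = 0.02)
  # oracle: exhaustive scan for above-threshold extrema
  fg <- which(canvas > 0.02, arr.ind = TRUE)
  h <- diff(range(fg[, 1])) + 1L; w <- diff(range(fg[, 2])) + 1L
  expect_equal(dim(out), c(max(h, w), max(h, w)))
  # all foreground preserved, centered on the bounding box
  expect_equal(sum(out > 0.02), sum(canvas > 0.02))
  rows <- range(which(rowSums(out > 0.02) > 0))
  expect_equal(rows[1] - 1L, nrow(out) - rows[2])
})

test_that("autocrop is the identity on borderless images and idempotent", {
  m <- matrix(runif(64 * 64, 0.2, 1), 64, 64)
  expect_identical(autocropSquare(m), m)
  for (i in 1:5) {
    set.seed(i)
    canvas <- matrix(0, 80, 80)
    r <- sort(sample(80, 2)); c <- sort(sample(80, 2))
    canvas[r[1]:r[2], c[1]:c[2]] <- runif(1, 0.5, 1)
    once <- autocropSquare(canvas)
    expect_identical(autocropSquare(once), once)
  }
  expect_error(autocropSquare(matrix(0, 10, 10)),
               class = "retinavasc_data_error")
})

test_that("gamma correction follows p * I^gamma with its fixed points", {
  m <- matrix(seq(0, 1, length.out = 25), 5, 5)
  expect_identical(gammaCorrect(m, 1, 1), m)
  expect_equal(gammaCorrect(matrix(1), gamma = 3.7, p = 1)[1, 1], 1)
  # direct scalar oracle at the classical setting gamma = 1/1.2
  expect_equal(gammaCorrect(matrix(0.5), 1 / 1.2, 1)[1, 1], 0.5612,
               tolerance = 1e-4)
  expect_error(gammaCorrect(m, gamma = 0), class = "retinavasc_config_error")
  expect_error(gammaCorrect(m, gamma = 1, p = -1),
               class = "retinavasc_config_error")
})

test_that("gamma correction is monotone for any positive gamma and p", {
  I <- sort(runif(100))
  for (g in c(0.3, 1 / 1.2, 1, 2.4)) {
    for (p in c(0.5, 1, 1.6)) {
      out <- gammaCorrect(matrix(I, 1), g, p)
      expect_true(all(diff(out[1, ]) >= 0))
      expect_true(all(out >= 0 & out <= 1))
    }
  }
})

test_that("single-tile unclipped CLAHE equals global histogram equalization", {
  set.seed(3)
  m <- matrix(runif(64 * 64), 64, 64)
  out <- claheEqualize(m, tiles = 1L, clip = Inf)
  # independent CDF-mapping oracle on the same 256-bin quantization
  bin <- pmin(256L, floor(m * 256) + 1L)
  cdf <- cumsum(tabulate(bin, 256L)) / length(m)
  oracle <- matrix(cdf[bin], 64, 64)
  expect_equal(out, oracle, tolerance = 1e-12)
})

test_that("CLAHE respects the range contract and degenerate inputs", {
  set.seed(4)
  m <- matrix(runif(80 * 80), 80, 80)
  out <- claheEqualize(m, tiles = 8L, clip = 0.01)
  expect_true(all(out >= 0 & out <= 1))
  flat <- claheEqualize(matrix(0.4, 32, 32), tiles = 4L, clip = 0.02)
  expect_equal(max(flat) - min(flat), 0)
  expect_error(claheEqualize(matrix(0.5, 4, 4), tiles = 8L),
               class = "retinavasc_config_error")
})

test_that("the enhancement chain yields the target size, determinism and contrast", {
  co <- smallCohort()
  img <- co$records[[1]]$image
  cfg <- preprocessConfig(targetSide = 96L)
  e1 <- enhanceImage(img, cfg)
  e2 <- enhanceImage(img, cfg)
  expect_s4_class(e1, "FundusImage")
  expect_equal(dim(pixels(e1)), c(96L, 96L))
  expect_identical(pixels(e1), pixels(e2))
  expect_equal(provenance(e1), "enhanced")
  expect_true(all(pixels(e1) >= 0 & pixels(e1) <= 1))
  # enhanced image has higher RMS local contrast (sliding-window sd oracle)
  localRms <- function(m, k = 6L) {
    n <- nrow(m) %/% k
    v <- numeric(0)
    for (i in seq_len(n)) for (j in seq_len(n))
      v <- c(v, sd(m[((i - 1) * k + 1):(i * k), ((j - 1) * k + 1):(j * k)]))
    mean(v)
  }
  raw96 <- retinavasc:::resizeMatrix(pixels(img), 96L)
  expect_gt(localRms(pixels(e1)), localRms(raw96))
})

test_that("op order is configurable and changes the result", {
  co <- smallCohort()
  img <- pixels(co$records[[2]]$image)
  a <- enhanceImage(img, preprocessConfig(targetSide = 64L,
                                          opOrder = c("clahe", "gamma")))
  b <- enhanceImage(img, preprocessConfig(targetSide = 64L,
                                          opOrder = c("gamma", "clahe")))
  expect_false(identical(a, b))
})

test_that("enhancePair transports mask and coordinates through the transform", {
  co <- smallCohort()
  rec <- co$records[[1]]
  pre <- preprocessConfig(targetSide = 128L)
  p <- enhancePair(rec$image, rec$mask, pre)
  expect_identical(dim(pixels(p$image)), dim(p$mask@pixels))
  expect_true(all(p$mask@pixels %in% c(0, 1)))
  # transformed bifurcation coordinates must land on (near) the new mask
  bf <- rec$bifurcations
  tr <- p$transform
  x2 <- (bf$x - tr$x0) * tr$scale
  y2 <- (bf$y - tr$y0) * tr$scale
  dil <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(p$mask@pixels * 1), EBImage::makeBrush(5, "disc"))) > 0
  onMask <- mean(dil[cbind(pmin(pmax(round(y2) + 1, 1), 128),
                           pmin(pmax(round(x2) + 1, 1), 128))])
  expect_gte(onMask, 0.9)
})
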