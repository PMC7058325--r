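# Shared fixtures, built in code on first use and cached for the session.
# Heavy objects (trained models, cohorts) are memoised so that several
# test files can share them without retraining.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# Desk-scale simulator world shared across tests.
testSimConfig <- function(...) simulatorConfig(...)

# A small rendered cohort (6 images per class at 128 px).
smallCohort <- function() {
  fixture("smallCohort", function() {
    generateCohort(testSimConfig(), 6L, seed = 42L)
  })
}

# Enhanced (image, mask) pairs at 128 px from an independent seed.
enhancedPairs <- function(n, seed) {
  key <- sprintf("pairs_%d_%d", n, seed)
  fixture(key, function() {
    pre <- preprocessConfig(targetSide = 128L)
    co <- generateCohort(testSimConfig(), as.integer(ceiling(n / 2)),
                         seed = seed)
    lapply(co$records[seq_len(n)], function(r) {
      p <- enhancePair(r$image, r$mask, pre)
      list(image = p$image, mask = p$mask)
    })
  })
}

# Tiny trained classifier for contract tests (32 px input, quick).
tinyClassifierConfig <- function(epochs = 3L, ...) {
  classifierConfig(convFilters = c(4L, 6L, 8L, 8L, 8L),
                   poolSizes = c(2L, 2L, 2L, 2L, 1L),
                   denseUnits = c(8L, 2L), dropoutRates = c(0.2, 0),
                   inputSide = 32L, trainResizeSide = 36L,
                   epochs = epochs, batchSize = 8L, ...)
}
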