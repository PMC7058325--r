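# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package funnel
# through this so that every result is reproducible from explicit seeds.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# Stage-specific sub-seed derivation: a small fixed offset per pipeline
# stage keeps stages independently reproducible while everything follows
# from one global seed. Kept well below 2^31.
deriveSeed <- function(seed, stage) {
  offsets <- c(simulate = 101L, preprocess = 211L, segment = 307L,
               folds = 401L, train = 503L, attribution = 601L,
               augment = 701L, cohort = 809L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 20000000L) * 100L + offsets[[stage]]
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Bilinear resize of a plain [row, col] matrix via EBImage (separable
# filter, so the row/column transposition EBImage applies is immaterial).
resizeMatrix <- function(m, side) {
  if (nrow(m) == side && ncol(m) == side) return(m)
  out <- EBImage::resize(EBImage::Image(m), w = side, h = side)
  matrix(EBImage::imageData(out), side, side)
}

isSquare <- function(m) nrow(m) == ncol(m)

stopConfig <- function(...) stop(errorCondition(paste0(...),
                                                class = "retinavasc_config_error"))
stopData <- function(...) stop(errorCondition(paste0(...),
                                              class = "retinavasc_data_error"))
stopModel <- function(...) stop(errorCondition(paste0(...),
                                               class = "retinavasc_model_error"))
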