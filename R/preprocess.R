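# Image preparation: auto-crop of black borders to a square field of view,
# bilinear resize, CLAHE, and power-law gamma correction, producing the
# "enhanced" provenance stage.

#' Create a preprocessing configuration
#'
#' @param targetSide side length after resizing, pixels. The default 565
#'   matches the classical fundus pipeline; desk-scale analyses use smaller
#'   values.
#' @param gamma exponent of the power-law mapping \eqn{I_\gamma = p I^\gamma}.
#'   The default 1/1.2 brightens the image and stretches contrast at low
#'   gray levels.
#' @param gammaNorm normalization factor p. On \[0,1\] intensities the
#'   natural choice is 1, which keeps white a fixed point.
#' @param claheTiles CLAHE grid dimension (tiles x tiles).
#' @param claheClip CLAHE clip limit as a fraction of the tile pixel count.
#' @param borderThreshold intensity at or below which a pixel counts as
#'   black border for cropping.
#' @param opOrder order of the two enhancement steps; default CLAHE first,
#'   then gamma.
#' @return a named list of class `"PreprocessConfig"`.
#' @export
preprocessConfig <- function(targetSide = 565L, gamma = 1 / 1.2,
                             gammaNorm = 1, claheTiles = 8L,
                             claheClip = 0.01, borderThreshold = 0.02,
                             opOrder = c("clahe", "gamma")) {
  if (gamma <= 0 || gammaNorm <= 0) stopConfig("gamma and gammaNorm must be > 0")
  if (claheTiles < 1L) stopConfig("claheTiles must be >= 1")
  if (claheClip <= 0) stopConfig("claheClip must be > 0")
  if (!all(opOrder %in% c("clahe", "gamma")))
    stopConfig("opOrder entries must be 'clahe' and/or 'gamma'")
  structure(list(targetSide = as.integer(targetSide), gamma = gamma,
                 gammaNorm = gammaNorm, claheTiles = as.integer(claheTiles),
                 claheClip = claheClip, borderThreshold = borderThreshold,
                 opOrder = opOrder),
            class = "PreprocessConfig")
}

.pixelsOf <- function(image) {
  if (is(image, "FundusImage")) image@pixels else image
}

.rewrap <- function(image, m, provenance = NULL) {
  if (is(image, "FundusImage")) {
    out <- image
    out@pixels <- m
    if (!is.null(provenance)) out@provenance <- provenance
    validObject(out)
    out
  } else m
}

# Square crop window (top-left 1-based row/col and side) of the
# above-threshold bounding box, shared by autocropSquare and enhancePair.
.cropWindow <- function(m, borderThreshold) {
  fg <- m > borderThreshold
  if (!any(fg)) stopData("empty field of view: no pixel above the border threshold")
  rows <- range(which(rowSums(fg) > 0))
  cols <- range(which(colSums(fg) > 0))
  h <- rows[2] - rows[1] + 1L
  w <- cols[2] - cols[1] + 1L
  side <- max(h, w)
  list(r0 = rows[1] - (side - h) %/% 2L,
       c0 = cols[1] - (side - w) %/% 2L, side = side)
}

.applyWindow <- function(m, win) {
  canvas <- matrix(0, win$side, win$side)
  rr <- win$r0:(win$r0 + win$side - 1L)
  cc <- win$c0:(win$c0 + win$side - 1L)
  rin <- rr >= 1L & rr <= nrow(m)
  cin <- cc >= 1L & cc <= ncol(m)
  canvas[rin, cin] <- m[rr[rin], cc[cin]]
  canvas
}

#' Auto-crop black borders to a square field of view
#'
#' Finds the bounding box of all pixels strictly above `borderThreshold`,
#' expands it symmetrically to a square centered on the box (zero-padding
#' where the square extends past the original image), and returns that
#' window without any distortion. Idempotent: cropping a cropped image is
#' the identity.
#'
#' @param image a [FundusImage-class] or plain intensity matrix.
#' @param borderThreshold background intensity cutoff.
#' @return the cropped image, same type as the input.
#' @export
autocropSquare <- function(image, borderThreshold = 0.02) {
  m <- .pixelsOf(image)
  win <- .cropWindow(m, borderThreshold)
  .rewrap(image, .applyWindow(m, win))
}

#' Gamma correction
#'
#' Pointwise power-law intensity mapping \eqn{I_\gamma = p \cdot I^\gamma},
#' clipped to \[0,1\]. Monotone non-decreasing in the input for all
#' `gamma, p > 0`; with `gamma = p = 1` it is the identity.
#'
#' @param image a [FundusImage-class] or intensity matrix in \[0,1\].
#' @param gamma exponent (> 0).
#' @param p normalization factor (> 0).
#' @export
gammaCorrect <- function(image, gamma = 1 / 1.2, p = 1) {
  if (gamma <= 0 || p <= 0) stopConfig("gamma and p must be > 0")
  m <- .pixelsOf(image)
  .rewrap(image, clip01(p * m^gamma))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Divides the image into `tiles x tiles` sections, computes a 256-bin
#' histogram per tile, clips each histogram at `clip` times the tile pixel
#' count (redistributing the excess uniformly over all bins), maps
#' intensities through the per-tile clipped CDF, and blends the tile
#' mappings bilinearly to avoid block artifacts. With `tiles = 1` and
#' `clip = Inf` this reduces to plain global histogram equalization.
#'
#' @param image a [FundusImage-class] or intensity matrix in \[0,1\].
#' @param tiles grid dimension (>= 1; tiles must not outnumber pixels per
#'   side).
#' @param clip clip limit as a fraction of the tile pixel count; `Inf`
#'   disables clipping.
#' @param nbins number of histogram bins.
#' @export
claheEqualize <- function(image, tiles = 8L, clip = 0.01, nbins = 256L) {
  m <- .pixelsOf(image)
  H <- nrow(m); W <- ncol(m)
  if (tiles > min(H, W)) stopConfig("more CLAHE tiles than pixels per side")
  tiles <- as.integer(tiles)
  bin <- floor(m * nbins) + 1L  # 1..nbins
  bin[bin > nbins] <- nbins
  bin[bin < 1L] <- 1L
  # tile index boundaries (as even as possible)
  tileIdx <- function(n) {
    if (tiles == 1L) rep(1L, n)
    else as.integer(cut(seq_len(n), tiles, labels = FALSE))
  }
  rowTile <- tileIdx(H)
  colTile <- tileIdx(W)
  # per-tile clipped-CDF lookup, stored as (tiles, tiles, nbins)
  maps <- array(0, c(tiles, tiles, nbins))
  for (i in seq_len(tiles)) {
    for (j in seq_len(tiles)) {
      v <- bin[rowTile == i, colTile == j]
      h <- tabulate(v, nbins)
      npx <- length(v)
      lim <- clip * npx
      if (is.finite(lim)) {
        excess <- sum(pmax(h - lim, 0))
        h <- pmin(h, lim) + excess / nbins
      }
      maps[i, j, ] <- cumsum(h) / npx
    }
  }
  # bilinear blending between the four surrounding tile centers
  centerOf <- function(tileIdx, n) {
    b <- tapply(seq_len(n), tileIdx, function(ix) mean(range(ix)))
    as.numeric(b)
  }
  rc <- centerOf(rowTile, H)
  cc <- centerOf(colTile, W)
  interpIdx <- function(pos, centers) {
    i0 <- findInterval(pos, centers)
    i0 <- pmin(pmax(i0, 1L), length(centers) - if (length(centers) > 1) 1L else 0L)
    if (length(centers) == 1L) return(list(lo = rep(1L, length(pos)),
                                           hi = rep(1L, length(pos)),
                                           w = rep(0, length(pos))))
    i1 <- i0 + 1L
    w <- (pos - centers[i0]) / (centers[i1] - centers[i0])
    list(lo = i0, hi = i1, w = pmin(1, pmax(0, w)))
  }
  ri <- interpIdx(seq_len(H), rc)
  ci <- interpIdx(seq_len(W), cc)
  rowLo <- matrix(ri$lo, H, W); rowHi <- matrix(ri$hi, H, W)
  rowW <- matrix(ri$w, H, W)
  colLo <- matrix(ci$lo, H, W, byrow = TRUE)
  colHi <- matrix(ci$hi, H, W, byrow = TRUE)
  colW <- matrix(ci$w, H, W, byrow = TRUE)
  look <- function(rt, ct) maps[cbind(as.vector(rt), as.vector(ct),
                                      as.vector(bin))]
  out <- (1 - rowW) * (1 - colW) * look(rowLo, colLo) +
    (1 - rowW) * colW * look(rowLo, colHi) +
    rowW * (1 - colW) * look(rowHi, colLo) +
    rowW * colW * look(rowHi, colHi)
  dim(out) <- c(H, W)
  .rewrap(image, clip01(out))
}

#' Run the full enhancement chain
#'
#' Auto-crop to a square field of view, bilinear resize to
#' `config$targetSide`, then the two contrast-enhancement steps in
#' `config$opOrder` (default CLAHE, then gamma correction). Deterministic;
#' the result carries provenance `"enhanced"`.
#'
#' @param image a [FundusImage-class] or intensity matrix (a 3-channel
#'   array is first collapsed to luminance).
#' @param config a [preprocessConfig()].
#' @return the enhanced image, same type as the input.
#' @export
enhanceImage <- function(image, config = preprocessConfig()) {
  m <- .pixelsOf(image)
  if (length(dim(m)) == 3L)
    m <- 0.2126 * m[, , 1] + 0.7152 * m[, , 2] + 0.0722 * m[, , 3]
  m <- .pixelsOf(autocropSquare(m, config$borderThreshold))
  m <- resizeMatrix(m, config$targetSide)
  m <- clip01(m)
  for (op in config$opOrder) {
    m <- if (op == "clahe")
      claheEqualize(m, config$claheTiles, config$claheClip)
    else gammaCorrect(m, config$gamma, config$gammaNorm)
  }
  .rewrap(image, m, provenance = "enhanced")
}

#' Enhance an image together with its aligned vessel mask
#'
#' Applies the enhancement chain to the image while carrying the vessel
#' mask (and, optionally, point annotations) through the same geometric
#' transform: the crop window is computed from the image and applied to
#' both, both are resized to `targetSide` (the mask by bilinear resampling
#' re-binarized at 0.25, preserving thin vessels), and only the image
#' receives CLAHE/gamma. Returns the coordinate transform so annotations
#' can follow: `x' = (x - x0) * scale`, `y' = (y - y0) * scale` in 0-based
#' coordinates.
#'
#' @param image a [FundusImage-class] or matrix.
#' @param mask a [VesselMask-class] or binary matrix aligned to `image`.
#' @param config a [preprocessConfig()].
#' @return list with `image`, `mask` and `transform`
#'   (`list(x0, y0, scale)`).
#' @export
enhancePair <- function(image, mask, config = preprocessConfig()) {
  m <- .pixelsOf(image)
  mk <- if (is(mask, "VesselMask")) mask@pixels else mask
  if (!identical(dim(m), dim(mk)))
    stopData("image and mask dimensions are misaligned")
  win <- .cropWindow(m, config$borderThreshold)
  scale <- config$targetSide / win$side
  mi <- clip01(resizeMatrix(.applyWindow(m, win), config$targetSide))
  for (op in config$opOrder) {
    mi <- if (op == "clahe")
      claheEqualize(mi, config$claheTiles, config$claheClip)
    else gammaCorrect(mi, config$gamma, config$gammaNorm)
  }
  mm <- (resizeMatrix(.applyWindow(mk, win), config$targetSide) > 0.25) * 1
  list(image = .rewrap(image, mi, provenance = "enhanced"),
       mask = if (is(mask, "VesselMask")) new("VesselMask", pixels = mm)
       else mm,
       transform = list(x0 = win$c0 - 1L, y0 = win$r0 - 1L, scale = scale))
}
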