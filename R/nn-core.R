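# Compact CNN engine on GEMM-lowered convolutions.
#
# Batches are column-major arrays of dim (H, W, C, N). Convolutions are
# computed by im2col lowering (src/) followed by a single BLAS GEMM; the
# backward pass is the exact adjoint (col2im). All layers used by the
# segmenter and classifier live here: conv, batch norm, ReLU, max pool,
# nearest-neighbour upsampling, global max pool, dense, dropout, and the
# softmax/sigmoid losses, plus an Adam optimizer over flat parameter lists.
#
# Everything is deterministic given the R RNG state; no internal seeding.

nnConvInit <- function(k, cin, cout) {
  # He initialization for ReLU nets
  list(W = matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                  nrow = k * k * cin, ncol = cout),
       b = numeric(cout))
}

nnConvFwd <- function(x, W, b, k, pad = (k - 1L) %/% 2L, stride = 1L) {
  d <- dim(x)
  cols <- .im2col_cpp(as.numeric(x), d[1], d[2], d[3], d[4], k, pad, stride)
  Ho <- (d[1] + 2L * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2L * pad - k) %/% stride + 1L
  cout <- ncol(W)
  ymat <- crossprod(W, cols) + b
  y <- .chw_to_hwc_cpp(ymat, Ho, Wo, d[4])
  dim(y) <- c(Ho, Wo, cout, d[4])
  list(y = y, cache = list(cols = cols, dims = d, k = k, pad = pad,
                           stride = stride, Ho = Ho, Wo = Wo, cout = cout))
}

nnConvBwd <- function(dy, cache, W) {
  dymat <- .hwc_to_chw_cpp(as.numeric(dy), cache$Ho, cache$Wo, cache$cout,
                           cache$dims[4])
  dW <- cache$cols %*% t(dymat)
  db <- rowSums(dymat)
  dcols <- W %*% dymat
  d <- cache$dims
  dx <- array(.col2im_cpp(dcols, d[1], d[2], d[3], d[4], cache$k,
                          cache$pad, cache$stride), d)
  list(dx = dx, dW = dW, db = db)
}

nnBnInit <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c), rm = numeric(c), rv = rep(1, c))
}

# Channel-wise batch normalization over (H, W, N). Returns updated running
# statistics alongside the output; inference uses the running statistics.
#
# Implementation note: the (H, W, C, N) layout is never permuted. Per-channel
# statistics come from column sums of the (H*W) x (C*N) view, folded over N;
# the normalization itself is a single fused multiply-add with per-element
# scale/shift vectors expanded from the channel pattern.

# per-channel sums of an (H, W, C, N) array without permuting it
bnChannelSums <- function(x, d) {
  cs <- .colSums(x, d[1] * d[2], d[3] * d[4])
  .rowSums(matrix(cs, d[3], d[4]), d[3], d[4])
}

# expand a per-channel vector to the full (H, W, C, N) element pattern
bnExpand <- function(v, d) {
  rep_len(rep(v, each = d[1] * d[2]), d[1] * d[2] * d[3] * d[4])
}

nnBnFwd <- function(x, bn, training, momentum = 0.9, eps = 1e-5) {
  d <- dim(x)
  nPix <- d[1] * d[2] * d[4]
  if (training) {
    mu <- bnChannelSums(x, d) / nPix
    v <- bnChannelSums(x * x, d) / nPix - mu^2
    bn$rm <- momentum * bn$rm + (1 - momentum) * mu
    bn$rv <- momentum * bn$rv + (1 - momentum) * v
  } else {
    mu <- bn$rm; v <- bn$rv
  }
  invstd <- 1 / sqrt(v + eps)
  scale <- bn$gamma * invstd
  y <- x * bnExpand(scale, d) + bnExpand(bn$beta - scale * mu, d)
  dim(y) <- d
  xhat <- x * bnExpand(invstd, d) - bnExpand(invstd * mu, d)
  dim(xhat) <- d
  list(y = y, bn = bn,
       cache = list(xhat = xhat, invstd = invstd, dims = d,
                    training = training))
}

nnBnBwd <- function(dy, cache, bn) {
  d <- cache$dims
  nPix <- d[1] * d[2] * d[4]
  xhat <- cache$xhat
  dgamma <- bnChannelSums(dy * xhat, d)
  dbeta <- bnChannelSums(dy, d)
  if (cache$training) {
    # dx = invstd * gamma * (dy - mean(dy) - xhat * mean(dy * xhat))
    dx <- (dy - bnExpand(dbeta / nPix, d) -
             xhat * bnExpand(dgamma / nPix, d)) *
      bnExpand(bn$gamma * cache$invstd, d)
  } else {
    dx <- dy * bnExpand(bn$gamma * cache$invstd, d)
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

nnReluFwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
nnReluBwd <- function(dy, cache) dy * cache

nnPoolFwd <- function(x, p) {
  if (p == 1L) return(list(y = x, cache = NULL, p = 1L))
  d <- dim(x)
  r <- .maxpool_cpp(as.numeric(x), d[1], d[2], d[3], d[4], p)
  list(y = array(r$y, c(d[1] %/% p, d[2] %/% p, d[3], d[4])),
       cache = list(argmax = r$argmax, len = prod(d), dims = d), p = p)
}

nnPoolBwd <- function(dy, pool) {
  if (pool$p == 1L) return(dy)
  array(.maxpool_bwd_cpp(as.numeric(dy), pool$cache$argmax, pool$cache$len),
        pool$cache$dims)
}

# Nearest-neighbour x2 upsampling (U-Net decoder); backward sums 2x2 blocks.
nnUpFwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

nnUpBwd <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  dy[i1, j1, , , drop = FALSE] + dy[i1, j2, , , drop = FALSE] +
    dy[i2, j1, , , drop = FALSE] + dy[i2, j2, , , drop = FALSE]
}

nnGmpFwd <- function(x) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1] * d[2])
  am <- max.col(t(xm), ties.method = "first")
  j <- seq_len(ncol(xm))
  list(y = matrix(xm[cbind(am, j)], d[3], d[4]),
       cache = list(am = am, dims = d))
}

nnGmpBwd <- function(dy, cache) {
  d <- cache$dims
  dxm <- matrix(0, d[1] * d[2], d[3] * d[4])
  dxm[cbind(cache$am, seq_len(ncol(dxm)))] <- as.numeric(dy)
  array(dxm, d)
}

nnDenseInit <- function(din, dout) {
  list(W = matrix(rnorm(din * dout, sd = sqrt(2 / din)), din, dout),
       b = numeric(dout))
}

nnDenseFwd <- function(x, W, b) list(y = crossprod(W, x) + b, cache = x)
nnDenseBwd <- function(dy, cache, W) {
  list(dx = W %*% dy, dW = cache %*% t(dy), db = rowSums(dy))
}

nnDropoutFwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, cache = NULL))
  mask <- (runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(y = x * mask, cache = mask)
}

nnDropoutBwd <- function(dy, cache) if (is.null(cache)) dy else dy * cache

# Softmax + cross-entropy over logits (K x N); labels are 1-based indices.
nnSoftmaxCE <- function(logits, labels) {
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  p <- sweep(e, 2, colSums(e), `/`)
  n <- ncol(logits)
  pick <- cbind(labels, seq_len(n))
  pickT <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(t(p)[pickT], 1e-12)))
  onehot <- matrix(0, nrow(logits), n)
  onehot[pick] <- 1
  list(loss = loss, probs = p, dlogits = (p - onehot) / n)
}

nnSigmoid <- function(x) 1 / (1 + exp(-x))

# Per-pixel binary cross-entropy on logits; returns mean loss and dlogits.
nnBCE <- function(logits, target) {
  p <- nnSigmoid(logits)
  loss <- -mean(target * log(pmax(p, 1e-12)) +
                  (1 - target) * log(pmax(1 - p, 1e-12)))
  list(loss = loss, dlogits = (p - target) / length(p))
}

nnAdamInit <- function(params) {
  zeros <- lapply(params, function(p) { p[] <- 0; p })
  list(m = zeros, v = zeros, t = 0L)
}

# One Adam update over a flat named parameter list. Entries named *.rm/*.rv
# (batch-norm running statistics) are carried, not optimized, and never
# receive gradients.
nnAdamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
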