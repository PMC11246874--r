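# Neural-network layer primitives on plain 3D arrays (H x W x C), with
# hand-derived backward passes.  The hot kernels (3x3 convolution via
# im2col, 2x2 max pooling, 2x2 transposed convolution, per-channel plane
# normalization) are compiled (src/layers.cpp) and reduce to BLAS matrix
# products; everything else is plain R.  No deep-learning framework is
# involved.
#
# Conventions
#   * feature maps: dim (H, W, C), column-major R arrays
#   * 3x3 conv weights: matrix (9*Cin x Cout); row block (k-1)*Cin + c holds
#     kernel offset k = 3*di + dj + 1 (di, dj in 0..2), input channel c
#   * 2x2 transposed-conv weights: matrix (Cin x 4*Cout); column block
#     (k-1)*Cout + co holds output offset k = 2*di + dj + 1 (di, dj in 0..1)

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- 3x3 convolution (stride 1, zero pad 1) --------------------------------

# convolution precision: "single" (default; fast, the training path) or
# "double" (used by numerical verification, e.g. gradient checks)
conv_single <- function() {
  !identical(getOption("sarcoseg.conv_precision"), "double")
}

conv3_fw <- function(x, W, b) {
  conv3_fw_cpp(x, W, b, conv_single())
}

conv3_bw <- function(x, dy, W) {
  out <- conv3_bw_cpp(x, dy, W, conv_single())
  out$db <- as.vector(out$db)
  out
}

## ---- 1x1 convolution -------------------------------------------------------

conv1_fw <- function(x, W, b) {
  d <- dim(x)
  y <- sweep(matrix(x, d[1] * d[2]) %*% W, 2, b, `+`)
  array(y, c(d[1], d[2], ncol(W)))
}

conv1_bw <- function(x, dy, W) {
  d <- dim(x)
  X <- matrix(x, d[1] * d[2])
  dY <- matrix(dy, d[1] * d[2])
  list(dx = array(tcrossprod(dY, W), d),
       dW = crossprod(X, dY), db = colSums(dY))
}

## ---- 2x2 max pooling (stride 2) --------------------------------------------

# returns list(y, idx); idx holds the winning 2x2 candidate (1..4, ties to
# the first in offset order), consumed by pool_bw
pool_fw <- function(x) {
  d <- dim(x)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  pool_fw_cpp(x)
}

pool_bw <- function(dy, idx, H, W, C) {
  pool_bw_cpp(dy, idx)
}

## ---- 2x2 transposed convolution (stride 2, upsampling) ---------------------

tconv_fw <- function(x, W, b) {
  tconv_fw_cpp(x, W, b)
}

tconv_bw <- function(x, dy, W, Cout) {
  out <- tconv_bw_cpp(x, dy, W, as.integer(Cout))
  out$db <- as.vector(out$db)
  out
}

# add a per-channel bias to an (H, W, C) array
sweep_c <- function(x, b) {
  d <- dim(x)
  array(sweep(matrix(x, d[1] * d[2]), 2, b, `+`), d)
}

## ---- per-channel normalization (over the spatial plane) --------------------

# Normalizes each channel to zero mean / unit variance over its H x W plane
# before a learned affine (gamma, beta).  With the per-sample gradient
# accumulation used here this is instance normalization.

norm_fw <- function(x, g, beta, eps = 1e-5) {
  norm_fw_cpp(x, g, beta, eps)
}

norm_bw <- function(dy, cache, g) {
  out <- norm_bw_cpp(dy, cache$xhat, as.vector(cache$istd), g)
  out$dg <- as.vector(out$dg)
  out$dbeta <- as.vector(out$dbeta)
  out
}

## ---- Adam ------------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(params = params, state = state)
}

# Kaiming-uniform initialization: U(-sqrt(6/fan_in), sqrt(6/fan_in))
kaiming <- function(nrow, ncol, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}
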