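#' Channel-gate parameters
#'
#' The channel attention gate squeezes a feature map to one statistic per
#' channel by global average pooling and re-expands it through a two-layer
#' bottleneck: `W1` maps the C pooled values to C/2 (followed by ReLU), `W2`
#' maps back to C, and a sigmoid turns the result into a per-channel gate in
#' (0, 1).  The reduction ratio is fixed at 2, so C must be even.  Neither
#' layer carries a bias.
#'
#' @param C number of channels (even).
#' @param init `"kaiming"` for random initialization (uses the current RNG
#'   state) or `"zero"` for all-zero weights (gate = 0.5 everywhere).
#' @return list with `W1` (C/2 x C) and `W2` (C x C/2), class
#'   `channel_gate_params`.
#' @export
channel_gate_params <- function(C, init = c("kaiming", "zero")) {
  init <- match.arg(init)
  C <- as.integer(C)
  if (C < 2 || C %% 2 != 0) stop("channel_gate_params: C must be even, >= 2")
  h <- C %/% 2L
  p <- if (init == "zero")
    list(W1 = matrix(0, h, C), W2 = matrix(0, C, h))
  else
    list(W1 = kaiming(h, C, C), W2 = kaiming(C, h, h))
  structure(p, class = "channel_gate_params")
}

#' Spatial-gate parameters
#'
#' The spatial attention gate scores every pixel position by combining a
#' learned 1x1-convolution projection of the channel vector (`ws`, one
#' weight per channel, no bias) with a parameter-free channel-wise max, and
#' squashes the sum through a sigmoid into a per-position gate in (0, 1).
#'
#' @param C number of channels.
#' @param init `"kaiming"` or `"zero"` (gate = sigmoid(channel max)).
#' @return list with `ws` (length-C numeric), class `spatial_gate_params`.
#' @export
spatial_gate_params <- function(C, init = c("kaiming", "zero")) {
  init <- match.arg(init)
  C <- as.integer(C)
  if (C < 1) stop("spatial_gate_params: C must be >= 1")
  ws <- if (init == "zero") numeric(C) else as.vector(kaiming(C, 1, C))
  structure(list(ws = ws), class = "spatial_gate_params")
}

check_fmap <- function(F_, C = NULL, what = "feature map") {
  d <- dim(F_)
  if (is.null(d) || length(d) != 3L)
    stop(what, " must be a 3D array (H x W x C)")
  if (!all(is.finite(F_))) stop(what, " contains non-finite values")
  if (!is.null(C) && d[3] != C)
    stop(what, " has ", d[3], " channels, parameters expect ", C)
  d
}

#' Channel attention
#'
#' Re-weights each channel of a feature map by a data-dependent gate:
#' `Z_k = mean over the H x W plane of channel k`;
#' `g = sigmoid(W2 %*% relu(W1 %*% Z))`; output channel k is `g_k` times
#' input channel k.  The gate lies strictly in (0, 1), so the output never
#' exceeds the input in magnitude.
#'
#' @param F_ feature map, 3D array (H x W x C).
#' @param params a [channel_gate_params()] for C channels.
#' @return Gated feature map of the same shape (attribute `"gate"` carries
#'   the per-channel gate).
#' @export
channel_attention <- function(F_, params) {
  d <- check_fmap(F_, nrow(params$W2))
  out <- channel_attention_fw(F_, params$W1, params$W2)
  structure(out$y, gate = out$g)
}

channel_attention_fw <- function(x, W1, W2) {
  d <- dim(x)
  X <- matrix(x, d[1] * d[2])
  z <- colMeans(X)
  h <- pmax(as.vector(W1 %*% z), 0)
  g <- sigmoid(as.vector(W2 %*% h))
  y <- array(sweep(X, 2, g, `*`), d)
  list(y = y, z = z, h = h, g = g)
}

channel_attention_bw <- function(x, dy, W1, W2, cache) {
  d <- dim(x)
  X <- matrix(x, d[1] * d[2])
  dY <- matrix(dy, d[1] * d[2])
  g <- cache$g; h <- cache$h; z <- cache$z
  dx_mat <- sweep(dY, 2, g, `*`)
  dg <- colSums(dY * X)
  dzh <- dg * g * (1 - g)
  dW2 <- dzh %*% t(h)
  dh <- as.vector(crossprod(W2, dzh))
  dpre <- dh * (h > 0)
  dW1 <- dpre %*% t(z)
  dz <- as.vector(crossprod(W1, dpre))
  dx_mat <- sweep(dx_mat, 2, dz / (d[1] * d[2]), `+`)
  list(dx = array(dx_mat, d), dW1 = dW1, dW2 = dW2)
}

#' Spatial attention
#'
#' Re-weights each pixel position of a feature map by a data-dependent gate:
#' `q(i,j)` is the learned linear combination of the channel vector at
#' (i, j) (1x1 convolution with weight `ws`), `p(i,j)` is the channel-wise
#' maximum at (i, j), and the gate is `sigmoid(p + q)`; every channel at
#' (i, j) is multiplied by the gate.
#'
#' @param F_ feature map, 3D array (H x W x C).
#' @param params a [spatial_gate_params()] for C channels.
#' @return Gated feature map of the same shape (attribute `"gate"` carries
#'   the H x W gate).
#' @export
spatial_attention <- function(F_, params) {
  d <- check_fmap(F_, length(params$ws))
  out <- spatial_attention_fw(F_, params$ws)
  structure(out$y, gate = matrix(out$g, d[1], d[2]))
}

spatial_attention_fw <- function(x, ws) {
  d <- dim(x)
  X <- matrix(x, d[1] * d[2])
  q <- as.vector(X %*% ws)
  pidx <- max.col(X, ties.method = "first")
  p <- X[cbind(seq_len(nrow(X)), pidx)]
  g <- sigmoid(p + q)
  y <- array(X * g, d)
  list(y = y, g = g, pidx = pidx)
}

spatial_attention_bw <- function(x, dy, ws, cache) {
  d <- dim(x)
  X <- matrix(x, d[1] * d[2])
  dY <- matrix(dy, d[1] * d[2])
  g <- cache$g
  dx_mat <- dY * g
  dg <- rowSums(dY * X)
  ds <- dg * g * (1 - g)
  dws <- as.vector(crossprod(X, ds))
  dx_mat <- dx_mat + outer(ds, ws)
  sel <- cbind(seq_len(nrow(X)), cache$pidx)
  dx_mat[sel] <- dx_mat[sel] + ds
  list(dx = array(dx_mat, d), dws = dws)
}

#' Fusion parameters for a set of modality feature maps
#'
#' @param M number of modality feature maps to fuse.
#' @param C_per_modality channels of each input map (`M * C_per_modality`
#'   must be even).
#' @param init `"kaiming"` or `"zero"`.
#' @return list with `ca` ([channel_gate_params()]) and `sa`
#'   ([spatial_gate_params()]) sized for the concatenated map.
#' @export
fusion_params <- function(M, C_per_modality, init = c("kaiming", "zero")) {
  init <- match.arg(init)
  C <- as.integer(M) * as.integer(C_per_modality)
  structure(list(ca = channel_gate_params(C, init),
                 sa = spatial_gate_params(C, init)),
            class = "fusion_params")
}

#' Attention-weighted modality fusion
#'
#' Fuses the per-modality encoder features at one resolution level:
#' the M maps are concatenated along the channel axis (in manifest modality
#' order: T1WI, T2WI, STIR), and the fused output is the sum of the
#' channel-gated and the spatially-gated versions of the concatenation,
#' `F_f = F_c + F_s`.  With all-zero gate weights both gates are 0.5
#' everywhere, so the fusion reduces to the identity on the concatenation.
#'
#' @param features list of M feature maps, all of identical shape (H x W x
#'   C_per_modality).
#' @param params a [fusion_params()] for `M * C_per_modality` channels.
#' @return Fused feature map, 3D array (H x W x M*C_per_modality).
#' @export
attention_fusion <- function(features, params) {
  x <- concat_channels(features)
  out <- fusion_fw(x, params)
  out$y
}

concat_channels <- function(features) {
  if (!is.list(features) || length(features) < 1)
    stop("attention_fusion: 'features' must be a nonempty list")
  dims <- lapply(features, function(f) check_fmap(f))
  d0 <- dims[[1]]
  for (d in dims)
    if (!identical(d, d0))
      stop("attention_fusion: all feature maps must share the same shape")
  M <- length(features)
  out <- array(0, c(d0[1], d0[2], d0[3] * M))
  for (m in seq_len(M))
    out[, , ((m - 1) * d0[3] + 1):(m * d0[3])] <- features[[m]]
  out
}

fusion_fw <- function(x, params) {
  ca <- channel_attention_fw(x, params$ca$W1, params$ca$W2)
  sa <- spatial_attention_fw(x, params$sa$ws)
  list(y = ca$y + sa$y, ca = ca, sa = sa)
}

fusion_bw <- function(x, dy, params, cache) {
  bc <- channel_attention_bw(x, dy, params$ca$W1, params$ca$W2, cache$ca)
  bs <- spatial_attention_bw(x, dy, params$sa$ws, cache$sa)
  list(dx = bc$dx + bs$dx, dW1 = bc$dW1, dW2 = bc$dW2, dws = bs$dws)
}
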