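# Independent dense-loop / brute-force oracles used to cross-check the
# vectorized implementations.  These are deliberately written as explicit
# loops over scalars, sharing no code with the package internals.

oracle_channel_attention <- function(F_, W1, W2) {
  d <- dim(F_); H <- d[1]; W <- d[2]; C <- d[3]
  z <- numeric(C)
  for (k in 1:C) {
    s <- 0
    for (i in 1:H) for (j in 1:W) s <- s + F_[i, j, k]
    z[k] <- s / (H * W)
  }
  h <- numeric(nrow(W1))
  for (a in seq_len(nrow(W1))) {
    s <- 0
    for (k in 1:C) s <- s + W1[a, k] * z[k]
    h[a] <- max(s, 0)
  }
  g <- numeric(C)
  for (k in 1:C) {
    s <- 0
    for (a in seq_len(ncol(W2))) s <- s + W2[k, a] * h[a]
    g[k] <- 1 / (1 + exp(-s))
  }
  out <- array(0, d)
  for (i in 1:H) for (j in 1:W) for (k in 1:C)
    out[i, j, k] <- g[k] * F_[i, j, k]
  out
}

oracle_spatial_attention <- function(F_, ws) {
  d <- dim(F_); H <- d[1]; W <- d[2]; C <- d[3]
  out <- array(0, d)
  for (i in 1:H) for (j in 1:W) {
    q <- 0
    for (k in 1:C) q <- q + ws[k] * F_[i, j, k]
    p <- F_[i, j, 1]
    for (k in 1:C) p <- max(p, F_[i, j, k])
    g <- 1 / (1 + exp(-(p + q)))
    for (k in 1:C) out[i, j, k] <- g * F_[i, j, k]
  }
  out
}

oracle_fusion <- function(features, params) {
  M <- length(features)
  d <- dim(features[[1]])
  cat_ <- array(0, c(d[1], d[2], d[3] * M))
  for (m in 1:M)
    for (k in 1:d[3])
      cat_[, , (m - 1) * d[3] + k] <- features[[m]][, , k]
  oracle_channel_attention(cat_, params$ca$W1, params$ca$W2) +
    oracle_spatial_attention(cat_, params$sa$ws)
}

oracle_confusion <- function(pred, gt) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && gt[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && gt[i] == 0) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# all-pairs directed percentile Hausdorff on pixel index sets
oracle_hausdorff <- function(pred, gt, percentile, spacing = c(1, 1)) {
  A <- which(pred > 0, arr.ind = TRUE)
  B <- which(gt > 0, arr.ind = TRUE)
  dir_d <- function(P, Q) {
    mins <- numeric(nrow(P))
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q))) {
        dd <- sqrt(((P[i, 1] - Q[j, 1]) * spacing[1])^2 +
                   ((P[i, 2] - Q[j, 2]) * spacing[2])^2)
        if (dd < best) best <- dd
      }
      mins[i] <- best
    }
    unname(quantile(mins, percentile / 100, type = 7))
  }
  max(dir_d(A, B), dir_d(B, A))
}

# random small binary mask guaranteed nonempty
random_mask <- function(h, w, p = 0.2) {
  m <- matrix(rbinom(h * w, 1, p), h, w)
  if (!any(m > 0)) m[sample(h, 1), sample(w, 1)] <- 1
  m
}
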