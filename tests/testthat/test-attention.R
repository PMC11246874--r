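test_that("channel attention: annihilation, neutral gate, and oracle
           equivalence", {
  z <- array(0, c(3, 3, 4))
  p0 <- channel_gate_params(4, init = "zero")
  expect_equal(as.vector(channel_attention(z, p0)), rep(0, 36))

  set.seed(20)
  F_ <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  half <- channel_attention(F_, p0)   # zero weights -> sigmoid(0) = 0.5
  expect_equal(unclass(half), 0.5 * F_, tolerance = 1e-12,
               ignore_attr = TRUE)

  pr <- channel_gate_params(4)
  expect_equal(unclass(channel_attention(F_, pr)),
               oracle_channel_attention(F_, pr$W1, pr$W2),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(channel_attention(array(0, c(2, 2, 6)), pr), "channels")
  expect_error(channel_gate_params(5), "even")
})

test_that("spatial attention: zero input, C = 1 closed form, oracle
           equivalence", {
  p0 <- spatial_gate_params(4, init = "zero")
  expect_equal(as.vector(spatial_attention(array(0, c(3, 3, 4)), p0)),
               rep(0, 36))

  # C = 1 with ws = 1: p = q = F, gate = sigmoid(2F)
  set.seed(21)
  F1 <- array(rnorm(16), c(4, 4, 1))
  ps <- spatial_gate_params(1); ps$ws <- 1
  out <- spatial_attention(F1, ps)
  expect_equal(unclass(out), 1 / (1 + exp(-2 * F1)) * F1, tolerance = 1e-12,
               ignore_attr = TRUE)

  F_ <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  pr <- spatial_gate_params(4)
  expect_equal(unclass(spatial_attention(F_, pr)),
               oracle_spatial_attention(F_, pr$ws),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("attention fusion composes the two gates on the concatenation", {
  set.seed(22)
  # M = 1 with zero weights: the channel gate is 0.5 everywhere, and the
  # spatial gate is sigmoid(p) with p the parameter-free channel max, so
  # when every position's channel max is 0 both gates are 0.5 and
  # F_f = 0.5 F + 0.5 F = F
  F_ <- array(-abs(rnorm(2 * 2 * 4)), c(2, 2, 4))
  F_[, , 1] <- 0                                  # channel max = 0 everywhere
  expect_equal(attention_fusion(list(F_), fusion_params(1, 4, init = "zero")),
               F_, tolerance = 1e-12)
  expect_equal(attention_fusion(list(array(0, c(2, 2, 2)),
                                     array(0, c(2, 2, 2))),
                                fusion_params(2, 2)),
               array(0, c(2, 2, 4)))

  feats <- lapply(1:3, function(m) array(rnorm(2 * 2 * 2), c(2, 2, 2)))
  pr <- fusion_params(3, 2)
  expect_equal(attention_fusion(feats, pr), oracle_fusion(feats, pr),
               tolerance = 1e-10)
  bad <- feats; bad[[2]] <- array(0, c(3, 2, 2))
  expect_error(attention_fusion(bad, pr), "same shape")
})

test_that("attention ops match the dense-loop oracles on random tensors", {
  set.seed(23)
  for (trial in 1:30) {
    H <- sample(2:4, 1); W <- sample(2:4, 1); C <- sample(c(2, 4, 6, 8), 1)
    F_ <- array(rnorm(H * W * C, sd = runif(1, 0.3, 3)), c(H, W, C))
    pc <- channel_gate_params(C); psp <- spatial_gate_params(C)
    expect_lt(max(abs(channel_attention(F_, pc) -
                        oracle_channel_attention(F_, pc$W1, pc$W2))), 1e-6)
    expect_lt(max(abs(spatial_attention(F_, psp) -
                        oracle_spatial_attention(F_, psp$ws))), 1e-6)
  }
})

test_that("gates stay in (0,1): outputs never exceed inputs in sup-norm", {
  set.seed(24)
  for (trial in 1:20) {
    F_ <- array(rnorm(4 * 4 * 6, sd = 2), c(4, 4, 6))
    pc <- channel_gate_params(6); ps <- spatial_gate_params(6)
    Fc <- channel_attention(F_, pc); Fs <- spatial_attention(F_, ps)
    expect_lte(max(abs(Fc)), max(abs(F_)))
    expect_lte(max(abs(Fs)), max(abs(F_)))
    gc_ <- attr(Fc, "gate"); gs <- attr(Fs, "gate")
    expect_true(all(gc_ > 0 & gc_ < 1))
    expect_true(all(gs > 0 & gs < 1))
    Ff <- attention_fusion(list(F_), list(ca = pc, sa = ps))
    expect_lte(max(abs(Ff)), 2 * max(abs(F_)))
  }
})

test_that("fusion is covariant under simultaneous spatial permutation", {
  set.seed(25)
  feats <- lapply(1:2, function(m) array(rnorm(4 * 4 * 2), c(4, 4, 2)))
  pr <- fusion_params(2, 2)
  pi_r <- sample(4); pi_c <- sample(4)
  out <- attention_fusion(feats, pr)
  perm_feats <- lapply(feats, function(f) f[pi_r, pi_c, , drop = FALSE])
  out_perm <- attention_fusion(perm_feats, pr)
  expect_equal(out_perm, out[pi_r, pi_c, , drop = FALSE], tolerance = 1e-12)
})

test_that("attention backward passes agree with finite differences", {
  set.seed(26)
  F_ <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  pc <- channel_gate_params(4); ps <- spatial_gate_params(4)
  pr <- list(ca = pc, sa = ps)
  loss <- function(x, w1, w2, ws) {
    p <- list(ca = list(W1 = w1, W2 = w2), sa = list(ws = ws))
    sum(sin(sarcoseg:::fusion_fw(x, p)$y))
  }
  fw <- sarcoseg:::fusion_fw(F_, pr)
  bw <- sarcoseg:::fusion_bw(F_, cos(fw$y), pr, fw)
  h <- 1e-6
  for (rep in 1:10) {
    i <- sample(length(F_), 1)
    xp <- F_; xp[i] <- xp[i] + h; xm <- F_; xm[i] <- xm[i] - h
    num <- (loss(xp, pc$W1, pc$W2, ps$ws) - loss(xm, pc$W1, pc$W2, ps$ws)) / (2 * h)
    expect_equal(bw$dx[i], num, tolerance = 1e-4)
  }
  i <- sample(length(pc$W1), 1)
  wp <- pc$W1; wp[i] <- wp[i] + h; wm <- pc$W1; wm[i] <- wm[i] - h
  num <- (loss(F_, wp, pc$W2, ps$ws) - loss(F_, wm, pc$W2, ps$ws)) / (2 * h)
  expect_equal(bw$dW1[i], num, tolerance = 1e-4)
  i <- sample(length(ps$ws), 1)
  vp <- ps$ws; vp[i] <- vp[i] + h; vm <- ps$ws; vm[i] <- vm[i] - h
  num <- (loss(F_, pc$W1, pc$W2, vp) - loss(F_, pc$W1, pc$W2, vm)) / (2 * h)
  expect_equal(bw$dws[i], num, tolerance = 1e-4)
})
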