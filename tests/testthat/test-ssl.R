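test_that("boundary masking is local, clamped and deterministic", {
  set.seed(40)
  slice <- matrix(runif(256 * 256), 256, 256)
  gt <- matrix(0, 256, 256); gt[80:140, 60:150] <- 1

  set.seed(1); r1 <- apply_boundary_mask(slice, gt, 30)
  set.seed(1); r2 <- apply_boundary_mask(slice, gt, 30)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$corruption, r2$corruption)

  diff <- which(r1$data != slice, arr.ind = TRUE)
  expect_lte(nrow(diff), 900)
  tl <- r1$corruption$patch_top_left
  expect_true(all(diff[, 1] >= tl[1] + 1 & diff[, 1] <= tl[1] + 30))
  expect_true(all(diff[, 2] >= tl[2] + 1 & diff[, 2] <= tl[2] + 30))
  expect_true(all(r1$data[(tl[1] + 1):(tl[1] + 30), (tl[2] + 1):(tl[2] + 30)] == 0))

  # patch centre sits on the mask boundary (window within 15 px of it)
  bnd <- which(sarcoseg:::mask_boundary(gt > 0), arr.ind = TRUE)
  ctr <- tl + 15
  expect_lte(min(abs(bnd[, 1] - ctr[1]) + abs(bnd[, 2] - ctr[2])), 16)

  expect_error(apply_boundary_mask(slice, matrix(0, 256, 256)), "empty")
})

test_that("a full-frame mask clamps the patch at the border and changes
           exactly the window", {
  slice <- matrix(5, 64, 64)
  gt <- matrix(1, 64, 64)            # boundary = frame edge
  set.seed(2)
  r <- apply_boundary_mask(slice, gt, 30, fill_value = 0)
  tl <- r$corruption$patch_top_left
  expect_true(all(tl >= 0 & tl <= 64 - 30))
  expect_equal(sum(r$data != slice), 900)
})

test_that("corruption stays local over many random slices", {
  set.seed(41)
  for (i in 1:30) {
    sl <- matrix(runif(64 * 64), 64, 64)
    gt <- matrix(0, 64, 64)
    r0 <- sample(10:40, 2); c0 <- sample(10:40, 2)
    gt[min(r0):max(r0 + 5), min(c0):max(c0 + 5)] <- 1
    r <- apply_boundary_mask(sl, gt, 16)
    d <- which(r$data != sl, arr.ind = TRUE)
    expect_lte(nrow(d), 256)
    if (nrow(d) > 0) {
      expect_lte(max(d[, 1]) - min(d[, 1]), 15)
      expect_lte(max(d[, 2]) - min(d[, 2]), 15)
    }
  }
})

test_that("cosine similarity loss has the expected geometry", {
  expect_equal(cosine_similarity_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosine_similarity_loss(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_similarity_loss(c(1, 2), c(-1, -2)), 2)
  expect_equal(cosine_similarity_loss(c(1, 0), c(0, 1), mode = "literal_cos"), 0)
  set.seed(42)
  f <- rnorm(20); g <- rnorm(20)
  expect_equal(cosine_similarity_loss(f, g), cosine_similarity_loss(g, f))
  expect_equal(cosine_similarity_loss(3.7 * f, 0.2 * g),
               cosine_similarity_loss(f, g), tolerance = 1e-12)
  expect_error(cosine_similarity_loss(f, rep(0, 20)), "zero-norm")
  expect_error(cosine_similarity_loss(f, g[1:10]), "length")
  # gradient agrees with finite differences
  gr <- sarcoseg:::cosine_loss_grad(f, g)
  h <- 1e-6
  for (i in c(1, 7)) {
    fp <- f; fp[i] <- fp[i] + h; fm <- f; fm[i] <- fm[i] - h
    expect_equal(gr$dF[i],
                 (cosine_similarity_loss(fp, g) - cosine_similarity_loss(fm, g)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("dice loss matches hand arithmetic and stays in [-1, 0]", {
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(dice_loss(y, y), -1)                       # perfect overlap
  expect_equal(dice_loss(matrix(c(1, 0, 0, 0), 2), matrix(c(0, 1, 0, 0), 2)),
               -2e-5 / (2 + 2e-5))                        # disjoint
  yp <- matrix(0.5, 2, 2); yt <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice_loss(yp, yt), -(2 * 1 + 2e-5) / (2 + 2 + 2e-5))
  expect_equal(dice_loss(matrix(0, 2, 2), matrix(0, 2, 2)), -1)  # empty-empty
  set.seed(43)
  for (i in 1:20) {
    p <- matrix(runif(16), 4, 4); t <- matrix(rbinom(16, 1, 0.4), 4, 4)
    l <- dice_loss(p, t)
    expect_gte(l, -1); expect_lte(l, 0)
  }
  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
  expect_error(dice_loss(matrix(2, 2, 2), matrix(1, 2, 2)), "0, 1")
  # gradient check
  p <- matrix(runif(16), 4, 4); t <- matrix(rbinom(16, 1, 0.5), 4, 4)
  g <- sarcoseg:::dice_loss_grad(p, t)
  h <- 1e-7
  i <- 5
  pp <- p; pp[i] <- pp[i] + h; pm <- p; pm[i] <- pm[i] - h
  expect_equal(g[i], (dice_loss(pp, t) - dice_loss(pm, t)) / (2 * h),
               tolerance = 1e-5)
})

test_that("pretraining is reproducible and satisfies the loss identity", {
  set.seed(44)
  slices <- lapply(1:4, function(i) matrix(runif(64 * 64), 64, 64))
  masks <- lapply(1:4, function(i) {
    m <- matrix(0, 64, 64); m[20:40, 15:45] <- 1; m
  })
  r1 <- pretrain_encoder(slices, masks, steps = 10, lr = 1e-3,
                         base_channels = 4, patch_size = 12, seed = 9)
  r2 <- pretrain_encoder(slices, masks, steps = 10, lr = 1e-3,
                         base_channels = 4, patch_size = 12, seed = 9)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$encoder_weights, r2$encoder_weights)
  expect_equal(r1$history$l_total,
               r1$history$l_similarity + r1$history$l_dice, tolerance = 1e-12)
  expect_true(all(grepl("^l[1-4]\\.", names(r1$encoder_weights))))
})

test_that("weight transfer round-trips exactly and rejects mismatched
           schedules", {
  set.seed(45)
  slices <- lapply(1:2, function(i) matrix(runif(32 * 32), 32, 32))
  masks <- lapply(1:2, function(i) {
    m <- matrix(0, 32, 32); m[10:20, 8:24] <- 1; m
  })
  pres <- lapply(1:3, function(m)
    pretrain_encoder(slices, masks, steps = 2, lr = 1e-3, base_channels = 4,
                     patch_size = 8, seed = m)$encoder_weights)
  model <- build_model(model_config("ours", base_channels = 4), seed = 1)
  model <- transfer_weights(pres, model)
  for (m in 1:3)
    for (nm in names(pres[[m]]))
      expect_identical(model$params[[sprintf("enc%d.%s", m, nm)]],
                       pres[[m]][[nm]])
  # decoder / fusion untouched relative to a fresh build
  fresh <- build_model(model_config("ours", base_channels = 4), seed = 1)
  expect_identical(model$params[["dec.l1.c1.W"]], fresh$params[["dec.l1.c1.W"]])
  expect_identical(model$params[["fuse.l2.ca.W1"]], fresh$params[["fuse.l2.ca.W1"]])

  wrong <- build_model(model_config("ours", base_channels = 8), seed = 1)
  expect_error(transfer_weights(pres, wrong), "shape mismatch at 'enc1")

  # transferred model still yields valid probabilities
  out <- forward_segment(model, lapply(1:3, function(m) matrix(runif(32 * 32), 32, 32)))
  expect_lt(max(abs(out$prob[, , 1] + out$prob[, , 2] - 1)), 1e-5)
})
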