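test_that("model configuration fixes the channel schedule", {
  cfg <- model_config("ours")
  expect_equal(cfg$channels, c(64, 128, 256, 512))
  expect_equal(cfg$bottleneck_channels, 1024)
  cfg16 <- model_config("ours", base_channels = 16)
  expect_equal(cfg16$channels, c(16, 32, 64, 128))
})

test_that("parameter sets are a pure function of the configuration", {
  cfg <- model_config("ours", base_channels = 8)
  m1 <- build_model(cfg, seed = 1)
  m2 <- build_model(cfg, seed = 2)
  expect_identical(names(m1$params), names(m2$params))
  expect_identical(lapply(m1$params, dim), lapply(m2$params, dim))
  expect_identical(param_count(m1), param_count(m2))
  expect_false(identical(m1$params, m2$params))         # different seeds
  expect_identical(build_model(cfg, seed = 1)$params, m1$params)

  # variants share encoder shapes but differ around fusion / bottleneck
  expect_true(any(grepl("^fuse\\.", names(m1$params))))
  expect_false(any(grepl("^fuse\\.", names(build_model(model_config("munet",
    base_channels = 8), seed = 1)$params))))
})

test_that("encoder features follow the published resolution/channel
           schedule on a 256x256 input", {
  cfg <- model_config("ours", base_channels = 4)
  model <- build_model(cfg, seed = 3)
  xs <- lapply(1:3, function(m) matrix(runif(256 * 256), 256, 256))
  fw <- sarcoseg:::model_forward(model, xs, keep_cache = TRUE)
  skips <- fw$cache$encs[[1]]$skips
  sizes <- c(256, 128, 64, 32)
  for (l in 1:4)
    expect_equal(dim(skips[[l]]), c(sizes[l], sizes[l], cfg$channels[l]))
  expect_equal(dim(fw$cache$encs[[1]]$pooled), c(16, 16, cfg$channels[4]))
  expect_equal(dim(fw$cache$bn$y), c(16, 16, cfg$bottleneck_channels))
  expect_equal(dim(fw$probs), c(256, 256, 2))
})

test_that("the softmax head conserves probability and predictions are
           deterministic with ties to background", {
  set.seed(30)
  for (variant in c("ours", "munet", "sunet")) {
    model <- build_model(model_config(variant, base_channels = 4), seed = 4)
    stack <- lapply(1:3, function(m) matrix(runif(64 * 64), 64, 64))
    out1 <- forward_segment(model, stack)
    out2 <- forward_segment(model, stack)
    expect_identical(out1$prob, out2$prob)
    sums <- out1$prob[, , 1] + out1$prob[, , 2]
    expect_lt(max(abs(sums - 1)), 1e-5)
    expect_true(all(out1$prob >= 0 & out1$prob <= 1))
    expect_true(all(out1$pred %in% c(0L, 1L)))
  }
  # equal logits (zeroed head) break ties toward background
  model <- build_model(model_config("sunet", base_channels = 4), seed = 4)
  model$params[["head.W"]][] <- 0
  model$params[["head.b"]][] <- 0
  out <- forward_segment(model, lapply(1:3, function(m) matrix(runif(32 * 32), 32, 32)))
  expect_true(all(out$pred == 0L))
})

test_that("shape violations are rejected", {
  model <- build_model(model_config("ours", base_channels = 4), seed = 5)
  expect_error(forward_segment(model, lapply(1:2, function(m) matrix(0, 64, 64))),
               "expected 3")
  expect_error(forward_segment(model, lapply(1:3, function(m) matrix(0, 60, 60))),
               "divisible by 16")
})

test_that("a modality stack given as an M x H x W array is accepted", {
  model <- build_model(model_config("ours", base_channels = 4), seed = 6)
  arr <- array(runif(3 * 32 * 32), c(3, 32, 32))
  a <- forward_segment(model, arr)
  b <- forward_segment(model, lapply(1:3, function(m) arr[m, , ]))
  expect_identical(a$prob, b$prob)
})

test_that("analytic gradients match finite differences for all variants", {
  set.seed(31)
  H <- 32
  xs <- lapply(1:2, function(m) matrix(rnorm(H * H), H, H))
  gt <- matrix(0, H, H); gt[9:20, 10:24] <- 1
  ns <- asNamespace("sarcoseg")
  withr::local_options(sarcoseg.conv_precision = "double")
  for (variant in c("ours", "munet", "sunet")) {
    cfg <- model_config(variant, n_modalities = 2, base_channels = 4)
    model <- build_model(cfg, seed = 7)
    lossfn <- function(mod) {
      fw <- ns$model_forward(mod, xs, keep_cache = TRUE)
      sl <- ns$supervised_loss(fw$probs, gt, ce_weight = 0.3)
      list(loss = sl$loss, fw = fw, sl = sl)
    }
    r <- lossfn(model)
    genv <- ns$model_backward(model, r$fw, r$sl$dlogits)
    for (nm in sample(names(model$params), 8)) {
      p <- model$params[[nm]]
      i <- sample(length(p), 1)
      h <- 1e-5
      m2 <- model; m2$params[[nm]][i] <- p[i] + h
      m3 <- model; m3$params[[nm]][i] <- p[i] - h
      num <- (lossfn(m2)$loss - lossfn(m3)$loss) / (2 * h)
      ana <- genv[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-5, abs(num), abs(ana)), 1e-3)
    }
  }
})

test_that("residual variant gradients match finite differences under a
           smooth objective", {
  set.seed(32)
  H <- 32
  xs <- lapply(1:2, function(m) matrix(rnorm(H * H), H, H))
  ns <- asNamespace("sarcoseg")
  withr::local_options(sarcoseg.conv_precision = "double")
  cfg <- model_config("munet", n_modalities = 2, base_channels = 4,
                      residual_blocks = TRUE)
  model <- build_model(cfg, seed = 8)
  # smooth objective on down-scaled logits: the raw logits of a residual
  # stack are large enough to saturate the softmax, which would leave
  # finite differences without signal
  lossfn <- function(mod) {
    fw <- ns$model_forward(mod, xs, keep_cache = TRUE)
    list(loss = sum(sin(fw$logits / 50)) * 50, fw = fw)
  }
  r <- lossfn(model)
  genv <- ns$model_backward(model, r$fw, cos(r$fw$logits / 50))
  for (nm in sample(names(model$params), 8)) {
    p <- model$params[[nm]]
    i <- sample(length(p), 1)
    h <- 1e-5
    m2 <- model; m2$params[[nm]][i] <- p[i] + h
    m3 <- model; m3$params[[nm]][i] <- p[i] - h
    num <- (lossfn(m2)$loss - lossfn(m3)$loss) / (2 * h)
    ana <- genv[[nm]][i]
    expect_lt(abs(num - ana) / max(1e-5, abs(num), abs(ana)), 1e-3)
  }
})

test_that("the fast single-precision convolution path tracks the double
           path", {
  set.seed(33)
  model <- build_model(model_config("ours", base_channels = 4), seed = 10)
  xs <- lapply(1:3, function(m) matrix(runif(64 * 64), 64, 64))
  fast <- forward_segment(model, xs)
  slow <- withr::with_options(list(sarcoseg.conv_precision = "double"),
                              forward_segment(model, xs))
  expect_lt(max(abs(fast$prob - slow$prob)), 1e-3)
  expect_gt(mean(fast$pred == slow$pred), 0.999)
})

test_that("checkpoints round-trip models and fits", {
  model <- build_model(model_config("munet", base_channels = 4), seed = 9)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, model$params)
  saveRDS(list(1), f)
  expect_error(load_checkpoint(f), "not a sarcoseg checkpoint")
})
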