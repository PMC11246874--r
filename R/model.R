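#' Segmentation model configuration
#'
#' Describes one of the three architectures compared in the package:
#' \describe{
#'   \item{`"sunet"`}{single-encoder U-Net: the M modality slices are
#'     stacked as input channels of one encoder; skips are plain
#'     concatenation of that encoder's features.}
#'   \item{`"munet"`}{multi-encoder U-Net: one encoder per modality; the
#'     per-modality features are channel-concatenated at every skip level
#'     and at the bottleneck input.}
#'   \item{`"ours"`}{multi-encoder U-Net with attention-weighted fusion
#'     ([attention_fusion()]) applied to the concatenated features at every
#'     skip level and at the bottleneck input.}
#' }
#'
#' All variants share the backbone: 4 encoder layers of two 3x3
#' convolutions + 2x2 max pooling, channels doubling per layer from
#' `base_channels` (64 -> 512 at the default), a two-convolution bottleneck
#' at `16 * base_channels` channels, a decoder of 2x2 transposed
#' convolutions (halving channels) and two 3x3 convolutions per layer, and a
#' 1x1 convolution + per-pixel softmax head with `n_classes = 2`.
#'
#' @param variant `"ours"`, `"munet"` or `"sunet"`.
#' @param n_modalities number of input modalities M (default 3).
#' @param base_channels first-layer channel count (default 64; tests and
#'   small runs use 16).
#' @param n_classes output classes (default 2: background, tumor).
#' @param use_norm include a per-channel normalization layer after each
#'   convolution (default `TRUE`).
#' @param residual_blocks add identity shortcuts around each double-conv
#'   (1x1 projection where channel counts differ); default `FALSE`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(variant = c("ours", "munet", "sunet"),
                         n_modalities = 3L, base_channels = 64L,
                         n_classes = 2L, use_norm = TRUE,
                         residual_blocks = FALSE) {
  variant <- match.arg(variant)
  bc <- as.integer(base_channels)
  stopifnot(bc >= 1, n_modalities >= 1, n_classes >= 2)
  structure(list(variant = variant,
                 n_modalities = as.integer(n_modalities),
                 n_layers = 4L,
                 base_channels = bc,
                 channels = bc * c(1L, 2L, 4L, 8L),
                 bottleneck_channels = bc * 16L,
                 n_classes = as.integer(n_classes),
                 use_norm = isTRUE(use_norm),
                 residual_blocks = isTRUE(residual_blocks)),
            class = "model_config")
}

# encoder count and skip-channel schedule implied by a config
enc_count <- function(cfg) if (cfg$variant == "sunet") 1L else cfg$n_modalities
skip_channels <- function(cfg, l) {
  if (cfg$variant == "sunet") cfg$channels[l] else cfg$n_modalities * cfg$channels[l]
}

## ---- parameter construction ------------------------------------------------

init_block <- function(params, prefix, Cin, Cout, cfg) {
  params[[paste0(prefix, ".c1.W")]] <- kaiming(9 * Cin, Cout, 9 * Cin)
  params[[paste0(prefix, ".c1.b")]] <- numeric(Cout)
  params[[paste0(prefix, ".c2.W")]] <- kaiming(9 * Cout, Cout, 9 * Cout)
  params[[paste0(prefix, ".c2.b")]] <- numeric(Cout)
  if (cfg$use_norm) {
    for (k in c("n1", "n2")) {
      params[[paste0(prefix, ".", k, ".g")]] <- rep(1, Cout)
      params[[paste0(prefix, ".", k, ".b")]] <- numeric(Cout)
    }
  }
  if (cfg$residual_blocks && Cin != Cout) {
    params[[paste0(prefix, ".sc.W")]] <- kaiming(Cin, Cout, Cin)
    params[[paste0(prefix, ".sc.b")]] <- numeric(Cout)
  }
  params
}

init_fusion <- function(params, prefix, C) {
  h <- C %/% 2L
  params[[paste0(prefix, ".ca.W1")]] <- kaiming(h, C, C)
  params[[paste0(prefix, ".ca.W2")]] <- kaiming(C, h, h)
  params[[paste0(prefix, ".sa.ws")]] <- as.vector(kaiming(C, 1, C))
  params
}

#' Build a segmentation model
#'
#' Instantiates the parameters of a [model_config()] with Kaiming-uniform
#' convolution weights and zero biases, deterministically from `seed`.  The
#' parameter count is a pure function of the configuration.
#'
#' @param config a [model_config()].
#' @param seed integer seed fixing the initialization.
#' @return An object of class `sarcoseg_model`: list with `config`, `params`
#'   (named flat list of weight arrays) and `seed`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  cfg <- config
  p <- list()
  ne <- enc_count(cfg)
  in_ch <- if (cfg$variant == "sunet") cfg$n_modalities else 1L
  for (m in seq_len(ne)) {
    Cin <- in_ch
    for (l in 1:4) {
      p <- init_block(p, sprintf("enc%d.l%d", m, l), Cin, cfg$channels[l], cfg)
      Cin <- cfg$channels[l]
    }
  }
  if (cfg$variant == "ours") {
    for (l in 1:4)
      p <- init_fusion(p, sprintf("fuse.l%d", l), skip_channels(cfg, l))
    p <- init_fusion(p, "fuse.p", cfg$n_modalities * cfg$channels[4])
  }
  bn_in <- if (cfg$variant == "sunet") cfg$channels[4] else
    cfg$n_modalities * cfg$channels[4]
  p <- init_block(p, "bn", bn_in, cfg$bottleneck_channels, cfg)
  for (l in 4:1) {
    Cup <- if (l == 4) cfg$bottleneck_channels else cfg$channels[l + 1]
    Cl <- cfg$channels[l]
    p[[sprintf("dec.l%d.up.W", l)]] <- kaiming(Cup, 4 * Cl, Cup)
    p[[sprintf("dec.l%d.up.b", l)]] <- numeric(Cl)
    p <- init_block(p, sprintf("dec.l%d", l), Cl + skip_channels(cfg, l), Cl, cfg)
  }
  p[["head.W"]] <- kaiming(cfg$channels[1], cfg$n_classes, cfg$channels[1])
  p[["head.b"]] <- numeric(cfg$n_classes)
  structure(list(config = cfg, params = p, seed = as.integer(seed)),
            class = "sarcoseg_model")
}

#' Number of trainable parameters of a model
#' @param model a `sarcoseg_model`.
#' @return integer count.
#' @export
param_count <- function(model) {
  sum(vapply(model$params, length, 0L))
}

#' @export
print.sarcoseg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<sarcoseg_model> variant=%s  M=%d  base=%d  params=%s\n",
              cfg$variant, cfg$n_modalities, cfg$base_channels,
              format(param_count(x), big.mark = ",")))
  cat(sprintf("  channels %s | bottleneck %d | norm=%s residual=%s\n",
              paste(cfg$channels, collapse = "-"), cfg$bottleneck_channels,
              cfg$use_norm, cfg$residual_blocks))
  invisible(x)
}

## ---- forward / backward ----------------------------------------------------

block_fw <- function(p, prefix, x, cfg) {
  a1 <- conv3_fw(x, p[[paste0(prefix, ".c1.W")]], p[[paste0(prefix, ".c1.b")]])
  if (cfg$use_norm) {
    nc1 <- norm_fw(a1, p[[paste0(prefix, ".n1.g")]], p[[paste0(prefix, ".n1.b")]])
    h1 <- nc1$y
  } else { nc1 <- NULL; h1 <- a1 }
  r1 <- pmax(h1, 0)
  a2 <- conv3_fw(r1, p[[paste0(prefix, ".c2.W")]], p[[paste0(prefix, ".c2.b")]])
  if (cfg$use_norm) {
    nc2 <- norm_fw(a2, p[[paste0(prefix, ".n2.g")]], p[[paste0(prefix, ".n2.b")]])
    h2 <- nc2$y
  } else { nc2 <- NULL; h2 <- a2 }
  r2 <- pmax(h2, 0)
  out <- r2
  if (cfg$residual_blocks) {
    scW <- p[[paste0(prefix, ".sc.W")]]
    sc <- if (is.null(scW)) x else conv1_fw(x, scW, p[[paste0(prefix, ".sc.b")]])
    out <- out + sc
  }
  list(y = out, x = x, r1 = r1, r2 = r2, nc1 = nc1, nc2 = nc2)
}

block_bw <- function(p, prefix, cache, dout, cfg, genv) {
  acc <- function(nm, g) {
    cur <- genv[[nm]]
    genv[[nm]] <- if (is.null(cur)) g else cur + g
  }
  dr2 <- dout
  dx_res <- 0
  if (cfg$residual_blocks) {
    scW <- p[[paste0(prefix, ".sc.W")]]
    if (is.null(scW)) dx_res <- dout
    else {
      bsc <- conv1_bw(cache$x, dout, scW)
      acc(paste0(prefix, ".sc.W"), bsc$dW); acc(paste0(prefix, ".sc.b"), bsc$db)
      dx_res <- bsc$dx
    }
  }
  dh2 <- dr2 * (cache$r2 > 0)
  if (cfg$use_norm) {
    nb2 <- norm_bw(dh2, cache$nc2, p[[paste0(prefix, ".n2.g")]])
    acc(paste0(prefix, ".n2.g"), nb2$dg); acc(paste0(prefix, ".n2.b"), nb2$dbeta)
    da2 <- nb2$dx
  } else da2 <- dh2
  b2 <- conv3_bw(cache$r1, da2, p[[paste0(prefix, ".c2.W")]])
  acc(paste0(prefix, ".c2.W"), b2$dW); acc(paste0(prefix, ".c2.b"), b2$db)
  dh1 <- b2$dx * (cache$r1 > 0)
  if (cfg$use_norm) {
    nb1 <- norm_bw(dh1, cache$nc1, p[[paste0(prefix, ".n1.g")]])
    acc(paste0(prefix, ".n1.g"), nb1$dg); acc(paste0(prefix, ".n1.b"), nb1$dbeta)
    da1 <- nb1$dx
  } else da1 <- dh1
  b1 <- conv3_bw(cache$x, da1, p[[paste0(prefix, ".c1.W")]])
  acc(paste0(prefix, ".c1.W"), b1$dW); acc(paste0(prefix, ".c1.b"), b1$db)
  b1$dx + dx_res
}

fusion_params_of <- function(p, prefix) {
  list(ca = list(W1 = p[[paste0(prefix, ".ca.W1")]],
                 W2 = p[[paste0(prefix, ".ca.W2")]]),
       sa = list(ws = p[[paste0(prefix, ".sa.ws")]]))
}

# forward pass of one encoder path; x is (H, W, Cin)
encoder_fw <- function(p, cfg, m, x) {
  skips <- vector("list", 4); blocks <- vector("list", 4)
  pools <- vector("list", 4)
  t <- x
  for (l in 1:4) {
    bc <- block_fw(p, sprintf("enc%d.l%d", m, l), t, cfg)
    blocks[[l]] <- bc
    skips[[l]] <- bc$y
    pl <- pool_fw(bc$y)
    pools[[l]] <- list(idx = pl$idx, dims = dim(bc$y))
    t <- pl$y
  }
  list(skips = skips, pooled = t, blocks = blocks, pools = pools)
}

encoder_bw <- function(p, cfg, m, cache, dskips, dpooled, genv) {
  dt <- dpooled
  for (l in 4:1) {
    dm <- dim(cache$blocks[[l]]$y)
    dy <- pool_bw(dt, cache$pools[[l]]$idx, dm[1], dm[2], dm[3])
    if (!is.null(dskips[[l]])) dy <- dy + dskips[[l]]
    dt <- block_bw(p, sprintf("enc%d.l%d", m, l), cache$blocks[[l]], dy, cfg, genv)
  }
  dt
}

# Full forward pass.  xs: list of M matrices (H x W).  Returns logits,
# per-pixel class probabilities and (optionally) all caches for backward.
model_forward <- function(model, xs, keep_cache = FALSE) {
  cfg <- model$config; p <- model$params
  M <- cfg$n_modalities
  if (length(xs) != M)
    stop("model_forward: expected ", M, " modality slices, got ", length(xs))
  d <- dim(xs[[1]])
  for (x in xs) if (!identical(dim(x), d))
    stop("model_forward: modality slices differ in shape")
  if (any(d %% 16 != 0))
    stop("model_forward: spatial size must be divisible by 16, got ",
         paste(d, collapse = "x"))

  ne <- enc_count(cfg)
  enc_in <- if (cfg$variant == "sunet") {
    ar <- array(0, c(d[1], d[2], M))
    for (m in seq_len(M)) ar[, , m] <- xs[[m]]
    list(ar)
  } else lapply(xs, function(x) array(x, c(d[1], d[2], 1)))

  encs <- lapply(seq_len(ne), function(m) encoder_fw(p, cfg, m, enc_in[[m]]))

  # skip-level fusion
  fuse_cache <- vector("list", 4)
  fused <- vector("list", 4)
  for (l in 1:4) {
    feats <- lapply(encs, function(e) e$skips[[l]])
    if (cfg$variant == "ours") {
      xcat <- concat_channels(feats)
      fc <- fusion_fw(xcat, fusion_params_of(p, sprintf("fuse.l%d", l)))
      fused[[l]] <- fc$y
      fuse_cache[[l]] <- list(x = xcat, cache = fc)
    } else if (cfg$variant == "munet") {
      fused[[l]] <- concat_channels(feats)
    } else fused[[l]] <- feats[[1]]
  }

  # bottleneck input
  pooled <- lapply(encs, function(e) e$pooled)
  if (cfg$variant == "ours") {
    pcat <- concat_channels(pooled)
    fp <- fusion_fw(pcat, fusion_params_of(p, "fuse.p"))
    bn_in <- fp$y
    fuse_p_cache <- list(x = pcat, cache = fp)
  } else if (cfg$variant == "munet") {
    bn_in <- concat_channels(pooled)
    fuse_p_cache <- NULL
  } else { bn_in <- pooled[[1]]; fuse_p_cache <- NULL }

  bn <- block_fw(p, "bn", bn_in, cfg)

  # decoder
  y <- bn$y
  dec_cache <- vector("list", 4)
  for (l in 4:1) {
    upW <- p[[sprintf("dec.l%d.up.W", l)]]
    up <- tconv_fw(y, upW, p[[sprintf("dec.l%d.up.b", l)]])
    skip <- fused[[l]]
    dup <- dim(up)
    cat_ <- array(0, c(dup[1], dup[2], dup[3] + dim(skip)[3]))
    cat_[, , 1:dup[3]] <- up
    cat_[, , (dup[3] + 1):dim(cat_)[3]] <- skip
    bcache <- block_fw(p, sprintf("dec.l%d", l), cat_, cfg)
    dec_cache[[l]] <- list(x_up = y, up_ch = dup[3], block = bcache)
    y <- bcache$y
  }

  logits <- conv1_fw(y, p[["head.W"]], p[["head.b"]])
  probs <- softmax_channels(logits)

  out <- list(logits = logits, probs = probs)
  if (keep_cache)
    out$cache <- list(encs = encs, fuse = fuse_cache, fuse_p = fuse_p_cache,
                      bn = bn, bn_in = bn_in, dec = dec_cache,
                      head_in = y, enc_in = enc_in)
  out
}

softmax_channels <- function(logits) {
  d <- dim(logits)
  Z <- matrix(logits, d[1] * d[2])
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  array(E / rowSums(E), d)
}

# dL/dlogits from dL/dprobs through the per-pixel softmax
softmax_bw <- function(probs, dprobs) {
  d <- dim(probs)
  P <- matrix(probs, d[1] * d[2])
  dP <- matrix(dprobs, d[1] * d[2])
  array(P * (dP - rowSums(dP * P)), d)
}

# Backward pass; dlogits has the shape of the logits.  Returns an
# environment of accumulated gradients keyed like model$params.
model_backward <- function(model, fw, dlogits, genv = NULL,
                           extra_dpooled = NULL) {
  cfg <- model$config; p <- model$params
  cache <- fw$cache
  if (is.null(genv)) genv <- new.env(parent = emptyenv())
  acc <- function(nm, g) {
    cur <- genv[[nm]]
    genv[[nm]] <- if (is.null(cur)) g else cur + g
  }

  hb <- conv1_bw(cache$head_in, dlogits, p[["head.W"]])
  acc("head.W", hb$dW); acc("head.b", hb$db)
  dy <- hb$dx

  ne <- enc_count(cfg)
  dskips <- lapply(seq_len(ne), function(m) vector("list", 4))
  dfused <- vector("list", 4)

  for (l in 1:4) {
    dc <- cache$dec[[l]]
    dcat <- block_bw(p, sprintf("dec.l%d", l), dc$block, dy, cfg, genv)
    dup <- dcat[, , 1:dc$up_ch, drop = FALSE]
    dfused[[l]] <- dcat[, , (dc$up_ch + 1):dim(dcat)[3], drop = FALSE]
    Cl <- cfg$channels[l]
    tb <- tconv_bw(dc$x_up, dup, p[[sprintf("dec.l%d.up.W", l)]], Cl)
    acc(sprintf("dec.l%d.up.W", l), tb$dW); acc(sprintf("dec.l%d.up.b", l), tb$db)
    dy <- tb$dx
  }
  # dy is now the gradient at the bottleneck output
  dbn_in <- block_bw(p, "bn", cache$bn, dy, cfg, genv)

  # bottleneck-input fusion / concat back to per-encoder pooled gradients
  C4 <- cfg$channels[4]
  if (cfg$variant == "ours") {
    fpar <- fusion_params_of(p, "fuse.p")
    fb <- fusion_bw(cache$fuse_p$x, dbn_in, fpar, cache$fuse_p$cache)
    acc("fuse.p.ca.W1", fb$dW1); acc("fuse.p.ca.W2", fb$dW2)
    acc("fuse.p.sa.ws", fb$dws)
    dpool_cat <- fb$dx
    dpooled <- lapply(seq_len(ne), function(m)
      dpool_cat[, , ((m - 1) * C4 + 1):(m * C4), drop = FALSE])
  } else if (cfg$variant == "munet") {
    dpooled <- lapply(seq_len(ne), function(m)
      dbn_in[, , ((m - 1) * C4 + 1):(m * C4), drop = FALSE])
  } else dpooled <- list(dbn_in)
  if (!is.null(extra_dpooled))
    for (m in seq_len(ne))
      if (!is.null(extra_dpooled[[m]]))
        dpooled[[m]] <- dpooled[[m]] + extra_dpooled[[m]]

  # skip-level fusion backward
  for (l in 1:4) {
    Cl <- cfg$channels[l]
    if (cfg$variant == "ours") {
      fpar <- fusion_params_of(p, sprintf("fuse.l%d", l))
      fb <- fusion_bw(cache$fuse[[l]]$x, dfused[[l]], fpar, cache$fuse[[l]]$cache)
      acc(sprintf("fuse.l%d.ca.W1", l), fb$dW1)
      acc(sprintf("fuse.l%d.ca.W2", l), fb$dW2)
      acc(sprintf("fuse.l%d.sa.ws", l), fb$dws)
      dcat <- fb$dx
      for (m in seq_len(ne))
        dskips[[m]][[l]] <- dcat[, , ((m - 1) * Cl + 1):(m * Cl), drop = FALSE]
    } else if (cfg$variant == "munet") {
      for (m in seq_len(ne))
        dskips[[m]][[l]] <- dfused[[l]][, , ((m - 1) * Cl + 1):(m * Cl), drop = FALSE]
    } else dskips[[1]][[l]] <- dfused[[l]]
  }

  for (m in seq_len(ne))
    encoder_bw(p, cfg, m, cache$encs[[m]], dskips[[m]], dpooled[[m]], genv)

  genv
}

#' Run a model on one modality stack
#'
#' Deterministic inference: the M modality slices are pushed through the
#' network and the per-pixel class probabilities (softmax, summing to 1) and
#' the argmax binary prediction are returned.  Probability ties are broken
#' toward background.
#'
#' @param model a `sarcoseg_model` (or `sarcoseg_fit`).
#' @param stack list of M matrices, or a 3D array `M x H x W`.
#' @return list with `prob` (H x W x n_classes) and `pred` (H x W integer
#'   0/1 matrix, 1 = tumor).
#' @export
forward_segment <- function(model, stack) {
  if (inherits(model, "sarcoseg_fit")) model <- model$model
  stopifnot(inherits(model, "sarcoseg_model"))
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[1]), function(m) stack[m, , ])
  fw <- model_forward(model, stack, keep_cache = FALSE)
  fg <- fw$probs[, , 2]
  bg <- fw$probs[, , 1]
  list(prob = fw$probs, pred = matrix(as.integer(fg > bg), nrow(fg), ncol(fg)))
}

#' Save / load a model or fit checkpoint
#'
#' Checkpoints carry the weights, the [model_config()], the seed and any
#' training metadata, serialized with `saveRDS()`.
#' @param object a `sarcoseg_model` or `sarcoseg_fit`.
#' @param path file path.
#' @return `save_checkpoint`: `invisible(path)`; `load_checkpoint`: the object.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, c("sarcoseg_model", "sarcoseg_fit")))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, c("sarcoseg_model", "sarcoseg_fit")))
    stop("load_checkpoint: not a sarcoseg checkpoint: ", path)
  obj
}
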