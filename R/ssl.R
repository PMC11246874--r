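#' Mask-corrupt a slice at the tumor boundary
#'
#' The self-supervised pretext task hides a square patch of the image at the
#' tumor boundary: a patch centre is drawn uniformly from the boundary
#' pixels of the ground-truth mask (mask pixels 4-adjacent to a non-mask
#' pixel, with out-of-image treated as non-mask), the
#' `patch_size x patch_size` window is clamped to lie inside the slice, and
#' every pixel inside it is set to `fill_value`.  All other pixels are
#' untouched.  Uses the current RNG state, so it is deterministic under
#' `set.seed()`.
#'
#' @param slice 2D numeric array (the clean input I).
#' @param gt_mask binary 2D array of the same shape; must be nonempty.
#' @param patch_size side of the square patch (default 30).
#' @param fill_value intensity written inside the patch (default 0, the
#'   post-normalization background level).
#' @return list with `data` (corrupted slice I') and `corruption` (list with
#'   `patch_size`, `patch_top_left` — 0-based (row, col) — and `fill_value`).
#' @export
apply_boundary_mask <- function(slice, gt_mask, patch_size = 30L,
                                fill_value = 0) {
  d <- dim(slice)
  if (is.null(d) || length(d) != 2L) stop("apply_boundary_mask: 'slice' must be 2D")
  if (!identical(dim(gt_mask), d))
    stop("apply_boundary_mask: mask/slice shape mismatch")
  m <- gt_mask > 0
  if (!any(m)) stop("apply_boundary_mask: empty ground-truth mask (no tumor)")
  patch_size <- as.integer(patch_size)
  stopifnot(patch_size >= 1, patch_size <= min(d))

  bound <- mask_boundary(m)
  pix <- which(bound)
  ctr <- if (length(pix) == 1) pix else pix[sample.int(length(pix), 1)]
  r <- ((ctr - 1) %% d[1]) + 1
  c <- ((ctr - 1) %/% d[1]) + 1
  r0 <- min(max(r - patch_size %/% 2, 1), d[1] - patch_size + 1)
  c0 <- min(max(c - patch_size %/% 2, 1), d[2] - patch_size + 1)
  out <- slice
  out[r0:(r0 + patch_size - 1), c0:(c0 + patch_size - 1)] <- fill_value
  list(data = out,
       corruption = list(patch_size = patch_size,
                         patch_top_left = c(r0 - 1L, c0 - 1L),
                         fill_value = fill_value))
}

# logical matrix of mask pixels 4-adjacent to a non-mask pixel (image border
# counts as non-mask)
mask_boundary <- function(m) {
  d <- dim(m)
  pad <- matrix(FALSE, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- m
  nb <- pad[1:d[1], 2:(d[2] + 1)] & pad[3:(d[1] + 2), 2:(d[2] + 1)] &
        pad[2:(d[1] + 1), 1:d[2]] & pad[2:(d[1] + 1), 3:(d[2] + 2)]
  m & !nb
}

#' Cosine-similarity feature loss
#'
#' Measures agreement between the encoder features of the clean input
#' (`F`) and of its mask-corrupted version (`G`):
#' `cos = <F, G> / (||F||_2 ||G||_2)`.  The default mode returns
#' `1 - cos` (in \[0, 2\]), which is minimized when the two feature vectors
#' align — the pretraining objective of making the encoder robust to the
#' hidden patch.  `mode = "literal_cos"` returns the raw cosine instead.
#'
#' @param F_,G_ numeric vectors (or arrays, flattened) of equal length,
#'   both nonzero.
#' @param mode `"one_minus_cos"` (default) or `"literal_cos"`.
#' @return scalar loss.
#' @export
cosine_similarity_loss <- function(F_, G_, mode = c("one_minus_cos", "literal_cos")) {
  mode <- match.arg(mode)
  f <- as.vector(F_); g <- as.vector(G_)
  if (length(f) != length(g))
    stop("cosine_similarity_loss: length mismatch")
  nf <- sqrt(sum(f^2)); ng <- sqrt(sum(g^2))
  if (nf == 0 || ng == 0)
    stop("cosine_similarity_loss: zero-norm feature vector")
  cs <- sum(f * g) / (nf * ng)
  if (mode == "one_minus_cos") 1 - cs else cs
}

# gradients of (1 - cos) wrt F and G
cosine_loss_grad <- function(f, g) {
  nf <- sqrt(sum(f^2)); ng <- sqrt(sum(g^2))
  cs <- sum(f * g) / (nf * ng)
  list(dF = -(g / (nf * ng) - cs * f / nf^2),
       dG = -(f / (nf * ng) - cs * g / ng^2))
}

#' Soft Dice segmentation loss
#'
#' The negative soft Dice overlap between the predicted foreground
#' probabilities and the binary ground truth:
#' `L = -2 * sum(y_p * y_t) / (sum(y_p) + sum(y_t))`, a value in \[-1, 0\]
#' with -1 at perfect overlap.  A smoothing constant `eps` is added to
#' numerator and denominator (as `2*(I + eps) / (S + 2*eps)`) so the
#' empty-prediction/empty-truth case is defined and equals -1.
#'
#' @param y_p numeric array of foreground probabilities in \[0, 1\].
#' @param y_t binary array of the same shape.
#' @param eps smoothing constant (default 1e-5).
#' @return scalar loss in \[-1, 0\].
#' @export
dice_loss <- function(y_p, y_t, eps = 1e-5) {
  if (!identical(dim(y_p), dim(y_t)) &&
      !(is.null(dim(y_p)) && is.null(dim(y_t)) && length(y_p) == length(y_t)))
    stop("dice_loss: shape mismatch")
  if (any(y_p < -1e-9) || any(y_p > 1 + 1e-9))
    stop("dice_loss: probabilities must lie in [0, 1]")
  inter <- sum(y_p * y_t)
  -(2 * inter + 2 * eps) / (sum(y_p) + sum(y_t) + 2 * eps)
}

# gradient of dice_loss wrt y_p
dice_loss_grad <- function(y_p, y_t, eps = 1e-5) {
  num <- 2 * sum(y_p * y_t) + 2 * eps
  den <- sum(y_p) + sum(y_t) + 2 * eps
  -(2 * y_t * den - num) / den^2
}

#' Self-supervised pretraining of one modality encoder
#'
#' Trains a single-encoder U-Net on one modality with the twin-branch
#' masking pretext: per optimization step one slice is drawn, a boundary
#' patch is hidden with [apply_boundary_mask()], the clean slice runs
#' through the full network (features `F` = flattened deepest pooled
#' encoder activation, plus a segmentation prediction) and the corrupted
#' slice runs through the *same* encoder (weight sharing) to give features
#' `G`.  The step loss is
#' `cosine_similarity_loss(F, G) + dice_loss(prediction, gt)`, and both
#' branches backpropagate into the one shared parameter set; the masked
#' branch contributes no Dice term.
#'
#' @param slices list of 2D arrays (one modality's normalized slices).
#' @param masks list of matching binary ground-truth masks.
#' @param steps number of Adam steps (default 200).
#' @param lr learning rate (default 1e-5, the supervised protocol's value).
#' @param base_channels encoder width (default 64).
#' @param patch_size boundary mask patch side (default 30).
#' @param seed RNG seed (initialization, slice order, patch placement).
#' @param use_norm,residual_blocks backbone options, see [model_config()].
#' @return list with `encoder_weights` (named list keyed by layer, e.g.
#'   `l1.c1.W`), `model` (the trained single-encoder model), `history`
#'   (data.frame step, l_similarity, l_dice, l_total) and `config`.
#' @export
pretrain_encoder <- function(slices, masks, steps = 200L, lr = 1e-5,
                             base_channels = 64L, patch_size = 30L,
                             seed = 1L, use_norm = TRUE,
                             residual_blocks = FALSE) {
  stopifnot(length(slices) >= 1, length(slices) == length(masks))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  cfg <- model_config("sunet", n_modalities = 1L,
                      base_channels = base_channels, use_norm = use_norm,
                      residual_blocks = residual_blocks)
  model <- build_model(cfg, seed = sample.int(2^31 - 1, 1))
  state <- adam_state(model$params)
  hist <- data.frame(step = integer(steps), l_similarity = numeric(steps),
                     l_dice = numeric(steps), l_total = numeric(steps))

  for (s in seq_len(steps)) {
    i <- sample.int(length(slices), 1)
    x <- slices[[i]]; gt <- masks[[i]]
    corr <- apply_boundary_mask(x, gt, patch_size = patch_size)

    fw <- model_forward(model, list(x), keep_cache = TRUE)
    pooled_clean <- fw$cache$encs[[1]]$pooled
    enc_masked <- encoder_fw(model$params, cfg, 1L,
                             array(corr$data, c(dim(x), 1L)))
    fvec <- as.vector(pooled_clean)
    gvec <- as.vector(enc_masked$pooled)

    l_sim <- cosine_similarity_loss(fvec, gvec)
    yp <- fw$probs[, , 2]
    l_dice <- dice_loss(yp, gt)
    hist$step[s] <- s
    hist$l_similarity[s] <- l_sim
    hist$l_dice[s] <- l_dice
    hist$l_total[s] <- l_sim + l_dice

    # backward: dice through softmax head, cosine through both encoder passes
    dprobs <- array(0, dim(fw$probs))
    dprobs[, , 2] <- dice_loss_grad(yp, gt)
    dlogits <- softmax_bw(fw$probs, dprobs)
    cg <- cosine_loss_grad(fvec, gvec)
    genv <- model_backward(model, fw, dlogits,
                           extra_dpooled = list(array(cg$dF, dim(pooled_clean))))
    encoder_bw(model$params, cfg, 1L, enc_masked,
               dskips = vector("list", 4),
               dpooled = array(cg$dG, dim(enc_masked$pooled)), genv = genv)

    upd <- adam_step(model$params, as.list(genv), state, lr)
    model$params <- upd$params
    state <- upd$state
  }

  enc_names <- grep("^enc1\\.", names(model$params), value = TRUE)
  ew <- model$params[enc_names]
  names(ew) <- sub("^enc1\\.", "", names(ew))
  list(encoder_weights = ew, model = model, history = hist,
       config = list(steps = steps, lr = lr, base_channels = base_channels,
                     patch_size = patch_size, seed = seed))
}

#' Transfer pretrained encoder weights into a multi-encoder model
#'
#' Copies the encoder weights pretrained on modality m into encoder path m
#' of a multi-encoder model (decoder, fusion and bottleneck weights are
#' untouched), then verifies numerical equality of every transferred
#' tensor.  Shape mismatches (e.g. a different channel schedule) abort with
#' the offending layer named.
#'
#' @param pretrained list of `enc_count` encoder weight sets (the
#'   `encoder_weights` element of [pretrain_encoder()]), in modality order.
#' @param model a `sarcoseg_model` with matching encoder schedule.
#' @return The model with transferred weights.
#' @export
transfer_weights <- function(pretrained, model) {
  stopifnot(inherits(model, "sarcoseg_model"))
  ne <- enc_count(model$config)
  if (length(pretrained) != ne)
    stop("transfer_weights: need ", ne, " encoder weight sets, got ",
         length(pretrained))
  for (m in seq_len(ne)) {
    ew <- pretrained[[m]]
    for (nm in names(ew)) {
      tgt <- sprintf("enc%d.%s", m, nm)
      if (is.null(model$params[[tgt]]))
        stop("transfer_weights: model has no parameter '", tgt, "'")
      if (!identical(dim0(model$params[[tgt]]), dim0(ew[[nm]])))
        stop("transfer_weights: shape mismatch at '", tgt, "': model ",
             paste(dim0(model$params[[tgt]]), collapse = "x"), " vs pretrained ",
             paste(dim0(ew[[nm]]), collapse = "x"))
      model$params[[tgt]] <- ew[[nm]]
    }
    for (nm in names(ew))  # verification pass
      stopifnot(identical(model$params[[sprintf("enc%d.%s", m, nm)]], ew[[nm]]))
  }
  model
}

dim0 <- function(x) if (is.null(dim(x))) length(x) else dim(x)
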