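#' Supervised training configuration
#'
#' The training protocol: Adam at learning rate 1e-5, at most 100 epochs,
#' early stopping when the validation loss has not improved for 10 epochs,
#' batches of 4 slices, and an 80/20 patient-level train/test split.  The
#' validation set for early stopping is carved from the training patients
#' (`val_fraction`, default 10%).
#'
#' @param learning_rate Adam step size (default 1e-5).
#' @param max_epochs epoch budget (default 100).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (default 10; must be below `max_epochs`).
#' @param batch_size slices per gradient step (default 4).
#' @param split_fraction train fraction of the patient split (default 0.8).
#' @param val_fraction fraction of train patients held out for early
#'   stopping (default 0.1).
#' @param ce_weight weight of an optional per-pixel cross-entropy term
#'   added to the Dice loss (default 0 = pure Dice).
#' @param seed RNG seed (shuffling, validation carve-out).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, max_epochs = 100L,
                         early_stop_patience = 10L, batch_size = 4L,
                         split_fraction = 0.8, val_fraction = 0.1,
                         ce_weight = 0, seed = 1L) {
  stopifnot(learning_rate > 0, max_epochs >= 1,
            early_stop_patience >= 1, early_stop_patience < max_epochs,
            batch_size >= 1, split_fraction > 0, split_fraction < 1,
            val_fraction >= 0, val_fraction < 1, ce_weight >= 0)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 batch_size = as.integer(batch_size),
                 split_fraction = split_fraction,
                 val_fraction = val_fraction,
                 ce_weight = ce_weight, seed = as.integer(seed)),
            class = "train_config")
}

#' Patient-level train/test split
#'
#' Randomly assigns whole patients (all their slices together) to train or
#' test: `round(fraction * N)` patients train, the rest test.  Deterministic
#' given `seed`; the two manifests are disjoint and exhaustive.
#'
#' @param manifest a `dataset_manifest` (from [build_dataset()]).
#' @param fraction train fraction (default 0.8).
#' @param seed RNG seed.
#' @return list with `train` and `test` manifests (the `split` column set).
#' @export
patient_split <- function(manifest, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  ids <- unique(manifest$patient)
  if (length(ids) < 2)
    stop("patient_split: need at least 2 patients, have ", length(ids))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n_train <- round(fraction * length(ids))
  n_train <- min(max(n_train, 1), length(ids) - 1)
  train_ids <- sort(sample(ids, n_train))
  tr <- manifest[manifest$patient %in% train_ids, , drop = FALSE]
  te <- manifest[!(manifest$patient %in% train_ids), , drop = FALSE]
  tr$split <- "train"; te$split <- "test"
  a <- attributes(manifest)
  list(train = structure(tr, params = a$params, path = a$path,
                         class = class(manifest)),
       test = structure(te, params = a$params, path = a$path,
                        class = class(manifest)))
}

# Early-stopping rule on a validation-loss trace: the best epoch is the
# first strict minimum; training stops once `patience` epochs have passed
# without a new strict best.  Returns TRUE when the trace says "stop now".
early_stop_now <- function(val_losses, patience) {
  length(val_losses) - which.min(val_losses) >= patience
}

## ---- core optimization step ------------------------------------------------

# supervised loss on one sample; returns loss pieces and dlogits
supervised_loss <- function(probs, gt, ce_weight = 0) {
  yp <- probs[, , 2]
  l_dice <- dice_loss(yp, gt)
  dprobs <- array(0, dim(probs))
  dprobs[, , 2] <- dice_loss_grad(yp, gt)
  loss <- l_dice
  if (ce_weight > 0) {
    pt <- ifelse(gt > 0, probs[, , 2], probs[, , 1])
    pt <- pmax(pt, 1e-12)
    loss <- loss + ce_weight * mean(-log(pt))
    n <- length(gt)
    dprobs[, , 2] <- dprobs[, , 2] + ce_weight * ifelse(gt > 0, -1 / (pt * n), 0)
    dprobs[, , 1] <- dprobs[, , 1] + ce_weight * ifelse(gt > 0, 0, -1 / (pt * n))
  }
  list(loss = loss, dlogits = softmax_bw(probs, dprobs))
}

#' Train a model on in-memory slices for a fixed step budget
#'
#' The step-level workhorse behind [fit_segmenter()], also useful on its
#' own for small experiments: per Adam step a mini-batch of slices is drawn
#' (without replacement within an epoch-like pass), per-sample gradients of
#' the Dice loss (plus optional cross-entropy) are averaged, and the
#' parameters are updated.  Optionally stops early once the training Dice
#' overlap of the argmax prediction reaches `stop_dice`.
#'
#' @param model a `sarcoseg_model`.
#' @param stacks list; element i is a list of M modality matrices (slice i).
#' @param masks list of matching binary ground-truth masks.
#' @param steps Adam step budget.
#' @param learning_rate Adam step size.
#' @param batch_size slices per step.
#' @param ce_weight optional cross-entropy weight (default 0).
#' @param stop_dice if non-`NULL`, training stops as soon as the mean
#'   training Dice (checked every `check_every` steps) reaches this value.
#' @param check_every training-Dice check interval (default 10 steps).
#' @param seed RNG seed for batch order.
#' @return list with `model` (updated), `history` (data.frame step, loss),
#'   `train_dice` (last measured training Dice, `NA` if never measured) and
#'   `steps_run`.
#' @export
train_on_slices <- function(model, stacks, masks, steps = 100L,
                            learning_rate = 1e-3, batch_size = 4L,
                            ce_weight = 0, stop_dice = NULL,
                            check_every = 10L, seed = 1L) {
  stopifnot(inherits(model, "sarcoseg_model"),
            length(stacks) >= 1, length(stacks) == length(masks))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  state <- adam_state(model$params)
  n <- length(stacks)
  order_pool <- integer(0)
  hist <- data.frame(step = integer(0), loss = numeric(0))
  train_dice <- NA_real_
  steps_run <- 0L

  for (s in seq_len(steps)) {
    if (length(order_pool) < batch_size)
      order_pool <- c(order_pool, sample.int(n))
    batch <- order_pool[seq_len(min(batch_size, n))]
    order_pool <- order_pool[-seq_len(min(batch_size, n))]

    genv <- new.env(parent = emptyenv())
    loss <- 0
    for (i in batch) {
      fw <- model_forward(model, stacks[[i]], keep_cache = TRUE)
      sl <- supervised_loss(fw$probs, masks[[i]], ce_weight)
      loss <- loss + sl$loss
      model_backward(model, fw, sl$dlogits / length(batch), genv = genv)
    }
    loss <- loss / length(batch)
    upd <- adam_step(model$params, as.list(genv), state, learning_rate)
    model$params <- upd$params
    state <- upd$state
    hist <- rbind(hist, data.frame(step = s, loss = loss))
    steps_run <- s

    # the full-set Dice measurement costs several forwards; only run it
    # once the soft Dice loss says the target is plausibly reached
    near <- mean(tail(hist$loss, 3)) <= -(stop_dice - 0.03)
    if (!is.null(stop_dice) && s %% check_every == 0 && (near || s == steps)) {
      train_dice <- mean(vapply(seq_len(n), function(i) {
        pr <- forward_segment(model, stacks[[i]])
        d <- dice_score(confusion_counts(pr$pred, masks[[i]]))
        if (is.na(d)) 0 else d
      }, 0))
      if (train_dice >= stop_dice) break
    }
  }
  list(model = model, history = hist, train_dice = train_dice,
       steps_run = steps_run)
}

## ---- manifest-driven slice loading -----------------------------------------

# Load every slice of a manifest into memory as (stacks, masks) lists.
# Stack NIfTIs are read once each via an environment cache.
load_manifest_slices <- function(manifest) {
  cache <- new.env(parent = emptyenv())
  stacks <- vector("list", nrow(manifest))
  masks <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    sl <- load_slice(manifest[i, ], cache)
    stacks[[i]] <- sl$modalities
    masks[[i]] <- sl$mask
  }
  list(stacks = stacks, masks = masks)
}

#' Fit a segmentation model with the full supervised protocol
#'
#' Epoch-based training with Adam, patient-level validation carve-out and
#' early stopping: per epoch every training slice is visited once in random
#' order in batches of `config$batch_size`; after each epoch the mean Dice
#' loss on the validation slices is computed, and training stops at
#' `max_epochs` or when validation loss has not improved for
#' `early_stop_patience` consecutive epochs.  The returned fit carries the
#' weights of the best-validation epoch.
#'
#' @param model a `sarcoseg_model` (fresh or with pretrained encoders).
#' @param manifest training `dataset_manifest` (e.g. the `train` half of
#'   [patient_split()]).
#' @param config a [train_config()].
#' @return An object of class `sarcoseg_fit`: list with `model` (best
#'   weights), `config`, `history` (per-epoch train/val loss), `best_epoch`,
#'   `val_patients` and run metadata.
#' @export
fit_segmenter <- function(model, manifest, config = train_config()) {
  stopifnot(inherits(model, "sarcoseg_model"), inherits(config, "train_config"))
  if (nrow(manifest) == 0) stop("fit_segmenter: empty training manifest")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  ids <- unique(manifest$patient)
  if (length(ids) >= 2 && config$val_fraction > 0) {
    n_val <- max(1, round(config$val_fraction * length(ids)))
    n_val <- min(n_val, length(ids) - 1)
    val_ids <- sort(sample(ids, n_val))
  } else val_ids <- character(0)
  val_rows <- manifest$patient %in% val_ids
  tr <- load_manifest_slices(manifest[!val_rows, , drop = FALSE])
  va <- if (any(val_rows)) load_manifest_slices(manifest[val_rows, , drop = FALSE])
        else NULL

  state <- adam_state(model$params)
  n <- length(tr$stacks)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  best <- list(loss = Inf, params = model$params, epoch = 0L)

  for (ep in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (lo in seq(1, n, by = config$batch_size)) {
      batch <- ord[lo:min(lo + config$batch_size - 1, n)]
      genv <- new.env(parent = emptyenv())
      bl <- 0
      for (i in batch) {
        fw <- model_forward(model, tr$stacks[[i]], keep_cache = TRUE)
        sl <- supervised_loss(fw$probs, tr$masks[[i]], config$ce_weight)
        bl <- bl + sl$loss
        model_backward(model, fw, sl$dlogits / length(batch), genv = genv)
      }
      upd <- adam_step(model$params, as.list(genv), state, config$learning_rate)
      model$params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + bl / length(batch); nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb

    val_loss <- if (!is.null(va)) {
      mean(vapply(seq_along(va$stacks), function(i) {
        fw <- model_forward(model, va$stacks[[i]], keep_cache = FALSE)
        dice_loss(fw$probs[, , 2], va$masks[[i]])
      }, 0))
    } else ep_loss
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_loss = val_loss))

    if (val_loss < best$loss)
      best <- list(loss = val_loss, params = model$params, epoch = ep)
    if (early_stop_now(hist$val_loss, config$early_stop_patience)) break
  }

  model$params <- best$params
  structure(list(model = model, config = config, history = hist,
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 val_patients = val_ids,
                 meta = list(fitted_at = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                             package_version = as.character(utils::packageVersion("sarcoseg")),
                             n_train_slices = n,
                             n_val_slices = if (is.null(va)) 0L else length(va$stacks))),
            class = "sarcoseg_fit")
}

#' @export
print.sarcoseg_fit <- function(x, ...) {
  cat(sprintf("<sarcoseg_fit> %s model, %d epochs run (best epoch %d, val loss %.4f)\n",
              x$model$config$variant, nrow(x$history), x$best_epoch,
              x$best_val_loss))
  invisible(x)
}

#' @export
summary.sarcoseg_fit <- function(object, ...) {
  cat("Segmentation fit\n")
  print(object$model)
  cat(sprintf("  epochs run     : %d / %d (early stop patience %d)\n",
              nrow(object$history), object$config$max_epochs,
              object$config$early_stop_patience))
  cat(sprintf("  best epoch     : %d (validation Dice loss %.4f)\n",
              object$best_epoch, object$best_val_loss))
  cat(sprintf("  train slices   : %d  validation slices: %d\n",
              object$meta$n_train_slices, object$meta$n_val_slices))
  if (length(object$val_patients))
    cat("  val patients   : ", paste(object$val_patients, collapse = ", "), "\n")
  invisible(object)
}

#' Predict segmentations for manifest rows
#'
#' @param object a `sarcoseg_fit`.
#' @param newdata a `dataset_manifest` (rows to segment).
#' @param ... unused.
#' @return list of per-row results from [forward_segment()].
#' @export
predict.sarcoseg_fit <- function(object, newdata, ...) {
  sl <- load_manifest_slices(newdata)
  lapply(sl$stacks, function(s) forward_segment(object$model, s))
}

#' @export
plot.sarcoseg_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", lwd = 2,
                 xlab = "epoch", ylab = "Dice loss",
                 ylim = range(c(h$train_loss, h$val_loss)), ...)
  graphics::lines(h$epoch, h$val_loss, lwd = 2, lty = 2, col = 2)
  graphics::abline(v = x$best_epoch, lty = 3, col = "grey40")
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   col = 1:2, lwd = 2, bty = "n")
  invisible(x)
}

#' Evaluate models on a test manifest
#'
#' For every test slice and every model, the argmax segmentation is scored
#' with accuracy, Dice, sensitivity, specificity and the 95th-percentile
#' Hausdorff distance against the rectangle ground truth, and metrics are
#' averaged over slices (undefined values excluded and counted).  A
#' per-patient breakdown is included.
#'
#' @param models named list of `sarcoseg_model` / `sarcoseg_fit` objects
#'   (e.g. `list(SUNet = ..., MUNet = ..., Ours = ...)`).
#' @param manifest test `dataset_manifest`.
#' @param pixel_spacing in-plane pixel size in mm for the Hausdorff column
#'   (default `c(1, 1)`, the resampled grid).
#' @return An object of class `metrics_report`: list with `table` (one row
#'   per model: Model, Acc, Dice, Sensitivity, Specificity, Hausdorff95),
#'   `per_patient`, `undefined_counts` and `aggregation`.
#' @export
evaluate_models <- function(models, manifest, pixel_spacing = c(1, 1)) {
  stopifnot(length(models) >= 1, !is.null(names(models)),
            nrow(manifest) >= 1)
  sl <- load_manifest_slices(manifest)
  rows <- list(); per_pat <- list(); undef <- list()
  for (nm in names(models)) {
    mod <- models[[nm]]
    if (inherits(mod, "sarcoseg_fit")) mod <- mod$model
    vals <- data.frame(patient = manifest$patient,
                       Acc = NA_real_, Dice = NA_real_,
                       Sensitivity = NA_real_, Specificity = NA_real_,
                       Hausdorff95 = NA_real_)
    for (i in seq_len(nrow(manifest))) {
      pred <- forward_segment(mod, sl$stacks[[i]])$pred
      cc <- confusion_counts(pred, sl$masks[[i]])
      vals$Acc[i] <- accuracy(cc)
      vals$Dice[i] <- dice_score(cc)
      vals$Sensitivity[i] <- sensitivity(cc)
      vals$Specificity[i] <- specificity(cc)
      vals$Hausdorff95[i] <- hausdorff_distance(pred, sl$masks[[i]],
                                                percentile = 95,
                                                pixel_spacing = pixel_spacing)
    }
    mcols <- c("Acc", "Dice", "Sensitivity", "Specificity", "Hausdorff95")
    rows[[nm]] <- data.frame(Model = nm,
                             t(colMeans(vals[mcols], na.rm = TRUE)))
    undef[[nm]] <- colSums(is.na(vals[mcols]))
    agg <- stats::aggregate(vals[mcols], by = list(patient = vals$patient),
                            FUN = function(v) mean(v, na.rm = TRUE))
    agg$Model <- nm
    per_pat[[nm]] <- agg
  }
  structure(list(table = do.call(rbind, rows),
                 per_patient = do.call(rbind, per_pat),
                 undefined_counts = do.call(rbind, undef),
                 aggregation = "mean over test slices (undefined excluded); Hausdorff95 in mm"),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation results\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) sprintf("%.4f", v))
  print(tab, row.names = FALSE)
  cat("Aggregation:", x$aggregation, "\n")
  nd <- rowSums(x$undefined_counts)
  if (any(nd > 0))
    cat("Undefined slice metrics excluded:",
        paste(sprintf("%s=%d", names(nd), nd), collapse = ", "), "\n")
  invisible(x)
}
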