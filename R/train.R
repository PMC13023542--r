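# Losses, optimization, PSG pre-training, PSG->radar fine-tuning with
# partial layer freezing, stratified folds, and event-F1 model selection.

#' Loss configuration
#'
#' Combined segmentation loss `alpha * Dice + (1 - alpha) * weighted BCE`
#' with `alpha = 0.8`, positive-class weight 2.0 and negative weight 1.0;
#' Dice smoothing `epsilon = 1e-6`, BCE probability clipping `delta = 1e-7`.
#'
#' @param alpha_mix Convex mixing weight of the Dice term, in `[0, 1]`.
#' @param w_pos,w_neg Positive/negative BCE class weights (> 0).
#' @param epsilon Dice smoothing constant.
#' @param delta BCE probability clipping bound.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha_mix = 0.8, w_pos = 2.0, w_neg = 1.0,
                        epsilon = 1e-6, delta = 1e-7) {
  stopifnot(alpha_mix >= 0, alpha_mix <= 1, w_pos > 0, w_neg > 0,
            epsilon >= 0, delta > 0)
  structure(list(alpha_mix = alpha_mix, w_pos = w_pos, w_neg = w_neg,
                 epsilon = epsilon, delta = delta), class = "loss_config")
}

#' Training configuration
#'
#' Adam with gradient-norm clipping; defaults follow the two training
#' stages: learning rate `1e-4` for pre-training and `5e-5` for
#' fine-tuning, batch size 96, early stopping patience 3 with best weights
#' restored, and learning-rate reduction on validation-loss plateaus
#' (factor 0.5, patience 2, floor `1e-6`). `freeze_ratio` is the fraction
#' of earliest layers frozen during fine-tuning (0.6 default; 0 = scratch).
#'
#' @param lr Learning rate.
#' @param clipnorm Global gradient-norm clip.
#' @param batch_size Windows per optimization step.
#' @param max_epochs Epoch budget.
#' @param freeze_ratio Fraction of earliest layers frozen, in `[0, 1)`.
#' @param bn_freeze Freeze batch-norm layers (parameters and running
#'   statistics) during fine-tuning.
#' @param early_stop_patience Epochs without improvement before stopping.
#' @param lr_factor,lr_patience,lr_min Plateau scheduler settings.
#' @param select_metric `"event_f1"` (default) or `"val_loss"` for
#'   checkpoint selection.
#' @param seed Seed for shuffling, dropout and initialization.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, clipnorm = 1.0, batch_size = 96L,
                         max_epochs = 80L, freeze_ratio = 0,
                         bn_freeze = FALSE, early_stop_patience = 3L,
                         lr_factor = 0.5, lr_patience = 2L, lr_min = 1e-6,
                         select_metric = c("event_f1", "val_loss"),
                         seed = 1L) {
  select_metric <- match.arg(select_metric)
  stopifnot(lr > 0, clipnorm > 0, batch_size >= 1, max_epochs >= 1,
            freeze_ratio >= 0, freeze_ratio < 1)
  structure(list(lr = lr, clipnorm = clipnorm,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 freeze_ratio = freeze_ratio, bn_freeze = bn_freeze,
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 lr_min = lr_min, select_metric = select_metric,
                 seed = as.integer(seed)), class = "train_config")
}

# ---- losses ---------------------------------------------------------------

#' Dice loss
#'
#' `1 - (2 * sum(y * yhat) + eps) / (sum(y) + sum(yhat) + eps)`, computed
#' over the whole tensor. Zero for a perfect binary overlap and for the
#' all-empty case (epsilon rescue).
#'
#' @param y Ground-truth 0/1 tensor.
#' @param yhat Predicted probabilities in `[0, 1]`, same shape.
#' @param epsilon Smoothing constant.
#' @return Scalar loss in `[0, 1)`.
#' @export
dice_loss <- function(y, yhat, epsilon = 1e-6) {
  if (length(y) != length(yhat)) stop("shape mismatch")
  num <- 2 * sum(y * yhat) + epsilon
  den <- sum(y) + sum(yhat) + epsilon
  1 - num / den
}

dice_loss_grad <- function(y, yhat, epsilon = 1e-6) {
  num <- 2 * sum(y * yhat) + epsilon
  den <- sum(y) + sum(yhat) + epsilon
  -(2 * y * den - num) / den^2
}

#' Weighted binary cross-entropy
#'
#' `-mean(w_pos * y * log(yhat) + w_neg * (1 - y) * log(1 - yhat))` with
#' probabilities clipped to `(delta, 1 - delta)`.
#'
#' @param y 0/1 tensor.
#' @param yhat Probabilities, same shape.
#' @param w_pos,w_neg Class weights.
#' @param delta Clipping bound.
#' @return Scalar loss.
#' @export
weighted_bce <- function(y, yhat, w_pos = 2.0, w_neg = 1.0, delta = 1e-7) {
  if (length(y) != length(yhat)) stop("shape mismatch")
  p <- clip(yhat, delta, 1 - delta)
  -mean(w_pos * y * log(p) + w_neg * (1 - y) * log(1 - p))
}

weighted_bce_grad <- function(y, yhat, w_pos = 2.0, w_neg = 1.0,
                              delta = 1e-7) {
  p <- clip(yhat, delta, 1 - delta)
  -(w_pos * y / p - w_neg * (1 - y) / (1 - p)) / length(y)
}

#' Combined segmentation loss
#'
#' Convex combination `alpha * Dice + (1 - alpha) * weighted BCE`.
#'
#' @param y,yhat Tensors as in [dice_loss()].
#' @param cfg A [loss_config()].
#' @return Scalar loss.
#' @export
combined_loss <- function(y, yhat, cfg = loss_config()) {
  cfg$alpha_mix * dice_loss(y, yhat, cfg$epsilon) +
    (1 - cfg$alpha_mix) * weighted_bce(y, yhat, cfg$w_pos, cfg$w_neg,
                                       cfg$delta)
}

combined_loss_grad <- function(y, yhat, cfg = loss_config()) {
  cfg$alpha_mix * dice_loss_grad(y, yhat, cfg$epsilon) +
    (1 - cfg$alpha_mix) * weighted_bce_grad(y, yhat, cfg$w_pos, cfg$w_neg,
                                            cfg$delta)
}

# ---- freezing -------------------------------------------------------------

#' Freeze the first fraction of layers (and optionally all batch norms)
#'
#' The ordered layer list is the block definition order: encoder stages,
#' bottleneck (ASPP, transformer blocks), decoder stages, smoothing conv,
#' head. The first `floor(rho * L)` blocks become non-trainable. With
#' `bn_freeze`, every batch-normalization layer in the model additionally
#' becomes non-trainable and uses its stored running statistics during
#' training.
#'
#' @param model A `segnet`.
#' @param rho Freezing ratio in `[0, 1)`; 0 freezes nothing (scratch mode).
#' @param bn_freeze Freeze all batch-norm layers.
#' @return The model, invisibly (modified in place).
#' @export
freeze_layers <- function(model, rho = 0.6, bn_freeze = TRUE) {
  if (rho >= 1) stop("rho must be < 1: freezing everything leaves nothing to train")
  if (rho < 0) stop("rho must be >= 0")
  block_names <- names(model$blocks)
  n_freeze <- floor(rho * length(block_names))
  for (i in seq_along(block_names)) {
    for (ly in model$blocks[[i]]$sub) {
      if (i <= n_freeze) {
        ly$trainable <- FALSE
        if (ly$kind == "bn") ly$frozen_stats <- TRUE
      }
      if (bn_freeze && ly$kind == "bn") {
        ly$trainable <- FALSE
        ly$frozen_stats <- TRUE
      }
    }
  }
  attr(model, "n_frozen_blocks") <- n_freeze
  invisible(model)
}

#' Number of ordered freezable layers (blocks) in a model
#' @param model A `segnet`.
#' @return Integer count.
#' @export
n_layers <- function(model) length(model$blocks)

# ---- Adam -----------------------------------------------------------------

adam_new <- function(lr, clipnorm, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$clipnorm <- clipnorm
  e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$t <- 0L
  e$m <- list(); e$v <- list()
  e
}

adam_step <- function(opt, model) {
  envs <- layer_envs(model)
  # global gradient norm over trainable params
  gn2 <- 0
  for (ly in envs) {
    if (!ly$trainable) next
    for (pn in names(ly$grads)) gn2 <- gn2 + sum(ly$grads[[pn]]^2)
  }
  gn <- sqrt(gn2)
  scale <- if (gn > opt$clipnorm) opt$clipnorm / gn else 1
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (ly in envs) {
    if (!ly$trainable) next
    for (pn in names(ly$params)) {
      key <- paste0(ly$name, "/", pn)
      g <- ly$grads[[pn]] * scale
      if (is.null(opt$m[[key]])) {
        opt$m[[key]] <- g * 0
        opt$v[[key]] <- g * 0
      }
      opt$m[[key]] <- opt$beta1 * opt$m[[key]] + (1 - opt$beta1) * g
      opt$v[[key]] <- opt$beta2 * opt$v[[key]] + (1 - opt$beta2) * g^2
      ly$params[[pn]] <- ly$params[[pn]] -
        opt$lr * (opt$m[[key]] / bc1) / (sqrt(opt$v[[key]] / bc2) + opt$eps)
    }
  }
  invisible(gn)
}

# ---- validation callback --------------------------------------------------

#' Event-level F1 on validation nights (sliding-window fusion)
#'
#' Runs inference on every validation night, fuses overlapping window
#' predictions, applies temporal post-processing, matches events against
#' the ground truth and pools TP/FP/FN over nights (pooled-count F1, not a
#' mean of per-night F1 values).
#'
#' @param model A `segnet`.
#' @param val_nights List of validation nights, each a list with `windows`
#'   (a `window_set`) and `truth_events` (`event_intervals` at 10 Hz).
#' @param postproc_cfg A [postproc_config()].
#' @param fs Sampling rate (Hz).
#' @return List with pooled `f1`, `precision`, `recall`, counts, and
#'   per-night evaluation records.
#' @export
event_f1_callback <- function(model, val_nights, postproc_cfg = postproc_config(),
                              fs = 10) {
  if (length(val_nights) == 0L) stop("no validation nights")
  evals <- lapply(val_nights, function(nt) {
    probs <- segnet_predict(model, nt$windows$X)
    evaluate_night(probs, nt$windows$starts, nt$windows$L,
                   nt$truth_events, postproc_cfg, fs)
  })
  tp <- sum(vapply(evals, `[[`, numeric(1), "tp"))
  fp <- sum(vapply(evals, `[[`, numeric(1), "fp"))
  fn <- sum(vapply(evals, `[[`, numeric(1), "fn"))
  prf <- precision_recall_f1(tp, fp, fn)
  c(prf, list(tp = tp, fp = fp, fn = fn, per_night = evals))
}

# ---- training loop --------------------------------------------------------

batch_loss_and_grads <- function(model, Xb, yb, loss_cfg) {
  fwd <- segnet_forward(model, Xb, training = TRUE)
  p <- fwd$p
  loss <- combined_loss(yb, p, loss_cfg)
  dp <- combined_loss_grad(yb, p, loss_cfg)
  dim(dp) <- dim(p)
  pc <- clip(p, loss_cfg$delta, 1 - loss_cfg$delta)
  zero_grads(model)
  segnet_backward(model, fwd, dp, p_clip = pc)
  loss
}

#' Fit a segmentation model with event-F1 model selection
#'
#' Mini-batch Adam with gradient clipping; after every epoch the validation
#' event-level F1 (sliding-window fusion + post-processing) and validation
#' loss are computed. The best checkpoint by the selection metric is
#' retained and restored at the end. Early stopping (patience on the
#' selection metric) and plateau learning-rate decay on validation loss are
#' applied.
#'
#' @param model A `segnet` (freezing already applied if desired).
#' @param X,y Training windows `N x T x 2` and labels `N x T`.
#' @param val_nights Validation nights for [event_f1_callback()].
#' @param cfg A [train_config()].
#' @param loss_cfg A [loss_config()].
#' @param postproc_cfg A [postproc_config()].
#' @return A checkpoint: list with `weights`, `model_cfg`, `history`
#'   (per-epoch data.frame), `best_epoch`, `best_val_f1`, `best_val_loss`.
#' @export
fit_segnet <- function(model, X, y, val_nights, cfg = train_config(),
                       loss_cfg = loss_config(),
                       postproc_cfg = postproc_config()) {
  N <- dim(X)[1L]
  if (N == 0L) stop("empty training set")
  opt <- adam_new(cfg$lr, cfg$clipnorm)
  history <- NULL
  best_metric <- -Inf
  best_weights <- NULL
  best_epoch <- 0L
  best_f1 <- NA_real_; best_vloss <- NA_real_
  stall <- 0L; lr_stall <- 0L
  best_vloss_seen <- Inf
  withr::with_seed(derive_seed(cfg$seed, "fit"), {
    for (epoch in seq_len(cfg$max_epochs)) {
      idx <- sample.int(N)
      ep_loss <- 0; nb <- 0L
      for (s in seq(1L, N, by = cfg$batch_size)) {
        bi <- idx[s:min(s + cfg$batch_size - 1L, N)]
        Xb <- X[bi, , , drop = FALSE]
        yb <- y[bi, , drop = FALSE]
        ep_loss <- ep_loss + batch_loss_and_grads(model, Xb, yb, loss_cfg)
        adam_step(opt, model)
        nb <- nb + 1L
      }
      ep_loss <- ep_loss / nb
      cb <- event_f1_callback(model, val_nights, postproc_cfg)
      vloss <- validation_loss(model, val_nights, loss_cfg)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = ep_loss, val_loss = vloss,
        val_event_f1 = cb$f1, lr = opt$lr))
      log_msg("epoch %d: loss %.4f val_loss %.4f val_event_f1 %.4f lr %.2g",
              epoch, ep_loss, vloss, cb$f1, opt$lr)
      metric <- if (cfg$select_metric == "event_f1") cb$f1 else -vloss
      if (metric > best_metric + 1e-12) {
        best_metric <- metric
        best_weights <- get_weights(model)
        best_epoch <- epoch
        best_f1 <- cb$f1
        best_vloss <- vloss
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      # plateau scheduler on validation loss
      if (vloss < best_vloss_seen - 1e-12) {
        best_vloss_seen <- vloss
        lr_stall <- 0L
      } else {
        lr_stall <- lr_stall + 1L
        if (lr_stall >= cfg$lr_patience) {
          opt$lr <- max(opt$lr * cfg$lr_factor, cfg$lr_min)
          lr_stall <- 0L
        }
      }
      if (stall >= cfg$early_stop_patience) break
    }
  })
  if (!is.null(best_weights)) set_weights(model, best_weights)
  list(weights = get_weights(model), model_cfg = model$cfg,
       history = history, best_epoch = best_epoch,
       best_val_f1 = best_f1, best_val_loss = best_vloss)
}

validation_loss <- function(model, val_nights, loss_cfg) {
  tot <- 0; n <- 0L
  for (nt in val_nights) {
    p <- segnet_predict(model, nt$windows$X)
    tot <- tot + combined_loss(nt$windows$y, p, loss_cfg) * nrow(p)
    n <- n + nrow(p)
  }
  tot / n
}

#' Pre-train a model on source-domain (PSG-like) windows
#'
#' Builds a fresh seeded model and fits it; the returned checkpoint bundles
#' the weights with the serialized model configuration so a student model
#' can later be reconstructed identically before weight loading.
#'
#' @param model_cfg A [model_config()].
#' @param X,y Training windows and labels.
#' @param val_nights Validation nights (disjoint from training nights).
#' @param cfg A [train_config()] (learning rate `1e-4` by convention).
#' @param loss_cfg,postproc_cfg Loss / post-processing settings.
#' @return A checkpoint (see [fit_segnet()]).
#' @export
pretrain <- function(model_cfg, X, y, val_nights, cfg = train_config(),
                     loss_cfg = loss_config(),
                     postproc_cfg = postproc_config()) {
  model <- build_model(model_cfg, seed = cfg$seed)
  fit_segnet(model, X, y, val_nights, cfg, loss_cfg, postproc_cfg)
}

#' Fine-tune a pre-trained checkpoint on target-domain (radar) windows
#'
#' Reconstructs the identical architecture from the checkpoint's serialized
#' configuration (a mismatch with `expected_cfg` is a hard error), loads
#' the teacher weights, applies partial layer freezing and batch-norm
#' freezing, and optimizes at the fine-tuning learning rate.
#'
#' @param teacher_ckpt Checkpoint from [pretrain()] / [fit_segnet()].
#' @param X,y Target-domain windows and labels.
#' @param val_nights Validation nights.
#' @param cfg A [train_config()]; `freeze_ratio` and `bn_freeze` control
#'   the transfer regime (`lr = 5e-5` by convention).
#' @param expected_cfg Optional `model_config` the teacher must match.
#' @param loss_cfg,postproc_cfg Loss / post-processing settings.
#' @return A checkpoint.
#' @export
finetune <- function(teacher_ckpt, X, y, val_nights,
                     cfg = train_config(lr = 5e-5, freeze_ratio = 0.6,
                                        bn_freeze = TRUE),
                     expected_cfg = NULL, loss_cfg = loss_config(),
                     postproc_cfg = postproc_config()) {
  if (!is.null(expected_cfg) &&
      !identical(unclass(teacher_ckpt$model_cfg), unclass(expected_cfg))) {
    stop("teacher configuration does not match the expected model ",
         "configuration: refusing silent mismatch")
  }
  model <- build_model(teacher_ckpt$model_cfg, seed = cfg$seed)
  set_weights(model, teacher_ckpt$weights)
  freeze_layers(model, rho = cfg$freeze_ratio, bn_freeze = cfg$bn_freeze)
  fit_segnet(model, X, y, val_nights, cfg, loss_cfg, postproc_cfg)
}

#' Save / load a checkpoint
#'
#' The checkpoint bundles weights and the model configuration; loading
#' rebuilds the identical graph before assigning weights and fails loudly
#' on mismatch.
#'
#' @param ckpt A checkpoint list.
#' @param path File path.
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: a
#'   list with the rebuilt `model` and the checkpoint fields.
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  model <- build_model(ckpt$model_cfg, seed = 1L)
  set_weights(model, ckpt$weights)
  ckpt$model <- model
  ckpt
}

# ---- cross-validation folds -----------------------------------------------

#' Severity-stratified K-fold assignment of nights
#'
#' Shuffles nights within each severity class (seeded) and deals them
#' round-robin to folds, so per-class counts differ by at most one across
#' folds. Deterministic given the seed.
#'
#' @param night_ids Character vector of night identifiers.
#' @param severities Integer severity class (0-3) per night.
#' @param K Number of folds.
#' @param seed Seed.
#' @return A data.frame (`night_id`, `severity`, `fold`) of class
#'   `fold_plan`.
#' @export
stratified_folds <- function(night_ids, severities, K = 3L, seed = 1L) {
  stopifnot(length(night_ids) == length(severities))
  if (K > length(night_ids)) stop("K exceeds the number of nights")
  out <- NULL
  withr::with_seed(derive_seed(seed, "folds"), {
    for (cls in sort(unique(severities))) {
      ids <- night_ids[severities == cls]
      ids <- ids[sample.int(length(ids))]
      fold <- ((seq_along(ids) - 1L) %% K) + 1L
      out <- rbind(out, data.frame(night_id = ids,
                                   severity = cls, fold = fold))
    }
  })
  out <- out[match(night_ids, out$night_id), ]
  rownames(out) <- NULL
  class(out) <- c("fold_plan", "data.frame")
  out
}

# ---- domain-gap diagnostics -----------------------------------------------

#' Feature-space domain-gap report
#'
#' Quantifies the discrepancy between two feature matrices (e.g. PSG vs
#' radar windows at the `smooth_conv` layer):
#' \itemize{
#'   \item `probe_auc`: cross-validated linear (logistic) domain-probe AUC
#'     on standardized features; 0.5 = maximal domain confusion.
#'   \item `mmd2`: squared maximum mean discrepancy with an RBF kernel
#'     (median-heuristic bandwidth; V-statistic, so identical sets give 0).
#'   \item `coral`: squared Frobenius distance between the two feature
#'     covariance matrices, scaled by `1/(4 d^2)`.
#'   \item `knn_mixing`: mean fraction of opposite-domain points among the
#'     k nearest neighbours of every point.
#' }
#'
#' @param features_a,features_b Feature matrices with equal column count.
#' @param k Neighbourhood size for the mixing ratio.
#' @param n_folds Cross-validation folds for the probe.
#' @param seed Seed for fold assignment.
#' @return List with `probe_auc`, `mmd2`, `coral`, `knn_mixing`.
#' @export
domain_gap_report <- function(features_a, features_b, k = 10L, n_folds = 5L,
                              seed = 1L) {
  features_a <- as.matrix(features_a); features_b <- as.matrix(features_b)
  if (ncol(features_a) != ncol(features_b)) stop("feature dimensionality mismatch")
  na <- nrow(features_a); nb <- nrow(features_b)
  if (min(na, nb) <= k) stop("fewer samples than k neighbours")
  Xall <- rbind(features_a, features_b)
  dom <- c(rep(0L, na), rep(1L, nb))
  mu <- colMeans(Xall); sdv <- apply(Xall, 2L, sd); sdv[sdv < 1e-12] <- 1
  Z <- sweep(sweep(Xall, 2L, mu), 2L, sdv, `/`)

  # pairwise squared distances
  G <- tcrossprod(Z)
  sq <- diag(G)
  D2 <- outer(sq, sq, `+`) - 2 * G
  D2[D2 < 0] <- 0

  # MMD^2, RBF with median-heuristic bandwidth (V-statistic)
  med <- median(sqrt(D2[upper.tri(D2)]))
  gamma <- if (med > 0) 1 / (2 * med^2) else 1
  Kmat <- exp(-gamma * D2)
  ia <- seq_len(na); ib <- na + seq_len(nb)
  mmd2 <- mean(Kmat[ia, ia]) + mean(Kmat[ib, ib]) - 2 * mean(Kmat[ia, ib])

  # CORAL
  d <- ncol(Z)
  Ca <- stats::cov(Z[ia, , drop = FALSE])
  Cb <- stats::cov(Z[ib, , drop = FALSE])
  coral <- sum((Ca - Cb)^2) / (4 * d^2)

  # kNN mixing
  diag(D2) <- Inf
  mix <- vapply(seq_len(nrow(D2)), function(i) {
    nn <- order(D2[i, ])[seq_len(k)]
    mean(dom[nn] != dom[i])
  }, numeric(1))

  # cross-validated linear probe AUC
  folds <- withr::with_seed(derive_seed(seed, "probe"),
                            sample(rep_len(seq_len(n_folds), na + nb)))
  scores <- numeric(na + nb)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    df_tr <- data.frame(y = dom[tr], Z[tr, , drop = FALSE])
    fit <- suppressWarnings(glm(y ~ ., data = df_tr, family = binomial()))
    df_te <- data.frame(Z[!tr, , drop = FALSE])
    scores[!tr] <- suppressWarnings(
      predict(fit, newdata = df_te, type = "link"))
  }
  probe_auc <- sample_roc_auc(scores, dom)

  list(probe_auc = probe_auc, mmd2 = mmd2, coral = coral,
       knn_mixing = mean(mix))
}
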