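# Losses, balanced sampling, the AdamW + cosine-decay optimiser, and the
# training/evaluation loops. Everything is seed-deterministic: the training
# seed drives initialisation, the train/validation split, the sampler and the
# augmentation draws.

#' Combined soft-Dice and cross-entropy segmentation loss
#'
#' `loss = dice_w * (1 - mean_c softDice_c) + ce_w * crossEntropy`, where the
#' soft Dice of class `c` is `(2 * sum_i p_ic y_ic + s) / (sum_i p_ic +
#' sum_i y_ic + s)` with probabilities `p` from a row-wise softmax of the
#' logits, one-hot reference `y`, and smoothing `s = 1e-5`.
#'
#' @param logits `|V| x K` matrix of class logits.
#' @param labels Length-`|V|` integer vector with values in `[0, K)`.
#' @param weights Length-2 vector `(dice_w, ce_w)`, default `c(0.5, 0.5)`.
#' @param smooth Dice smoothing constant.
#' @return Scalar loss with attribute `"gradient"` (`|V| x K` matrix of
#'   derivatives with respect to the logits) and attribute `"parts"`.
#' @export
dice_ce_loss <- function(logits, labels, weights = c(0.5, 0.5),
                         smooth = 1e-5) {
  K <- ncol(logits)
  if (K < 2) stop("`logits` needs at least 2 classes")
  n <- nrow(logits)
  labels <- as.integer(labels)
  if (any(labels < 0 | labels >= K))
    stop(sprintf("labels must lie in [0, %d)", K))
  p <- .softmax_rows(logits)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), labels + 1L)] <- 1
  ce <- -mean(log(pmax(p[cbind(seq_len(n), labels + 1L)], 1e-300)))
  I <- colSums(p * Y)
  A <- colSums(p)
  B <- colSums(Y)
  dice_c <- (2 * I + smooth) / (A + B + smooth)
  dice_loss <- 1 - mean(dice_c)
  loss <- weights[1] * dice_loss + weights[2] * ce
  # d loss / dp, then chain through the softmax
  denom <- A + B + smooth
  ddice_dp <- -sweep(2 * Y, 2, denom, "/") +
    matrix((2 * I + smooth) / denom^2, n, K, byrow = TRUE)
  dp <- weights[1] * ddice_dp / K + weights[2] * (-Y / pmax(p, 1e-300)) / n
  dlogits <- p * (dp - rowSums(dp * p))
  structure(loss, gradient = dlogits,
            parts = c(dice = dice_loss, ce = ce))
}

#' Balanced sampling weights for an imbalanced regression target
#'
#' Targets are binned into fixed-width bins; every sample is weighted by the
#' inverse of its bin's occupancy and weights are normalised to sum to one, so
#' the expected sampling mass is equal across non-empty bins.
#'
#' @param targets Numeric vector of regression targets.
#' @param bin_width Bin width in target units (default 1, e.g. one week for
#'   age-in-weeks targets).
#' @return Numeric vector of probabilities summing to 1.
#' @export
balanced_sample_weights <- function(targets, bin_width = 1) {
  if (length(targets) == 0) stop("`targets` must be non-empty")
  if (bin_width <= 0) stop("`bin_width` must be positive")
  bins <- floor(targets / bin_width)
  counts <- table(bins)
  w <- 1 / as.vector(counts[as.character(bins)])
  w / sum(w)
}

#' Cosine-decay learning rate
#'
#' `lr(step) = lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * step /
#' total_steps))`: `lr_max` at step 0, `lr_min` at the final step, monotone
#' non-increasing in between.
#'
#' @param step Current step, `0 <= step <= total_steps`.
#' @param config A [train_config()] (or any list with `lr_max`, `lr_min`,
#'   `total_steps`).
#' @return Scalar learning rate.
#' @export
cosine_decay_lr <- function(step, config) {
  if (any(step < 0 | step > config$total_steps))
    stop(sprintf("`step` must be in [0, %d]", config$total_steps))
  config$lr_min + 0.5 * (config$lr_max - config$lr_min) *
    (1 + cos(pi * step / config$total_steps))
}

#' Training configuration
#'
#' @param task `"regression"` or `"segmentation"`.
#' @param lr_max,lr_min Cosine schedule endpoints.
#' @param total_steps Total optimiser steps.
#' @param weight_decay Decoupled AdamW weight decay (matrices only).
#' @param batch_size Samples per optimiser step.
#' @param seed Seed driving every stochastic choice of the run.
#' @param balance_bin_width Bin width of the balanced regression sampler.
#' @param val_fraction Fraction of subjects held out when the manifest has no
#'   `split` column.
#' @param patience Early-stopping patience in epochs (`Inf` to disable).
#' @param loss_weights Dice/CE mix for segmentation.
#' @param augmentation An [augmentation_config()], or `NULL` to disable.
#' @return An object of class `train_config`.
#' @export
train_config <- function(task = c("regression", "segmentation"),
                         lr_max = 1e-3, lr_min = 1e-5, total_steps = 400,
                         weight_decay = 0.01, batch_size = 8, seed = 0,
                         balance_bin_width = 1, val_fraction = 0.2,
                         patience = 20, loss_weights = c(0.5, 0.5),
                         augmentation = augmentation_config(
                           max_rotation_deg = if (match.arg(task) == "segmentation") 15 else 30)) {
  task <- match.arg(task)
  if (lr_min > lr_max) stop("`lr_min` must not exceed `lr_max`")
  if (total_steps <= 0) stop("`total_steps` must be positive")
  out <- list(task = task, lr_max = lr_max, lr_min = lr_min,
              total_steps = as.integer(total_steps),
              weight_decay = weight_decay, batch_size = as.integer(batch_size),
              seed = as.integer(seed), balance_bin_width = balance_bin_width,
              val_fraction = val_fraction, patience = patience,
              loss_weights = loss_weights, augmentation = augmentation)
  class(out) <- "train_config"
  out
}

# ---- AdamW over nested parameter lists -------------------------------------

.zeros_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

# reorder a gradient structure so it is congruent with the parameter skeleton
.match_structure <- function(p, g) {
  if (!is.list(p)) return(g)
  nm <- names(p)
  if (!is.null(nm) && !is.null(names(g))) g <- g[nm]
  mapply(.match_structure, p, g, SIMPLIFY = FALSE)
}

.adamw_step <- function(state, params, grads, lr, weight_decay,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(walk, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    upd <- (m / b1t) / (sqrt(v / b2t) + eps)
    wd <- if (is.matrix(p)) weight_decay else 0  # no decay on biases/gains
    list(p = p - lr * (upd + wd * p), m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(t = state$t, m = res$m, v = res$v))
}

# ---- dataset loading --------------------------------------------------------

.load_dataset <- function(manifest, task) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  n <- nrow(manifest)
  signals <- vector("list", n)
  labels <- if (task == "segmentation") vector("list", n) else NULL
  for (i in seq_len(n)) {
    signals[[i]] <- read_metric(manifest$metric_path[i])
    if (task == "segmentation") {
      if (!"label_path" %in% names(manifest) || is.na(manifest$label_path[i]))
        stop(sprintf("missing label annotation for subject %s",
                     manifest$subject_id[i]))
      labels[[i]] <- read_labels(manifest$label_path[i])
    }
  }
  targets <- if (task == "regression") {
    if (!"target" %in% names(manifest) || anyNA(manifest$target))
      stop(sprintf("missing target annotation for subjects: %s",
                   paste(manifest$subject_id[is.na(manifest$target)],
                         collapse = ", ")))
    as.numeric(manifest$target)
  } else NULL
  list(manifest = manifest, signals = signals, labels = labels,
       targets = targets, n = n)
}

.split_dataset <- function(ds, val_fraction) {
  if ("split" %in% names(ds$manifest)) {
    train_idx <- which(ds$manifest$split == "train")
    val_idx <- which(ds$manifest$split == "val")
  } else {
    n_val <- max(1L, round(ds$n * val_fraction))
    perm <- sample.int(ds$n)
    val_idx <- perm[seq_len(n_val)]
    train_idx <- perm[-seq_len(n_val)]
  }
  list(train = train_idx, val = val_idx)
}

.channel_stats <- function(signals, idx) {
  mat <- do.call(rbind, lapply(signals[idx], `[[`, "values"))
  list(mean = colMeans(mat), sd = pmax(apply(mat, 2, stats::sd), 1e-8))
}

.normalise_signal <- function(signal, stats_) {
  vals <- sweep(sweep(signal$values, 2, stats_$mean), 2, stats_$sd, "/")
  surface_signal(vals, signal$channel_names, signal$mesh_order)
}

# ---- training loop ----------------------------------------------------------

#' Train a multiscale surface transformer
#'
#' Runs AdamW with a cosine-decay schedule on MSE (regression) or Dice +
#' cross-entropy (segmentation). Training samples are drawn with the balanced
#' sampler for regression (uniformly for segmentation) and augmented
#' per-sample. Channels are z-scored with training-set statistics that are
#' stored in the returned checkpoint. The best-validation parameters are kept;
#' the whole run is a pure function of the data and `train_config$seed`.
#'
#' @param manifest Manifest data frame or CSV path (see [read_manifest()]).
#' @param model_config An [mssit_config()].
#' @param config A [train_config()] with a matching task.
#' @return A checkpoint: list with `params` (best validation), `model_config`,
#'   `train_config`, `norm` (channel/target statistics), `history` (per-epoch
#'   data frame) and `best_val`.
#' @export
train <- function(manifest, model_config, config) {
  stopifnot(inherits(model_config, "mssit_config"),
            inherits(config, "train_config"))
  if ((config$task == "segmentation") != (model_config$task == "segmentation"))
    stop("model and training task disagree")
  set.seed(config$seed)
  ds <- .load_dataset(manifest, config$task)
  split <- .split_dataset(ds, config$val_fraction)
  stats_ <- .channel_stats(ds$signals, split$train)
  signals <- lapply(ds$signals, .normalise_signal, stats_ = stats_)
  target_norm <- NULL
  if (config$task == "regression") {
    t_tr <- ds$targets[split$train]
    target_norm <- list(mean = mean(t_tr), sd = max(stats::sd(t_tr), 1e-8))
    targets_z <- (ds$targets - target_norm$mean) / target_norm$sd
    samp_w <- balanced_sample_weights(t_tr, config$balance_bin_width)
  }
  geo <- .config_geometry(model_config)
  params <- init_mssit_params(model_config, seed = config$seed)
  state <- list(t = 0L, m = .zeros_like(params), v = .zeros_like(params))
  steps_per_epoch <- max(1L, ceiling(length(split$train) / config$batch_size))
  n_epochs <- ceiling(config$total_steps / steps_per_epoch)
  history <- data.frame()
  best_val <- Inf
  best_params <- params
  since_best <- 0
  step <- 0L
  for (epoch in seq_len(n_epochs)) {
    epoch_losses <- c()
    while (step < epoch * steps_per_epoch && step < config$total_steps) {
      lr <- cosine_decay_lr(step, config)
      batch <- if (config$task == "regression")
        sample(split$train, config$batch_size, replace = TRUE, prob = samp_w)
      else sample(split$train, config$batch_size, replace = TRUE)
      grads <- NULL
      batch_loss <- 0
      for (i in batch) {
        sig <- signals[[i]]
        lab <- if (config$task == "segmentation") ds$labels[[i]] else NULL
        if (!is.null(config$augmentation)) {
          aug <- augment(sig, config$augmentation, labels = lab)
          sig <- aug$signal
          if (!is.null(lab)) lab <- aug$labels
        }
        if (config$task == "regression") {
          fw <- .forward_reg_full(sig, model_config, params, geo, train = TRUE)
          err <- fw$pred - targets_z[i]
          loss_i <- mean(err^2)
          g_i <- .backward_reg_full(model_config, geo, params, fw,
                                    2 * err / length(err))
        } else {
          fw <- .forward_seg_full(sig, model_config, params, geo, train = TRUE)
          li <- dice_ce_loss(fw$logits, lab$labels, config$loss_weights)
          loss_i <- as.numeric(li)
          g_i <- .backward_seg_full(model_config, geo, params, fw,
                                    attr(li, "gradient"))
        }
        if (!is.finite(loss_i))
          stop(sprintf("non-finite loss at step %d (lr %.3g)", step, lr))
        batch_loss <- batch_loss + loss_i / length(batch)
        g_i <- .match_structure(params, g_i)
        grads <- if (is.null(grads)) .scale_params(g_i, 1 / length(batch))
        else .add_params(grads, g_i, 1 / length(batch))
      }
      upd <- .adamw_step(state, params, grads, lr, config$weight_decay)
      params <- upd$params
      state <- upd$state
      epoch_losses <- c(epoch_losses, batch_loss)
      step <- step + 1L
    }
    val <- .validate(params, model_config, geo, config, signals, ds, split,
                     target_norm)
    history <- rbind(history, data.frame(
      epoch = epoch, step = step, lr = cosine_decay_lr(step - 1L, config),
      train_loss = mean(epoch_losses), val_metric = val))
    if (val < best_val - 1e-12) {
      best_val <- val
      best_params <- params
      since_best <- 0
    } else since_best <- since_best + 1
    if (since_best > config$patience) break
  }
  ck <- list(params = best_params, model_config = model_config,
             train_config = config,
             norm = list(channel = stats_, target = target_norm),
             history = history, best_val = best_val)
  class(ck) <- "mssit_checkpoint"
  ck
}

.scale_params <- function(g, s) rapply(g, function(x) x * s, how = "replace")
.add_params <- function(a, b, s) {
  walk <- function(x, y) {
    if (is.list(x)) mapply(walk, x, y, SIMPLIFY = FALSE) else x + y * s
  }
  walk(a, b)
}

# validation metric: regression MAE on the raw target scale, segmentation
# 1 - mean Dice (both "lower is better")
.validate <- function(params, model_config, geo, config, signals, ds, split,
                      target_norm) {
  if (config$task == "regression") {
    preds <- vapply(split$val, function(i)
      .forward_reg_full(signals[[i]], model_config, params, geo)$pred[1],
      numeric(1))
    preds <- preds * target_norm$sd + target_norm$mean
    mean(abs(preds - ds$targets[split$val]))
  } else {
    dices <- vapply(split$val, function(i) {
      fw <- .forward_seg_full(signals[[i]], model_config, params, geo)
      pred <- max.col(fw$logits, ties.method = "first") - 1L
      mean(dice_per_region(pred, ds$labels[[i]]$labels,
                           model_config$num_classes), na.rm = TRUE)
    }, numeric(1))
    1 - mean(dices)
  }
}

#' Hard Dice overlap per region
#'
#' `2 |A intersect B| / (|A| + |B|)` between predicted and reference label
#' sets. Regions absent from both prediction and reference give `NA`.
#'
#' @param pred,ref Integer label vectors (0-based region ids).
#' @param num_classes Number of regions K (ids `0..K-1`).
#' @return Numeric vector of length `num_classes`.
#' @export
dice_per_region <- function(pred, ref, num_classes) {
  vapply(seq_len(num_classes) - 1L, function(k) {
    a <- pred == k
    b <- ref == k
    s <- sum(a) + sum(b)
    if (s == 0) NA_real_ else 2 * sum(a & b) / s
  }, numeric(1))
}

#' Evaluate a trained checkpoint on a manifest
#'
#' @param checkpoint A [train()] result.
#' @param manifest Manifest data frame or CSV path.
#' @return An `eval_report`: for regression, per-subject predictions and the
#'   mean absolute error `mae`; for segmentation, a per-region Dice matrix
#'   (subjects x regions), the per-region mean `dice` and the unweighted
#'   `mean_dice`.
#' @export
evaluate <- function(checkpoint, manifest) {
  stopifnot(inherits(checkpoint, "mssit_checkpoint"))
  mc <- checkpoint$model_config
  tc <- checkpoint$train_config
  ds <- .load_dataset(manifest, tc$task)
  geo <- .config_geometry(mc)
  signals <- lapply(ds$signals, .normalise_signal,
                    stats_ = checkpoint$norm$channel)
  if (tc$task == "regression") {
    preds <- vapply(seq_len(ds$n), function(i)
      .forward_reg_full(signals[[i]], mc, checkpoint$params, geo)$pred[1],
      numeric(1))
    preds <- preds * checkpoint$norm$target$sd + checkpoint$norm$target$mean
    out <- list(task = "regression",
                predictions = data.frame(subject_id = ds$manifest$subject_id,
                                         prediction = preds,
                                         target = ds$targets),
                mae = mean(abs(preds - ds$targets)))
  } else {
    dmat <- t(vapply(seq_len(ds$n), function(i) {
      fw <- .forward_seg_full(signals[[i]], mc, checkpoint$params, geo)
      pred <- max.col(fw$logits, ties.method = "first") - 1L
      dice_per_region(pred, ds$labels[[i]]$labels, mc$num_classes)
    }, numeric(mc$num_classes)))
    out <- list(task = "segmentation", dice_matrix = dmat,
                dice = colMeans(dmat, na.rm = TRUE),
                mean_dice = mean(colMeans(dmat, na.rm = TRUE), na.rm = TRUE))
  }
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  if (x$task == "regression")
    cat(sprintf("eval_report (regression): %d subjects, MAE = %.4f\n",
                nrow(x$predictions), x$mae))
  else
    cat(sprintf("eval_report (segmentation): %d subjects, mean Dice = %.4f\n",
                nrow(x$dice_matrix), x$mean_dice))
  invisible(x)
}

#' Predict with a trained checkpoint
#'
#' @param checkpoint A [train()] result.
#' @param signal A [surface_signal()] on the model's input icosphere.
#' @return Regression: numeric prediction on the raw target scale.
#'   Segmentation: a [label_map()] of argmax labels.
#' @export
predict_mssit <- function(checkpoint, signal) {
  stopifnot(inherits(checkpoint, "mssit_checkpoint"))
  mc <- checkpoint$model_config
  geo <- .config_geometry(mc)
  sig <- .normalise_signal(signal, checkpoint$norm$channel)
  if (checkpoint$train_config$task == "regression") {
    p <- .forward_reg_full(sig, mc, checkpoint$params, geo)$pred
    p * checkpoint$norm$target$sd + checkpoint$norm$target$mean
  } else {
    fw <- .forward_seg_full(sig, mc, checkpoint$params, geo)
    label_map(max.col(fw$logits, ties.method = "first") - 1L)
  }
}
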