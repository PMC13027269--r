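# Optimization loop: seeded mini-batch Adam on the cross-entropy objective,
# with plateau-based learning-rate reduction keyed to validation macro-F1
# and best-validation checkpointing.

#' Training configuration
#'
#' @param learning_rate initial Adam step size.
#' @param batch_size mini-batch size.
#' @param epochs number of passes over the training set.
#' @param seed seed controlling shuffling and augmentation draws.
#' @param lr_factor multiplicative learning-rate decay on a validation
#'   plateau.
#' @param lr_patience epochs without validation improvement before decay.
#' @param min_lr floor on the learning rate.
#' @param weight_decay decoupled L2 weight decay applied with the Adam
#'   step (0 disables it).
#' @param augment apply random crop + scale-perturbation augmentation to
#'   training images each epoch.
#' @param ppcfg [preprocess_config()] providing the augmentation windows
#'   (only used when `augment = TRUE`).
#' @return a list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 16L, epochs = 50L,
                         seed = 1L, lr_factor = 0.5, lr_patience = 5L,
                         min_lr = 1e-5, weight_decay = 1e-4,
                         augment = FALSE, ppcfg = NULL) {
  stopifnot(learning_rate >= 0, batch_size >= 1, epochs >= 0,
            lr_factor > 0, lr_factor <= 1, lr_patience >= 1, min_lr >= 0,
            weight_decay >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 min_lr = min_lr, weight_decay = weight_decay,
                 augment = augment, ppcfg = ppcfg),
            class = "train_config")
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    # decay weight matrices only (not biases, BN affines, fusion logits)
    if (weight_decay > 0 && (grepl("W", nm) || grepl("^head\\.P\\.", nm))) {
      step <- step + lr * weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - step
  }
  params
}

# mini-batch index blocks; a trailing fragment smaller than half a batch is
# merged into the previous block so batch statistics stay meaningful
batch_blocks <- function(ord, batch_size) {
  starts <- seq(1, length(ord), by = batch_size)
  blocks <- lapply(starts, function(s) ord[s:min(s + batch_size - 1, length(ord))])
  nb <- length(blocks)
  if (nb > 1 && length(blocks[[nb]]) < batch_size / 2) {
    blocks[[nb - 1]] <- c(blocks[[nb - 1]], blocks[[nb]])
    blocks[[nb]] <- NULL
  }
  blocks
}

# re-estimate batch-norm population statistics under the current weights:
# cumulative average of batch statistics over one deterministic pass
refresh_bn_stats <- function(model, samples, batch_size = 64L) {
  if (!length(model$bn)) return(invisible(model))
  for (st in model$bn) {
    st$run_mean <- st$run_mean * 0
    st$run_var <- st$run_var * 0 + 1
  }
  blocks <- batch_blocks(seq_along(samples$images), batch_size)
  for (i in seq_along(blocks)) {
    x <- images_to_input(samples$images[blocks[[i]]])
    s <- samples$sensor[blocks[[i]], , drop = FALSE]
    mvcf_forward(model, x, s, training = TRUE, bn_momentum = 1 / i)
  }
  invisible(model)
}

samples_subset <- function(samples, idx) {
  s <- samples
  s$images <- s$images[idx]
  s$sensor <- s$sensor[idx, , drop = FALSE]
  for (f in c("labels", "groups", "density", "timestamps", "matched_timestamps")) {
    if (!is.null(s[[f]])) s[[f]] <- s[[f]][idx]
  }
  s
}

#' Fit the classifier
#'
#' Minimizes the softmax cross-entropy with seeded mini-batch Adam. When a
#' validation set is supplied, the learning rate is halved after
#' `lr_patience` epochs without macro-F1 improvement and the
#' best-validation weights are restored at the end.
#'
#' @param model an `"mvcf_model"` from [build_variant()].
#' @param samples training `"aligned_samples"`.
#' @param cfg a [train_config()].
#' @param val optional validation `"aligned_samples"`.
#' @param verbose print one line per epoch.
#' @return an object of class `"mvcf_fit"`: the trained model, the
#'   per-epoch `history` data frame, and the configuration.
#' @export
train_model <- function(model, samples, cfg = train_config(), val = NULL,
                        verbose = FALSE) {
  set.seed(cfg$seed)
  n <- length(samples$images)
  labels <- samples$labels
  opt <- new.env(parent = emptyenv())
  opt$t <- 0L; opt$m <- list(); opt$v <- list()
  lr <- cfg$learning_rate
  best <- list(metric = -Inf, params = NULL, epoch = 0L)
  stall <- 0L
  hist <- NULL
  # without a validation set there is no plateau signal; fall back to one
  # fixed step decay late in training
  decay_epoch <- if (is.null(val)) ceiling(0.75 * cfg$epochs) else NA_integer_
  for (ep in seq_len(cfg$epochs)) {
    if (!is.na(decay_epoch) && ep == decay_epoch + 1L) {
      lr <- max(cfg$min_lr, lr * cfg$lr_factor)
    }
    ord <- sample.int(n)
    ep_loss <- 0
    ep_hits <- 0
    for (idx in batch_blocks(ord, cfg$batch_size)) {
      imgs <- samples$images[idx]
      if (cfg$augment) {
        pc <- if (is.null(cfg$ppcfg)) {
          d <- dim(imgs[[1]])
          preprocess_config(h0 = d[1], w0 = d[2])
        } else cfg$ppcfg
        imgs <- lapply(imgs, augment_image, cfg = pc)
      }
      x <- images_to_input(imgs)
      s <- samples$sensor[idx, , drop = FALSE]
      ag_tape_start()
      fw <- mvcf_forward(model, x, s, training = TRUE)
      ce <- ag_softmax_ce(fw$logits, labels[idx])
      ag_backward(ce$loss)
      ag_tape_stop()
      loss <- ag_value(ce$loss)
      if (!is.finite(loss)) {
        stop(sprintf("train_model(): non-finite loss at epoch %d (lr %.2g, batch of %d)",
                     ep, lr, length(idx)), call. = FALSE)
      }
      grads <- lapply(fw$leaves, function(nd) nd$grad)
      null_g <- vapply(grads, is.null, logical(1))
      grads <- grads[!null_g]
      model$params <- adam_step(model$params, grads, opt, lr,
                                weight_decay = cfg$weight_decay)
      ep_loss <- ep_loss + loss * length(idx)
      ep_hits <- ep_hits + sum(max.col(ce$probs, ties.method = "first") == labels[idx])
    }
    row <- data.frame(epoch = ep, lr = lr, train_loss = ep_loss / n,
                      train_acc = ep_hits / n, val_acc = NA_real_,
                      val_f1 = NA_real_)
    if (!is.null(val)) {
      refresh_bn_stats(model, samples, batch_size = cfg$batch_size)
      rep_v <- suppressWarnings(evaluate_model(model, val))
      row$val_acc <- rep_v$overall[["accuracy"]]
      vf1 <- rep_v$macro[["f1"]]
      if (is.na(vf1)) vf1 <- rep_v$overall[["accuracy"]]
      row$val_f1 <- vf1
      if (vf1 > best$metric + 1e-4) {
        best <- list(metric = vf1, params = model$params, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$lr_patience && lr > cfg$min_lr) {
          lr <- max(cfg$min_lr, lr * cfg$lr_factor)
          stall <- 0L
        }
      }
    }
    hist <- rbind(hist, row)
    if (verbose) {
      cat(sprintf("epoch %3d | loss %.4f | train acc %.3f%s\n", ep,
                  row$train_loss, row$train_acc,
                  if (!is.null(val)) sprintf(" | val acc %.3f F1 %.3f", row$val_acc, row$val_f1) else ""))
    }
  }
  if (!is.null(best$params)) {
    model$params <- best$params
  }
  # inference-mode batch-norm statistics for the returned weights
  refresh_bn_stats(model, samples, batch_size = cfg$batch_size)
  structure(list(model = model, history = hist, config = cfg,
                 best_epoch = if (best$epoch > 0) best$epoch else nrow(hist)),
            class = "mvcf_fit")
}

#' @export
predict.mvcf_fit <- function(object, samples, ...) {
  predict(object$model, samples, ...)
}

#' @export
print.mvcf_fit <- function(x, ...) {
  cat(sprintf("Fitted vision-sensor pest classifier (variant: %s)\n",
              paste(x$model$variant, collapse = "+")))
  h <- x$history
  if (!is.null(h) && nrow(h)) {
    last <- h[nrow(h), ]
    cat(sprintf("  epochs: %d | final train loss %.4f, acc %.3f\n",
                nrow(h), last$train_loss, last$train_acc))
    if (!is.na(last$val_acc)) {
      cat(sprintf("  best val F1 %.3f at epoch %d\n",
                  max(h$val_f1, na.rm = TRUE), x$best_epoch))
    }
  }
  invisible(x)
}

#' @export
summary.mvcf_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  parameters: %s\n", format(num_params(object), big.mark = ",")))
  if (!is.null(object$model$params$fus.logits)) {
    cat(sprintf("  fusion weights: %s (sum %.6f)\n",
                paste(sprintf("%.3f", fusion_weights(object)), collapse = " "),
                sum(fusion_weights(object))))
  }
  invisible(object)
}

#' @export
plot.mvcf_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "cross-entropy loss", main = "Training history", ...)
  if (any(!is.na(h$val_acc))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$val_acc, type = "l", col = "firebrick",
                   axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4)
    graphics::mtext("validation accuracy", side = 4, line = 2, col = "firebrick")
  }
  invisible(x)
}

#' Ablation grid over model variants with grouped cross-validation
#'
#' Trains and evaluates each variant on each fold of a shared grouped
#' split: fold `f` serves as the held-out set, the remaining folds as
#' training data. Reports fold-mean and fold-sd of the overall metrics per
#' variant.
#'
#' @param samples training-partition `"aligned_samples"`.
#' @param folds a [make_folds()] assignment over `samples`.
#' @param variants list (or character vector) of variant names for
#'   [build_variant()].
#' @param spec a [pyramid_spec()].
#' @param cfg a [train_config()].
#' @param relational passed to [build_variant()].
#' @param verbose print progress.
#' @return a list with `table` (variant x metric mean/sd data frame) and
#'   `reports` (per-variant, per-fold eval reports).
#' @export
run_ablation_grid <- function(samples, folds, variants = list("full", "no_sensor_prior"),
                              spec = pyramid_spec(), cfg = train_config(),
                              relational = TRUE, verbose = FALSE) {
  if (length(variants) < 1) stop("need at least one variant", call. = FALSE)
  fold_ids <- sort(unique(folds$fold[!is.na(folds$fold)]))
  reports <- list()
  rows <- NULL
  for (v in variants) {
    vkey <- paste(v, collapse = "+")
    metr <- NULL
    for (f in fold_ids) {
      hold <- which(folds$fold == f)
      tr <- which(!is.na(folds$fold) & folds$fold != f)
      model <- build_variant(v, spec = spec, n_classes = length(samples$class_names),
                             relational = relational, seed = cfg$seed + f)
      fit <- train_model(model, samples_subset(samples, tr), cfg,
                         val = samples_subset(samples, hold))
      rep_f <- suppressWarnings(evaluate_model(fit, samples_subset(samples, hold)))
      reports[[vkey]][[as.character(f)]] <- rep_f
      metr <- rbind(metr, rep_f$overall)
      if (verbose) {
        cat(sprintf("variant %-18s fold %d: acc %.3f F1 %.3f\n", vkey, f,
                    rep_f$overall[["accuracy"]], rep_f$overall[["f1"]]))
      }
    }
    rows <- rbind(rows, data.frame(
      variant = vkey,
      accuracy_mean = mean(metr[, "accuracy"]), accuracy_sd = stats::sd(metr[, "accuracy"]),
      precision_mean = mean(metr[, "precision"]), precision_sd = stats::sd(metr[, "precision"]),
      recall_mean = mean(metr[, "recall"]), recall_sd = stats::sd(metr[, "recall"]),
      f1_mean = mean(metr[, "f1"]), f1_sd = stats::sd(metr[, "f1"])))
  }
  list(table = rows, reports = reports)
}
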