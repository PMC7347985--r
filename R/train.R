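# Training regime: Adam over shuffled mini-batches of the combined
# cross-entropy + Dice loss, a step-decayed learning rate (divided by 10
# every 30 epochs by default), per-epoch validation Dice, and
# best-validation-Dice checkpointing. The ablation harness trains the four
# attention configurations (none / CA / SA / SA+CA) under one shared seed
# and data order.

#' Training configuration
#'
#' @param lr0 Initial learning rate (default 1e-4).
#' @param batch_size Mini-batch size (default 4).
#' @param epochs Total epochs (default 100).
#' @param decay_every Epoch interval of the learning-rate step decay.
#' @param decay_factor Multiplicative decay per step; 1 disables decay.
#' @param lambda Cross-entropy weight of the combined loss.
#' @param augment Optional [augment_config()] applied per epoch; NULL
#'   disables augmentation.
#' @param seed Seed for shuffling (and Adam is deterministic given it).
#' @return A `train_config` list.
#' @export
train_config <- function(lr0 = 1e-4, batch_size = 4L, epochs = 100L,
                         decay_every = 30L, decay_factor = 0.1,
                         lambda = 0.5, augment = NULL, seed = 1L) {
  stopifnot(lr0 > 0, batch_size >= 1, epochs >= 1, decay_every >= 1,
            decay_factor > 0, decay_factor <= 1)
  structure(list(lr0 = lr0, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 decay_every = as.integer(decay_every),
                 decay_factor = decay_factor, lambda = lambda,
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

#' Step-decayed learning rate
#'
#' `lr0 * decay_factor ^ floor(epoch / decay_every)` with 0-based epochs:
#' at the defaults the rate is 1e-4 for epochs 0-29, 1e-5 for 30-59, and so
#' on.
#'
#' @param epoch 0-based epoch index (vectorised).
#' @param cfg A [train_config()].
#' @return Learning rate(s).
#' @export
lr_schedule <- function(epoch, cfg = train_config()) {
  stopifnot(all(epoch >= 0))
  cfg$lr0 * cfg$decay_factor^(floor(epoch / cfg$decay_every))
}

# Stack dataset rows into network tensors: x (3,H,W,N) in [0,1], y (H,W,N).
make_batch <- function(data, rows) {
  n <- length(rows)
  d <- dim(data$image[[rows[1]]])
  x <- array(0, c(3L, d[1], d[2], n))
  y <- array(0L, c(d[1], d[2], n))
  for (k in seq_len(n)) {
    x[, , , k] <- aperm(data$image[[rows[k]]], c(3, 1, 2))
    y[, , k] <- data$mask[[rows[k]]]
  }
  list(x = x, y = y)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# Mean Dice of argmax predictions over a dataset (eval mode).
mean_dice <- function(model, data) {
  scores <- vapply(seq_len(nrow(data)), function(i) {
    pred <- predict_mask(model, aperm(data$image[[i]], c(3, 1, 2)))
    dice_score(data$mask[[i]], pred)
  }, numeric(1))
  mean(scores)
}

#' Train a SCAU-Net model
#'
#' Minimises the combined loss with Adam (beta1 0.9, beta2 0.999, eps 1e-8)
#' over shuffled mini-batches; after every epoch the mean validation Dice of
#' the binarised (argmax) predictions is computed and the parameters with
#' the best validation Dice so far are kept as the returned model.
#'
#' @param model A [build_scau_net()] model.
#' @param train_data,val_data Dataset tibbles (`id`, `image`, `mask`);
#'   images must already be at a size divisible by `2^depth`.
#' @param cfg A [train_config()].
#' @param verbose Print a line per epoch.
#' @return An object of class `scau_fit`: `model` (best checkpoint),
#'   `final_model`, `log` (per-epoch tibble: `epoch`, `lr`, `train_loss`,
#'   `train_dice`, `val_dice`), `best_epoch`, `best_val_dice`, `config`.
#' @export
train_scau_net <- function(model, train_data, val_data, cfg = train_config(),
                           verbose = FALSE) {
  stopifnot(inherits(model, "scau_net"), inherits(cfg, "train_config"))
  if (nrow(train_data) == 0) stop("empty training set", call. = FALSE)
  if (nrow(val_data) == 0) stop("empty validation set", call. = FALSE)
  loss_cfg <- loss_config(lambda = cfg$lambda)
  state <- adam_init(model$params)
  log <- vector("list", cfg$epochs)
  best <- list(val_dice = -Inf, params = model$params, bn = model$bn,
               epoch = NA_integer_)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs) - 1L) {
      lr <- lr_schedule(epoch, cfg)
      epoch_data <- if (is.null(cfg$augment)) train_data else
        augment_dataset(train_data, cfg$augment, epoch = epoch)
      order_ <- sample.int(nrow(epoch_data))
      losses <- c()
      dices <- c()
      for (start in seq(1, length(order_), by = cfg$batch_size)) {
        rows <- order_[start:min(start + cfg$batch_size - 1L, length(order_))]
        b <- make_batch(epoch_data, rows)
        fw <- net_forward(model, b$x, train = TRUE, keep_cache = TRUE)
        model$bn <- fw$bn
        lg <- combined_loss_grad(fw$logits, b$y, loss_cfg)
        if (!is.finite(lg$loss)) {
          stop(sprintf("non-finite loss at epoch %d (lr %.3g, batch starting at %d)",
                       epoch, lr, start), call. = FALSE)
        }
        grads <- net_backward(model, fw, lg$dlogits)
        st <- adam_step(model$params, grads, state, lr)
        model$params <- st$params
        state <- st$state
        losses <- c(losses, lg$loss)
        for (k in seq_along(rows)) {
          pm <- argmax_mask(array(fw$logits[, , , k],
                                  dim(fw$logits)[1:3]))
          dices <- c(dices, dice_score(b$y[, , k], pm))
        }
      }
      val_dice <- mean_dice(model, val_data)
      if (val_dice > best$val_dice) {
        best <- list(val_dice = val_dice, params = model$params,
                     bn = model$bn, epoch = epoch)
      }
      log[[epoch + 1L]] <- tibble::tibble(
        epoch = epoch, lr = lr, train_loss = mean(losses),
        train_dice = mean(dices), val_dice = val_dice)
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2g  loss %.4f  train dice %.4f  val dice %.4f",
                        epoch, lr, mean(losses), mean(dices), val_dice))
      }
    }
  })
  best_model <- model
  best_model$params <- best$params
  best_model$bn <- best$bn
  structure(list(model = best_model, final_model = model,
                 log = dplyr::bind_rows(log), best_epoch = best$epoch,
                 best_val_dice = best$val_dice, config = cfg),
            class = "scau_fit")
}

#' @export
print.scau_fit <- function(x, ...) {
  cat(sprintf("<scau_fit> %d epochs; best val Dice %.4f at epoch %d\n",
              nrow(x$log), x$best_val_dice, x$best_epoch))
  invisible(x)
}

#' Per-epoch training log of a fit
#' @param x A `scau_fit`.
#' @param ... Unused.
#' @return The per-epoch tibble (`epoch`, `lr`, `train_loss`, `train_dice`,
#'   `val_dice`).
#' @export
tidy.scau_fit <- function(x, ...) x$log

#' One-row summary of a fit
#' @param x A `scau_fit`.
#' @param ... Unused.
#' @return Tibble with `epochs`, `best_epoch`, `best_val_dice`,
#'   `final_train_loss`, `final_train_dice`, `n_parameters`.
#' @export
glance.scau_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$log), best_epoch = x$best_epoch,
                 best_val_dice = x$best_val_dice,
                 final_train_loss = x$log$train_loss[nrow(x$log)],
                 final_train_dice = x$log$train_dice[nrow(x$log)],
                 n_parameters = n_parameters(x$model))
}

#' Evaluate a model on a dataset
#'
#' Computes per-image Dice, Jaccard and RVD on the argmax masks
#' (deterministic: batch norm uses running statistics).
#'
#' @param model A `scau_net`.
#' @param data Dataset tibble.
#' @return A `scau_metrics` tibble (see [metrics_report()]).
#' @export
evaluate_scau_net <- function(model, data) {
  if (nrow(data) == 0) stop("empty evaluation set", call. = FALSE)
  preds <- lapply(seq_len(nrow(data)), function(i) {
    predict_mask(model, aperm(data$image[[i]], c(3, 1, 2)))
  })
  metrics_report(data$mask, preds, ids = data$id)
}

#' Run the four-arm attention ablation
#'
#' Trains and evaluates the four configurations — plain U-Net (`none`),
#' channel attention only (`CA`), spatial attention only (`SA`), and both
#' (`SA+CA`) — with the same seed, the same data and the same data order in
#' every arm.
#'
#' @param train_data,test_data Dataset tibbles.
#' @param model_cfg Base [scau_config()]; the attention flags are overridden
#'   per arm.
#' @param train_cfg A [train_config()] shared by all arms.
#' @return A tibble of class `scau_ablation`, one row per arm: `arm`,
#'   `n_parameters`, `dice`, `jaccard`, `rvd` (test-set means), plus the
#'   per-arm fits in the `fit` list column.
#' @export
run_ablation <- function(train_data, test_data, model_cfg = scau_config(),
                         train_cfg = train_config()) {
  arms <- list(
    none    = c(sa = FALSE, ca = FALSE),
    CA      = c(sa = FALSE, ca = TRUE),
    SA      = c(sa = TRUE,  ca = FALSE),
    `SA+CA` = c(sa = TRUE,  ca = TRUE)
  )
  rows <- lapply(names(arms), function(arm) {
    fl <- arms[[arm]]
    cfg <- model_cfg
    cfg$use_spatial_attention <- unname(fl["sa"])
    cfg$use_channel_attention <- unname(fl["ca"])
    model <- build_scau_net(cfg)
    fit <- train_scau_net(model, train_data, test_data, train_cfg)
    rep_ <- evaluate_scau_net(fit$model, test_data)
    sm <- glance(rep_)
    tibble::tibble(arm = arm, n_parameters = n_parameters(model),
                   dice = sm$mean_dice, jaccard = sm$mean_jaccard,
                   rvd = sm$mean_rvd, fit = list(fit))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scau_ablation", class(out))
  out
}

#' Write an ablation table to CSV
#'
#' One row per arm with the three test-set mean metrics, mirroring the
#' standard attention-ablation table layout.
#'
#' @param ablation A `scau_ablation` tibble.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ablation_csv <- function(ablation, path) {
  utils::write.csv(
    as.data.frame(ablation[, c("arm", "n_parameters", "dice", "jaccard", "rvd")]),
    path, row.names = FALSE)
  invisible(path)
}

# ---- checkpoints -------------------------------------------------------------

#' Save a model checkpoint
#'
#' Serialises parameters and batch-norm statistics to `path` and writes a
#' JSON sidecar `<path>.json` describing the model configuration, so a
#' checkpoint is self-describing. The round trip is bit-exact.
#'
#' @param model A `scau_net`.
#' @param path Checkpoint file path.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "scau_net"))
  saveRDS(model, path)
  cfg <- model$config
  jsonlite::write_json(unclass(cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Path written by [save_checkpoint()].
#' @return The `scau_net` model.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  model <- readRDS(path)
  if (!inherits(model, "scau_net")) stop("not a scau_net checkpoint: ", path, call. = FALSE)
  model
}
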