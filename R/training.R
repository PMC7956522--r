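# Joint training of the multitask network with adaptive validation-trend
# task weighting. Each epoch has a training phase (momentum-SGD on the
# weighted per-task RMSE) and a validation phase (per-batch MAE statistics
# from which the loss importances are re-learned).

#' Training configuration
#'
#' Optimizer and schedule settings. `learning_rate`, `batch_size`,
#' `momentum`, the plateau schedule (`lr_decay_factor`, `lr_patience`) and
#' the L2 penalty `weight_decay` default to the reference values; only
#' `max_epochs` defaults to a desk-scale 30 (the reference schedule is 500).
#'
#' @param learning_rate Initial SGD learning rate.
#' @param batch_size Mini-batch size for the training phase.
#' @param momentum Momentum coefficient.
#' @param lr_decay_factor Multiplier applied to the learning rate on a
#'   plateau of the training loss.
#' @param lr_patience Epochs without training-loss improvement before the
#'   rate is decayed.
#' @param weight_decay Factor of the explicit L2 penalty added to the loss
#'   over all weights and biases.
#' @param max_epochs Number of epochs.
#' @param seed Master seed (parameter init and per-epoch shuffles derive
#'   from it).
#' @param loss_kind Per-task training loss: `"rmse"` (default) or `"mae"`.
#' @param uniform_weights If `TRUE`, fix every task weight at 1 (the
#'   uniform multitask ablation) instead of adapting.
#' @param single_task `NULL`, or one of `"sbp"`, `"dbp"`, `"map"` to train
#'   the single-task ablation (same trunk, one head, weight 1).
#' @param val_batch_size Validation batch size; defaults to `batch_size`
#'   but is reduced so that at least 2 validation batches exist.
#' @param epsilon Guard for the divisions of the trend and weight updates.
#' @return Object of class `bp_train_config`.
#' @export
train_config <- function(learning_rate = 8e-4, batch_size = 128L,
                         momentum = 0.9, lr_decay_factor = 0.9,
                         lr_patience = 4L, weight_decay = 0.1,
                         max_epochs = 30L, seed = 1L, loss_kind = "rmse",
                         uniform_weights = FALSE, single_task = NULL,
                         val_batch_size = NULL, epsilon = 1e-12) {
  if (learning_rate <= 0 || batch_size < 1 || lr_decay_factor <= 0)
    stop("rates and sizes must be positive")
  if (lr_patience < 1) stop("`lr_patience` must be >= 1")
  loss_kind <- match.arg(loss_kind, c("rmse", "mae"))
  if (!is.null(single_task))
    single_task <- match.arg(single_task, c("sbp", "dbp", "map"))
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         momentum = momentum, lr_decay_factor = lr_decay_factor,
         lr_patience = as.integer(lr_patience), weight_decay = weight_decay,
         max_epochs = as.integer(max_epochs), seed = as.integer(seed),
         loss_kind = loss_kind, uniform_weights = uniform_weights,
         single_task = single_task, val_batch_size = val_batch_size,
         epsilon = epsilon),
    class = "bp_train_config"
  )
}

.task_loss <- function(err, kind) {
  switch(kind, rmse = sqrt(mean(err^2)), mae = mean(abs(err)))
}

#' Weighted joint loss over a batch
#'
#' Per-task loss (root-mean-square error by default) combined as
#' `sum_i theta_i * L_i`.
#'
#' @param pred,target `n x k` matrices of predictions and targets (mmHg).
#' @param weights Numeric task weights of length `k`.
#' @param loss_kind `"rmse"` or `"mae"`.
#' @return List with the scalar `total` and the unweighted `per_task`
#'   losses.
#' @export
joint_loss <- function(pred, target, weights, loss_kind = "rmse") {
  pred <- as.matrix(pred); target <- as.matrix(target)
  if (!all(dim(pred) == dim(target))) stop("batch shapes disagree")
  if (any(!is.finite(pred))) stop("training diverged: non-finite predictions")
  per_task <- vapply(seq_len(ncol(pred)), function(k)
    .task_loss(target[, k] - pred[, k], loss_kind), numeric(1))
  list(total = sum(weights * per_task), per_task = per_task)
}

# near-equal contiguous batch index blocks
.batch_blocks <- function(n, m) {
  bounds <- round(seq(0, n, length.out = m + 1L))
  lapply(seq_len(m), function(i) (bounds[i] + 1L):bounds[i + 1L])
}

#' Per-task validation loss statistics at one epoch
#'
#' The validation set is divided into `M >= 2` batches; the mean absolute
#' error of each batch is computed per task, and the mean and (population)
#' standard deviation of those `M` batch losses are returned. The model is
#' not modified.
#'
#' @param model A trained `bp_model`, a `bp_model_params` +`cfg` pair, or a
#'   function `x -> prediction matrix` (handy for testing).
#' @param x,y Validation inputs and targets.
#' @param epoch Epoch index recorded in the result.
#' @param batch_size Target batch size (reduced so that `M >= 2`).
#' @param cfg A [model_config()] when `model` is a raw parameter set.
#' @return Object of class `val_loss_stats`: `epoch`, per-task `mean` and
#'   `sd`, and `n_batches`.
#' @export
validation_stats <- function(model, x, y, epoch = 0L, batch_size = 128L,
                             cfg = NULL) {
  y <- as.matrix(y)
  n <- nrow(y)
  if (n < 2L) stop("validation set must yield at least 2 batches")
  m <- max(2L, as.integer(ceiling(n / batch_size)))
  predict_fun <-
    if (is.function(model)) model
    else if (inherits(model, "bp_model")) function(xx) predict(model, xx)
    else function(xx) predict_bp(model, xx, cfg)
  blocks <- .batch_blocks(n, m)
  batch_mae <- t(vapply(blocks, function(idx) {
    p <- predict_fun(x[idx, , drop = FALSE])
    colMeans(abs(y[idx, , drop = FALSE] - p))
  }, numeric(ncol(y))))
  mu <- colMeans(batch_mae)
  sdv <- sqrt(colMeans(sweep(batch_mae, 2L, mu)^2))  # population convention
  structure(list(epoch = as.integer(epoch), mean = mu, sd = sdv,
                 n_batches = m),
            class = "val_loss_stats")
}

#' Validation-loss trends between consecutive epochs
#'
#' Relative change of the per-task validation loss mean and standard
#' deviation, `T_i = (L_i(k) - L_i(k-1)) / L_i(k)`, with the denominator
#' floored at `epsilon`. Negative values indicate improvement.
#'
#' @param curr,prev `val_loss_stats` of epochs `k` and `k - 1`.
#' @param epsilon Denominator floor.
#' @return Object of class `trend_stats` with `mean` and `sd` trends.
#' @export
compute_trends <- function(curr, prev, epsilon = 1e-12) {
  if (curr$epoch != prev$epoch + 1L)
    stop("`curr` must be the epoch immediately after `prev`")
  structure(
    list(mean = (curr$mean - prev$mean) / pmax(curr$mean, epsilon),
         sd = (curr$sd - prev$sd) / pmax(curr$sd, epsilon),
         epoch = curr$epoch),
    class = "trend_stats"
  )
}

#' Re-learn task weights from validation trends
#'
#' Raw importance `r_i = |T_mean_i * T_std_i| * (L_mean_i + L_std_i)`
#' normalized to the simplex; a task whose validation loss is still moving
#' and still large receives more weight. If all raw importances vanish the
#' weights fall back to uniform.
#'
#' @param trends A `trend_stats`.
#' @param stats The current `val_loss_stats`.
#' @param epsilon Degeneracy guard on the normalizer.
#' @return Named numeric task weights summing to 1.
#' @export
update_weights <- function(trends, stats, epsilon = 1e-12) {
  r <- abs(trends$mean * trends$sd) * (stats$mean + stats$sd)
  s <- sum(r)
  w <- if (!is.finite(s) || s < epsilon) rep(1 / length(r), length(r)) else r / s
  names(w) <- names(stats$mean)
  w
}

# L2 penalty term over every weight and bias
.l2_penalty <- function(params, lambda) {
  lambda * sum(rapply(params, function(p) sum(p^2), how = "unlist"))
}

#' Train the multitask blood-pressure model
#'
#' Runs the full epoch loop: task weights start uniform at 1/3; each epoch
#' performs momentum-SGD over shuffled mini-batches on the weighted
#' per-task RMSE plus an explicit L2 penalty, then computes validation MAE
#' statistics and (from the second epoch on) re-learns the task weights
#' from the validation trends. The learning rate is multiplied by
#' `lr_decay_factor` after `lr_patience` consecutive epochs without
#' training-loss improvement. Fully deterministic given the config.
#'
#' @param data A `labeled_bp_data` with `train` and `val` splits (only
#'   QC-passed segments are used).
#' @param model_cfg A [model_config()].
#' @param cfg A [train_config()].
#' @return Object of class `bp_model`: trained `params`, the configs, the
#'   final task `weights`, and a per-epoch `log` data frame (epoch, lr,
#'   theta, training loss, validation mean/sd per task).
#' @export
train_bp_model <- function(data, model_cfg = model_config(hidden_size = 64L),
                           cfg = train_config()) {
  if (!inherits(data, "labeled_bp_data")) stop("`data` must be labeled_bp_data")
  if (!is.null(cfg$single_task)) {
    model_cfg$n_tasks <- 1L
    model_cfg$tasks <- cfg$single_task
  }
  tasks <- model_cfg$tasks
  use <- data$qc & !is.na(data$y[, 1])
  tr <- use & data$meta$split == "train"
  va <- use & data$meta$split == "val"
  if (!any(tr) || sum(va) < 2L)
    stop("empty training or validation split after quality control")
  x_tr <- data$x[tr, , drop = FALSE]; y_tr <- data$y[tr, tasks, drop = FALSE]
  x_va <- data$x[va, , drop = FALSE]; y_va <- data$y[va, tasks, drop = FALSE]

  params <- init_params(model_cfg, seed = .derive_seed(cfg$seed, 1L))
  vel <- .zeros_like(params)
  k_tasks <- model_cfg$n_tasks
  theta <- if (cfg$uniform_weights || !is.null(cfg$single_task))
    rep(1, k_tasks) else rep(1 / 3, k_tasks)
  adapt <- !cfg$uniform_weights && is.null(cfg$single_task)

  lr <- cfg$learning_rate
  best_train <- Inf; stall <- 0L
  prev_stats <- NULL
  log_rows <- vector("list", cfg$max_epochs)
  n_tr <- nrow(x_tr)
  val_bs <- if (is.null(cfg$val_batch_size)) cfg$batch_size else cfg$val_batch_size

  for (k in seq_len(cfg$max_epochs) - 1L) {
    ord <- withr::with_seed(.derive_seed(cfg$seed, 100L + k), sample.int(n_tr))
    n_batches <- max(1L, ceiling(n_tr / cfg$batch_size))
    epoch_loss <- 0
    for (b in seq_len(n_batches)) {
      idx <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n_tr)]
      xb <- x_tr[idx, , drop = FALSE]; yb <- y_tr[idx, , drop = FALSE]
      fw <- .model_forward(params, xb, model_cfg, with_cache = TRUE)
      jl <- joint_loss(fw$pred, yb, theta, cfg$loss_kind)
      epoch_loss <- epoch_loss + jl$total * length(idx)
      # d total / d pred for the weighted per-task loss
      nb <- length(idx)
      dPred <- matrix(0, nb, k_tasks)
      for (j in seq_len(k_tasks)) {
        err <- fw$pred[, j] - yb[, j]
        dPred[, j] <- if (cfg$loss_kind == "rmse") {
          if (jl$per_task[j] > 0) theta[j] * err / (nb * jl$per_task[j]) else 0
        } else theta[j] * sign(err) / nb
      }
      grads <- .model_backward(params, fw, dPred, model_cfg)
      if (cfg$weight_decay > 0)
        grads <- .map2_params(function(g, w) g + 2 * cfg$weight_decay * w,
                              grads, params)
      vel <- .map2_params(function(v, g) cfg$momentum * v - lr * g, vel, grads)
      params <- .map2_params(`+`, params, vel)
    }
    train_loss <- epoch_loss / n_tr

    stats <- validation_stats(params, x_va, y_va, epoch = k,
                              batch_size = val_bs, cfg = model_cfg)
    names(stats$mean) <- tasks; names(stats$sd) <- tasks
    if (k > 0L && adapt) {
      trends <- compute_trends(stats, prev_stats, cfg$epsilon)
      theta <- update_weights(trends, stats, cfg$epsilon)
    }
    prev_stats <- stats

    # plateau schedule on the training loss
    if (train_loss < best_train - 1e-10) {
      best_train <- train_loss; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$lr_patience) {
        lr <- lr * cfg$lr_decay_factor
        stall <- 0L
      }
    }
    if (!is.finite(train_loss))
      stop("training diverged: non-finite loss at epoch ", k)

    row <- data.frame(epoch = k, lr = lr, train_loss = train_loss)
    for (j in seq_len(k_tasks)) row[[paste0("theta_", tasks[j])]] <- theta[j]
    for (j in seq_len(k_tasks)) row[[paste0("val_mean_", tasks[j])]] <- stats$mean[j]
    for (j in seq_len(k_tasks)) row[[paste0("val_sd_", tasks[j])]] <- stats$sd[j]
    log_rows[[k + 1L]] <- row
  }
  structure(
    list(params = params, model_cfg = model_cfg, train_cfg = cfg,
         weights = stats::setNames(theta, tasks),
         log = do.call(rbind, log_rows)),
    class = "bp_model"
  )
}

#' @export
predict.bp_model <- function(object, newdata, ...) {
  predict_bp(object$params, newdata, object$model_cfg)
}

#' @export
print.bp_model <- function(x, ...) {
  n_ep <- nrow(x$log)
  cat(sprintf("Trained multitask BP model (%d epochs). Final task weights: %s\n",
              n_ep, paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                          collapse = ", ")))
  invisible(x)
}
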