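# Shared 2-layer bidirectional LSTM trunk with three identical task-specific
# fully connected heads (SBP, DBP, MAP). Implemented directly in matrix
# code; the matching backward pass lives in backprop.R.

#' Model architecture configuration
#'
#' A 10-s ECG segment (1000 samples at 100 Hz) is folded into `seq_len`
#' steps of `step_dim` consecutive samples and run through a
#' `trunk_layers`-deep bidirectional LSTM with `hidden_size` units per
#' direction. The final hidden states of the two directions (last layer)
#' are concatenated into a `2 * hidden_size` feature on which each head
#' applies ReLU-affine(`head_hidden_1`), ReLU-affine(`head_hidden_2`) and a
#' linear scalar readout in mmHg.
#'
#' @param seq_len Number of unroll steps.
#' @param step_dim Samples per step; `seq_len * step_dim` must equal the
#'   segment length.
#' @param hidden_size LSTM units per direction.
#' @param trunk_layers Number of stacked BiLSTM layers.
#' @param head_hidden_1,head_hidden_2 Head layer widths; the first must
#'   equal the trunk output width `2 * hidden_size`.
#' @param n_tasks Number of regression heads (3, or 1 for the single-task
#'   ablation).
#' @param tasks Names of the regressed quantities.
#' @return Object of class `bp_model_config`.
#' @examples
#' model_config(hidden_size = 64) # desk-scale variant
#' @export
model_config <- function(seq_len = 20L, step_dim = 50L, hidden_size = 256L,
                         trunk_layers = 2L,
                         head_hidden_1 = 2L * hidden_size,
                         head_hidden_2 = hidden_size,
                         n_tasks = 3L,
                         tasks = c("sbp", "dbp", "map")[seq_len(n_tasks)]) {
  if (head_hidden_1 != 2L * hidden_size)
    stop("`head_hidden_1` must equal the trunk output width 2 * hidden_size")
  if (n_tasks != length(tasks)) stop("`tasks` must have length `n_tasks`")
  structure(
    list(seq_len = as.integer(seq_len), step_dim = as.integer(step_dim),
         hidden_size = as.integer(hidden_size),
         trunk_layers = as.integer(trunk_layers), bidirectional = TRUE,
         head_hidden_1 = as.integer(head_hidden_1),
         head_hidden_2 = as.integer(head_hidden_2),
         n_tasks = as.integer(n_tasks), tasks = tasks),
    class = "bp_model_config"
  )
}

#' Fold segments into the step sequence consumed by the trunk
#'
#' Order-preserving contiguous fold: step `t` holds samples
#' `((t-1) * step_dim + 1) : (t * step_dim)`. Accepts one segment (vector)
#' or a batch (rows of a matrix).
#'
#' @param x Numeric vector of length `seq_len * step_dim`, or an
#'   `n x (seq_len * step_dim)` matrix.
#' @param cfg A [model_config()].
#' @return A list of `seq_len` matrices, each `n x step_dim`.
#' @export
reshape_segment <- function(x, cfg) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  want <- cfg$seq_len * cfg$step_dim
  if (ncol(x) != want)
    stop(sprintf("segment length %d does not match seq_len * step_dim = %d",
                 ncol(x), want))
  lapply(seq_len(cfg$seq_len), function(t)
    x[, ((t - 1L) * cfg$step_dim + 1L):(t * cfg$step_dim), drop = FALSE])
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.new_cell <- function(d_in, h, draw) {
  list(Wx = matrix(draw(d_in * 4L * h), d_in, 4L * h),
       Wh = matrix(draw(h * 4L * h), h, 4L * h),
       b = draw(4L * h))
}

.new_head <- function(d_in, h1, h2, draw) {
  list(W1 = matrix(draw(d_in * h1), d_in, h1), b1 = draw(h1),
       W2 = matrix(draw(h1 * h2), h1, h2), b2 = draw(h2),
       W3 = matrix(draw(h2), h2, 1L), b3 = draw(1L))
}

#' Initialize model parameters
#'
#' All weights and biases are drawn from the uniform distribution
#' `U(-1/sqrt(hidden_size), 1/sqrt(hidden_size))`, excluding exact zeros —
#' small non-zero values that keep the recurrent dynamics stable at the
#' start of training. Deterministic given `seed`.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed.
#' @return Nested parameter list (class `bp_model_params`): `trunk` (per
#'   layer, `fwd`/`bwd` cells with `Wx`, `Wh`, `b`) and `heads` (per task,
#'   `W1`, `b1`, `W2`, `b2`, `W3`, `b3`).
#' @export
init_params <- function(cfg, seed = 1L) {
  bound <- 1 / sqrt(cfg$hidden_size)
  withr::with_seed(as.integer(seed), {
    draw <- function(n) {
      v <- stats::runif(n, -bound, bound)
      v[v == 0] <- bound / 2
      v
    }
    h <- cfg$hidden_size
    trunk <- vector("list", cfg$trunk_layers)
    d_in <- cfg$step_dim
    for (l in seq_len(cfg$trunk_layers)) {
      trunk[[l]] <- list(fwd = .new_cell(d_in, h, draw),
                         bwd = .new_cell(d_in, h, draw))
      d_in <- 2L * h
    }
    heads <- stats::setNames(
      lapply(cfg$tasks, function(task)
        .new_head(2L * h, cfg$head_hidden_1, cfg$head_hidden_2, draw)),
      cfg$tasks)
    structure(list(trunk = trunk, heads = heads), class = "bp_model_params")
  })
}

# total number of scalar parameters
.n_params <- function(params) {
  sum(rapply(params, length, how = "unlist"))
}

# one LSTM direction over steps given in processing order;
# returns per-step hidden states and the caches needed for BPTT
.lstm_dir_forward <- function(xs, cell) {
  T_ <- length(xs); n <- nrow(xs[[1L]]); h <- ncol(cell$Wh)/4L
  hprev <- matrix(0, n, h); cprev <- matrix(0, n, h)
  H <- vector("list", T_); cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    z <- xs[[t]] %*% cell$Wx + hprev %*% cell$Wh + rep(cell$b, each = n)
    i <- .sigmoid(z[, 1:h, drop = FALSE])
    f <- .sigmoid(z[, (h + 1):(2 * h), drop = FALSE])
    g <- tanh(z[, (2 * h + 1):(3 * h), drop = FALSE])
    o <- .sigmoid(z[, (3 * h + 1):(4 * h), drop = FALSE])
    c_t <- f * cprev + i * g
    tc <- tanh(c_t)
    h_t <- o * tc
    H[[t]] <- h_t
    cache[[t]] <- list(x = xs[[t]], hprev = hprev, cprev = cprev,
                       i = i, f = f, g = g, o = o, tc = tc)
    hprev <- h_t; cprev <- c_t
  }
  list(H = H, cache = cache)
}

.head_forward <- function(z, head) {
  n <- nrow(z)
  a1p <- z %*% head$W1 + rep(head$b1, each = n); a1 <- pmax(a1p, 0)
  a2p <- a1 %*% head$W2 + rep(head$b2, each = n); a2 <- pmax(a2p, 0)
  out <- a2 %*% head$W3 + rep(head$b3, each = n)
  list(out = out, z = z, a1 = a1, a2 = a2)
}

# full forward pass; caches retained for the backward pass when asked
.model_forward <- function(params, x, cfg, with_cache = FALSE) {
  steps <- reshape_segment(x, cfg)
  T_ <- cfg$seq_len; h <- cfg$hidden_size
  layer_caches <- vector("list", cfg$trunk_layers)
  for (l in seq_len(cfg$trunk_layers)) {
    fwd <- .lstm_dir_forward(steps, params$trunk[[l]]$fwd)
    bwd <- .lstm_dir_forward(rev(steps), params$trunk[[l]]$bwd)
    steps <- lapply(seq_len(T_), function(t)
      cbind(fwd$H[[t]], bwd$H[[T_ - t + 1L]]))
    layer_caches[[l]] <- list(fwd = fwd, bwd = bwd)
  }
  z <- cbind(layer_caches[[cfg$trunk_layers]]$fwd$H[[T_]],
             layer_caches[[cfg$trunk_layers]]$bwd$H[[T_]])
  head_caches <- lapply(params$heads, function(hd) .head_forward(z, hd))
  pred <- do.call(cbind, lapply(head_caches, `[[`, "out"))
  colnames(pred) <- cfg$tasks
  if (with_cache)
    list(pred = pred, layers = layer_caches, heads = head_caches, z = z)
  else
    pred
}

#' Predict blood pressure for ECG segments
#'
#' @param params A `bp_model_params` (or a trained `bp_model`, via
#'   [predict.bp_model()]).
#' @param x One normalized segment (length `seq_len * step_dim`) or a batch
#'   matrix with segments in rows.
#' @param cfg The matching [model_config()].
#' @return `n x n_tasks` matrix of predictions in mmHg.
#' @export
predict_bp <- function(params, x, cfg) {
  .model_forward(params, x, cfg, with_cache = FALSE)
}

#' @export
print.bp_model_config <- function(x, ...) {
  cat(sprintf(
    "BiLSTM BP model: %d steps x %d, %d-layer trunk (hidden %d, bidirectional), heads %d-%d-1, %d task(s): %s\n",
    x$seq_len, x$step_dim, x$trunk_layers, x$hidden_size,
    x$head_hidden_1, x$head_hidden_2, x$n_tasks,
    paste(x$tasks, collapse = ", ")))
  invisible(x)
}
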