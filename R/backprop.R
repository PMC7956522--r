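# Backpropagation through the BiLSTM trunk and the task heads. Gradients
# mirror the parameter structure exactly; correctness is pinned by a
# finite-difference check in the test suite.

.zeros_like <- function(p) {
  if (is.list(p)) lapply(p, .zeros_like)
  else if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
  else numeric(length(p))
}

# elementwise combination of two parameter trees
.map2_params <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) .map2_params(f, x, y), a, b, SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    out
  } else f(a, b)
}

# BPTT through one direction; `cache` comes from .lstm_dir_forward and
# dH_ext[[t]] is the external gradient on h_t (NULL means zero)
.lstm_dir_backward <- function(cell, cache, dH_ext) {
  T_ <- length(cache)
  n <- nrow(cache[[1L]]$x); h <- ncol(cell$Wh) / 4L
  gWx <- matrix(0, nrow(cell$Wx), ncol(cell$Wx))
  gWh <- matrix(0, h, 4L * h)
  gb <- numeric(4L * h)
  dX <- vector("list", T_)
  dh_next <- matrix(0, n, h); dc_next <- matrix(0, n, h)
  for (t in rev(seq_len(T_))) {
    cc <- cache[[t]]
    dh <- dh_next
    if (!is.null(dH_ext[[t]])) dh <- dh + dH_ext[[t]]
    do_ <- dh * cc$tc
    dct <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dct * cc$g
    df <- dct * cc$cprev
    dg <- dct * cc$i
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    gWx <- gWx + crossprod(cc$x, dz)
    gWh <- gWh + crossprod(cc$hprev, dz)
    gb <- gb + colSums(dz)
    dX[[t]] <- dz %*% t(cell$Wx)
    dh_next <- dz %*% t(cell$Wh)
    dc_next <- dct * cc$f
  }
  list(g = list(Wx = gWx, Wh = gWh, b = gb), dX = dX)
}

.head_backward <- function(head, hc, dout) {
  dA2 <- (dout %*% t(head$W3)) * (hc$a2 > 0)
  dA1 <- (dA2 %*% t(head$W2)) * (hc$a1 > 0)
  list(g = list(W1 = crossprod(hc$z, dA1), b1 = colSums(dA1),
                W2 = crossprod(hc$a1, dA2), b2 = colSums(dA2),
                W3 = crossprod(hc$a2, dout), b3 = sum(dout)),
       dZ = dA1 %*% t(head$W1))
}

# full backward pass given the cached forward `fw` and dPred (n x n_tasks)
.model_backward <- function(params, fw, dPred, cfg) {
  T_ <- cfg$seq_len; h <- cfg$hidden_size
  n <- nrow(dPred)
  head_grads <- vector("list", cfg$n_tasks)
  dZ <- matrix(0, n, 2L * h)
  for (k in seq_len(cfg$n_tasks)) {
    hb <- .head_backward(params$heads[[k]], fw$heads[[k]],
                         dPred[, k, drop = FALSE])
    head_grads[[k]] <- hb$g
    dZ <- dZ + hb$dZ
  }
  names(head_grads) <- cfg$tasks

  trunk_grads <- vector("list", cfg$trunk_layers)
  # external per-step gradients entering the top layer: only the two
  # readout states carry gradient
  dH_fwd <- vector("list", T_); dH_bwd <- vector("list", T_)
  dH_fwd[[T_]] <- dZ[, 1:h, drop = FALSE]
  dH_bwd[[T_]] <- dZ[, (h + 1):(2 * h), drop = FALSE]  # processing order
  for (l in rev(seq_len(cfg$trunk_layers))) {
    lc <- fw$layers[[l]]
    bf <- .lstm_dir_backward(params$trunk[[l]]$fwd, lc$fwd$cache, dH_fwd)
    bb <- .lstm_dir_backward(params$trunk[[l]]$bwd, lc$bwd$cache, dH_bwd)
    trunk_grads[[l]] <- list(fwd = bf$g, bwd = bb$g)
    if (l > 1L) {
      # dX of the backward direction is in processing (reversed) order
      dH_fwd <- vector("list", T_); dH_bwd <- vector("list", T_)
      for (t in seq_len(T_)) {
        din <- bf$dX[[t]] + bb$dX[[T_ - t + 1L]]
        dH_fwd[[t]] <- din[, 1:h, drop = FALSE]
        dH_bwd[[T_ - t + 1L]] <- din[, (h + 1):(2 * h), drop = FALSE]
      }
    }
  }
  structure(list(trunk = trunk_grads, heads = head_grads),
            class = "bp_model_params")
}
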