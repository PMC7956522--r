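# BiLSTM trunk + heads: shapes, initialization, forward contracts, and
# exactness of the analytic gradients.

test_that("reshape is a contiguous, invertible fold", {
  cfg <- model_config(hidden_size = 64L)
  x <- as.numeric(0:999)
  steps <- reshape_segment(x, cfg)
  expect_length(steps, 20L)
  expect_equal(as.numeric(steps[[1]]), 0:49)
  expect_equal(as.numeric(steps[[20]]), 950:999)
  flat <- do.call(cbind, steps)
  expect_equal(as.numeric(flat), x)
  expect_error(reshape_segment(rnorm(999), cfg), "1000")
})

test_that("initialization is uniform in (-1/sqrt(h), 1/sqrt(h)), non-zero, seeded", {
  cfg <- model_config(hidden_size = 256L)
  p <- init_params(cfg, seed = 3L)
  vals <- unlist(rapply(p, identity, how = "unlist"))
  expect_true(all(abs(vals) < 1 / sqrt(256)))
  expect_true(all(vals != 0))
  expect_identical(init_params(cfg, seed = 3L), p)
  expect_false(identical(init_params(cfg, seed = 4L), p))
  # empirical mean of the uniform draw is 0 within 3 standard errors
  n <- length(vals)
  se <- (2 * 0.0625) / sqrt(12) / sqrt(n)
  expect_lt(abs(mean(vals)), 3 * se)
  expect_gt(n, 1e5)
})

test_that("parameter count matches the architecture arithmetic", {
  for (h in c(5L, 64L)) {
    cfg <- model_config(seq_len = 4L, step_dim = 3L, hidden_size = h)
    p <- init_params(cfg, seed = 1L)
    d <- cfg$step_dim; h1 <- cfg$head_hidden_1; h2 <- cfg$head_hidden_2
    trunk <- 4 * h * (d + h + 1) * 2 +          # layer 1, both directions
      4 * h * (2 * h + h + 1) * 2               # layer 2, both directions
    heads <- 3 * (2 * h * h1 + h1 + h1 * h2 + h2 + h2 + 1)
    expect_equal(ecgbp:::.n_params(p), trunk + heads)
  }
})

test_that("zero weights collapse predictions to the output biases", {
  cfg <- tiny_model_cfg()
  p <- init_params(cfg, seed = 5L)
  p <- rapply(p, function(a) a * 0, how = "replace")
  b3 <- c(sbp = 4.2, dbp = -1.1, map = 0.7)
  for (k in seq_along(b3)) p$heads[[k]]$b3 <- unname(b3[k])
  pred <- predict_bp(p, matrix(runif(24), 2, 12), cfg)
  expect_equal(pred[1, ], b3)
  expect_equal(pred[2, ], b3)
})

test_that("predictions are invariant to batch composition", {
  cfg <- tiny_model_cfg()
  p <- init_params(cfg, seed = 6L)
  x <- matrix(runif(5 * 12), 5, 12)
  batch <- predict_bp(p, x, cfg)
  for (i in 1:5)
    expect_equal(predict_bp(p, x[i, ], cfg)[1, ], batch[i, ], tolerance = 1e-12)
  # identical rows give identical predictions
  xx <- x[c(2, 2, 2), ]
  pp <- predict_bp(p, xx, cfg)
  expect_equal(pp[1, ], pp[2, ])
  expect_equal(pp[2, ], pp[3, ])
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, seed = 7L)
  withr::with_seed(2, {
    x <- matrix(runif(3 * 12), 3, 12)
    y <- matrix(rnorm(9, 100, 10), 3, 3)
  })
  theta <- c(0.5, 0.3, 0.2)
  loss_of <- function(p)
    joint_loss(ecgbp:::.model_forward(p, x, cfg), y, theta)$total
  fw <- ecgbp:::.model_forward(params, x, cfg, with_cache = TRUE)
  jl <- joint_loss(fw$pred, y, theta)
  dPred <- sapply(1:3, function(j)
    theta[j] * (fw$pred[, j] - y[, j]) / (nrow(x) * jl$per_task[j]))
  grads <- ecgbp:::.model_backward(params, fw, dPred, cfg)

  pluck <- function(p, path) { for (k in path) p <- p[[k]]; p }
  paths <- list(list("trunk", 1, "fwd", "Wx"), list("trunk", 1, "fwd", "Wh"),
                list("trunk", 1, "fwd", "b"), list("trunk", 1, "bwd", "Wx"),
                list("trunk", 1, "bwd", "Wh"), list("trunk", 2, "fwd", "Wx"),
                list("trunk", 2, "fwd", "Wh"), list("trunk", 2, "bwd", "Wh"),
                list("trunk", 2, "bwd", "b"), list("heads", "sbp", "W1"),
                list("heads", "dbp", "W2"), list("heads", "map", "W3"),
                list("heads", "sbp", "b1"), list("heads", "dbp", "b2"),
                list("heads", "map", "b3"))
  eps <- 1e-4
  for (path in paths) {
    arr <- pluck(params, path)
    ana <- pluck(grads, path)
    for (idx in unique(c(1L, min(9L, length(arr)), length(arr)))) {
      p_hi <- params; p_lo <- params
      hi <- arr; hi[idx] <- hi[idx] + eps
      lo <- arr; lo[idx] <- lo[idx] - eps
      assign_path <- function(p, v) {
        if (length(path) == 4) p[[path[[1]]]][[path[[2]]]][[path[[3]]]][[path[[4]]]] <- v
        else p[[path[[1]]]][[path[[2]]]][[path[[3]]]] <- v
        p
      }
      p_hi <- assign_path(p_hi, hi); p_lo <- assign_path(p_lo, lo)
      num <- (loss_of(p_hi) - loss_of(p_lo)) / (2 * eps)
      expect_lt(abs(num - ana[idx]), 1e-6 * max(1, abs(num)))
    }
  }
})
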