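# Joint loss, validation statistics, trend-based weight learning, and the
# epoch loop.

test_that("joint loss weights per-task RMSE", {
  y <- matrix(c(120, 118, 60, 61, 80, 79), 2, 3)
  expect_equal(joint_loss(y, y, rep(1 / 3, 3))$total, 0)
  p <- y; p[, 1] <- p[, 1] + c(3, -4)
  expect_equal(joint_loss(p, y, c(1, 0, 0))$total, sqrt(12.5))
  expect_equal(joint_loss(p, y, rep(1 / 3, 3))$total, sqrt(12.5) / 3)
  p2 <- y; p2[, 2] <- p2[, 2] + c(1, -1)
  expect_equal(joint_loss(p2, y, c(0, 1, 0), loss_kind = "mae")$total, 1)
  expect_error(joint_loss(p[, 1:2], y, c(1, 1)), "disagree")
  expect_error(joint_loss(matrix(Inf, 2, 3), y, rep(1, 3)), "diverged")
})

test_that("validation statistics are per-batch MAE mean and population sd", {
  # stub model whose predictions force batch MAEs of 1, 2, 3 on task 1
  x <- matrix(0, 6, 4)
  y <- cbind(c(1, 1, 2, 2, 3, 3), 0, 0)
  stub <- function(xx) matrix(0, nrow(xx), 3)
  st <- validation_stats(stub, x, y, epoch = 0L, batch_size = 2L)
  expect_equal(st$n_batches, 3L)
  expect_equal(unname(st$mean[1]), 2)
  expect_equal(unname(st$sd[1]), sqrt(2 / 3))   # population convention
  expect_equal(unname(st$mean[2]), 0)
  expect_equal(unname(st$sd[3]), 0)
  # perfect model: all means and sds zero
  st2 <- validation_stats(function(xx) xx, y, y, batch_size = 2L)
  expect_equal(unname(st2$mean), c(0, 0, 0))
  expect_equal(unname(st2$sd), c(0, 0, 0))
  expect_error(validation_stats(stub, x[1, , drop = FALSE],
                                y[1, , drop = FALSE]), "at least 2")
})

test_that("trends are relative loss changes with an epoch-sequencing guard", {
  mk <- function(epoch, m, s) structure(
    list(epoch = epoch, mean = m, sd = s, n_batches = 2L),
    class = "val_loss_stats")
  prev <- mk(3L, c(1, 2, 2), c(1, 1, 1))
  curr <- mk(4L, c(2, 2, 1), c(1, 1, 1))
  tr <- compute_trends(curr, prev)
  expect_equal(unname(tr$mean), c(0.5, 0, -1))
  expect_equal(unname(tr$sd), c(0, 0, 0))
  expect_error(compute_trends(prev, curr), "immediately after")
})

test_that("weight updates normalize importances with a uniform fallback", {
  mk_stats <- function(m, s) structure(
    list(epoch = 1L, mean = m, sd = s, n_batches = 2L),
    class = "val_loss_stats")
  mk_tr <- function(m, s) structure(list(mean = m, sd = s, epoch = 1L),
                                    class = "trend_stats")
  # symmetric inputs give exactly uniform weights
  w <- update_weights(mk_tr(c(.3, .3, .3), c(.2, .2, .2)),
                      mk_stats(c(5, 5, 5), c(1, 1, 1)))
  expect_equal(unname(w), rep(1 / 3, 3))
  # r = (2, 1, 1) normalizes to (1/2, 1/4, 1/4)
  w2 <- update_weights(mk_tr(c(2, 1, 1), c(1, 1, 1)),
                       mk_stats(c(1, 1, 1), c(0, 0, 0)))
  expect_equal(unname(w2), c(0.5, 0.25, 0.25))
  # mixed-sign trends still give a convex combination
  withr::with_seed(10, {
    for (i in 1:25) {
      w3 <- update_weights(mk_tr(rnorm(3), rnorm(3)),
                           mk_stats(abs(rnorm(3)), abs(rnorm(3))))
      expect_equal(sum(w3), 1)
      expect_true(all(w3 >= 0))
    }
  })
  # vanished importances fall back to uniform
  w4 <- update_weights(mk_tr(c(0, 0, 0), c(1, 1, 1)),
                       mk_stats(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(unname(w4), rep(1 / 3, 3))
})

test_that("task weights start at exactly 1/3 and stay on the simplex", {
  lab <- tiny_labeled_data()
  fit <- train_bp_model(lab, tiny_model_cfg(),
                        train_config(max_epochs = 6L, batch_size = 8L,
                                     seed = 2L))
  th <- as.matrix(fit$log[, c("theta_sbp", "theta_dbp", "theta_map")])
  expect_equal(unname(th[1, ]), rep(1 / 3, 3))   # epoch 0: no adaptation yet
  expect_equal(unname(rowSums(th)), rep(1, nrow(th)), tolerance = 1e-9)
  expect_true(all(th >= 0))
})

test_that("a frozen model yields zero trends and the uniform fallback", {
  lab <- tiny_labeled_data()
  fit <- train_bp_model(lab, tiny_model_cfg(),
                        train_config(learning_rate = 1e-30, weight_decay = 0,
                                     max_epochs = 4L, batch_size = 64L,
                                     seed = 3L))
  th <- as.matrix(fit$log[, c("theta_sbp", "theta_dbp", "theta_map")])
  # from the second adapted epoch on, losses are static -> uniform weights
  expect_equal(unname(th[3, ]), rep(1 / 3, 3), tolerance = 1e-9)
  expect_equal(unname(th[4, ]), rep(1 / 3, 3), tolerance = 1e-9)
})

test_that("training is reproducible and ablation modes fix the weights", {
  lab <- tiny_labeled_data()
  cfg <- train_config(max_epochs = 4L, batch_size = 8L, seed = 9L)
  f1 <- train_bp_model(lab, tiny_model_cfg(), cfg)
  f2 <- train_bp_model(lab, tiny_model_cfg(), cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params, f2$params)

  uni <- train_bp_model(lab, tiny_model_cfg(),
                        train_config(max_epochs = 3L, batch_size = 8L,
                                     seed = 9L, uniform_weights = TRUE))
  expect_true(all(as.matrix(uni$log[, c("theta_sbp", "theta_dbp",
                                        "theta_map")]) == 1))

  single <- train_bp_model(lab, tiny_model_cfg(),
                           train_config(max_epochs = 3L, batch_size = 8L,
                                        seed = 9L, single_task = "dbp"))
  expect_equal(single$model_cfg$tasks, "dbp")
  expect_equal(ncol(predict(single, lab$x[1:2, ])), 1L)
  # single-task trunk has the same parameter count as the multitask trunk
  count_trunk <- function(fit)
    sum(rapply(fit$params$trunk, length, how = "unlist"))
  expect_equal(count_trunk(single), count_trunk(f1))
})

test_that("the plateau schedule decays the learning rate on stalls", {
  lab <- tiny_labeled_data()
  fit <- train_bp_model(lab, tiny_model_cfg(),
                        train_config(learning_rate = 1e-30, weight_decay = 0,
                                     lr_patience = 2L, max_epochs = 6L,
                                     batch_size = 64L, seed = 4L))
  lrs <- fit$log$lr
  # loss never improves after epoch 0 -> decay every `patience` epochs
  expect_lt(lrs[6], lrs[1])
  expect_equal(sort(unique(round(lrs / 1e-30, 6)), decreasing = TRUE)[2], 0.9)
})
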