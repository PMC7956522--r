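# Shared fixtures, built in code at test time.

# tiny architecture for fast exact checks (12-sample "segments")
tiny_model_cfg <- function(n_tasks = 3L) {
  model_config(seq_len = 4L, step_dim = 3L, hidden_size = 5L,
               n_tasks = n_tasks)
}

# hand-built labeled dataset on the tiny architecture: targets are a fixed
# linear readout of the inputs plus an offset, so a mapping exists
tiny_labeled_data <- function(n = 40L, seed = 123L, p = 12L) {
  withr::with_seed(seed, {
    x <- matrix(runif(n * p), n, p)
    w <- matrix(c(30, -20, 15), nrow = 1)
    base <- x %*% matrix(runif(p * 3, -1, 1), p, 3)
    y <- sweep(base * 10, 2, c(120, 60, 80), `+`)
    colnames(y) <- c("sbp", "dbp", "map")
    split <- rep("train", n)
    split[seq_len(max(2L, round(0.2 * n)))] <- "val"
    split[n - seq_len(max(2L, round(0.1 * n))) + 1L] <- "test"
    structure(list(x = x, y = y, qc = rep(TRUE, n),
                   meta = data.frame(record_id = seq_len(n) - 1L,
                                     split = split,
                                     start_index = 1L)),
              class = "labeled_bp_data")
  })
}

# one small synthetic cohort reused across label/pipeline tests
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_dataset(sim_config(n_records = 12L, duration_s = 30,
                                        seed = 77L))
    }
    cache
  }
})

expect_all_close <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
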