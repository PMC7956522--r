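# Error metrics, cumulative percentages, BHS/AAMI verdicts and the two
# Bland-Altman variants.

test_that("error metrics match hand computation", {
  m0 <- error_metrics(c(120, 60), c(120, 60))
  expect_equal(c(m0$merr, m0$maerr, m0$rmserr), c(0, 0, 0))
  m1 <- error_metrics(c(103, 57), c(100, 60))   # errors +3, -3
  expect_equal(c(m1$merr, m1$maerr, m1$rmserr), c(0, 3, 3))
  m2 <- error_metrics(c(103, 104), c(100, 100)) # errors 3, 4
  expect_equal(c(m2$merr, m2$maerr, m2$rmserr), c(3.5, 3.5, sqrt(12.5)))
  expect_error(error_metrics(numeric(0), numeric(0)), "non-empty")
})

test_that("RMSErr >= MAErr >= |MErr| on random data", {
  withr::with_seed(14, {
    for (i in 1:50) {
      y <- rnorm(30, 100, 20); p <- y + rnorm(30, sd = runif(1, 0.1, 15))
      m <- error_metrics(y, p)
      expect_gte(m$rmserr, m$maerr)
      expect_gte(m$maerr, abs(m$merr))
    }
  })
})

test_that("cumulative percentages count inclusively and are monotone", {
  y <- c(0, 0, 0, 0)
  p <- -c(4, 6, 14, 20)
  expect_equal(unname(cumulative_percentages(y, p)), c(25, 50, 75))
  expect_equal(unname(cumulative_percentages(c(5), c(0))), c(100, 100, 100))
  expect_equal(unname(cumulative_percentages(y, y)), c(100, 100, 100))
  withr::with_seed(15, {
    for (i in 1:25) {
      y <- rnorm(40, 100, 10); p <- y + rnorm(40, sd = runif(1, 1, 12))
      cp <- cumulative_percentages(y, p)
      expect_true(cp[1] <= cp[2] && cp[2] <= cp[3])
      expect_true(all(cp >= 0 & cp <= 100))
    }
  })
})

test_that("BHS grading applies the published thresholds inclusively", {
  expect_equal(bhs_grade(c(71.52, 89.56, 95.03)), "A")  # DBP-like CP table: grade A
  expect_equal(bhs_grade(c(70.03, 88.07, 94.12)), "B")  # MAP-like CP table: grade B
  expect_equal(bhs_grade(c(53.05, 76.56, 86.64)), "C")  # SBP-like CP table: grade C
  expect_equal(bhs_grade(c(60, 85, 95)), "A")           # inclusive boundary
  expect_equal(bhs_grade(c(39, 100, 100)), "fail")
  # monotone: raising any CP never worsens the grade
  rank <- c(A = 1, B = 2, C = 3, fail = 4)
  withr::with_seed(16, {
    for (i in 1:40) {
      cp <- sort(runif(3, 30, 100))
      bump <- pmin(cp + c(runif(1, 0, 20), 0, 0), 100)
      bump <- cummax(bump)
      expect_lte(rank[bhs_grade(bump)], rank[bhs_grade(cp)])
    }
  })
})

test_that("AAMI verdicts respect the inclusive bounds in both modes", {
  mk <- function(me, mae, sd = 0) structure(
    list(merr = me, maerr = mae, rmserr = mae, sd_err = sd, n = 100L),
    class = "bp_error_metrics")
  expect_equal(aami_check(mk(0.13, 4.36)), "pass")  # typical good DBP metrics
  expect_equal(aami_check(mk(5, 8)), "pass")
  expect_equal(aami_check(mk(6, 4)), "fail")
  expect_equal(aami_check(mk(-5.1, 4)), "fail")
  expect_equal(aami_check(mk(0, 10, sd = 7), mode = "strict"), "pass")
  expect_equal(aami_check(mk(0, 4, sd = 9), mode = "strict"), "fail")
})

test_that("Bland-Altman statistics and sign convention", {
  y <- c(100, 110, 120, 130)
  ba <- bland_altman(y, y + 2)
  expect_equal(ba$mean_diff, 2)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$lower_loa, ba$upper_loa), c(2, 2))
  expect_equal(ba$export$x, y + 1)
  # sd_diff of 10.83 gives a limits half-width matching the reported 21.22
  a <- 10.83 / sqrt(2)
  ba2 <- bland_altman(c(100, 100), c(100 + a, 100 - a))
  expect_equal(ba2$sd_diff, 10.83)
  expect_lt(abs((ba2$upper_loa - ba2$mean_diff) - 21.22), 0.02)
  # overestimation gives positive differences
  withr::with_seed(17, {
    y <- rnorm(20, 100, 10)
    expect_gt(bland_altman(y, y + abs(rnorm(20)))$mean_diff, 0)
  })
  expect_error(bland_altman(1, 1), "length >= 2")
})

test_that("variant Bland-Altman uses truth on the x-axis, same statistics", {
  withr::with_seed(18, {
    y <- rnorm(15, 120, 5); p <- y + rnorm(15, sd = 3)
  })
  ba <- bland_altman(y, p)
  vb <- variant_bland_altman(y, p)
  expect_equal(vb$mean_diff, ba$mean_diff)
  expect_equal(vb$sd_diff, ba$sd_diff)
  expect_equal(vb$export$x, y)
  expect_equal(vb$export$diff, ba$export$diff)
  expect_equal(variant_bland_altman(y, y)$export$diff, rep(0, 15))
  cluster <- variant_bland_altman(rep(120, 5), rep(120, 5) + 1:5)
  expect_true(all(cluster$export$x == 120))
})

test_that("the full report is internally consistent and serializable", {
  withr::with_seed(19, {
    truth <- cbind(sbp = rnorm(60, 120, 10), dbp = rnorm(60, 60, 6),
                   map = rnorm(60, 80, 7))
    pred <- truth + rnorm(180, sd = 4)
  })
  rep <- evaluate_bp(truth, pred)
  expect_named(rep$tasks, c("sbp", "dbp", "map"))
  for (tk in rep$tasks) {
    expect_equal(tk$bhs, bhs_grade(tk$cp))
    expect_gte(tk$metrics$rmserr, tk$metrics$maerr)
  }
  dir <- withr::local_tempdir()
  write_eval_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  parsed <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(parsed$sbp$bhs_grade, rep$tasks$sbp$bhs)
  expect_true(file.exists(file.path(dir, "variant_bland_altman_map.csv")))
})
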