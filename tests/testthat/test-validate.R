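# The statistical validation battery.

test_that("coefficient of determination behaves at its anchors", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 5)), 0)
  # worked 5-point set vs hand arithmetic
  yh <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  expect_equal(r_squared(y, yh),
               1 - sum((y - yh)^2) / sum((y - mean(y))^2))
  expect_error(r_squared(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("hat-matrix LOO q2 equals explicit n-refit LOO", {
  for (seed in 1:10) {
    tbl <- random_table(20, 2, seed = 300 + seed)
    X <- as.matrix(tbl[, descriptor_names(tbl)])
    y <- tbl$log_ic50
    got <- q2_loo(X, y)
    # brute-force oracle: refit n times
    press <- 0
    for (i in seq_len(nrow(X))) {
      f <- lm.fit(cbind(1, X[-i, , drop = FALSE]), y[-i])
      pred <- c(1, X[i, ]) %*% f$coefficients
      press <- press + (y[i] - pred)^2
    }
    expect_equal(got$press, as.numeric(press), tolerance = 1e-10)
    expect_equal(got$q2, 1 - as.numeric(press) / sum((y - mean(y))^2),
                 tolerance = 1e-10)
  }
})

test_that("LOO q2 handles exact and degenerate inputs", {
  x <- matrix(1:12, ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(q2_loo(x, as.vector(3 * x + 1))$q2, 1)
  expect_error(q2_loo(x, rep(2, 12)), "zero variance")
})

test_that("external pred_r2 is referenced to the training mean", {
  tbl <- random_table(30, 2, seed = 77)
  X <- as.matrix(tbl[, descriptor_names(tbl)])
  m <- fit_mlr(X, tbl$log_ic50)
  test_tbl <- random_table(10, 2, seed = 78)
  got <- pred_r2(m, test_tbl)
  y <- test_tbl$log_ic50
  yh <- predict(m, test_tbl)$pred_log_ic50
  expect_equal(got$pred_r2,
               1 - sum((y - yh)^2) / sum((y - mean(tbl$log_ic50))^2),
               tolerance = 1e-12)
  # perfect predictions give 1
  perf <- test_tbl
  perf$log_ic50 <- yh
  expect_equal(pred_r2(m, perf)$pred_r2, 1)
})

test_that("rm2 battery matches its anchors and a spreadsheet-style oracle", {
  y <- c(0.2, 0.9, 1.4, 2.1, 3.0)
  res <- rm2_battery(y, y)
  expect_equal(res$rm2_avg, 1)
  expect_equal(res$rm2_delta, 0)

  yp <- c(0.4, 0.8, 1.6, 1.9, 3.2)
  got <- rm2_battery(y, yp)
  # independent arithmetic, both directions
  dir_rm2 <- function(x, yy) {
    r2 <- cor(x, yy)^2
    k <- sum(x * yy) / sum(x^2)
    r02 <- 1 - sum((yy - k * x)^2) / sum((yy - mean(yy))^2)
    r2 * (1 - sqrt(abs(r2 - r02)))
  }
  f <- dir_rm2(yp, y); r <- dir_rm2(y, yp)
  expect_equal(got$rm2_avg, (f + r) / 2, tolerance = 1e-9)
  expect_equal(got$rm2_delta, abs(f - r), tolerance = 1e-9)
  expect_error(rm2_battery(rep(1, 4), rep(1, 4)), "zero-variance")
})

test_that("F statistic follows its definition and flags perfect fits", {
  tbl <- random_table(25, 3, seed = 55)
  X <- as.matrix(tbl[, descriptor_names(tbl)])
  m <- fit_mlr(X, tbl$log_ic50)
  fs <- f_statistic(m)
  n <- 25; k <- 3
  ssres <- sum(m$fit_stats$residuals^2)
  ssreg <- sum((m$fit_stats$fitted - mean(tbl$log_ic50))^2)
  expect_equal(fs$F, (ssreg / k) / (ssres / (n - k - 1)), tolerance = 1e-10)
  expect_equal(fs$df, n - k - 1)
  expect_false(fs$perfect_fit)

  x <- matrix(1:10, ncol = 1)
  mp <- fit_mlr(x, as.vector(2 * x))
  expect_true(f_statistic(mp)$perfect_fit)
  expect_equal(f_statistic(mp)$F, Inf)
})

test_that("F stays small when the truth is pure noise", {
  fs <- vapply(1:100, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(30 * 2), 30, 2)
    fit_mlr(X, rnorm(30))$fit_stats$F
  }, numeric(1))
  expect_lt(median(fs), 3)
})

test_that("Y-randomization is seeded, detects signal, and rejects scrambles", {
  set.seed(123)
  n <- 100
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1.2 * X[, 1] - 0.8 * X[, 2] + rnorm(n, 0, 0.05)
  r1 <- y_randomization(X, y, n_trials = 99, seed = 42)
  r2 <- y_randomization(X, y, n_trials = 99, seed = 42)
  expect_identical(r1, r2)
  expect_equal(r1$alpha, 1 / 100)
  expect_gt(r1$zscore_r2, 3)
  expect_lt(r1$best_ran_r2, r1$actual_r2)

  expect_error(y_randomization(X, rep(1, n), n_trials = 10), "constant")
  expect_error(y_randomization(X, y, n_trials = 0), "n_trials")
})

test_that("randomization can rerun stepwise selection inside each trial", {
  tbl <- sim_model3_table(n = 60, k_noise = 3, seed = 5)
  X <- as.matrix(tbl[, descriptor_names(tbl)])
  res <- y_randomization(X, tbl$log_ic50,
                         model_builder = stepwise_builder(max_terms = 3),
                         n_trials = 19, seed = 9)
  expect_equal(res$alpha, 1 / 20)
  expect_gt(res$actual_r2, res$best_ran_r2)
})

test_that("standard errors are RMSEs with the documented denominators", {
  tbl <- random_table(30, 2, seed = 66)
  X <- as.matrix(tbl[, descriptor_names(tbl)])
  y <- tbl$log_ic50
  m <- fit_mlr(X, y)
  q2c <- q2_loo(X, y)
  test_tbl <- random_table(12, 2, seed = 67)
  prc <- pred_r2(m, test_tbl)
  se <- standard_errors(m, q2c, prc)
  expect_equal(se$r2_se, sqrt(sum(m$fit_stats$residuals^2) / (30 - 2 - 1)))
  expect_equal(se$q2_se, sqrt(q2c$press / 30))
  expect_equal(se$pred_r2_se, sqrt(sum(prc$residuals^2) / 12))
  # homogeneity: scaling residuals scales the RMSE linearly
  m2 <- fit_mlr(X, m$fit_stats$fitted + 2 * m$fit_stats$residuals)
  expect_equal(standard_errors(m2)$r2_se, 2 * se$r2_se, tolerance = 1e-8)
})

test_that("the assembled report is invariant under row permutation", {
  tbl <- random_table(40, 3, seed = 44)
  perm <- tbl[sample(nrow(tbl)), ]
  attr(perm, "descriptor_names") <- descriptor_names(tbl)
  class(perm) <- class(tbl)
  r1 <- validate_model(tbl, n_random_trials = 19, seed = 3)
  r2 <- validate_model(perm, n_random_trials = 19, seed = 3)
  for (f in c("r2", "q2_loo", "df", "f_stat", "r2_se", "q2_se"))
    expect_equal(r1[[f]], r2[[f]], tolerance = 1e-10, info = f)
})

test_that("the full battery produces a coherent report on a real split", {
  tbl <- sim_model3_table(n = 120, k_noise = 2, seed = 31)
  split <- sphere_exclusion_split(tbl, sphere_radius_for_fraction(
    tbl, 0.8)$radius, seed = 1)
  train <- tbl[tbl$compound_id %in% split$train_ids, ]
  test <- tbl[tbl$compound_id %in% split$test_ids, ]
  for (x in list(train, test)) {
    attr(x, "descriptor_names") <- descriptor_names(tbl)
  }
  attr(train, "descriptor_names") <- descriptor_names(tbl)
  attr(test, "descriptor_names") <- descriptor_names(tbl)
  class(train) <- class(test) <- class(tbl)
  m <- suppressWarnings(stepwise_forward(train, max_terms = 3))
  rep_ <- validate_model(train, test, model = m, n_random_trials = 49,
                         seed = 11)
  expect_gt(rep_$r2, 0.9)          # planted signal, low noise
  expect_gt(rep_$q2_loo, 0.9)
  expect_gt(rep_$pred_r2, 0.8)
  expect_equal(rep_$df, nrow(train) - m$fit_stats$k - 1)
  expect_equal(rep_$alpha, 1 / 50)
  expect_equal(rep_$ad_outlier_count,
               sum(applicability_flag(m, test)))
  expect_output(print(rep_), "alpha_test")
})
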