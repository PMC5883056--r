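# MLR fitting, stepwise-forward selection, the frozen published equations,
# prediction and the applicability domain.

test_that("OLS fit recovers exact linear data and rejects bad inputs", {
  x <- matrix(1:10, ncol = 1, dimnames = list(NULL, "x"))
  m <- fit_mlr(x, 2 * (1:10))
  expect_equal(unname(m$coefficients), 2, tolerance = 1e-12)
  expect_equal(m$intercept, 0, tolerance = 1e-10)
  expect_equal(m$fit_stats$r2, 1)

  X <- cbind(a = rnorm(10), b = 0)
  X[, "b"] <- X[, "a"]
  expect_error(fit_mlr(X, rnorm(10)), "collinear")
  expect_error(fit_mlr(matrix(rnorm(6), 3, 2), rnorm(3)),
               "degrees-of-freedom")
})

test_that("OLS coefficients match a normal-equations oracle", {
  set.seed(99)
  n <- 200
  X <- cbind(x1 = runif(n), x2 = rnorm(n))
  y <- 0.3 + 1.5 * X[, 1] - 0.7 * X[, 2] + rnorm(n, 0, 0.05)
  m <- fit_mlr(X, y)
  # independent oracle: solve the normal equations directly
  Xi <- cbind(1, X)
  beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)[, 1]
  expect_equal(m$intercept, unname(beta[1]), tolerance = 1e-8)
  expect_equal(unname(m$coefficients), unname(beta[-1]), tolerance = 1e-8)
  # hat diagonal equals the closed-form X(X'X)^-1 X' diagonal
  H <- Xi %*% solve(t(Xi) %*% Xi) %*% t(Xi)
  expect_equal(m$fit_stats$hat, diag(H), tolerance = 1e-10)
  # F statistic agrees with summary.lm
  sf <- summary(lm(y ~ X))
  expect_equal(m$fit_stats$F, unname(sf$fstatistic[1]), tolerance = 1e-8)
  expect_equal(m$fit_stats$r2, sf$r.squared, tolerance = 1e-12)
})

test_that("stepwise selection finds a single planted descriptor", {
  set.seed(17)
  n <- 100
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("d", 1:10)))
  y <- 2 * X[, "d4"] + rnorm(n, 0, 0.3)
  m <- stepwise_forward(X, y, max_terms = 1)
  # oracle: exhaustive size-1 search over all columns
  rss1 <- vapply(colnames(X), function(cl)
    sum(lm.fit(cbind(1, X[, cl]), y)$residuals^2), numeric(1))
  expect_equal(m$descriptor_names, names(which.min(rss1)))
  expect_equal(m$descriptor_names, "d4")
})

test_that("stepwise on pure noise stays intercept-only almost always", {
  # with two candidate columns the F-to-enter = 4 gate admits a spurious
  # descriptor with chance ~1 - (1 - 0.05)^2, so ~90% of runs stay empty
  intercept_only <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    X <- matrix(rnorm(40 * 2), 40, 2)
    y <- rnorm(40)
    m <- suppressWarnings(stepwise_forward(X, y, f_to_enter = 4))
    if (length(m$descriptor_names) == 0L)
      intercept_only <- intercept_only + 1L
  }
  expect_gte(intercept_only, 90L)
})

test_that("stepwise respects max_terms and the correlation gate", {
  tbl <- sim_model3_table(seed = 2)
  X <- as.matrix(tbl[, descriptor_names(tbl)])
  m0 <- suppressWarnings(
    stepwise_forward(X, tbl$log_ic50, max_terms = 0))
  expect_length(m0$descriptor_names, 0L)
  expect_equal(m0$intercept, mean(tbl$log_ic50))

  # with a duplicated informative column the gate admits only one copy
  X2 <- cbind(X, dup = X[, "T_O_O_3"])
  m <- stepwise_forward(X2, tbl$log_ic50, corr_cutoff = 0.7)
  expect_length(intersect(c("T_O_O_3", "dup"), m$descriptor_names), 1L)
})

test_that("published equations carry exactly the printed coefficients", {
  m1 <- published_model("model1")
  expect_equal(m1$coefficients,
               c("DeltaEpsilonC" = -39.0090, "MMFF_29" = -0.8078,
                 "SssssCcount" = -1.0827, "T_2_2_1" = -0.0483,
                 "SdsCHE-index" = 0.5053))
  expect_equal(m1$intercept, -0.0560)

  m2 <- published_model("model2")
  expect_equal(m2$coefficients,
               c("SdssCE-index" = -0.6407, "T_2_2_2" = -0.0336,
                 "H-AcceptorCount" = -0.1278, "SdsCHE-index" = 0.2226,
                 "T_O_O_3" = 0.5877))
  expect_equal(m2$intercept, 0.5940)

  m3 <- published_model("model3")
  expect_equal(m3$coefficients,
               c("T_T_N_4" = 0.0948, "T_O_O_3" = 0.5217,
                 "SssssCE-index" = 0.3687))
  expect_equal(m3$intercept, 1.1313)

  expect_error(published_model("model9"), "valid ids")
})

test_that("prediction is affine with exact micromolar back-transform", {
  m3 <- published_model("model3")
  zero <- setNames(rep(0, 3), m3$descriptor_names)
  p0 <- predict(m3, zero)
  expect_equal(p0$pred_log_ic50, 1.1313)
  expect_equal(p0$pred_ic50_uM, 10^1.1313)

  ones <- setNames(rep(1, 3), m3$descriptor_names)
  expect_equal(predict(m3, ones)$pred_log_ic50, 2.1165, tolerance = 1e-12)

  # three-point collinearity (affinity)
  v1 <- setNames(c(1, 2, -0.5), m3$descriptor_names)
  v2 <- setNames(c(3, 0, 1.5), m3$descriptor_names)
  a <- 0.3
  mid <- a * v1 + (1 - a) * v2
  expect_equal(predict(m3, mid)$pred_log_ic50,
               a * predict(m3, v1)$pred_log_ic50 +
                 (1 - a) * predict(m3, v2)$pred_log_ic50,
               tolerance = 1e-12)

  expect_error(predict(m3, data.frame(T_T_N_4 = 1)), "missing descriptor")
})

test_that("model JSON round-trips with ranges intact", {
  tbl <- random_table(30, 3, seed = 8)
  m <- fit_mlr(as.matrix(tbl[, descriptor_names(tbl)]), tbl$log_ic50)
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_equal(back$coefficients, m$coefficients, tolerance = 1e-12)
  expect_equal(back$intercept, m$intercept, tolerance = 1e-12)
  expect_equal(back$ranges$min, unname(m$ranges$min), tolerance = 1e-12)
})

test_that("applicability flag uses inclusive training ranges", {
  tbl <- random_table(30, 2, seed = 4)
  X <- as.matrix(tbl[, descriptor_names(tbl)])
  m <- fit_mlr(X, tbl$log_ic50)
  expect_equal(applicability_flag(m, tbl), rep(0L, nrow(tbl)))
  at_max <- setNames(apply(X, 2, max), colnames(X))
  expect_equal(applicability_flag(m, at_max), 0L)
  above <- at_max; above[1] <- above[1] + 1e-6
  expect_equal(applicability_flag(m, above), 1L)
  expect_identical(applicability_flag(published_model("model3"),
                                      setNames(rep(0, 3),
                                               published_model("model3")$descriptor_names)),
                   "unavailable")
})

test_that("stepwise recovers the frozen U251 coefficients from simulation", {
  ok_subset <- 0L; ok_coef <- 0L
  m3 <- published_model("model3")
  for (seed in 1:25) {
    tbl <- sim_model3_table(n = 150, noise_sd = 0.1, seed = 1000 + seed)
    m <- suppressWarnings(stepwise_forward(tbl, max_terms = 3))
    if (setequal(m$descriptor_names, names(m3$coefficients))) {
      ok_subset <- ok_subset + 1L
      if (all(abs(m$coefficients[names(m3$coefficients)] -
                    m3$coefficients) <= 0.05))
        ok_coef <- ok_coef + 1L
    }
  }
  expect_gte(ok_subset, 24L)
  expect_gte(ok_coef, 24L)
})
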