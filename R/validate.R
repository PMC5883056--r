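# The twelve-item statistical validation battery: r2, LOO q2, external
# pred_r2, rm2 metrics, F test, Y-randomization statistics, standard errors
# and the applicability-domain outlier count.

#' Coefficient of determination
#'
#' r2 = 1 - SSres/SStot of predictions against observations.
#'
#' @param y Observed values (>= 3, non-constant).
#' @param y_hat Predicted values.
#' @return r2 (at most 1; can be negative for predictions worse than the
#'   mean).
#' @export
r_squared <- function(y, y_hat) {
  if (length(y) < 3L || length(y) != length(y_hat))
    stop("need >= 3 paired points")
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) stop("undefined: observed values have zero variance")
  1 - sum((y - y_hat)^2) / sstot
}

#' Leave-one-out cross-validated q2 via the hat matrix
#'
#' PRESS = sum((e_i / (1 - h_ii))^2) from a single OLS fit; q2 = 1 -
#' PRESS/SStot. Algebraically identical to refitting the model n times with
#' one row held out each time (the closed-form LOO identity for linear
#' models).
#'
#' @param X Descriptor matrix.
#' @param y Activity vector.
#' @return List with `q2`, `press`, `sstot` and the per-row LOO residuals
#'   `loo_residuals`.
#' @export
q2_loo <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 2L) stop("need n > k + 2 for LOO cross-validation")
  fit <- fit_mlr(X, y)
  h <- fit$fit_stats$hat
  if (any(h >= 1 - 1e-12))
    stop("influential point: hat value of 1 at row ",
         paste(which(h >= 1 - 1e-12), collapse = ", "))
  loo_res <- fit$fit_stats$residuals / (1 - h)
  press <- sum(loo_res^2)
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) stop("undefined: observed values have zero variance")
  list(q2 = 1 - press / sstot, press = press, sstot = sstot,
       loo_residuals = loo_res)
}

#' External predictivity pred_r2
#'
#' pred_r2 = 1 - sum((y_test - y_hat)^2) / sum((y_test - mean(y_train))^2):
#' squared-error skill of the model on the held-out test set, referenced to
#' the training-set activity mean.
#'
#' @param model A `qsar_model`.
#' @param test_table An `activity_table` of test compounds (non-empty).
#' @param train_mean Mean training activity; defaults to the mean stored in
#'   the fitted model.
#' @return List with `pred_r2`, `residuals`, `n_test`.
#' @export
pred_r2 <- function(model, test_table, train_mean = NULL) {
  stopifnot(inherits(model, "qsar_model"),
            inherits(test_table, "activity_table"))
  if (nrow(test_table) == 0L) stop("test set is empty")
  if (is.null(train_mean)) {
    if (is.null(model$fit_stats)) stop("supply 'train_mean'")
    train_mean <- mean(model$fit_stats$y)
  }
  y <- test_table$log_ic50
  y_hat <- predict(model, test_table)$pred_log_ic50
  den <- sum((y - train_mean)^2)
  if (den == 0)
    stop("undefined: test activities all equal the training mean")
  list(pred_r2 = 1 - sum((y - y_hat)^2) / den,
       residuals = y - y_hat, n_test = length(y))
}

# squared Pearson correlation and the through-origin r0^2 of y on x
.r2_r02 <- function(x, y) {
  r2 <- stats::cor(x, y)^2
  k <- sum(x * y) / sum(x * x)          # slope-only least squares
  r02 <- 1 - sum((y - k * x)^2) / sum((y - mean(y))^2)
  c(r2 = r2, r02 = r02)
}

#' rm2 metrics (observed vs predicted, both axis orders)
#'
#' rm2 = r2 * (1 - sqrt(|r2 - r0^2|)), where r2 is the squared correlation
#' of observed and predicted values and r0^2 comes from the corresponding
#' through-origin fit; computed with observed on each axis in turn. Reports
#' the average and the absolute difference of the two directions. Values near
#' the average of 1 / delta of 0 indicate predictions falling on the
#' identity line.
#'
#' @param y_obs Observed activities (>= 3, non-constant).
#' @param y_pred Predicted activities.
#' @return List with `rm2_avg`, `rm2_delta`, `rm2_forward`, `rm2_reverse`.
#' @export
rm2_battery <- function(y_obs, y_pred) {
  if (length(y_obs) < 3L || length(y_obs) != length(y_pred))
    stop("need >= 3 paired points")
  if (stats::sd(y_obs) == 0 || stats::sd(y_pred) == 0)
    stop("undefined: zero-variance input")
  f <- .r2_r02(y_pred, y_obs)   # forward: predicted explains observed
  r <- .r2_r02(y_obs, y_pred)   # reverse: axes interchanged
  rm2_f <- f["r2"] * (1 - sqrt(abs(f["r2"] - f["r02"])))
  rm2_r <- r["r2"] * (1 - sqrt(abs(r["r2"] - r["r02"])))
  list(rm2_avg = unname((rm2_f + rm2_r) / 2),
       rm2_delta = unname(abs(rm2_f - rm2_r)),
       rm2_forward = unname(rm2_f), rm2_reverse = unname(rm2_r))
}

#' F statistic of a fitted model
#'
#' F = (SSreg/k) / (SSres/(n-k-1)) with df = n - k - 1. A perfect fit
#' (SSres = 0) is reported as `Inf` with `perfect_fit = TRUE`.
#'
#' @param fit A `qsar_model` from [fit_mlr()] or [stepwise_forward()].
#' @return List with `F`, `df`, `k`, `perfect_fit`.
#' @export
f_statistic <- function(fit) {
  stopifnot(inherits(fit, "qsar_model"))
  fs <- fit$fit_stats
  if (is.null(fs)) stop("model carries no fit statistics")
  list(F = fs$F, df = fs$df, k = fs$k, perfect_fit = fs$ssres == 0)
}

#' Y-randomization (activity scrambling) test
#'
#' Permutes the activity vector `n_trials` times and reruns the full
#' model-building pipeline each time, recording the random-model r2 and LOO
#' q2. Reports the best random statistics, Z-scores of the actual model
#' against the random distribution, and the empirical (add-one smoothed)
#' p-value `alpha = (#\{random r2 >= actual r2\} + 1)/(n_trials + 1)`.
#'
#' @param X Descriptor matrix or `activity_table`.
#' @param y Activity vector (ignored when `X` is an `activity_table`).
#' @param model_builder Function `(X, y)` returning a list with at least
#'   `r2` and `q2`; the default fits all supplied columns by OLS. Use
#'   [stepwise_builder()] to rerun descriptor selection inside every trial.
#' @param n_trials Number of permutations (>= 1; default 100).
#' @param seed Integer seed.
#' @return List: `best_ran_r2`, `best_ran_q2`, `zscore_r2`, `zscore_q2`,
#'   `alpha`, `n_trials`, `actual_r2`, `actual_q2`, `random_r2`, `random_q2`.
#' @export
y_randomization <- function(X, y = NULL, model_builder = NULL,
                            n_trials = 100L, seed = 1L) {
  if (inherits(X, "activity_table")) { y <- X$log_ic50; X <- .desc_matrix(X) }
  X <- as.matrix(X)
  if (n_trials < 1L) stop("'n_trials' must be >= 1")
  if (stats::sd(y) == 0) stop("activity vector is constant")
  if (is.null(model_builder)) model_builder <- mlr_builder()
  actual <- model_builder(X, y)
  set.seed(as.integer(seed))
  r2s <- q2s <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    res <- model_builder(X, sample(y))
    r2s[t] <- res$r2; q2s[t] <- res$q2
  }
  list(best_ran_r2 = max(r2s), best_ran_q2 = max(q2s),
       zscore_r2 = (actual$r2 - mean(r2s)) / stats::sd(r2s),
       zscore_q2 = (actual$q2 - mean(q2s)) / stats::sd(q2s),
       alpha = (sum(r2s >= actual$r2) + 1) / (n_trials + 1),
       n_trials = n_trials,
       actual_r2 = actual$r2, actual_q2 = actual$q2,
       random_r2 = r2s, random_q2 = q2s)
}

#' Model builders for the randomization test
#'
#' `mlr_builder()` fits all supplied descriptor columns by OLS;
#' `stepwise_builder()` reruns the full stepwise-forward selection inside
#' every randomization trial (the honest variant: chance gets the same
#' freedom to pick descriptors the real model had).
#'
#' @param f_to_enter,max_terms,corr_cutoff Passed to [stepwise_forward()].
#' @return A function `(X, y)` returning a list with `r2`, `q2` and `model`.
#' @export
mlr_builder <- function() {
  function(X, y) {
    m <- fit_mlr(X, y)
    q2 <- tryCatch(q2_loo(X, y)$q2, error = function(e) NA_real_)
    list(r2 = m$fit_stats$r2, q2 = q2, model = m)
  }
}

#' @rdname mlr_builder
#' @export
stepwise_builder <- function(f_to_enter = 4, max_terms = NULL,
                             corr_cutoff = 0.7) {
  function(X, y) {
    m <- suppressWarnings(
      stepwise_forward(X, y, f_to_enter = f_to_enter, max_terms = max_terms,
                       corr_cutoff = corr_cutoff))
    q2 <- if (length(m$descriptor_names) == 0L) 0 else
      tryCatch(q2_loo(X[, m$descriptor_names, drop = FALSE], y)$q2,
               error = function(e) NA_real_)
    list(r2 = m$fit_stats$r2, q2 = q2, model = m)
  }
}

#' Standard errors of estimate
#'
#' RMSE of the fitted, leave-one-out and external residual sets with
#' denominators n - k - 1, n and n_test respectively.
#'
#' @param fit A fitted `qsar_model`.
#' @param q2_ctx Result of [q2_loo()] (optional).
#' @param pred_ctx Result of [pred_r2()] (optional).
#' @return List with `r2_se` and, when contexts are given, `q2_se`,
#'   `pred_r2_se`.
#' @export
standard_errors <- function(fit, q2_ctx = NULL, pred_ctx = NULL) {
  stopifnot(inherits(fit, "qsar_model"))
  fs <- fit$fit_stats
  out <- list(r2_se = sqrt(fs$ssres / fs$df))
  if (!is.null(q2_ctx))
    out$q2_se <- sqrt(q2_ctx$press / length(q2_ctx$loo_residuals))
  if (!is.null(pred_ctx))
    out$pred_r2_se <- sqrt(sum(pred_ctx$residuals^2) / pred_ctx$n_test)
  out
}

#' Run the full validation battery on a train/test pair
#'
#' Assembles the complete validation report: training r2, LOO q2, external
#' pred_r2, rm2 metrics on the test set, degrees of freedom, F test,
#' Y-randomization statistics (best random r2/q2, Z-scores, empirical
#' alpha), the three standard errors and the applicability-domain outlier
#' count of the test set.
#'
#' @param train_table Training `activity_table` (descriptor columns are the
#'   model descriptors).
#' @param test_table Test `activity_table` (may be `NULL`: external items
#'   are then `NA`).
#' @param model Optional pre-fitted `qsar_model`; by default all descriptor
#'   columns of `train_table` are fitted by OLS.
#' @param model_builder Builder used inside Y-randomization; defaults to
#'   refitting the model's descriptor set.
#' @param n_random_trials Randomization trials (default 100).
#' @param seed Seed for the randomization test.
#' @return Object of class `validation_report` (a list of the statistics
#'   named as in the printed battery).
#' @export
validate_model <- function(train_table, test_table = NULL, model = NULL,
                           model_builder = NULL, n_random_trials = 100L,
                           seed = 1L) {
  stopifnot(inherits(train_table, "activity_table"))
  if (is.null(model)) {
    model <- fit_mlr(.desc_matrix(train_table), train_table$log_ic50,
                     training_ids = train_table$compound_id)
  }
  nms <- model$descriptor_names
  X <- .desc_matrix(train_table, nms)
  y <- train_table$log_ic50
  q2c <- q2_loo(X, y)
  pr <- rm2 <- NULL
  ad_outliers <- NA_integer_
  if (!is.null(test_table) && nrow(test_table) > 0L) {
    pr <- pred_r2(model, test_table, train_mean = mean(y))
    rm2 <- rm2_battery(test_table$log_ic50,
                       predict(model, test_table)$pred_log_ic50)
    adf <- applicability_flag(model, test_table)
    ad_outliers <- if (identical(adf, "unavailable")) NA_integer_ else
      sum(adf)
  }
  yr <- y_randomization(X, y, model_builder = model_builder,
                        n_trials = n_random_trials, seed = seed)
  se <- standard_errors(model, q2c, pr)
  structure(list(
    r2 = model$fit_stats$r2,
    q2_loo = q2c$q2,
    pred_r2 = if (is.null(pr)) NA_real_ else pr$pred_r2,
    rm2_avg = if (is.null(rm2)) NA_real_ else rm2$rm2_avg,
    rm2_delta = if (is.null(rm2)) NA_real_ else rm2$rm2_delta,
    df = model$fit_stats$df,
    f_stat = model$fit_stats$F,
    r2_se = se$r2_se,
    q2_se = se$q2_se,
    pred_r2_se = if (is.null(pr)) NA_real_ else se$pred_r2_se,
    best_ran_r2 = yr$best_ran_r2,
    best_ran_q2 = yr$best_ran_q2,
    zscore_r2 = yr$zscore_r2,
    zscore_q2 = yr$zscore_q2,
    alpha = yr$alpha,
    n_random_trials = yr$n_trials,
    ad_outlier_count = ad_outliers,
    residuals = model$fit_stats$residuals,
    q2_flag = q2c$q2 > model$fit_stats$r2,
    model = model),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", formatC(v, format = "f",
                                                    digits = 4))
  rows <- c("r2" = x$r2, "(LOOcv) q2" = x$q2_loo, "pred_r2" = x$pred_r2,
            "Average rm2" = x$rm2_avg, "Delta rm2" = x$rm2_delta,
            "Df" = x$df, "F test" = x$f_stat,
            "best_ran_r2" = x$best_ran_r2, "best_ran_q2" = x$best_ran_q2,
            "alpha_test" = x$alpha, "r2 se" = x$r2_se, "q2 se" = x$q2_se,
            "pred_r2 _se" = x$pred_r2_se,
            "ZScore (q2)" = x$zscore_q2, "ZScore (r2)" = x$zscore_r2,
            "Applicability domain" = x$ad_outlier_count)
  cat("Validation battery\n")
  for (nm in names(rows))
    cat(sprintf("  %-22s %s\n", nm, fmt(rows[[nm]])))
  if (isTRUE(x$q2_flag))
    cat("  note: q2 > r2 (numerical warning)\n")
  invisible(x)
}
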