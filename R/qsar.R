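# Linear QSAR models: OLS fitting, stepwise-forward descriptor selection,
# the three frozen published cell-line equations, prediction and the
# training-range applicability domain.

.new_qsar_model <- function(descriptor_names, coefficients, intercept,
                            provenance, fit_stats = NULL, ranges = NULL,
                            training_ids = NULL, name = provenance) {
  stopifnot(length(coefficients) == length(descriptor_names),
            all(is.finite(coefficients)), is.finite(intercept))
  structure(
    list(name = name,
         response = "Log10 IC50 (uM)",
         descriptor_names = descriptor_names,
         coefficients = stats::setNames(as.numeric(coefficients),
                                        descriptor_names),
         intercept = as.numeric(intercept),
         ranges = ranges,             # data.frame: descriptor, min, max
         training_ids = training_ids,
         fit_stats = fit_stats,       # n, k, r2, se, F, df, plus fit vectors
         provenance = provenance,
         version = "1"),
    class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  cat("qsar_model '", x$name, "' (", x$provenance, ")\n", sep = "")
  cat("  ", x$response, " = ", format(round(x$intercept, 4), nsmall = 4),
      sep = "")
  for (nm in x$descriptor_names) {
    cf <- x$coefficients[[nm]]
    cat(if (cf >= 0) " + " else " - ",
        format(round(abs(cf), 4), nsmall = 4), " x ", nm, sep = "")
  }
  cat("\n")
  if (!is.null(x$fit_stats))
    cat(sprintf("  n = %d, k = %d, r2 = %.4f, se = %.4f, F = %.2f\n",
                x$fit_stats$n, x$fit_stats$k, x$fit_stats$r2,
                x$fit_stats$se, x$fit_stats$F))
  invisible(x)
}

#' Fit a multiple linear regression QSAR model
#'
#' Ordinary least squares of activity on the supplied descriptor columns,
#' with explicit degrees-of-freedom and rank checks. The fitted object
#' carries everything the validation battery needs: residuals, hat-matrix
#' diagonal, r2, residual SE and the F statistic.
#'
#' @param X Descriptor matrix or data.frame (n x k).
#' @param y Numeric activity vector (log10 IC50 uM).
#' @param training_ids Optional compound ids stored on the model.
#' @param name Model name.
#' @return A `qsar_model` with provenance `"built"`.
#' @export
fit_mlr <- function(X, y, training_ids = NULL, name = "built") {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (n <= k + 1L)
    stop("degrees-of-freedom error: need n > k + 1 (n = ", n, ", k = ", k, ")")
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_ <- qr(Xi)
  if (qr_$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qr_$pivot[(qr_$rank + 1L):ncol(Xi)]]
    stop("singular descriptor matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(Xi, y)
  coefs <- fit$coefficients
  fitted <- as.vector(Xi %*% coefs)
  res <- y - fitted
  ssres <- sum(res^2)
  sstot <- sum((y - mean(y))^2)
  ssreg <- sstot - ssres
  r2 <- 1 - ssres / sstot
  df <- n - k - 1L
  se <- sqrt(ssres / df)
  Fst <- if (ssres == 0) Inf else (ssreg / k) / (ssres / df)
  # hat diagonal from the QR factorization
  Q <- qr.Q(qr_)
  hat <- rowSums(Q^2)
  rng <- data.frame(descriptor = colnames(X),
                    min = apply(X, 2, min), max = apply(X, 2, max),
                    row.names = NULL)
  .new_qsar_model(
    colnames(X), coefs[-1], coefs[1], provenance = "built",
    fit_stats = list(n = n, k = k, r2 = r2, se = se, F = Fst, df = df,
                     ssres = ssres, sstot = sstot, residuals = res,
                     fitted = fitted, hat = hat, y = y),
    ranges = rng, training_ids = training_ids, name = name)
}

# partial F for adding one column to an existing RSS
.partial_f <- function(rss0, rss1, n, k_new) {
  if (rss1 <= 0) return(Inf)
  (rss0 - rss1) / (rss1 / (n - k_new - 1))
}

#' Stepwise-forward MLR descriptor selection
#'
#' Starts from the intercept-only model; each round fits every remaining
#' candidate descriptor alongside the chosen set and adds the candidate with
#' the largest partial F, provided that F is at least `f_to_enter` and the
#' candidate's |Pearson r| with every already-chosen descriptor is at most
#' `corr_cutoff`. Stops at `max_terms` or when no candidate qualifies. Ties
#' go to the lowest column index.
#'
#' @param table An `activity_table`, or a descriptor matrix (then supply
#'   `y`).
#' @param y Activity vector when `table` is a matrix.
#' @param f_to_enter Minimum partial F to admit a descriptor (default 4).
#' @param max_terms Maximum number of descriptors (default `floor(n/6)`).
#' @param corr_cutoff Maximum |r| between chosen descriptors (default 0.7).
#' @return A `qsar_model`; intercept-only (no descriptors, with a warning)
#'   when nothing qualifies in round 1.
#' @export
stepwise_forward <- function(table, y = NULL, f_to_enter = 4,
                             max_terms = NULL, corr_cutoff = 0.7) {
  if (inherits(table, "activity_table")) {
    X <- .desc_matrix(table)
    y <- table$log_ic50
    ids <- table$compound_id
  } else {
    X <- as.matrix(table)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (is.null(y)) stop("supply 'y' when 'table' is a matrix")
    ids <- NULL
  }
  if (f_to_enter <= 0) stop("'f_to_enter' must be > 0")
  n <- nrow(X)
  if (is.null(max_terms)) max_terms <- floor(n / 6)
  chosen <- character(0)
  remaining <- colnames(X)
  rss <- sum((y - mean(y))^2)
  while (length(chosen) < max_terms && length(remaining) > 0L) {
    k_new <- length(chosen) + 1L
    if (n <= k_new + 1L) break
    best <- NULL; best_f <- -Inf
    for (cand in remaining) {
      if (length(chosen) > 0L &&
          any(abs(stats::cor(X[, cand], X[, chosen, drop = FALSE])) >
              corr_cutoff)) next
      Xi <- cbind(1, X[, c(chosen, cand), drop = FALSE])
      if (qr(Xi)$rank < ncol(Xi)) next
      f <- stats::lm.fit(Xi, y)
      pf <- .partial_f(rss, sum(f$residuals^2), n, k_new)
      if (pf > best_f) { best_f <- pf; best <- cand }  # ties: first = lowest index
    }
    if (is.null(best) || best_f < f_to_enter) break
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
    rss <- sum(stats::lm.fit(cbind(1, X[, chosen, drop = FALSE]),
                             y)$residuals^2)
  }
  if (length(chosen) == 0L) {
    warning("no descriptor met the entry criterion; intercept-only model")
    return(.new_qsar_model(
      character(0), numeric(0), mean(y), provenance = "built",
      fit_stats = list(n = n, k = 0L, r2 = 0, se = stats::sd(y), F = NA_real_,
                       df = n - 1L, ssres = sum((y - mean(y))^2),
                       sstot = sum((y - mean(y))^2),
                       residuals = y - mean(y),
                       fitted = rep(mean(y), n),
                       hat = rep(1 / n, n), y = y),
      training_ids = ids, name = "stepwise"))
  }
  fit_mlr(X[, chosen, drop = FALSE], y, training_ids = ids,
          name = "stepwise")
}

#' The frozen published cell-line models
#'
#' Loads one of the three published caged-xanthone QSAR equations, shipped as
#' packaged JSON coefficient sets: `model1` (A549, 5 descriptors), `model2`
#' (HepG2, 5 descriptors), `model3` (U251, 3 descriptors). The response of
#' each is predicted log10 IC50 in micromolar on raw descriptor scales.
#' Published models carry no training descriptor ranges, so their
#' applicability-domain flag is `"unavailable"`.
#'
#' @param which `"model1"`, `"model2"` or `"model3"`.
#' @return A `qsar_model` with provenance `"published:<which>"`.
#' @examples
#' \donttest{
#' m3 <- published_model("model3")
#' predict(m3, data.frame(`T_T_N_4` = 0, `T_O_O_3` = 0,
#'                        `SssssCE-index` = 0, check.names = FALSE))
#' }
#' @export
published_model <- function(which = c("model1", "model2", "model3")) {
  if (!is.character(which) || length(which) != 1L ||
      !which %in% c("model1", "model2", "model3"))
    stop("unknown model id; valid ids: model1, model2, model3")
  key <- paste0("pub_", which)
  if (is.null(.cx_env[[key]])) {
    path <- system.file("extdata", "models", paste0(which, ".json"),
                        package = "cxqsar")
    .cx_env[[key]] <- read_model_json(path)
  }
  .cx_env[[key]]
}

#' Read / write a QSAR model as JSON
#'
#' Schema: `{name, response, descriptors: [{name, coefficient, train_min?,
#' train_max?}], intercept, provenance, version}`.
#'
#' @param path File path.
#' @return A `qsar_model` (reader) or `path`, invisibly (writer).
#' @export
read_model_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  d <- j$descriptors
  ranges <- NULL
  if (!is.null(d$train_min) && !anyNA(d$train_min))
    ranges <- data.frame(descriptor = d$name, min = d$train_min,
                         max = d$train_max, row.names = NULL)
  .new_qsar_model(d$name, d$coefficient, j$intercept,
                  provenance = j$provenance, ranges = ranges, name = j$name)
}

#' @rdname read_model_json
#' @param model A `qsar_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "qsar_model"))
  d <- data.frame(name = model$descriptor_names,
                  coefficient = unname(model$coefficients))
  if (!is.null(model$ranges)) {
    d$train_min <- model$ranges$min[match(d$name, model$ranges$descriptor)]
    d$train_max <- model$ranges$max[match(d$name, model$ranges$descriptor)]
  }
  jsonlite::write_json(
    list(name = model$name, response = model$response, descriptors = d,
         intercept = model$intercept, provenance = model$provenance,
         version = model$version),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# extract the model's descriptor columns from newdata (data.frame or named
# vector); errors on any missing name, never zero-fills
.model_matrix_from <- function(model, newdata) {
  nms <- model$descriptor_names
  if (is.null(dim(newdata))) {
    if (is.null(names(newdata))) stop("newdata must be named")
    newdata <- as.data.frame(as.list(newdata), check.names = FALSE)
  }
  missing <- setdiff(nms, colnames(newdata))
  if (length(missing) > 0L)
    stop("missing descriptor value(s): ", paste(missing, collapse = ", "))
  as.matrix(as.data.frame(newdata, check.names = FALSE)[, nms, drop = FALSE])
}

#' Predict activity with a QSAR model
#'
#' Evaluates the affine scoring function intercept + sum(coefficient x
#' value) and reports both the predicted log10 IC50 and the back-transformed
#' IC50 in micromolar. A missing descriptor is an error, never a silent
#' zero-fill.
#'
#' @param object A `qsar_model`.
#' @param newdata data.frame (one row per compound) or a single named vector
#'   covering all model descriptors.
#' @param ... Unused.
#' @return data.frame with `pred_log_ic50` and `pred_ic50_uM = 10^pred`.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  M <- .model_matrix_from(object, newdata)
  lp <- as.vector(M %*% object$coefficients) + object$intercept
  data.frame(pred_log_ic50 = lp, pred_ic50_uM = 10^lp)
}

#' Applicability-domain flag (training-range rule)
#'
#' Flag 0: every descriptor value lies within the model's training range
#' (inclusive bounds) — the prediction interpolates. Flag 1: at least one
#' descriptor extrapolates (outlier). Published models ship without training
#' ranges and return `"unavailable"`.
#'
#' @param model A `qsar_model`.
#' @param newdata data.frame or named vector; see [predict.qsar_model()].
#' @return Integer vector of 0/1, or the character `"unavailable"` when the
#'   model carries no ranges.
#' @export
applicability_flag <- function(model, newdata) {
  stopifnot(inherits(model, "qsar_model"))
  if (is.null(model$ranges)) return("unavailable")
  M <- .model_matrix_from(model, newdata)
  r <- model$ranges[match(colnames(M), model$ranges$descriptor), ]
  out <- integer(nrow(M))
  for (i in seq_len(nrow(M)))
    out[i] <- as.integer(any(M[i, ] < r$min | M[i, ] > r$max))
  out
}
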