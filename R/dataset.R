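# Descriptor/activity tables, pre-modeling hygiene and the sphere-exclusion
# train/test split.

#' Construct an activity table
#'
#' Standard container for QSAR modeling: one row per compound with a unique
#' id, optional SMILES, descriptor columns and the observed activity. IC50
#' values supplied in micromolar are log10-transformed at load time; both
#' columns are retained. Rows with missing descriptor values are excluded
#' (never imputed) with a recorded count.
#'
#' @param data data.frame containing id, activity and descriptor columns.
#' @param id_col Name of the compound-id column (default `"compound_id"`).
#' @param activity_col Name of the activity column.
#' @param activity_unit `"log10_uM"` (already log10 IC50 in micromolar) or
#'   `"uM"` (raw IC50, transformed at load).
#' @param smiles_col Optional name of a SMILES column.
#' @return data.frame of class `activity_table` with canonical columns
#'   `compound_id`, optional `smiles`, optional `ic50_uM`, `log_ic50`, and
#'   the descriptor columns; attributes `descriptor_names` and
#'   `n_dropped_incomplete`.
#' @export
activity_table <- function(data, id_col = "compound_id",
                           activity_col = "log_ic50",
                           activity_unit = c("log10_uM", "uM"),
                           smiles_col = NULL) {
  activity_unit <- match.arg(activity_unit)
  stopifnot(is.data.frame(data))
  for (cl in c(id_col, activity_col))
    if (!cl %in% names(data)) stop("column '", cl, "' not found")
  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids)) stop("compound ids must be unique")
  act <- as.numeric(data[[activity_col]])
  desc_cols <- setdiff(names(data), c(id_col, activity_col, smiles_col))
  desc <- data[, desc_cols, drop = FALSE]
  if (!all(vapply(desc, is.numeric, logical(1))))
    stop("non-numeric descriptor column(s): ",
         paste(desc_cols[!vapply(desc, is.numeric, logical(1))],
               collapse = ", "))
  out <- data.frame(compound_id = ids, stringsAsFactors = FALSE)
  if (!is.null(smiles_col)) out$smiles <- as.character(data[[smiles_col]])
  if (activity_unit == "uM") {
    if (any(act <= 0, na.rm = TRUE)) stop("IC50 values must be positive")
    out$ic50_uM <- act
    out$log_ic50 <- log10(act)
  } else {
    out$log_ic50 <- act
  }
  out <- cbind(out, desc)
  complete <- stats::complete.cases(desc) & is.finite(out$log_ic50)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(n_dropped, " row(s) with missing values excluded")
  out <- out[complete, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, descriptor_names = desc_cols,
            n_dropped_incomplete = n_dropped,
            class = c("activity_table", "data.frame"))
}

#' @export
print.activity_table <- function(x, ...) {
  cat("activity_table:", nrow(x), "compounds,",
      length(attr(x, "descriptor_names")), "descriptors\n")
  NextMethod()
}

#' Descriptor names of an activity table
#' @param table An `activity_table`.
#' @return Character vector.
#' @export
descriptor_names <- function(table) {
  nm <- attr(table, "descriptor_names")
  if (is.null(nm)) stop("not an activity_table")
  nm
}

# descriptor matrix of an activity_table
.desc_matrix <- function(table, cols = descriptor_names(table)) {
  as.matrix(table[, cols, drop = FALSE])
}

#' Read / write activity tables as CSV
#'
#' RFC-4180 CSV with a header row; see [activity_table()] for column
#' conventions.
#' @param path File path.
#' @param ... Passed on to [activity_table()].
#' @return An `activity_table` (reader) or `path`, invisibly (writer).
#' @export
read_activity_csv <- function(path, ...) {
  activity_table(utils::read.csv(path, check.names = FALSE,
                                 stringsAsFactors = FALSE), ...)
}

#' @rdname read_activity_csv
#' @param table An `activity_table`.
#' @export
write_activity_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Prune highly correlated descriptors
#'
#' Greedy removal: while any descriptor pair has |Pearson r| above `cutoff`,
#' the pair member with the lower |correlation to activity| is dropped (tie:
#' the higher column index). Zero-variance descriptors are dropped first.
#' The full correlation matrix (over the original non-constant descriptors)
#' is returned for reporting.
#'
#' @param table An `activity_table`.
#' @param cutoff Maximum allowed |r| between retained descriptors, in (0, 1].
#' @return List: `retained`, `dropped` (with reasons), `zero_variance`,
#'   `corr_matrix`, `activity_corr`.
#' @export
correlation_prune <- function(table, cutoff = 0.99) {
  stopifnot(inherits(table, "activity_table"))
  if (!(cutoff > 0 && cutoff <= 1)) stop("'cutoff' must be in (0, 1]")
  if (nrow(table) < 2L) stop("need at least 2 rows")
  nms <- descriptor_names(table)
  X <- .desc_matrix(table)
  y <- table$log_ic50
  sds <- apply(X, 2, stats::sd)
  zero_var <- nms[sds == 0]
  keep <- nms[sds > 0]
  X <- X[, keep, drop = FALSE]
  cm <- if (length(keep) >= 2L) stats::cor(X) else
    matrix(1, length(keep), length(keep), dimnames = list(keep, keep))
  ya <- abs(stats::cor(X, y)[, 1])
  dropped <- character(0)
  active <- keep
  repeat {
    if (length(active) < 2L) break
    sub <- abs(cm[active, active, drop = FALSE])
    diag(sub) <- 0
    mx <- max(sub)
    if (mx <= cutoff) break
    w <- which(sub == mx, arr.ind = TRUE)[1, ]
    a <- active[w[1]]; b <- active[w[2]]
    # drop the one less correlated with activity; tie -> higher column index
    drop <- if (ya[a] < ya[b]) a
            else if (ya[b] < ya[a]) b
            else c(a, b)[which.max(match(c(a, b), nms))]
    dropped <- c(dropped, drop)
    active <- setdiff(active, drop)
  }
  list(retained = active,
       dropped = dropped,
       zero_variance = zero_var,
       corr_matrix = cm,
       activity_corr = ya)
}

#' Sphere-exclusion train/test split
#'
#' Diversity-based split in z-standardized descriptor space. Compounds are
#' visited in decreasing activity order (most potent, i.e. lowest log IC50,
#' first; exact-activity ties broken by the seed). Each still-unassigned
#' compound visited becomes a TRAIN point, and every still-unassigned
#' compound within Euclidean distance `radius` of it is assigned to TEST.
#'
#' @param table An `activity_table` with >= 2 rows.
#' @param radius Non-negative exclusion radius (standardized descriptor
#'   units).
#' @param seed Integer seed; only breaks exact-activity ties.
#' @return List of class `data_split`: `train_ids`, `test_ids`, `radius`,
#'   `seed`, `standardization` (per-descriptor mean/sd computed on the
#'   training set, for downstream use).
#' @export
sphere_exclusion_split <- function(table, radius, seed = 1L) {
  stopifnot(inherits(table, "activity_table"))
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    stop("'radius' must be a single non-negative number")
  n <- nrow(table)
  if (n < 2L) stop("need at least 2 rows")
  X <- .desc_matrix(table)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  set.seed(as.integer(seed))
  ord <- order(table$log_ic50, sample.int(n))
  assigned <- rep(NA_character_, n)
  D <- as.matrix(stats::dist(Z))
  for (i in ord) {
    if (!is.na(assigned[i])) next
    assigned[i] <- "train"
    cap <- which(is.na(assigned) & D[i, ] <= radius)
    assigned[cap] <- "test"
  }
  train <- table$compound_id[assigned == "train"]
  test <- table$compound_id[assigned == "test"]
  Xtr <- X[assigned == "train", , drop = FALSE]
  structure(
    list(train_ids = train, test_ids = test, radius = radius,
         seed = as.integer(seed),
         standardization = data.frame(
           descriptor = colnames(X),
           mean = colMeans(Xtr),
           sd = apply(Xtr, 2, stats::sd),
           row.names = NULL)),
    class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat("data_split: ", length(x$train_ids), " train / ", length(x$test_ids),
      " test (radius ", format(x$radius), ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Find a sphere-exclusion radius for a target training fraction
#'
#' Bisection helper: returns the radius whose split has a training fraction
#' closest to `train_fraction`.
#'
#' @param table An `activity_table`.
#' @param train_fraction Desired |train|/n, in (0, 1].
#' @param seed Seed forwarded to [sphere_exclusion_split()].
#' @param iterations Bisection steps.
#' @return List with `radius` and the achieved `train_fraction`.
#' @export
sphere_radius_for_fraction <- function(table, train_fraction = 0.8,
                                       seed = 1L, iterations = 30L) {
  stopifnot(inherits(table, "activity_table"))
  X <- .desc_matrix(table)
  sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, colMeans(X)), 2, sdv, "/")
  hi <- max(stats::dist(Z)) + 1e-9
  lo <- 0
  frac <- function(r) {
    s <- sphere_exclusion_split(table, r, seed)
    length(s$train_ids) / nrow(table)
  }
  best_r <- 0; best_gap <- Inf
  for (it in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    f <- frac(mid)
    gap <- abs(f - train_fraction)
    if (gap < best_gap) { best_gap <- gap; best_r <- mid }
    # larger radius -> fewer train points
    if (f > train_fraction) lo <- mid else hi <- mid
  }
  list(radius = best_r, train_fraction = frac(best_r))
}

#' Uni-column statistics for a train/test split
#'
#' Per-set mean, max, min and sd of the activity and every descriptor, plus
#' the range-coverage verdict: `"covered"` iff the test-set activity range
#' lies inside the training-set range (so the test set interpolates).
#'
#' @param table An `activity_table`.
#' @param split A `data_split` on the same table.
#' @return List: `stats` (data.frame: column, set, mean, max, min, sd) and
#'   `verdict` (`"covered"`, `"not covered"`, or `"not applicable"` when the
#'   test set is empty).
#' @export
unicolumn_stats <- function(table, split) {
  stopifnot(inherits(table, "activity_table"), inherits(split, "data_split"))
  cols <- c("log_ic50", descriptor_names(table))
  sets <- list(train = table[table$compound_id %in% split$train_ids, ],
               test = table[table$compound_id %in% split$test_ids, ])
  if (nrow(sets$test) == 0L) sets$test <- NULL
  rows <- list()
  for (s in names(sets)) for (cl in cols) {
    v <- sets[[s]][[cl]]
    rows[[length(rows) + 1L]] <- data.frame(
      column = cl, set = s, mean = mean(v), max = max(v), min = min(v),
      sd = stats::sd(v), stringsAsFactors = FALSE)
  }
  st <- do.call(rbind, rows)
  verdict <- if (is.null(sets$test)) "not applicable" else {
    tr <- sets$train$log_ic50; te <- sets$test$log_ic50
    if (max(te) <= max(tr) && min(te) >= min(tr)) "covered" else "not covered"
  }
  list(stats = st, verdict = verdict)
}
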