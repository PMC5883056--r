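# Synthetic-data generation: descriptor tables with a planted sparse linear
# activity relationship, hand-checkable fixture molecules, and screening
# libraries with constructed pass/fail ground truth.

#' Simulation configuration for descriptor/activity tables
#'
#' Describes the statistical structure the QSAR analysis assumes: descriptor
#' columns drawn from simple distributions (continuous uniform for E-state
#' style indices, non-negative integer counts for count descriptors), a
#' sparse true coefficient vector, and additive Gaussian noise on the log10
#' IC50 scale.
#'
#' @param n_compounds Number of rows (must be at least k + 3 so the table is
#'   fit-able).
#' @param descriptors Named list; each element is `list(dist = "uniform",
#'   min, max)` or `list(dist = "count", min, max)` (integer uniform).
#' @param true_beta Named numeric vector of true coefficients (a subset of
#'   the descriptor names; unnamed descriptors are noise columns).
#' @param intercept True intercept (default 0).
#' @param noise_sd Gaussian noise sd in log10 uM units (>= 0).
#' @param seed Mandatory integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_compounds, descriptors, true_beta, intercept = 0,
                       noise_sd = 0.1, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  stopifnot(is.list(descriptors), length(names(descriptors)) ==
              length(descriptors))
  if (!all(names(true_beta) %in% names(descriptors)))
    stop("true_beta names must be descriptor names")
  k <- length(descriptors)
  if (n_compounds < k + 3L)
    stop("need n_compounds >= k + 3 (k = ", k, ")")
  for (nm in names(descriptors)) {
    d <- descriptors[[nm]]
    if (!d$dist %in% c("uniform", "count"))
      stop("descriptor '", nm, "': unknown distribution '", d$dist, "'")
    if (d$min > d$max)
      stop("descriptor '", nm, "': impossible bounds")
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 descriptors = descriptors,
                 true_beta = true_beta, intercept = intercept,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default simulated descriptor set
#'
#' The three descriptors of the published U251 model with realistic ranges
#' (integer pair counts, a continuous E-state sum), plus `k_noise` inert
#' uniform(0, 1) columns.
#'
#' @param k_noise Number of noise descriptors.
#' @return Named list suitable for [sim_config()].
#' @export
default_sim_descriptors <- function(k_noise = 7L) {
  d <- list(
    "T_T_N_4" = list(dist = "count", min = 0, max = 8),
    "T_O_O_3" = list(dist = "count", min = 0, max = 5),
    "SssssCE-index" = list(dist = "uniform", min = -2, max = 2))
  for (i in seq_len(k_noise))
    d[[paste0("D", i)]] <- list(dist = "uniform", min = 0, max = 1)
  d
}

#' Simulate a descriptor/activity table
#'
#' Draws descriptor values per the configured distributions and sets
#' activity = intercept + sum(beta x) + Normal(0, noise_sd). Deterministic
#' for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return An `activity_table` with attribute `true_beta`.
#' @export
simulate_descriptor_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_compounds
  cols <- lapply(config$descriptors, function(d) {
    if (d$dist == "uniform") stats::runif(n, d$min, d$max)
    else as.numeric(sample(seq(d$min, d$max), n, replace = TRUE))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- names(config$descriptors)
  beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
  beta[names(config$true_beta)] <- config$true_beta
  y <- config$intercept + as.vector(X %*% beta) +
    stats::rnorm(n, 0, config$noise_sd)
  df <- data.frame(compound_id = sprintf("sim%04d", seq_len(n)),
                   log_ic50 = y, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(X, check.names = FALSE))
  out <- activity_table(df)
  attr(out, "true_beta") <- beta
  out
}

#' Hand-checkable fixture molecules with frozen oracle descriptor values
#'
#' A packaged set of small molecules (alkanes, alkenes, aromatics, alcohols,
#' amides, heteroaromatics, and a caged-xanthone-like polycycle) whose
#' descriptor values were precomputed with independent brute-force oracle
#' code and frozen as plain CSV. The live descriptor engine is regression-
#' tested against this table.
#'
#' @return data.frame: `name`, `smiles`, then one column per frozen
#'   descriptor value.
#' @export
fixture_molecules <- function() {
  path <- system.file("extdata", "fixture_descriptors.csv",
                      package = "cxqsar")
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Simulate a screening library with constructed ground truth
#'
#' Builds a descriptor-only library for a frozen model such that a requested
#' fraction of compounds falls at or under the activity threshold. Count
#' descriptors are sampled as integers; one designated continuous descriptor
#' is then solved so that the model prediction hits a target log10 IC50 drawn
#' on the requested side of the threshold. The ground-truth label stored on
#' each row is recomputed from the final descriptor vector, so label and
#' screen agree by construction.
#'
#' @param n Library size.
#' @param model A `qsar_model` (default the frozen U251 model); must contain
#'   at least one continuous descriptor with a nonzero coefficient.
#' @param pass_fraction Fraction of compounds constructed to pass, in
#'   \[0, 1\].
#' @param seed Integer seed.
#' @param threshold_uM Activity threshold the labels refer to (default 20).
#' @param free_descriptor Name of the continuous descriptor solved for the
#'   target (default `"SssssCE-index"` for the U251 model).
#' @param log_range Half-width of the target log10 IC50 band on either side
#'   of the threshold (default 1.5 decades).
#' @return data.frame: `compound_id`, model descriptors, `true_pred_log`,
#'   `true_pass`.
#' @export
simulate_screening_library <- function(n, model = published_model("model3"),
                                       pass_fraction, seed = 1L,
                                       threshold_uM = 20,
                                       free_descriptor = "SssssCE-index",
                                       log_range = 1.5) {
  stopifnot(inherits(model, "qsar_model"))
  if (pass_fraction < 0 || pass_fraction > 1)
    stop("'pass_fraction' must be in [0, 1]")
  if (!free_descriptor %in% model$descriptor_names ||
      model$coefficients[[free_descriptor]] == 0)
    stop("'free_descriptor' must be a model descriptor with nonzero ",
         "coefficient")
  set.seed(as.integer(seed))
  n_pass <- round(n * pass_fraction)
  thr_log <- log10(threshold_uM)
  margin <- 1e-6
  targets <- c(stats::runif(n_pass, thr_log - log_range, thr_log - margin),
               stats::runif(n - n_pass, thr_log + margin,
                            thr_log + log_range))
  targets <- sample(targets)
  other <- setdiff(model$descriptor_names, free_descriptor)
  X <- matrix(0, n, length(model$descriptor_names),
              dimnames = list(NULL, model$descriptor_names))
  for (nm in other)
    X[, nm] <- sample(0:4, n, replace = TRUE)
  X[, free_descriptor] <-
    (targets - model$intercept -
       as.vector(X[, other, drop = FALSE] %*%
                   model$coefficients[other])) /
    model$coefficients[[free_descriptor]]
  lib <- data.frame(compound_id = sprintf("lib%05d", seq_len(n)),
                    stringsAsFactors = FALSE)
  lib <- cbind(lib, as.data.frame(X, check.names = FALSE))
  pred <- predict(model, lib)$pred_log_ic50
  lib$true_pred_log <- pred
  lib$true_pass <- pred <= thr_log
  if (abs(mean(lib$true_pass) - pass_fraction) > max(2 / n, 0.01))
    stop("constructed pass fraction infeasible under the given settings")
  lib
}

#' Random molecular graphs (for property-based testing)
#'
#' Generates a random connected hydrogen-suppressed graph: a random spanning
#' tree plus optional extra edges, random C/N/O/S element labels, random
#' bond orders and hydrogen counts. Not guaranteed to be a chemically
#' sensible molecule; intended for invariance checks of the graph and
#' E-state machinery.
#'
#' @param n_atoms Number of heavy atoms (>= 2).
#' @param extra_edge_prob Probability of each possible extra edge.
#' @param seed Integer seed.
#' @return A `molgraph`.
#' @export
random_molgraph <- function(n_atoms, extra_edge_prob = 0.05, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  set.seed(as.integer(seed))
  stopifnot(n_atoms >= 2)
  a1 <- integer(0); a2 <- integer(0)
  for (i in 2:n_atoms) {            # random spanning tree
    a1 <- c(a1, sample.int(i - 1L, 1L)); a2 <- c(a2, i)
  }
  for (i in seq_len(n_atoms - 1L)) for (j in (i + 1L):n_atoms) {
    if (any(a1 == i & a2 == j)) next
    if (stats::runif(1) < extra_edge_prob) { a1 <- c(a1, i); a2 <- c(a2, j) }
  }
  bonds <- data.frame(a1 = a1, a2 = a2,
                      order = sample(c(1L, 1L, 1L, 2L), length(a1),
                                     replace = TRUE))
  molgraph(sample(c("C", "C", "C", "N", "O", "S"), n_atoms, replace = TRUE),
           bonds,
           attached_h = sample(0:2, n_atoms, replace = TRUE))
}
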