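# Virtual-screening cascade: predicted-activity cutoff, Lipinski rule of
# five, configurable risk rules, ranked report.

#' Predicted-activity filter
#'
#' Partitions compounds on predicted IC50: a compound passes iff its
#' predicted IC50 does not exceed `threshold_uM` on the designated model;
#' strictly greater values are excluded, so a compound sitting exactly on the
#' threshold passes. The comparison is made on the log10 scale
#' (`pred_log_ic50 <= log10(threshold_uM)`), which is exact at the boundary.
#' Compounds with a missing prediction go to an `unevaluated` bin, never a
#' silent pass.
#'
#' @param records data.frame with a `pred_log_ic50` column (e.g. the output
#'   of [predict.qsar_model()] bound to compound ids).
#' @param threshold_uM Positive IC50 cutoff in micromolar (default 20; the
#'   source study also discusses 15 as an alternative preset).
#' @return List of data.frames: `pass`, `fail`, `unevaluated`.
#' @export
activity_filter <- function(records, threshold_uM = 20) {
  stopifnot(is.data.frame(records), "pred_log_ic50" %in% names(records))
  if (!is.numeric(threshold_uM) || threshold_uM <= 0)
    stop("'threshold_uM' must be positive")
  lp <- records$pred_log_ic50
  un <- is.na(lp)
  ok <- !un & lp <= log10(threshold_uM)
  list(pass = records[ok, , drop = FALSE],
       fail = records[!un & !ok, , drop = FALSE],
       unevaluated = records[un, , drop = FALSE])
}

#' Lipinski rule-of-five verdict
#'
#' Violations: MW > 500, logP > 5, HBD > 5, HBA > 10 (inclusive limits, so a
#' compound exactly at a limit does not violate it). A compound passes with
#' at most `allowance` violations (classic allowance 1; set 0 for the strict
#' form). A missing property fails closed: it is recorded as an
#' `unevaluable` violation.
#'
#' @param properties List or one-row data.frame with `MW`, `logP`, `HBD`,
#'   `HBA` (see [rule_of_five_properties()]).
#' @param allowance Maximum violations still passing (default 1).
#' @return List with `pass` (logical) and `violations` (character vector).
#' @export
rule_of_five <- function(properties, allowance = 1L) {
  need <- c("MW", "logP", "HBD", "HBA")
  v <- character(0)
  for (p in need) {
    val <- properties[[p]]
    if (is.null(val) || is.na(val)) { v <- c(v, paste0(p, ":unevaluable")); next }
    lim <- c(MW = 500, logP = 5, HBD = 5, HBA = 10)[[p]]
    if (val > lim) v <- c(v, sprintf("%s>%g", p, lim))
  }
  list(pass = length(v) <= allowance && !any(grepl(":unevaluable$", v)),
       violations = v)
}

#' Configurable risk-rule stage
#'
#' Transparent stand-in for composite risk scores: each rule is a named
#' predicate over the property list with a non-negative weight; the risk
#' score is the sum of weights of triggered rules, and a compound is
#' excluded when the score reaches `cutoff`. A rule that references a
#' missing property counts as triggered (fail-closed) with a warning. The
#' default rule set is empty (score 0 for everything).
#'
#' @param properties Named list of compound properties.
#' @param rule_set List of rules, each a list with `name`, `predicate`
#'   (function of the property list returning `TRUE`/`FALSE`), `weight`
#'   (>= 0).
#' @param cutoff Exclusion threshold on the score (default 10).
#' @return List with `risk_score`, `triggered` (rule names), `excluded`.
#' @export
risk_rules <- function(properties, rule_set = list(), cutoff = 10) {
  score <- 0; trig <- character(0)
  for (rule in rule_set) {
    stopifnot(is.function(rule$predicate), rule$weight >= 0)
    hit <- tryCatch({
      r <- rule$predicate(properties)
      if (is.na(r)) stop("predicate returned NA")
      isTRUE(r)
    }, error = function(e) {
      warning("risk rule '", rule$name, "' unevaluable (", conditionMessage(e),
              "); counted as triggered", call. = FALSE)
      TRUE
    })
    if (hit) { score <- score + rule$weight; trig <- c(trig, rule$name) }
  }
  list(risk_score = score, triggered = trig, excluded = score >= cutoff)
}

#' Screen a compound library through the full cascade
#'
#' Stages in order: (1) predicted-activity cutoff on the designated model,
#' (2) Lipinski rule of five, (3) risk rules. Passing compounds are ranked
#' by predicted IC50 ascending (multi-model mode ranks by the worst-case,
#' i.e. maximum, predicted IC50 across models). The result is deterministic
#' given the inputs and invariant under row order of the library.
#'
#' @param library data.frame with `compound_id`, descriptor columns covering
#'   every model descriptor, optionally `smiles` (required for the
#'   rule-of-five stage unless `MW`/`logP`/`HBD`/`HBA` columns are present).
#' @param models A `qsar_model` or named list of them; the first is the
#'   designated ranking/threshold model.
#' @param threshold_uM Activity cutoff in micromolar (default 20).
#' @param ro5 Run the rule-of-five stage (default `TRUE` when properties are
#'   obtainable, set `FALSE` for descriptor-only libraries).
#' @param ro5_allowance See [rule_of_five()].
#' @param rule_set,risk_cutoff See [risk_rules()].
#' @return Object of class `screening_report`: list with `records` (one row
#'   per compound: predictions per model, applicability flags, stage
#'   verdicts, risk score, final verdict and failing stage), `ranked`
#'   (passing compounds in rank order) and `attrition` (per-stage counts).
#' @export
screen_library <- function(library, models, threshold_uM = 20, ro5 = TRUE,
                           ro5_allowance = 1L, rule_set = list(),
                           risk_cutoff = 10) {
  stopifnot(is.data.frame(library))
  if (nrow(library) == 0L) {
    warning("empty library")
    return(structure(list(records = library, ranked = library,
                          attrition = c(activity = 0, ro5 = 0, risk = 0)),
                     class = "screening_report"))
  }
  if (!"compound_id" %in% names(library))
    library$compound_id <- paste0("cpd", seq_len(nrow(library)))
  if (inherits(models, "qsar_model")) models <- list(models)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- paste0("model", seq_along(models))
  n <- nrow(library)

  rec <- data.frame(compound_id = library$compound_id,
                    stringsAsFactors = FALSE)
  if ("smiles" %in% names(library)) rec$smiles <- library$smiles
  worst_log <- rep(-Inf, n)
  for (mn in names(models)) {
    p <- predict(models[[mn]], library)
    rec[[paste0("pred_log_ic50_", mn)]] <- p$pred_log_ic50
    rec[[paste0("pred_ic50_uM_", mn)]] <- p$pred_ic50_uM
    adf <- applicability_flag(models[[mn]], library)
    rec[[paste0("ad_flag_", mn)]] <-
      if (identical(adf, "unavailable")) "unavailable" else adf
    worst_log <- pmax(worst_log, p$pred_log_ic50)
  }
  first <- names(models)[1]
  rec$pred_log_ic50 <- rec[[paste0("pred_log_ic50_", first)]]
  rank_log <- if (length(models) > 1L) worst_log else rec$pred_log_ic50

  # stage 1: activity
  af <- activity_filter(rec, threshold_uM)
  stage1_pass <- rec$compound_id %in% af$pass$compound_id
  unevaluated <- rec$compound_id %in% af$unevaluated$compound_id
  rec$activity_pass <- stage1_pass

  # stage 2: rule of five
  props_available <- all(c("MW", "logP", "HBD", "HBA") %in% names(library)) ||
    "smiles" %in% names(library)
  if (ro5 && !props_available)
    stop("rule-of-five stage needs MW/logP/HBD/HBA columns or a smiles column")
  rec$ro5_pass <- NA
  rec$ro5_violations <- ""
  rec$risk_score <- NA_real_
  rec$risk_pass <- NA
  get_props <- function(i) {
    if (all(c("MW", "logP", "HBD", "HBA") %in% names(library)))
      as.list(library[i, c("MW", "logP", "HBD", "HBA")])
    else rule_of_five_properties(parse_smiles(library$smiles[i]))
  }
  verdict <- ifelse(unevaluated, "unevaluated",
                    ifelse(stage1_pass, "pass", "fail"))
  stage <- ifelse(!stage1_pass & !unevaluated, "activity", "")
  for (i in which(stage1_pass)) {
    props <- NULL
    if (ro5 || length(rule_set) > 0L) props <- get_props(i)
    if (ro5) {
      r5 <- rule_of_five(props, allowance = ro5_allowance)
      rec$ro5_pass[i] <- r5$pass
      rec$ro5_violations[i] <- paste(r5$violations, collapse = ";")
      if (!r5$pass) { verdict[i] <- "fail"; stage[i] <- "rule_of_five"; next }
    }
    rr <- risk_rules(props, rule_set, cutoff = risk_cutoff)
    rec$risk_score[i] <- rr$risk_score
    rec$risk_pass[i] <- !rr$excluded
    if (rr$excluded) { verdict[i] <- "fail"; stage[i] <- "risk_rules" }
  }
  rec$verdict <- verdict
  rec$failing_stage <- stage
  attrition <- c(activity = sum(stage[nzchar(stage)] == "activity"),
                 ro5 = sum(stage == "rule_of_five"),
                 risk = sum(stage == "risk_rules"),
                 unevaluated = sum(unevaluated))
  passers <- which(verdict == "pass")
  ranked <- rec[passers[order(rank_log[passers])], , drop = FALSE]
  rownames(ranked) <- NULL
  structure(list(records = rec, ranked = ranked, attrition = attrition),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  n <- nrow(x$records)
  cat("screening_report:", n, "compounds,", nrow(x$ranked), "passed\n")
  cat("  attrition:",
      paste(names(x$attrition), x$attrition, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
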