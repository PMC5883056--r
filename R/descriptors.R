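# 2D descriptor calculators: atom-type counts, topological pair counts,
# hydrogen-bond acceptor count, rule-of-five properties, and the named
# descriptor dispatch used by the three published models.

#' Count atoms of an E-state or MMFF type
#'
#' @param graph A `molgraph`.
#' @param type_label Either an E-state environment label (e.g. `"ssssC"`) or
#'   an MMFF count label of the form `"MMFF_<n>"` (hydrogen types are counted
#'   over the implicit hydrogens).
#' @return Non-negative integer count.
#' @export
atom_type_count <- function(graph, type_label) {
  stopifnot(inherits(graph, "molgraph"))
  if (grepl("^MMFF_[0-9]+$", type_label)) {
    return(.mmff_count(graph, as.integer(sub("^MMFF_", "", type_label))))
  }
  if (!grepl("^[tdas]*[A-Z][A-Za-z]?(H[0-9]*)?[+-]*$", type_label))
    stop("unknown atom type label: '", type_label,
         "' (expected an E-state label such as 'ssssC' or 'MMFF_<n>')")
  n <- nrow(graph$atoms)
  sum(vapply(seq_len(n), function(i) estate_atom_type(graph, i),
             character(1)) == type_label)
}

# atom-class membership for topological pair descriptors
.tpair_class <- function(graph, cls) {
  a <- graph$atoms
  if (identical(cls, "T")) rep(TRUE, nrow(a))
  else if (identical(cls, "2")) a$n_double >= 1L
  else if (identical(cls, "3")) vapply(seq_len(nrow(a)), function(i)
    any(graph$bonds$order[graph$bonds$a1 == i | graph$bonds$a2 == i] == 3L),
    logical(1))
  else if (cls %in% .ELEMENTS$element) a$element == cls
  else stop("unknown atom class '", cls,
            "' (use 'T', '2', '3' or an element symbol)")
}

#' Topological atom-pair count (T_x_y_d descriptors)
#'
#' Number of unordered heavy-atom pairs \{i, j\} with i of class `class_a`,
#' j of class `class_b` (or swapped) separated by exactly `d` bonds along the
#' shortest path. Classes: `"T"` = any heavy atom; an element symbol; `"2"` =
#' atom bearing at least one (Kekule) double bond; `"3"` = atom bearing a
#' triple bond. Cross-fragment pairs (infinite distance) are never counted.
#'
#' @param graph A `molgraph`.
#' @param class_a,class_b Atom classes.
#' @param d Exact topological distance in bonds, >= 1.
#' @return Non-negative integer count.
#' @examples
#' \donttest{
#' tpair_count(parse_smiles("OCC(O)CO"), "O", "O", 3)  # glycerol: 2
#' }
#' @export
tpair_count <- function(graph, class_a, class_b, d) {
  stopifnot(inherits(graph, "molgraph"))
  if (!is.numeric(d) || length(d) != 1L || d < 1)
    stop("'d' must be a single distance >= 1")
  in_a <- .tpair_class(graph, class_a)
  in_b <- .tpair_class(graph, class_b)
  n <- nrow(graph$atoms)
  if (n < 2L) return(0L)
  cnt <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!is.finite(graph$dist[i, j]) || graph$dist[i, j] != d) next
    if ((in_a[i] && in_b[j]) || (in_b[i] && in_a[j])) cnt <- cnt + 1L
  }
  cnt
}

.hacceptor_rules <- function() {
  if (is.null(.cx_env$hacc_rules)) {
    path <- system.file("extdata", "hacceptor_rules.json", package = "cxqsar")
    .cx_env$hacc_rules <- jsonlite::fromJSON(path)
  }
  .cx_env$hacc_rules
}

#' Hydrogen-bond acceptor count (lone-pair rule set)
#'
#' Counts N and O atoms with an available lone pair under the rule set
#' shipped as data (inst/extdata/hacceptor_rules.json). The default rules
#' exclude positively charged N/O, amide/imide nitrogens and pyrrole-type
#' aromatic nitrogens. This is the `H-AcceptorCount` model descriptor and is
#' deliberately distinct from the Lipinski N+O count used by
#' [rule_of_five_properties()].
#'
#' @param graph A `molgraph`.
#' @param rules Optional rule list overriding the shipped one; a list with
#'   `elements` (character) and `exclude` (character vector of rule names
#'   among `positive_charge`, `amide_nitrogen`, `pyrrole_type_nitrogen`).
#' @return Non-negative integer count.
#' @export
h_acceptor_count <- function(graph, rules = NULL) {
  stopifnot(inherits(graph, "molgraph"))
  if (is.null(rules)) rules <- .hacceptor_rules()
  a <- graph$atoms
  cand <- which(a$element %in% rules$elements)
  excl <- rules$exclude
  ok <- vapply(cand, function(i) {
    if ("positive_charge" %in% excl && a$charge[i] > 0L) return(FALSE)
    if ("amide_nitrogen" %in% excl && a$element[i] == "N" &&
        !a$aromatic[i] &&
        any(vapply(.nbrs(graph, i), function(j)
          a$element[j] == "C" &&
            .has_bond_to(graph, j, 2L, "O", aromatic = FALSE),
          logical(1)))) return(FALSE)
    if ("pyrrole_type_nitrogen" %in% excl && a$element[i] == "N" &&
        a$aromatic[i] && (a$attached_h[i] > 0L || a$degree[i] == 3L))
      return(FALSE)
    TRUE
  }, logical(1))
  sum(ok)
}

#' Lipinski rule-of-five properties
#'
#' Molecular weight (average atomic weights, hydrogens included), logP
#' (OpenBabel atom-contribution estimator, delegated), hydrogen-bond donors
#' (N-H plus O-H hydrogens) and acceptors (total N + O count, the Lipinski
#' convention).
#'
#' @param graph A `molgraph` parsed from SMILES.
#' @return List with `MW`, `logP`, `HBD`, `HBA`. `logP` is `NA` if the
#'   estimator fails; downstream filters treat that as failing closed.
#' @examples
#' \donttest{
#' rule_of_five_properties(parse_smiles("NCC(=O)O"))  # glycine: HBD 3, HBA 3
#' }
#' @export
rule_of_five_properties <- function(graph) {
  stopifnot(inherits(graph, "molgraph"))
  a <- graph$atoms
  mw <- sum(.element_field(a$element, "weight")) +
    sum(a$attached_h) * .ELEMENTS$weight[.ELEMENTS$element == "H"]
  hbd <- sum(a$attached_h[a$element %in% c("N", "O")])
  hba <- sum(a$element %in% c("N", "O"))
  logp <- NA_real_
  if (!is.na(graph$smiles)) {
    logp <- tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(graph$smiles))
      p <- ChemmineR::propOB(sdf)
      as.numeric(p$logP[1])
    }, error = function(e) NA_real_)
  }
  list(MW = mw, logP = logp, HBD = hbd, HBA = hba)
}

# ---- named descriptor dispatch -------------------------------------------

#' Names of the descriptors used by the published models
#'
#' @param which One of `"model1"`, `"model2"`, `"model3"`, `"ro5"` or
#'   `"all"`.
#' @return Character vector of descriptor names.
#' @export
model_descriptor_names <- function(which = "all") {
  sets <- list(
    model1 = c("DeltaEpsilonC", "MMFF_29", "SssssCcount", "T_2_2_1",
               "SdsCHE-index"),
    model2 = c("SdssCE-index", "T_2_2_2", "H-AcceptorCount", "SdsCHE-index",
               "T_O_O_3"),
    model3 = c("T_T_N_4", "T_O_O_3", "SssssCE-index"),
    ro5 = c("MW", "logP", "HBD", "HBA"))
  sets$all <- unique(unlist(sets))
  if (!which %in% names(sets))
    stop("unknown descriptor set '", which, "'; use ",
         paste(names(sets), collapse = ", "))
  sets[[which]]
}

# resolve one descriptor name to a value; ro5 caches the property list
.calc_one <- function(graph, name, estate, ro5) {
  if (name == "DeltaEpsilonC") return(delta_epsilon_c(graph, estate))
  if (name == "H-AcceptorCount") return(h_acceptor_count(graph))
  if (grepl("^MMFF_[0-9]+$", name)) return(atom_type_count(graph, name))
  if (grepl("^S.+count$", name))
    return(atom_type_count(graph, sub("^S(.+)count$", "\\1", name)))
  if (grepl("^S.+E-index$", name))
    return(estate_group_index(graph, sub("^S(.+)E-index$", "\\1", name),
                              estate))
  if (grepl("^T_[^_]+_[^_]+_[0-9]+$", name)) {
    p <- strsplit(name, "_", fixed = TRUE)[[1]]
    return(tpair_count(graph, p[2], p[3], as.integer(p[4])))
  }
  if (name %in% c("MW", "logP", "HBD", "HBA")) return(ro5()[[name]])
  stop("unregistered descriptor name: '", name, "'. Known forms: ",
       "DeltaEpsilonC, H-AcceptorCount, MMFF_<n>, S<type>count, ",
       "S<type>E-index, T_<x>_<y>_<d>, MW, logP, HBD, HBA")
}

#' Compute a named descriptor vector for one molecule
#'
#' Dispatches over the registered descriptor vocabulary: `DeltaEpsilonC`,
#' `H-AcceptorCount`, `MMFF_<n>` counts, `S<type>count` atom counts,
#' `S<type>E-index` E-state sums, `T_<x>_<y>_<d>` pair counts and the
#' rule-of-five properties `MW`, `logP`, `HBD`, `HBA`.
#'
#' @param graph A `molgraph`.
#' @param descriptor_names Character vector of registered names.
#' @return Named numeric vector, one value per requested name, in order.
#' @export
descriptor_vector <- function(graph, descriptor_names) {
  stopifnot(inherits(graph, "molgraph"))
  estate <- estate_values(graph)
  ro5_cache <- NULL
  ro5 <- function() {
    if (is.null(ro5_cache)) ro5_cache <<- rule_of_five_properties(graph)
    ro5_cache
  }
  vals <- vapply(descriptor_names, function(nm)
    as.numeric(.calc_one(graph, nm, estate, ro5)), numeric(1))
  names(vals) <- descriptor_names
  vals
}

#' Compute descriptors for a set of SMILES
#'
#' @param smiles Character vector of SMILES strings.
#' @param descriptor_names Registered descriptor names, or a set keyword
#'   accepted by [model_descriptor_names()].
#' @param ids Optional compound ids (defaults to the SMILES).
#' @param fail_fast If `TRUE`, stop on the first unparsable molecule;
#'   otherwise record the error per row and continue.
#' @return data.frame with `compound_id`, `smiles`, one column per
#'   descriptor, and (when `fail_fast = FALSE`) an `error` column.
#' @export
calc_descriptors <- function(smiles, descriptor_names = "all", ids = NULL,
                             fail_fast = TRUE) {
  if (length(descriptor_names) == 1L &&
      descriptor_names %in% c("model1", "model2", "model3", "ro5", "all"))
    descriptor_names <- model_descriptor_names(descriptor_names)
  if (is.null(ids)) ids <- smiles
  rows <- vector("list", length(smiles))
  errs <- rep(NA_character_, length(smiles))
  for (i in seq_along(smiles)) {
    v <- tryCatch(descriptor_vector(parse_smiles(smiles[i]), descriptor_names),
                  error = function(e) e)
    if (inherits(v, "error")) {
      if (fail_fast) stop("molecule ", ids[i], ": ", conditionMessage(v))
      errs[i] <- conditionMessage(v)
      v <- stats::setNames(rep(NA_real_, length(descriptor_names)),
                           descriptor_names)
    }
    rows[[i]] <- v
  }
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  out <- cbind(data.frame(compound_id = ids, smiles = smiles,
                          stringsAsFactors = FALSE), out)
  if (!fail_fast) out$error <- errs
  rownames(out) <- NULL
  out
}
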