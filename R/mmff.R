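# MMFF94 symbolic atom typing, rule-table backend.
#
# The models only consume one MMFF count descriptor (MMFF_29, the
# phenolic/enolic hydroxyl hydrogen, symbolic HOCC), but the typer covers the
# common organic environments so that MMFF_<n> counts are generally
# available. The numeric-type -> symbolic-type table and the matching-rule
# ids are shipped as JSON data (inst/extdata/mmff_types.json) so the typing
# is auditable and the backend replaceable: `backend` may be any function
# (graph, atom_index, hydrogens) -> label.

.cx_env <- new.env(parent = emptyenv())

.mmff_table <- function() {
  if (is.null(.cx_env$mmff_table)) {
    path <- system.file("extdata", "mmff_types.json", package = "cxqsar")
    .cx_env$mmff_table <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  .cx_env$mmff_table
}

# neighbour indices of atom i over heavy bonds, optionally restricted
.nbrs <- function(graph, i) {
  b <- graph$bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

# does atom i have a bond of given order to an atom of element el?
.has_bond_to <- function(graph, i, order, el = NULL, aromatic = NA) {
  b <- graph$bonds
  inc <- which(b$a1 == i | b$a2 == i)
  for (r in inc) {
    j <- if (b$a1[r] == i) b$a2[r] else b$a1[r]
    if (!is.null(order) && b$order[r] != order) next
    if (!is.na(aromatic) && b$aromatic[r] != aromatic) next
    if (!is.null(el) && graph$atoms$element[j] != el) next
    return(TRUE)
  }
  FALSE
}

# Rule predicates, keyed by the `rule` field of the shipped table. Each takes
# (graph, i) for a heavy atom; hydrogen types are resolved through the heavy
# atom the hydrogens sit on.
.mmff_rules <- list(
  carbonyl_carbon = function(g, i)
    g$atoms$element[i] == "C" && .has_bond_to(g, i, 2L, "O", aromatic = FALSE),
  vinylic_carbon = function(g, i)
    g$atoms$element[i] == "C" && !g$atoms$aromatic[i] &&
      g$atoms$n_double[i] >= 1L && !.has_bond_to(g, i, 2L, "O", aromatic = FALSE),
  aromatic_carbon = function(g, i)
    g$atoms$element[i] == "C" && g$atoms$aromatic[i],
  alkyl_carbon = function(g, i)
    g$atoms$element[i] == "C" && !g$atoms$aromatic[i] &&
      g$atoms$n_double[i] == 0L && !.has_bond_to(g, i, 3L),
  ether_hydroxyl_oxygen = function(g, i)
    g$atoms$element[i] == "O" && g$atoms$charge[i] == 0L &&
      !g$atoms$aromatic[i] && g$atoms$n_double[i] == 0L,
  carbonyl_oxygen = function(g, i)
    g$atoms$element[i] == "O" && g$atoms$n_double[i] >= 1L,
  aromatic_oxygen = function(g, i)
    g$atoms$element[i] == "O" && g$atoms$aromatic[i],
  pyridine_nitrogen = function(g, i)
    g$atoms$element[i] == "N" && g$atoms$aromatic[i] &&
      g$atoms$attached_h[i] == 0L && g$atoms$degree[i] == 2L,
  pyrrole_nitrogen = function(g, i)
    g$atoms$element[i] == "N" && g$atoms$aromatic[i] &&
      (g$atoms$attached_h[i] > 0L || g$atoms$degree[i] == 3L),
  amide_nitrogen = function(g, i)
    g$atoms$element[i] == "N" && !g$atoms$aromatic[i] &&
      any(vapply(.nbrs(g, i), function(j)
        g$atoms$element[j] == "C" && .has_bond_to(g, j, 2L, "O", aromatic = FALSE),
        logical(1))),
  amine_nitrogen = function(g, i)
    g$atoms$element[i] == "N" && !g$atoms$aromatic[i] &&
      g$atoms$n_double[i] == 0L && g$atoms$charge[i] == 0L,
  thio_sulfur = function(g, i)
    g$atoms$element[i] == "S" && g$atoms$n_double[i] == 0L,
  fluorine = function(g, i) g$atoms$element[i] == "F",
  chlorine = function(g, i) g$atoms$element[i] == "Cl",
  bromine = function(g, i) g$atoms$element[i] == "Br",
  iodine = function(g, i) g$atoms$element[i] == "I",
  # hydrogen rules: i is the heavy atom carrying the hydrogens
  h_on_carboxyl_oxygen = function(g, i)
    g$atoms$element[i] == "O" && g$atoms$attached_h[i] > 0L &&
      any(vapply(.nbrs(g, i), function(j)
        g$atoms$element[j] == "C" && .has_bond_to(g, j, 2L, "O", aromatic = FALSE),
        logical(1))),
  h_on_enol_phenol_oxygen = function(g, i)
    g$atoms$element[i] == "O" && g$atoms$attached_h[i] > 0L &&
      !.mmff_rules$h_on_carboxyl_oxygen(g, i) &&
      any(vapply(.nbrs(g, i), function(j)
        g$atoms$element[j] == "C" &&
          (g$atoms$aromatic[j] || .has_bond_to(g, j, 2L, "C", aromatic = FALSE)),
        logical(1))),
  h_on_oxygen = function(g, i)
    g$atoms$element[i] == "O" && g$atoms$attached_h[i] > 0L,
  h_on_nitrogen = function(g, i)
    g$atoms$element[i] == "N" && g$atoms$attached_h[i] > 0L,
  h_on_carbon = function(g, i)
    g$atoms$element[i] == "C" && g$atoms$attached_h[i] > 0L
)

.mmff_type_one <- function(graph, i, hydrogens) {
  tab <- .mmff_table()
  rows <- tab[tab$hydrogen == hydrogens, , drop = FALSE]
  for (r in seq_len(nrow(rows))) {
    pred <- .mmff_rules[[rows$rule[r]]]
    if (!is.null(pred) && isTRUE(pred(graph, i)))
      return(list(numeric = rows$numeric[r], symbol = rows$symbol[r]))
  }
  list(numeric = NA_integer_, symbol = "untyped")
}

#' MMFF94 symbolic atom type (rule-table backend)
#'
#' Types a heavy atom, or the hydrogens attached to it, under the shipped
#' MMFF94 rule table. Atoms not covered by the table get the explicit label
#' `"untyped"` (never a silent type 0).
#'
#' @param graph A `molgraph`.
#' @param atom_index 1-based heavy-atom index.
#' @param hydrogens If `TRUE`, type the hydrogens attached to `atom_index`
#'   rather than the atom itself (MMFF hydrogen types such as 29/HOCC live on
#'   hydrogens; in the hydrogen-suppressed graph they are addressed through
#'   their parent heavy atom).
#' @param backend Optional replacement typer, a function
#'   `(graph, atom_index, hydrogens)` returning a list with `numeric` and
#'   `symbol`.
#' @return List with `numeric` (MMFF numeric type or `NA`) and `symbol`.
#' @export
mmff_symbolic_type <- function(graph, atom_index, hydrogens = FALSE,
                               backend = NULL) {
  stopifnot(inherits(graph, "molgraph"))
  n <- nrow(graph$atoms)
  if (!(atom_index >= 1 && atom_index <= n)) stop("invalid atom index")
  if (!is.null(backend)) return(backend(graph, atom_index, hydrogens))
  if (hydrogens && graph$atoms$attached_h[atom_index] == 0L)
    return(list(numeric = NA_integer_, symbol = "untyped"))
  .mmff_type_one(graph, atom_index, hydrogens)
}

#' Full MMFF typing table for a molecule
#'
#' @param graph A `molgraph`.
#' @param backend See [mmff_symbolic_type()].
#' @return data.frame with one row per heavy atom: element, heavy-atom
#'   numeric/symbolic type, count of attached hydrogens and their type.
#' @export
mmff_types <- function(graph, backend = NULL) {
  stopifnot(inherits(graph, "molgraph"))
  n <- nrow(graph$atoms)
  out <- data.frame(
    atom = seq_len(n), element = graph$atoms$element,
    type_num = NA_integer_, type_sym = "untyped",
    n_h = graph$atoms$attached_h,
    h_type_num = NA_integer_, h_type_sym = "untyped",
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    t1 <- mmff_symbolic_type(graph, i, FALSE, backend)
    out$type_num[i] <- t1$numeric; out$type_sym[i] <- t1$symbol
    if (out$n_h[i] > 0L) {
      t2 <- mmff_symbolic_type(graph, i, TRUE, backend)
      out$h_type_num[i] <- t2$numeric; out$h_type_sym[i] <- t2$symbol
    }
  }
  out
}

# count of atoms (hydrogens included, via their parent heavy atom) with a
# given MMFF numeric type
.mmff_count <- function(graph, numeric_type, backend = NULL) {
  tt <- mmff_types(graph, backend)
  sum(tt$type_num == numeric_type, na.rm = TRUE) +
    sum(tt$n_h[which(tt$h_type_num == numeric_type)])
}
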