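# Molecular graph construction: SMILES -> hydrogen-suppressed graph with
# atom typing fields and an all-pairs topological distance matrix.

# Element data for the organic subset handled by the descriptor engine.
.ELEMENTS <- data.frame(
  element = c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I"),
  Z       = c(1, 5, 6, 7, 8, 9, 14, 15, 16, 17, 35, 53),
  Zv      = c(1, 3, 4, 5, 6, 7, 4, 5, 6, 7, 7, 7),
  period  = c(1, 2, 2, 2, 2, 2, 3, 3, 3, 3, 4, 5),
  weight  = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998,
              28.086, 30.974, 32.06, 35.453, 79.904, 126.904),
  stringsAsFactors = FALSE
)

.element_field <- function(elements, field) {
  i <- match(elements, .ELEMENTS$element)
  if (anyNA(i)) {
    stop("unsupported element(s): ",
         paste(unique(elements[is.na(i)]), collapse = ", "))
  }
  .ELEMENTS[[field]][i]
}

#' Parse a SMILES string into a hydrogen-suppressed molecular graph
#'
#' The molecule is read through OpenBabel (via \pkg{ChemmineOB}), which
#' performs a fixed, deterministic Kekulization of aromatic input. Hydrogens
#' are folded into per-atom `attached_h` counts; all structural descriptors
#' operate on the heavy-atom graph. Aromaticity is perceived on the ring
#' system and recorded both per atom and per bond, so that E-state typing can
#' distinguish aromatic ('a') from genuine double ('d') bond environments
#' while Kekule double bonds still feed `double_bond_count`.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `molgraph`: a list with elements
#'   \describe{
#'     \item{atoms}{data.frame with one row per heavy atom: `element`,
#'       `charge`, `attached_h`, `degree` (heavy-atom sigma degree),
#'       `n_double` (Kekule double bonds at the atom), `aromatic`,
#'       `Zv` (valence electrons), `period` (principal quantum number),
#'       `Z` (atomic number).}
#'     \item{bonds}{data.frame `a1`, `a2`, `order` (1/2/3), `aromatic`.}
#'     \item{dist}{symmetric matrix of shortest-path bond counts; `Inf`
#'       between disconnected fragments.}
#'     \item{smiles}{the input SMILES.}
#'     \item{n_fragments}{number of connected components.}
#'   }
#'   Atom indices are 1-based throughout.
#' @examples
#' \donttest{
#' g <- parse_smiles("OCCO")
#' g$dist[1, 4]  # 3 bonds between the two oxygens
#' }
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles)))
    stop("'smiles' must be a single non-empty string")
  smiles <- trimws(smiles)
  sdf_text <- tryCatch(
    ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, "\n"),
      options = data.frame(names = "h", args = "", stringsAsFactors = FALSE)),
    error = function(e) "")
  if (!grepl("V2000", sdf_text, fixed = TRUE))
    stop("SMILES parse error: could not interpret '", smiles, "'")
  sdf <- suppressWarnings(
    ChemmineR::read.SDFset(strsplit(sdf_text, "\n", fixed = TRUE)[[1]]))[[1]]
  molgraph_from_sdf(sdf, smiles = smiles, sdf_text = sdf_text)
}

# Build a molgraph from a ChemmineR SDF object that carries explicit
# hydrogens. Heavy-atom order follows the SDF atom block.
molgraph_from_sdf <- function(sdf, smiles = NA_character_, sdf_text = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  elements_all <- sub("_[0-9]+$", "", rownames(ab))
  n_all <- length(elements_all)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(bb)) || nrow(bb) == 0L) {
    bb <- matrix(numeric(0), ncol = 3)
  } else {
    bb <- unname(as.matrix(bb[, 1:3, drop = FALSE]))
  }
  charges_all <- rep(0L, n_all)
  if (!is.null(sdf_text)) {
    for (ln in grep("^M  CHG", strsplit(sdf_text, "\n", fixed = TRUE)[[1]],
                    value = TRUE)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      k <- f[1]
      for (j in seq_len(k)) charges_all[f[2 * j]] <- f[2 * j + 1]
    }
  }
  heavy <- which(elements_all != "H")
  if (length(heavy) == 0L) stop("molecule has no heavy atoms")
  new_idx <- rep(NA_integer_, n_all)
  new_idx[heavy] <- seq_along(heavy)
  n <- length(heavy)

  elements <- elements_all[heavy]
  attached_h <- integer(n)
  keep <- logical(nrow(bb))
  for (r in seq_len(nrow(bb))) {
    i <- bb[r, 1]; j <- bb[r, 2]
    hi <- elements_all[i] == "H"; hj <- elements_all[j] == "H"
    if (hi && hj) next
    if (hi) { attached_h[new_idx[j]] <- attached_h[new_idx[j]] + 1L; next }
    if (hj) { attached_h[new_idx[i]] <- attached_h[new_idx[i]] + 1L; next }
    keep[r] <- TRUE
  }
  hb <- bb[keep, , drop = FALSE]
  bonds <- data.frame(
    a1 = new_idx[hb[, 1]], a2 = new_idx[hb[, 2]],
    order = as.integer(hb[, 3]))
  if (any(bonds$a1 == bonds$a2)) stop("self-bond in structure")

  # aromatic perception on the ring system (ChemmineR ring finder)
  arom_atom <- logical(n)
  arom_bond <- logical(nrow(bonds))
  if (nrow(bonds) >= 3L) {
    rr <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE)),
      error = function(e) NULL)
    if (!is.null(rr) && length(rr$RINGS) > 0L) {
      bond_key <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
      for (k in seq_along(rr$RINGS)) {
        if (!isTRUE(rr$AROMATIC[[k]])) next
        ring_old <- as.integer(sub("^.*_", "", rr$RINGS[[k]]))
        ring <- new_idx[ring_old]
        if (anyNA(ring)) next
        arom_atom[ring] <- TRUE
        nxt <- c(ring[-1], ring[1])
        arom_bond[bond_key %in% paste(pmin(ring, nxt), pmax(ring, nxt))] <- TRUE
      }
    }
  }
  bonds$aromatic <- arom_bond

  molgraph(elements, bonds, charge = charges_all[heavy],
           attached_h = attached_h, aromatic = arom_atom, smiles = smiles)
}

#' Construct a molecular graph from parts
#'
#' Low-level constructor used by the SMILES reader, the synthetic-graph
#' generators and the tests. Derives sigma degree, double-bond counts and the
#' topological distance matrix (breadth-first shortest paths via
#' \pkg{igraph}) from the bond list.
#'
#' @param elements Character vector of heavy-atom element symbols.
#' @param bonds data.frame with columns `a1`, `a2`, `order` (1/2/3) and
#'   optionally `aromatic` (logical).
#' @param charge Integer formal charges (default all 0).
#' @param attached_h Integer counts of attached hydrogens (default all 0).
#' @param aromatic Logical per-atom aromatic flags (default from bonds).
#' @param smiles Optional source SMILES recorded on the object.
#' @return A `molgraph` object; see [parse_smiles()].
#' @export
molgraph <- function(elements, bonds, charge = NULL, attached_h = NULL,
                     aromatic = NULL, smiles = NA_character_) {
  n <- length(elements)
  if (n == 0L) stop("empty molecule")
  if (is.null(charge)) charge <- rep(0L, n)
  if (is.null(attached_h)) attached_h <- rep(0L, n)
  if (nrow(bonds) > 0) {
    if (any(bonds$a1 < 1 | bonds$a1 > n | bonds$a2 < 1 | bonds$a2 > n))
      stop("bond endpoint out of range")
    if (any(bonds$a1 == bonds$a2)) stop("self-bond")
  }
  if (is.null(bonds$aromatic)) bonds$aromatic <- rep(FALSE, nrow(bonds))
  degree <- n_double <- integer(n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$a1[r]; j <- bonds$a2[r]
    degree[i] <- degree[i] + 1L; degree[j] <- degree[j] + 1L
    if (bonds$order[r] == 2L) {
      n_double[i] <- n_double[i] + 1L; n_double[j] <- n_double[j] + 1L
    }
  }
  if (is.null(aromatic)) {
    aromatic <- logical(n)
    ar <- bonds[bonds$aromatic, , drop = FALSE]
    aromatic[c(ar$a1, ar$a2)] <- TRUE
  }
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(bonds) > 0)
    ig <- igraph::add_edges(ig, rbind(bonds$a1, bonds$a2))
  d <- igraph::distances(ig)
  dimnames(d) <- NULL
  atoms <- data.frame(
    element = elements,
    charge = as.integer(charge),
    attached_h = as.integer(attached_h),
    degree = degree,
    n_double = n_double,
    aromatic = aromatic,
    Zv = .element_field(elements, "Zv"),
    period = .element_field(elements, "period"),
    Z = .element_field(elements, "Z"),
    stringsAsFactors = FALSE)
  structure(
    list(atoms = atoms, bonds = bonds, dist = d, smiles = smiles,
         n_fragments = igraph::components(ig)$no),
    class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat("molgraph:", nrow(x$atoms), "heavy atoms,", nrow(x$bonds), "bonds")
  if (!is.na(x$smiles)) cat(" [", x$smiles, "]", sep = "")
  if (x$n_fragments > 1) cat(" (", x$n_fragments, " fragments)", sep = "")
  cat("\n")
  invisible(x)
}

#' Canonical SMILES of a parsed molecule
#'
#' @param graph A `molgraph` with a recorded source SMILES.
#' @return Canonical SMILES string (OpenBabel canonicalization).
#' @export
canonical_smiles <- function(graph) {
  stopifnot(inherits(graph, "molgraph"))
  if (is.na(graph$smiles)) stop("graph carries no source SMILES")
  out <- ChemmineOB::convertFormat("SMI", "CAN", paste0(graph$smiles, "\n"))
  strsplit(trimws(out), "[ \t]")[[1]][1]
}

#' E-state atom-type label
#'
#' Returns the systematic electrotopological-state bonding-environment label
#' of a heavy atom: bond symbols in priority order t (triple), d (double),
#' a (aromatic), s (single), followed by the element symbol, an H count
#' suffix, and a charge mark. Aromatic bonds keep their own 'a' symbol, so a
#' benzene carbon is `aaCH`, never `dsCH`; the labels the published models
#' rely on are `dsCH`, `dssC` and `ssssC`.
#'
#' @param graph A `molgraph`.
#' @param atom_index 1-based heavy-atom index.
#' @return A single character label, e.g. `"dsCH"`, `"ssssC"`, `"aaCH"`.
#' @examples
#' \donttest{
#' estate_atom_type(parse_smiles("C=CC"), 2)  # "dsCH"
#' }
#' @export
estate_atom_type <- function(graph, atom_index) {
  stopifnot(inherits(graph, "molgraph"))
  n <- nrow(graph$atoms)
  if (!(atom_index >= 1 && atom_index <= n)) stop("invalid atom index")
  b <- graph$bonds
  inc <- b$a1 == atom_index | b$a2 == atom_index
  sym <- character(0)
  if (any(inc)) {
    sym <- ifelse(b$aromatic[inc], "a",
                  c("s", "d", "t")[b$order[inc]])
  }
  sym <- sym[order(match(sym, c("t", "d", "a", "s")))]
  h <- graph$atoms$attached_h[atom_index]
  hs <- if (h == 0) "" else if (h == 1) "H" else paste0("H", h)
  ch <- graph$atoms$charge[atom_index]
  cs <- if (ch > 0) strrep("+", ch) else if (ch < 0) strrep("-", -ch) else ""
  paste0(paste(sym, collapse = ""), graph$atoms$element[atom_index], hs, cs)
}
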