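# Independent brute-force oracle for the descriptor engine.
#
# Plain, loop-based implementations kept strictly apart from the package
# code: distances by Floyd-Warshall (the engine uses BFS), E-state sums by
# explicit double loops over ordered pairs, pair counts by exhaustive
# enumeration over the distance matrix. These functions consume the parsed
# atom/bond substrate of a molgraph but recompute everything downstream on
# their own. scripts/build_fixtures.R freezes their output for the packaged
# fixture set.

oracle_fw_dist <- function(graph) {
  n <- nrow(graph$atoms)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (r in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$a1[r]; j <- graph$bonds$a2[r]
    d[i, j] <- 1; d[j, i] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# systematic E-state label, written out longhand
oracle_type <- function(graph, i) {
  syms <- c()
  for (r in seq_len(nrow(graph$bonds))) {
    b <- graph$bonds[r, ]
    if (b$a1 != i && b$a2 != i) next
    if (isTRUE(b$aromatic)) syms <- c(syms, "a")
    else if (b$order == 1) syms <- c(syms, "s")
    else if (b$order == 2) syms <- c(syms, "d")
    else syms <- c(syms, "t")
  }
  ord <- c(t = 1, d = 2, a = 3, s = 4)
  syms <- syms[order(ord[syms])]
  h <- graph$atoms$attached_h[i]
  hsuf <- if (h == 0) "" else if (h == 1) "H" else paste0("H", h)
  ch <- graph$atoms$charge[i]
  csuf <- if (ch > 0) paste(rep("+", ch), collapse = "") else
    if (ch < 0) paste(rep("-", -ch), collapse = "") else ""
  paste0(paste(syms, collapse = ""), graph$atoms$element[i], hsuf, csuf)
}

# per-atom I, dI, S, epsilon via explicit loops
oracle_estate <- function(graph) {
  a <- graph$atoms
  n <- nrow(a)
  d <- oracle_fw_dist(graph)
  I <- eps <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    delta <- a$degree[i]
    dv <- if (a$period[i] == 2) a$Zv[i] - a$attached_h[i] else
      (a$Zv[i] - a$attached_h[i]) / (a$Z[i] - a$Zv[i] - 1)
    eps[i] <- (dv - delta) / a$period[i]^2
    if (delta >= 1) I[i] <- ((2 / a$period[i])^2 * dv + 1) / delta
  }
  dI <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(I[i])) next
    s <- 0
    for (j in seq_len(n)) {
      if (j == i || is.na(I[j]) || !is.finite(d[i, j])) next
      s <- s + (I[i] - I[j]) / (d[i, j] + 1)^2
    }
    dI[i] <- s
  }
  data.frame(I = I, dI = dI, S = I + dI, epsilon = eps)
}

oracle_group_index <- function(graph, label) {
  es <- oracle_estate(graph)
  total <- 0
  for (i in seq_len(nrow(graph$atoms)))
    if (!is.na(es$S[i]) && oracle_type(graph, i) == label)
      total <- total + es$S[i]
  total
}

oracle_type_count <- function(graph, label) {
  cnt <- 0
  for (i in seq_len(nrow(graph$atoms)))
    if (oracle_type(graph, i) == label) cnt <- cnt + 1
  cnt
}

oracle_tpair <- function(graph, cls_a, cls_b, dd) {
  d <- oracle_fw_dist(graph)
  n <- nrow(graph$atoms)
  member <- function(i, cls) {
    if (cls == "T") return(TRUE)
    if (cls == "2") {
      for (r in seq_len(nrow(graph$bonds))) {
        b <- graph$bonds[r, ]
        if ((b$a1 == i || b$a2 == i) && b$order == 2) return(TRUE)
      }
      return(FALSE)
    }
    graph$atoms$element[i] == cls
  }
  cnt <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (!is.finite(d[i, j]) || d[i, j] != dd) next
    if ((member(i, cls_a) && member(j, cls_b)) ||
        (member(i, cls_b) && member(j, cls_a))) cnt <- cnt + 1
  }
  cnt
}

oracle_delta_epsilon_c <- function(graph) {
  es <- oracle_estate(graph)
  vals <- c()
  for (i in seq_len(nrow(graph$atoms)))
    if (graph$atoms$element[i] == "C") vals <- c(vals, es$epsilon[i])
  if (length(vals) < 2) return(0)
  mx <- vals[1]; mn <- vals[1]
  for (v in vals) { if (v > mx) mx <- v; if (v < mn) mn <- v }
  mx - mn
}

oracle_neighbors <- function(graph, i) {
  out <- c()
  for (r in seq_len(nrow(graph$bonds))) {
    b <- graph$bonds[r, ]
    if (b$a1 == i) out <- c(out, b$a2)
    if (b$a2 == i) out <- c(out, b$a1)
  }
  out
}

oracle_hacceptor <- function(graph) {
  a <- graph$atoms
  cnt <- 0
  for (i in seq_len(nrow(a))) {
    if (!a$element[i] %in% c("N", "O")) next
    if (a$charge[i] > 0) next
    if (a$element[i] == "N") {
      if (a$aromatic[i] && (a$attached_h[i] > 0 || a$degree[i] == 3)) next
      if (!a$aromatic[i]) {
        amide <- FALSE
        for (j in oracle_neighbors(graph, i)) {
          if (a$element[j] != "C") next
          for (r in seq_len(nrow(graph$bonds))) {
            b <- graph$bonds[r, ]
            if ((b$a1 == j || b$a2 == j) && b$order == 2 && !b$aromatic) {
              other <- if (b$a1 == j) b$a2 else b$a1
              if (a$element[other] == "O") amide <- TRUE
            }
          }
        }
        if (amide) next
      }
    }
    cnt <- cnt + 1
  }
  cnt
}

# count of phenolic/enolic hydroxyl hydrogens (MMFF numeric type 29)
oracle_mmff29 <- function(graph) {
  a <- graph$atoms
  cnt <- 0
  for (i in seq_len(nrow(a))) {
    if (a$element[i] != "O" || a$attached_h[i] == 0) next
    carboxyl <- FALSE; enol <- FALSE
    for (j in oracle_neighbors(graph, i)) {
      if (a$element[j] != "C") next
      if (a$aromatic[j]) enol <- TRUE
      for (r in seq_len(nrow(graph$bonds))) {
        b <- graph$bonds[r, ]
        if ((b$a1 == j || b$a2 == j) && b$order == 2 && !b$aromatic) {
          other <- if (b$a1 == j) b$a2 else b$a1
          if (a$element[other] == "O") carboxyl <- TRUE
          if (a$element[other] == "C") enol <- TRUE
        }
      }
    }
    if (enol && !carboxyl) cnt <- cnt + a$attached_h[i]
  }
  cnt
}

oracle_weights <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007,
                    O = 15.999, F = 18.998, Si = 28.086, P = 30.974,
                    S = 32.06, Cl = 35.453, Br = 79.904, I = 126.904)

oracle_mw <- function(graph) {
  a <- graph$atoms
  total <- 0
  for (i in seq_len(nrow(a)))
    total <- total + oracle_weights[[a$element[i]]] +
      a$attached_h[i] * oracle_weights[["H"]]
  total
}

oracle_hbd <- function(graph) {
  a <- graph$atoms
  cnt <- 0
  for (i in seq_len(nrow(a)))
    if (a$element[i] %in% c("N", "O")) cnt <- cnt + a$attached_h[i]
  cnt
}

oracle_hba <- function(graph) {
  cnt <- 0
  for (e in graph$atoms$element) if (e %in% c("N", "O")) cnt <- cnt + 1
  cnt
}

# the full frozen descriptor set for the fixture table
oracle_descriptor_vector <- function(graph) {
  c("DeltaEpsilonC" = oracle_delta_epsilon_c(graph),
    "MMFF_29" = oracle_mmff29(graph),
    "SssssCcount" = oracle_type_count(graph, "ssssC"),
    "T_2_2_1" = oracle_tpair(graph, "2", "2", 1),
    "SdsCHE-index" = oracle_group_index(graph, "dsCH"),
    "SdssCE-index" = oracle_group_index(graph, "dssC"),
    "T_2_2_2" = oracle_tpair(graph, "2", "2", 2),
    "H-AcceptorCount" = oracle_hacceptor(graph),
    "T_O_O_3" = oracle_tpair(graph, "O", "O", 3),
    "T_T_N_4" = oracle_tpair(graph, "T", "N", 4),
    "SssssCE-index" = oracle_group_index(graph, "ssssC"),
    "MW" = oracle_mw(graph),
    "HBD" = oracle_hbd(graph),
    "HBA" = oracle_hba(graph))
}

# the fixture SMILES set (also used by scripts/build_fixtures.R)
fixture_smiles_set <- function() {
  c(methane = "C",
    ethane = "CC",
    ethene = "C=C",
    propene = "C=CC",
    isobutylene = "CC(=C)C",
    butadiene = "C=CC=C",
    neopentane = "CC(C)(C)C",
    benzene = "c1ccccc1",
    toluene = "Cc1ccccc1",
    phenol = "Oc1ccccc1",
    ethanol = "CCO",
    glycol = "OCCO",
    glycerol = "OCC(O)CO",
    acetone = "CC(C)=O",
    acetic_acid = "CC(=O)O",
    acetamide = "CC(=O)N",
    acrolein = "C=CC=O",
    pyridine = "c1ccncc1",
    pyrrole = "c1cc[nH]c1",
    aniline = "Nc1ccccc1",
    aminopyridine = "Nc1ccncc1",
    anisole = "COc1ccccc1",
    xanthone = "O=C1c2ccccc2Oc2ccccc21",
    caged_enone = "CC1(C)C2CC3CC1C(=O)C3(O)C2",
    tbutyl_phenol = "CC(C)(C)c1ccc(O)cc1")
}
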