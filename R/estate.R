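# Electrotopological-state (E-state) indices, Kier-Hall formulation.
#
# For each heavy atom: valence delta dv = Zv - h (second row) or
# (Zv - h)/(Z - Zv - 1) (higher rows); intrinsic state I = ((2/N)^2 dv + 1)/d;
# perturbation dI_i = sum_j (I_i - I_j)/(d_ij + 1)^2 over heavy atoms of the
# same fragment; E-state S = I + dI; Kier-Hall relative electronegativity
# eps = (dv - d)/N^2.

#' Per-atom E-state values
#'
#' Computes the Kier-Hall electrotopological-state quantities for every heavy
#' atom: sigma degree, valence delta, intrinsic state, perturbation, E-state
#' value, electronegativity and the systematic E-state type label.
#'
#' Isolated heavy atoms (sigma degree 0) have no defined intrinsic state; by
#' default they are flagged `estate_defined = FALSE` and carry `NA` for I and
#' S (they are skipped by, and do not perturb, the other atoms). With
#' `isolated = "unit_degree"` the degree is treated as 1 instead.
#' Cross-fragment perturbation terms are zero (infinite topological distance).
#'
#' @param graph A `molgraph`.
#' @param isolated How to treat atoms with no heavy neighbours: `"undefined"`
#'   (default) or `"unit_degree"`.
#' @return data.frame with one row per atom: `element`, `delta`, `delta_v`,
#'   `period`, `I`, `dI`, `S`, `epsilon`, `type`, `estate_defined`.
#' @examples
#' \donttest{
#' estate_values(parse_smiles("CC"))$I  # both carbons: 2.0
#' }
#' @export
estate_values <- function(graph, isolated = c("undefined", "unit_degree")) {
  stopifnot(inherits(graph, "molgraph"))
  isolated <- match.arg(isolated)
  a <- graph$atoms
  n <- nrow(a)
  delta <- a$degree
  delta_v <- ifelse(a$period == 2L, a$Zv - a$attached_h,
                    (a$Zv - a$attached_h) / (a$Z - a$Zv - 1))
  eff_delta <- delta
  defined <- delta >= 1L
  if (isolated == "unit_degree") {
    eff_delta[!defined] <- 1L
    defined <- rep(TRUE, n)
  }
  I <- ifelse(defined, ((2 / a$period)^2 * delta_v + 1) / eff_delta, NA_real_)
  dI <- rep(NA_real_, n)
  idx <- which(defined)
  if (length(idx) >= 1L) {
    d <- graph$dist[idx, idx, drop = FALSE]
    w <- 1 / (d + 1)^2
    w[!is.finite(d)] <- 0            # disconnected fragments never interact
    diag(w) <- 0
    Ii <- I[idx]
    # dI_i = sum_j w_ij (I_i - I_j)
    dI[idx] <- Ii * rowSums(w) - as.vector(w %*% Ii)
  }
  S <- I + dI
  eps <- (delta_v - delta) / a$period^2
  data.frame(
    element = a$element, delta = delta, delta_v = delta_v,
    period = a$period, I = I, dI = dI, S = S, epsilon = eps,
    type = vapply(seq_len(n), function(i) estate_atom_type(graph, i),
                  character(1)),
    estate_defined = defined,
    stringsAsFactors = FALSE)
}

#' E-state group index: sum of S over atoms of a bonding environment
#'
#' Realizes the `SdsCHE-index`, `SdssCE-index` and `SssssCE-index`
#' descriptors: the sum of per-atom E-state values over all atoms whose
#' systematic type matches `type_label`. Returns 0 when no atom matches.
#'
#' @param graph A `molgraph`.
#' @param type_label E-state type label, e.g. `"dsCH"`, `"dssC"`, `"ssssC"`.
#' @param estate Optional precomputed [estate_values()] table.
#' @return Sum of S over matching atoms (0 if none).
#' @export
estate_group_index <- function(graph, type_label, estate = NULL) {
  if (is.null(estate)) estate <- estate_values(graph)
  m <- estate$type == type_label & estate$estate_defined
  if (!any(m)) return(0.0)
  sum(estate$S[m])
}

#' Carbon electronegativity spread (DeltaEpsilonC)
#'
#' The adopted definition of the `DeltaEpsilonC` descriptor: the range
#' (max - min) of the Kier-Hall relative electronegativity
#' eps = (delta_v - delta)/N^2 taken over carbon atoms only; 0 when the
#' molecule has fewer than two carbons.
#'
#' @param graph A `molgraph`.
#' @param estate Optional precomputed [estate_values()] table.
#' @return Non-negative spread value.
#' @export
delta_epsilon_c <- function(graph, estate = NULL) {
  if (is.null(estate)) estate <- estate_values(graph)
  eps <- estate$epsilon[estate$element == "C"]
  if (length(eps) < 2L) return(0.0)
  max(eps) - min(eps)
}
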