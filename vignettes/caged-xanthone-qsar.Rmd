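---
title: "Methods: 2D-QSAR modeling, validation and screening in cxqsar"
author: "cxqsar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2D-QSAR modeling, validation and screening in cxqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxqsar)
```

## Scope and model

`cxqsar` implements a classical 2D-QSAR workflow for caged-xanthone
anticancer series: descriptor calculation from SMILES, rational train/test
splitting, stepwise-forward multiple linear regression, a twelve-item
statistical validation battery, and a ligand-based virtual-screening
cascade. The response throughout is log10 IC50 in micromolar; lower values
mean higher potency. The model class is deliberately plain ordinary least
squares on a small descriptor set — the regime where leave-one-out
statistics, Y-randomization and range-based applicability domains are
meaningful and cheap.

Three frozen cell-line equations (A549, HepG2, U251) ship as packaged JSON
coefficient sets and are treated as data, not code: `published_model()`
loads them, `predict()` evaluates the affine scoring function on raw
(unscaled) descriptor values, and a unit test pins every packaged
coefficient to its known value. The frozen models carry no training
descriptor ranges, so their applicability flag is reported as
`"unavailable"` rather than silently 0.

## The molecular graph

Molecules enter as SMILES and are parsed through OpenBabel
(ChemmineR/ChemmineOB). The working representation is a hydrogen-suppressed
graph: heavy atoms with `attached_h` counts, bonds with discrete orders, and
an all-pairs shortest-path matrix (breadth-first search via igraph;
disconnected fragments are accepted and sit at infinite distance, and
cross-fragment pairs never contribute to any descriptor). Atom indices are
1-based everywhere, the R convention; reports and graphs use the same
indexing so there is no internal/external offset to track.

Aromatic systems are handled with two deliberate conventions:

- **Kekulization** is performed once, deterministically, by the parser.
  Kekulé double bonds feed every "double-bonded atom" notion: the per-atom
  `double_bond_count` and membership in class `2` of the `T_2_x_d` pair
  descriptors. A benzene ring therefore contributes six class-2 atoms. The
  alternative — excluding aromatic atoms from class 2 — is defensible, but
  pair counts over "double-bonded atoms" need a discrete bond order, and
  Kekulé assignment is the standard way to get one.
- **E-state typing keeps aromatic bonds as their own symbol** (`a`), so a
  benzene CH is `aaCH` and never `dsCH`. This follows the universal E-state
  vocabulary: `SdsCHE-index` denotes vinylic/formyl CH groups, and typing
  aromatics by their Kekulé orders would sum every aromatic CH of these
  aromatic-rich scaffolds into it, changing the descriptor's meaning
  entirely. The two conventions coexist on purpose: typing is about the
  chemical environment, pair counting about discrete unsaturation.

## E-state machinery

For heavy atom *i* with sigma degree δ (heavy neighbours), hydrogen count
*h*, valence electron count *Zv* and principal quantum number *N*:

- valence delta: δv = Zv − h for second-row atoms and
  (Zv − h)/(Z − Zv − 1) for higher rows;
- intrinsic state: I = ((2/N)² δv + 1)/δ;
- perturbation: ΔI_i = Σ_j (I_i − I_j)/(d_ij + 1)², summed over atoms of
  the same fragment (topological distance d in bonds);
- E-state value: S = I + ΔI;
- Kier–Hall relative electronegativity: ε = (δv − δ)/N².

The perturbation is pairwise antisymmetric, so Σ ΔI = 0 over any molecule —
a property the tests verify on every fixture and on 1,000 random graphs.
Isolated heavy atoms (δ = 0) have no defined intrinsic state; by default
they are flagged `estate_defined = FALSE` and excluded from group sums
(an optional `unit_degree` mode treats δ as 1 instead, for users who prefer
the permissive convention).

The group indices `S<type>E-index` are sums of S over atoms of the named
environment, zero when no atom matches; `S<type>count` descriptors are pure
counts. `DeltaEpsilonC` is implemented as the carbon-restricted spread
max(ε) − min(ε), zero with fewer than two carbons. The proprietary
definition behind that descriptor name is not publicly documented, so this
adopted definition is versioned and isolated behind one function
(`delta_epsilon_c()`) where it can be swapped without touching anything
else.

## MMFF typing and the acceptor rules

No installed R toolkit exposes MMFF94 atom typing, so the default backend is
a rule table shipped as JSON (`inst/extdata/mmff_types.json`): each entry
maps a numeric MMFF type to its symbolic label and a documented matching
rule. Coverage is the common organic environments; anything else gets the
explicit label `"untyped"`, never a silent type 0. The one type the models
consume, `MMFF_29` (HOCC, the phenolic/enolic hydroxyl hydrogen), is fully
covered, including the disambiguation from carboxylic OH (HOCO, type 24).
The backend is pluggable: any function `(graph, atom_index, hydrogens)` can
replace the table.

`H-AcceptorCount` counts N/O atoms with an available lone pair under a rule
set also shipped as data: positively charged N/O, amide/imide nitrogens and
pyrrole-type aromatic nitrogens are excluded by default. This is distinct
from the Lipinski N+O count used by the rule-of-five filter, which is kept
deliberately crude per that rule's own convention. Molecular weight is an
average-atomic-weight sum including hydrogens; logP is delegated to
OpenBabel's atom-contribution estimator and never reimplemented — if it is
unavailable the rule-of-five stage fails closed.

## Data hygiene and splitting

`correlation_prune()` removes zero-variance columns first, then greedily
resolves every descriptor pair with |r| above the cutoff by dropping the
member less correlated with activity (ties: the higher column index), and
returns the full correlation matrix for reporting.

`sphere_exclusion_split()` implements the activity-ordered variant of
sphere exclusion: compounds are visited from most to least potent; each
still-unassigned visit becomes a training point and every still-unassigned
compound within the Euclidean radius (in z-standardized descriptor space,
inclusive boundary) goes to the test set. This guarantees the most potent
compound trains the model and that every test compound has a training
neighbour within the radius. The seed only breaks exact-activity ties, so
splits are bit-for-bit reproducible. Standardization for the split geometry
uses full-table moments (the split does not exist yet); the returned object
stores train-set moments for downstream use. `sphere_radius_for_fraction()`
bisects the radius to a requested train fraction (≈80/20 by default usage),
and `unicolumn_stats()` reports per-set mean/max/min/sd with a range-
coverage verdict (covered iff the test activity range interpolates the
training range).

## Stepwise-forward MLR

`stepwise_forward()` starts from the intercept-only model and admits, per
round, the candidate with the largest partial F provided it reaches
`f_to_enter` and its |r| with every chosen descriptor stays at or below
`corr_cutoff`; ties go to the lowest column index; entry stops at
`max_terms`. Defaults — `f_to_enter = 4` (the classic F-to-enter), `corr_cutoff
= 0.7`, `max_terms = floor(n/6)` (one term per six compounds) — are
configurable; none is dictated by the source models, so they follow common
QSAR practice. There is no backward-elimination step. With the gate never
met, the function returns an intercept-only model with a warning rather
than failing.

## The validation battery

All items are computed from first principles and cross-checked in the tests
against independent oracles:

- r² = 1 − SSres/SStot; F = (SSreg/k)/(SSres/(n−k−1)); df = n − k − 1.
- LOO q² uses the closed-form identity PRESS = Σ(e_i/(1−h_ii))² from one
  fit; the tests assert equality with explicit n-refit LOO to 1e−10. A hat
  value of 1 raises an influential-point error naming the row.
- pred_r² references the external squared error to the *training* activity
  mean.
- rm² metrics follow the penalized-correlation formulation
  rm² = r²(1 − √|r² − r0²|) with the through-origin r0² from a slope-only
  fit, computed with observed on each axis in turn; the average and the
  absolute difference are reported. Identity predictions give exactly
  (1, 0).
- Y-randomization permutes the activity vector per trial and reruns the
  model builder — optionally the full stepwise selection
  (`stepwise_builder()`), so chance gets the same descriptor-picking freedom
  the real model had. `alpha` is the add-one-smoothed empirical p-value
  (#{random r² ≥ actual} + 1)/(n_trials + 1); no distributional form is
  assumed. Z-scores are reported for both r² and q² since the conventional
  single "ZScore" row is ambiguous about its base statistic; the q²-based
  one is labelled primary in the printed report. Default 100 trials,
  always seeded.
- Standard errors are RMSEs of the fitted, LOO and external residual sets
  with denominators n−k−1, n and n_test.
- The applicability domain is the inclusive training hyper-rectangle:
  flag 0 inside, 1 outside; the report carries the count of test-set
  outliers.

## Screening cascade

`screen_library()` applies, in order: the predicted-activity cutoff, the
rule of five, and the risk-rule stage; survivors are ranked by predicted
IC50 ascending (worst-case across models in multi-model mode). The activity
cutoff defaults to 20 µM with "more than" read strictly — a compound
predicted at exactly 20 µM passes. The comparison runs on the log10 scale
(pred ≤ log10(threshold)), which is exact at the boundary where the
back-transform 10^x may not be. A 15 µM preset is exposed as well, since
both figures circulate for this series; neither is declared canonical.
The rule of five uses inclusive limits (500, 5, 5, 10) with the classic
one-violation allowance (configurable to strict). The risk stage is a
transparent rule engine — named predicates with non-negative weights,
exclusion at a summed score of 10 by default — shipped with an *empty*
default rule set: the proprietary composite risk scores it stands in for
are not reproducible, and pretending otherwise with invented weights would
be worse than abstaining. Rules referencing missing properties count as
triggered (fail-closed) with a warning.

## Synthetic data: what it emulates and what it does not

`simulate_descriptor_table()` draws descriptor columns independently
(continuous uniform for E-state-style indices, integer uniform for counts)
and sets activity = intercept + Σβx + N(0, σ). The shipped default planted
truth is the frozen U251 equation with σ = 0.1 log units and n = 150 — a
noise level and size at which a three-descriptor signal is clearly
recoverable yet not trivial, matching the scale of the original series'
training sets. `simulate_screening_library()` inverts the frozen model: it
samples the count descriptors, then solves the one continuous descriptor so
each compound's prediction lands on a requested side of the activity
threshold; the stored ground-truth label is recomputed from the final
vector, so label and screen agree by construction.

What the generator does *not* emulate: inter-descriptor correlation (real
descriptor tables are strongly collinear — the pruning step exists for a
reason), integer-valued E-state sums tied to actual substructures,
activity cliffs, and measurement error structure beyond i.i.d. Gaussian
noise. Passing the recovery tests therefore demonstrates the correctness of
the fitting and validation machinery under the stated assumptions, not
predictive validity on new chemistry.

Test and acceptance problem sizes were chosen to keep the full suite fast
while leaving the statistical assertions well-powered: 100 seeded
recovery runs at n = 150, 50 tables for the LOO identity, 200 outer
replicates × 99 permutation trials for the alpha calibration, 1,000 random
graphs for the E-state closure, a 1,000-compound screening library.

## Known limitations

- Descriptor values depend on OpenBabel's Kekulization and aromaticity
  perception; a different toolkit may type exotic heteroaromatics
  differently. The fixture regression suite pins the current behaviour.
- The MMFF rule table is partial by design; atoms outside the common
  organic set come back `"untyped"` and `MMFF_<n>` counts ignore them.
- `DeltaEpsilonC` is an adopted stand-in definition (documented above).
- The element table covers H, B, C, N, O, F, Si, P, S, Cl, Br, I;
  organometallics and salts of other elements are rejected at parse time.
- Published-model predictions carry no applicability information; rebuild
  the models on your own series to get training ranges and honest flags.
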