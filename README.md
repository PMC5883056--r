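# cxqsar

2D-QSAR modeling, validation and virtual screening for caged-xanthone
anticancer activity.

Caged *Garcinia* xanthones are a family of natural products with potent
cytotoxicity against several human cancer cell lines. `cxqsar` is an R
package for medicinal and computational chemists working with this (or any
structurally similar) series: it computes the 2D descriptors that drive the
three published cell-line models, rebuilds such models from descriptor
tables, runs the full statistical validation battery, and screens compound
libraries through a predicted-activity and drug-likeness cascade.

## The models

Each model is an ordinary least-squares regression of activity on a handful
of 2D descriptors,

    Log10 IC50 (µM) = b0 + Σ_j b_j · x_j ,

with the descriptor sets selected by stepwise-forward MLR after a
sphere-exclusion train/test split. The three frozen cell-line equations ship
as packaged JSON and load with `published_model()`:

| Model | Cell line | Descriptors |
|-------|-----------|-------------|
| model1 | A549 (lung) | DeltaEpsilonC, MMFF_29, SssssCcount, T_2_2_1, SdsCHE-index |
| model2 | HepG2 (liver) | SdssCE-index, T_2_2_2, H-AcceptorCount, SdsCHE-index, T_O_O_3 |
| model3 | U251 (glioma) | T_T_N_4, T_O_O_3, SssssCE-index |

The descriptor families:

- **E-state group indices** (`SdsCHE-index`, `SdssCE-index`,
  `SssssCE-index`): sums of per-atom electrotopological-state values
  S = I + ΔI over atoms of a named bonding environment (Kier–Hall
  formulation; see the methods vignette).
- **Atom-type counts** (`SssssCcount`, `MMFF_29`): counts of quaternary
  carbons and of phenolic/enolic hydroxyl hydrogens (MMFF94 type 29).
- **Topological pair counts** (`T_x_y_d`): unordered heavy-atom pairs of
  classes x and y separated by exactly d bonds (class 2 = double-bonded
  atom, T = any atom, or an element symbol).
- **DeltaEpsilonC**: spread of Kier–Hall relative electronegativity over the
  carbon atoms.
- **H-AcceptorCount**: N/O lone-pair acceptors under a shipped rule set.

## Worked example

```r
library(cxqsar)

smi <- c(xanthone = "O=C1c2ccccc2Oc2ccccc21",
         caged    = "CC1(C)C2CC3CC1C(=O)C3(O)C2",
         glycerol = "OCC(O)CO")
lib <- calc_descriptors(smi, "model3", ids = names(smi))
m3  <- published_model("model3")
print(m3)
#> qsar_model 'model3 (U251)' (published:model3)
#>   Log10 IC50 (uM) = 1.1313 + 0.0948 x T_T_N_4 + 0.5217 x T_O_O_3
#>                   + 0.3687 x SssssCE-index

predict(m3, lib)
#>   pred_log_ic50 pred_ic50_uM
#> 1        1.1313      13.5301   # xanthone
#> 2        1.3769      23.8178   # caged scaffold
#> 3        2.1747     149.5202   # glycerol (inactive control)

screen_library(lib, m3, threshold_uM = 20, ro5 = TRUE)
#> screening_report: 3 compounds, 1 passed
#>   attrition: activity=2, ro5=0, risk=0, unevaluated=0
```

Xanthone is predicted at 13.5 µM, inside the 20 µM activity cutoff, and
survives the rule-of-five stage; the other two are excluded at the activity
stage (predicted IC50 above 20 µM).

Model rebuilding on a synthetic table with the U251 coefficients planted as
ground truth:

```r
cfg <- sim_config(150, default_sim_descriptors(7),
                  true_beta = published_model("model3")$coefficients,
                  intercept = published_model("model3")$intercept,
                  noise_sd = 0.1, seed = 42)
tbl   <- simulate_descriptor_table(cfg)
model <- stepwise_forward(tbl, max_terms = 3)
report <- validate_model(tbl, model = model, n_random_trials = 99, seed = 1)
print(report)   # r2, LOO q2, F, Y-randomization Z-scores, alpha, ...
```

A thin command-line wrapper with the same functionality (subcommands
`calc`, `predict`, `simulate`, `split`, `train`, `validate`, `screen`)
is installed at `inst/cli/cxqsar`.

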