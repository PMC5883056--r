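#!/usr/bin/env Rscript
# Regenerates inst/extdata/fixture_descriptors.csv from the independent
# brute-force oracle in tests/testthat/helper-oracle.R. Run from the
# repository root after any change to the fixture set or the oracle.
suppressMessages(library(cxqsar))
source("tests/testthat/helper-oracle.R")

smi <- fixture_smiles_set()
rows <- list()
for (nm in names(smi)) {
  g <- parse_smiles(smi[[nm]])
  v <- oracle_descriptor_vector(g)
  rows[[nm]] <- data.frame(name = nm, smiles = smi[[nm]],
                           as.list(round(v, 10)), check.names = FALSE,
                           stringsAsFactors = FALSE)
}
out <- do.call(rbind, rows)
write.csv(out, "inst/extdata/fixture_descriptors.csv", row.names = FALSE)
cat("wrote", nrow(out), "fixture molecules\n")
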