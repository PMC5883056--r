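# Descriptor engine vs the independent brute-force oracle, plus the E-state
# and pair-count invariants.

test_that("E-state values on simple molecules match hand arithmetic", {
  es <- estate_values(fx_graph("CC"))
  expect_equal(es$I, c(2, 2))
  expect_equal(es$dI, c(0, 0))
  expect_equal(es$S, c(2, 2))

  # propene vs the independent double-loop oracle
  g <- fx_graph("C=CC")
  es <- estate_values(g)
  or <- oracle_estate(g)
  expect_equal(es$S, or$S, tolerance = 1e-12)
  expect_equal(es$I, or$I, tolerance = 1e-12)
})

test_that("perturbations sum to zero and S = I + dI on every fixture", {
  fx <- fixture_molecules()
  for (s in fx$smiles) {
    es <- estate_values(fx_graph(s))
    ok <- es$estate_defined
    expect_equal(sum(es$dI[ok]), 0, tolerance = 1e-10, info = s)
    expect_equal(es$S[ok], es$I[ok] + es$dI[ok], info = s)
  }
})

test_that("isolated heavy atoms are flagged E-state-undefined by default", {
  g2 <- parse_smiles("CCO.[Cl-]")
  es <- estate_values(g2)
  expect_false(es$estate_defined[4])
  expect_true(is.na(es$S[4]))
  es2 <- estate_values(g2, isolated = "unit_degree")
  expect_true(all(es2$estate_defined))
})

test_that("group indices realize the S-sum semantics", {
  expect_equal(estate_group_index(fx_graph("C=C"), "dsCH"), 0.0)
  np <- fx_graph("CC(C)(C)C")
  es <- estate_values(np)
  expect_equal(estate_group_index(np, "ssssC"), es$S[2])
  acr <- fx_graph("C=CC=O")
  expect_equal(estate_group_index(acr, "dsCH"),
               oracle_group_index(acr, "dsCH"), tolerance = 1e-12)
})

test_that("atom-type counts enumerate correctly", {
  expect_equal(atom_type_count(fx_graph("C"), "ssssC"), 0L)
  expect_equal(atom_type_count(fx_graph("CC(C)(C)C"), "ssssC"), 1L)
  expect_equal(atom_type_count(fx_graph("Oc1ccccc1"), "MMFF_29"), 1)
  expect_error(atom_type_count(fx_graph("C"), "@@bogus"), "unknown")
})

test_that("pair counts match examples and the exhaustive oracle", {
  expect_equal(tpair_count(fx_graph("OCCO"), "O", "O", 3), 1L)
  expect_equal(tpair_count(fx_graph("OCC(O)CO"), "O", "O", 3), 2L)
  expect_equal(tpair_count(fx_graph("C=CC=C"), "2", "2", 1), 3L)
  expect_equal(tpair_count(fx_graph("C"), "T", "T", 1), 0L)
  expect_error(tpair_count(fx_graph("CC"), "T", "T", 0), ">= 1")

  fx <- fixture_molecules()
  for (s in fx$smiles) {
    g <- fx_graph(s)
    for (spec in list(c("2", "2", 1), c("O", "O", 3), c("T", "N", 4),
                      c("T", "T", 2))) {
      expect_equal(
        tpair_count(g, spec[1], spec[2], as.integer(spec[3])),
        oracle_tpair(g, spec[1], spec[2], as.integer(spec[3])),
        info = paste(s, paste(spec, collapse = "_")))
    }
  }
})

test_that("cross-fragment pairs are never counted", {
  g <- parse_smiles("OCO.OCO")
  # within each fragment the O-O distance is 2; across fragments infinite
  expect_equal(tpair_count(g, "O", "O", 2), 2L)
  expect_equal(tpair_count(g, "O", "O", 3), 0L)
})

test_that("hydrogen-bond acceptor rules behave as documented", {
  expect_equal(h_acceptor_count(fx_graph("C")), 0L)
  expect_equal(h_acceptor_count(fx_graph("CCO")), 1L)
  expect_equal(h_acceptor_count(fx_graph("CC(=O)N")), 1L)  # amide N excluded
  expect_equal(h_acceptor_count(fx_graph("c1ccncc1")), 1L) # pyridine N in
  expect_equal(h_acceptor_count(fx_graph("c1cc[nH]c1")), 0L) # pyrrole N out
  expect_equal(h_acceptor_count(parse_smiles("C[N+](C)(C)C")), 0L)
})

test_that("carbon electronegativity spread follows the adopted definition", {
  expect_equal(delta_epsilon_c(fx_graph("c1ccccc1")), 0.0)
  expect_equal(delta_epsilon_c(fx_graph("C")), 0.0)
  g <- fx_graph("CCO")
  expect_equal(delta_epsilon_c(g), oracle_delta_epsilon_c(g),
               tolerance = 1e-12)
})

test_that("rule-of-five properties match atomic-mass sums and conventions", {
  p <- rule_of_five_properties(fx_graph("C"))
  expect_equal(p$HBD, 0L)
  expect_equal(p$HBA, 0L)
  p <- rule_of_five_properties(fx_graph("CCO"))
  expect_equal(p$MW, 46.07, tolerance = 1e-3)
  expect_equal(p$HBD, 1L)
  expect_equal(p$HBA, 1L)
  expect_true(is.finite(p$logP))
  p <- rule_of_five_properties(parse_smiles("NCC(=O)O"))
  expect_equal(p$HBD, 3L)
  expect_equal(p$HBA, 3L)
})

test_that("descriptor dispatch covers the registered vocabulary", {
  v <- descriptor_vector(fx_graph("C"), c("SssssCcount", "T_O_O_3"))
  expect_equal(unname(v), c(0, 0))
  v <- descriptor_vector(fx_graph("OCC(O)CO"), "T_O_O_3")
  expect_equal(unname(v), 2)
  expect_error(descriptor_vector(fx_graph("C"), "NotADescriptor"),
               "unregistered")
})

test_that("every fixture oracle value is reproduced by the live engine", {
  fx <- fixture_molecules()
  frozen <- setdiff(colnames(fx), c("name", "smiles", "MW", "HBD", "HBA"))
  int_cols <- c("MMFF_29", "SssssCcount", "T_2_2_1", "T_2_2_2",
                "H-AcceptorCount", "T_O_O_3", "T_T_N_4")
  for (r in seq_len(nrow(fx))) {
    g <- fx_graph(fx$smiles[r])
    v <- descriptor_vector(g, frozen)
    p <- rule_of_five_properties(g)
    for (nm in frozen) {
      if (nm %in% int_cols) expect_identical(as.integer(v[[nm]]),
                                             as.integer(fx[[nm]][r]),
                                             label = paste(fx$name[r], nm))
      else expect_equal(v[[nm]], fx[[nm]][r], tolerance = 1e-9,
                        info = paste(fx$name[r], nm))
    }
    expect_equal(p$MW, fx$MW[r], tolerance = 1e-6, info = fx$name[r])
    expect_identical(as.integer(p$HBD), as.integer(fx$HBD[r]))
    expect_identical(as.integer(p$HBA), as.integer(fx$HBA[r]))
  }
})

test_that("count descriptors are invariant under atom-order permutation", {
  variants <- list(
    c("OCC(O)CO", "C(O)(CO)CO", "OCC(CO)O"),
    c("Oc1ccccc1", "c1ccc(O)cc1", "c1cc(O)ccc1"),
    c("CC(=O)N", "NC(=O)C", "C(N)(=O)C"))
  nms <- model_descriptor_names("all")
  nms <- setdiff(nms, c("MW", "logP", "HBD", "HBA"))
  for (vs in variants) {
    ref <- descriptor_vector(fx_graph(vs[1]), nms)
    for (alt in vs[-1])
      expect_equal(descriptor_vector(fx_graph(alt), nms), ref,
                   tolerance = 1e-9, info = alt)
  }
})

test_that("ssssC group index is zero whenever the ssssC count is zero", {
  fx <- fixture_molecules()
  for (s in fx$smiles) {
    g <- fx_graph(s)
    if (atom_type_count(g, "ssssC") == 0)
      expect_identical(estate_group_index(g, "ssssC"), 0.0, label = s)
  }
})
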