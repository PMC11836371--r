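test_that("connection sites honor hydrogen rules and symmetry orbits", {
  expect_length(find_connection_sites("c1ccccc1", "single"), 1L)
  expect_length(find_connection_sites("CO", "single"), 2L)
  expect_length(find_connection_sites("c1ccccc1", "spiro"), 0L)
  expect_length(find_connection_sites("c1ccccc1", "triple"), 0L)
  expect_length(find_connection_sites("C", "triple"), 1L)
  # cyclohexane: one CH2 orbit for spiro, one ring-bond orbit for fusion
  expect_length(find_connection_sites("C1CCCCC1", "spiro"), 1L)
  expect_length(find_connection_sites("C1CCCCC1", "fusion"), 1L)
  # vinylic CH2 may not take a double-bond vector (would cumulate)
  s <- find_connection_sites("C=C", "double")
  expect_length(s, 0L)
})

test_that("activation tags carry the mechanism and invert exactly", {
  eth <- mol_from_smiles("CC")[[1]]
  site <- find_connection_sites(eth, "single")[[1]]
  act <- activate_substituent(eth, site)
  expect_identical(act$tagged_smiles, smi_canonical("CC[Lu]"))
  expect_identical(act$n_heavy, 2L)
  expect_identical(act$mechanism, "single")
  met <- mol_from_smiles("C")[[1]]
  actd <- activate_substituent(met, find_connection_sites(met, "double")[[1]])
  expect_identical(actd$tagged_smiles, smi_canonical("C=[Hf]"))
  # round trip for a mixed batch
  lib <- c("CCO", "c1ccccc1", "C1CCOC1", "CC(C)C")
  subs <- activate_library(lib)
  expect_identical(
    unname(vapply(subs$tagged_smiles, deactivate, character(1))),
    smi_canonical(subs$source_smiles))
  # invalid site errors
  bad <- list(mechanism = "triple", atom = 1L, chemotype = "aliphatic_CH")
  expect_error(activate_substituent(mol_from_smiles("c1ccccc1")[[1]], bad),
               "hydrogen")
})

test_that("orbit-level activation equals brute-force tagging with VF2 dedupe", {
  space <- enumerate_space(enumeration_config(3))$molecules
  for (mech in c("single", "double")) {
    subs <- activate_library(space, mech)
    brute <- list()
    for (s in space) {
      m <- mol_from_smiles(s)[[1]]
      for (site in growspace:::raw_sites(m, mech))
        brute[[length(brute) + 1L]] <- growspace:::attach_tag(m, site)
    }
    expect_identical(nrow(subs), iso_dedupe_count(brute),
                     info = paste("mechanism:", mech))
  }
})

test_that("every hydrogen-bearing molecule yields a single-bond substituent", {
  space <- enumerate_space(enumeration_config(3))$molecules
  subs <- activate_library(space)
  expect_gte(nrow(subs), length(space) - 3L)
  covered <- unique(subs$source_smiles[subs$mechanism == "single"])
  missed <- setdiff(space, covered)
  # the only molecules without a single-bond vector carry no hydrogens at all
  hyd <- vapply(mol_from_smiles(missed), function(m) sum(m$hyd), integer(1))
  expect_true(all(hyd == 0L))
})

test_that("shelves key by size/mechanism/chemotype and enforce compatibility", {
  subs <- activate_library(c("CCCCO", "CCCCN", "CCCCC"), "single")
  sh <- build_shelves(subs)
  # activated alcohols with five heavy atoms sit on the hydroxyl shelf
  expect_identical(shelf_get(sh, 5, "single", "aliphatic_CH"),
                   sort(subs$tagged_smiles))
  # an amine site must not be served an amine-tagged substituent
  served <- shelf_get(sh, 5, "single", "amine_N")
  expect_false(any(grepl("N\\[Lu\\]|\\[Lu\\]N", served)))
  expect_true(any(subs$chemotype == "amine_N"))
  # hydroxyl x hydroxyl is forbidden too
  served_o <- shelf_get(sh, 5, "single", "hydroxyl_O")
  expect_false(any(served_o %in% subs$tagged_smiles[subs$chemotype == "hydroxyl_O"]))
  # duplicates collapse
  dup <- build_shelves(activate_library(c("CC", "CC"), "single"))
  expect_identical(dup$n_substituents, 1L)
})
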