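test_that("fingerprints are deterministic and identity-consistent", {
  fp <- morgan_fingerprint(c("CCO", "CCO", "c1ccccc1", "OCC"))
  expect_identical(fp[[1]], fp[[2]])
  expect_identical(fp[[1]], fp[[4]])  # same canonical structure
  expect_identical(tanimoto(fp[[1]], fp[[2]]), 1)
  expect_lt(tanimoto(fp[[1]], fp[[3]]), 0.3)
  expect_true(all(fp[[1]] >= 0 & fp[[1]] < 1024))
})

test_that("leader clustering follows the greedy score-ranked rule", {
  # synthetic fingerprints with hand-computable similarities:
  # a/b share 2 of 3 bits (T = 0.5, NOT joined: rule is strictly greater),
  # a/c share 3 of 4 (T = 0.75, joined), d disjoint
  fps <- list(a = c(1L, 2L, 3L), b = c(2L, 3L, 4L),
              c = c(1L, 2L, 3L, 9L), d = c(7L, 8L))
  rk <- data.frame(smiles = names(fps), score = c(-10, -9, -8, -7))
  cl <- leader_cluster(rk, threshold = 0.5, fingerprints = fps)
  expect_identical(cl$cluster[match(c("a", "c"), cl$smiles)], c(1L, 1L))
  expect_identical(cl$cluster[cl$smiles == "b"], 2L)
  expect_identical(cl$cluster[cl$smiles == "d"], 3L)
  expect_identical(cl$smiles[cl$is_head], c("a", "b", "d"))
  # partition: every molecule in exactly one cluster
  expect_identical(sort(cl$smiles), sort(rk$smiles))
  expect_false(any(duplicated(cl$smiles)))
  # all-identical fingerprints -> one cluster headed by the best score
  same <- leader_cluster(rk, fingerprints = rep(list(c(1L, 2L)), 4))
  expect_identical(unique(same$cluster), 1L)
  expect_identical(same$smiles[same$is_head], "a")
  # all-disjoint -> singletons
  disj <- leader_cluster(rk, fingerprints = list(1L, 2L, 3L, 4L))
  expect_identical(disj$cluster, 1:4)
  # empty input -> empty output
  expect_identical(nrow(leader_cluster(rk[0, ])), 0L)
})

test_that("higher thresholds never produce fewer clusters", {
  set.seed(5)
  fps <- lapply(1:12, function(i) sort(sample(0:63, 12)))
  rk <- data.frame(smiles = sprintf("m%02d", 1:12), score = rnorm(12))
  n_prev <- 0L
  for (th in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    n <- max(leader_cluster(rk, th, fps)$cluster)
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("substructure search supports plain and constrained patterns", {
  lib <- c("c1ccccc1", "Cc1ccccc1", "Oc1ccccc1", "C1CCCCC1", "CCCC")
  expect_identical(substructure_search(lib, "c1ccccc1"),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_false(any(substructure_search(lib, "[CX3](=O)[OX2H]")))
  expect_error(substructure_search(lib, "not_a_smarts(("), "invalid")
  # constrained pattern: para position must stay unsubstituted
  lib2 <- c("Cc1ccccc1", "Cc1ccc(O)cc1", "Cc1ccccc1C", "Cc1cc(N)ccc1")
  pat_open <- scaffold_pattern("Cc1ccccc1")
  expect_true(all(substructure_search(lib2, pat_open)))
  # open only the methyl and ipso carbons (atoms 1 and 2 in canonical order)
  pat_con <- scaffold_pattern("Cc1ccccc1", open_atoms = c(1L, 2L),
                              constrained = TRUE)
  hits <- substructure_search(lib2, pat_con)
  expect_identical(hits, c(TRUE, FALSE, FALSE, FALSE))
  # constrained hits are a subset of unconstrained hits
  expect_true(all(!hits | substructure_search(lib2, pat_open)))
})

test_that("structural filters name the pattern that fired", {
  res <- structural_filters(c("Cc1ccccc1", "CC(=O)Nc1ccccc1", "Oc1ccccc1O"))
  expect_identical(res$pass, c(TRUE, FALSE, FALSE))
  expect_identical(res$reason[2], "nacyl_arylamine")
  expect_identical(res$reason[3], "catechol")
  expect_true(is.na(res$reason[1]))
})

test_that("core RMSD is computed in a fixed frame with symmetry handling", {
  ref <- mol_from_smiles("O=CNC1=NOC2=C1CCCC2", gen3d = TRUE)[[1]]
  expect_equal(core_rmsd(ref, ref), 0, tolerance = 1e-12)
  shifted <- ref
  shifted$coords <- sweep(ref$coords, 2, c(3, 0, 0), "+")
  expect_equal(core_rmsd(shifted, ref), 3, tolerance = 1e-9)
  # symmetric molecule: minimum over automorphisms, not an arbitrary map
  benz <- mol_from_smiles("c1ccccc1", gen3d = TRUE)[[1]]
  expect_equal(core_rmsd(benz, benz), 0, tolerance = 1e-9)
  expect_error(core_rmsd(benz, ref), "core")
})

test_that("pose filter selects lowest energy below the RMSD cutoff within top_k", {
  ref <- mol_from_smiles("O=CNC1=NOC2=C1CCCC2", gen3d = TRUE)[[1]]
  mk <- function(dx, e) {
    p <- ref; p$coords <- sweep(ref$coords, 2, c(dx, 0, 0), "+")
    list(mol = p, energy = e, title = sprintf("dx%.1f", dx))
  }
  # (E -10, RMSD 2.5) then (E -8, RMSD 0.4): the second must win
  sel <- core_rmsd_filter(list(mk(2.5, -10), mk(0.4, -8)), ref)
  expect_equal(sel$energy, -8)
  expect_equal(sel$rmsd, 0.4, tolerance = 1e-9)
  # nothing below the cutoff -> NULL
  expect_null(core_rmsd_filter(list(mk(2.5, -10), mk(3.5, -9)), ref))
  # top_k energy window: a passing pose outside the window is invisible
  poses <- list(mk(3.0, -12), mk(2.6, -11), mk(0.2, -5))
  expect_null(core_rmsd_filter(poses, ref, top_k = 2))
  sel2 <- core_rmsd_filter(poses, ref, top_k = 50)
  expect_equal(sel2$energy, -5)
  expect_lte(sel2$rank, 50)
})

test_that("reaction enumeration couples blocks and skips inert ones", {
  acids <- c("CC(=O)O", "OC(=O)C1CC1")
  amines <- c("NCc1ccccc1", "NC1CCC1")
  prods <- unique(unlist(lapply(acids, function(a)
    react_enumerate(amines, "amide_coupling", a))))
  expect_length(prods, 4L)
  expect_true(all(substructure_search(prods, "[CX3](=[OX1])[NX3]")))
  p <- react_enumerate(c("NCC", "CCCC"), "amide_coupling", "CC(=O)O")
  expect_identical(attr(p, "skipped_blocks"), "CCCC")
  # duplicate blocks do not duplicate products
  p2 <- react_enumerate(c("NCC", "NCC"), "amide_coupling", "CC(=O)O")
  expect_length(p2, 1L)
  # all four shipped couplings produce the expected bonds
  expect_equal(react_enumerate("OB(O)c1ccccc1", "suzuki_coupling",
                               "Brc1ccncc1"),
               smi_canonical("c1ccc(-c2ccncc2)cc1"), ignore_attr = TRUE)
  expect_equal(react_enumerate("NC1CCC1", "chan_lam_amination",
                               "OB(O)c1ccccc1"),
               smi_canonical("C1CC(C1)Nc1ccccc1"), ignore_attr = TRUE)
  expect_equal(react_enumerate("OCC", "ullmann_ether", "Brc1ccccc1"),
               smi_canonical("CCOc1ccccc1"), ignore_attr = TRUE)
  # SMIRKS strings from the registry resolve; unknown ones error
  reg <- reactions_default()
  sm <- reg$smirks[reg$name == "amide_coupling"]
  expect_equal(react_enumerate("NCC", sm, "CC(=O)O"),
               react_enumerate("NCC", "amide_coupling", "CC(=O)O"),
               ignore_attr = TRUE)
  expect_error(react_enumerate("NCC", "[C:1]>>[Xx:1]", "CC(=O)O"), "unknown")
})
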