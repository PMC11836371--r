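graph_rec <- function(edges, n) list(n = n, edges = edges, canonical_key = "")

test_that("saturation fills valences: CnH(2n+2-2r)", {
  tri <- saturate(graph_rec(cbind(c(1, 2, 3), c(2, 3, 1)), 3))
  expect_identical(smi_canonical(mol_to_smiles(tri)), smi_canonical("C1CC1"))
  expect_identical(sum(tri$hyd), 6L)  # cyclopropane C3H6
  path <- saturate(graph_rec(cbind(c(1, 2), c(2, 3)), 3))
  expect_identical(smi_canonical(mol_to_smiles(path)), smi_canonical("CCC"))
  expect_identical(sum(path$hyd), 8L)  # propane C3H8
  # general formula across all skeletons with up to 6 atoms
  for (rec in enumerate_graphs(6)) {
    m <- saturate(rec)
    r <- nrow(rec$edges) - rec$n + 1L  # cyclomatic number (connected)
    expect_identical(sum(m$hyd), 2L * rec$n + 2L - 2L * r)
  }
})

test_that("tetrahedral volumes match closed forms and are rigid-motion invariant", {
  # ideal center, C-C 1.54 A: edge = 1.54 * sqrt(8/3), V = edge^3 / (6 sqrt 2)
  a <- 1.54
  ideal <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    (a / sqrt(3))
  m <- gs_mol(rep("C", 5), c(0L, 3L, 3L, 3L, 3L),
              cbind(1L, 2:5, 1L),
              coords = rbind(c(0, 0, 0), ideal))
  v_expected <- (a * sqrt(8 / 3))^3 / (6 * sqrt(2))
  expect_equal(unname(tetrahedron_volumes(m)), v_expected, tolerance = 1e-10)
  expect_true(strain_filter(m, 0.145)$keep)
  # coplanar neighbors -> volume 0 -> discard
  m_flat <- m
  m_flat$coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(-1.5, 0, 0),
                         c(0, 1.5, 0), c(0, -1.5, 0))
  expect_equal(unname(tetrahedron_volumes(m_flat)), 0, tolerance = 1e-12)
  expect_false(strain_filter(m_flat, 0.145)$keep)
  # no quaternary center -> vacuous pass
  prop <- mol_from_smiles("CCC", gen3d = TRUE)[[1]]
  expect_length(tetrahedron_volumes(prop), 0)
  expect_true(strain_filter(prop)$keep)
  # rotation + translation invariance
  set.seed(11)
  for (k in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    m_rot <- m
    m_rot$coords <- m$coords %*% q + matrix(rnorm(3), 5, 3, byrow = TRUE)
    expect_equal(tetrahedron_volumes(m_rot), tetrahedron_volumes(m),
                 tolerance = 1e-8)
  }
})

test_that("deterministic embedding reproduces ideal quaternary volumes", {
  m1 <- mol_from_smiles("CC(C)(C)C", gen3d = TRUE)[[1]]
  m2 <- mol_from_smiles("CC(C)(C)C", gen3d = TRUE)[[1]]
  expect_identical(m1$coords, m2$coords)
  expect_equal(unname(tetrahedron_volumes(m1)), 1.87, tolerance = 0.05)
  # spiropentane's central carbon is a collapsed tetrahedron
  sp <- mol_from_smiles("C1CC12CC2", gen3d = TRUE)[[1]]
  expect_lt(max(tetrahedron_volumes(sp)), 0.145)
})

test_that("unsaturation enumerates what the bond-order oracle enumerates", {
  eth <- mol_from_smiles("CC")[[1]]
  expect_setequal(introduce_unsaturations(eth),
                  smi_canonical(c("C=C", "C#C")))
  expect_length(introduce_unsaturations(mol_from_smiles("C")[[1]]), 0)
  # oracle: all 3^6 bond-order assignments of cyclohexane, valence-filtered,
  # canonically deduplicated
  cyc <- mol_from_smiles("C1CCCCC1")[[1]]
  bonds <- cyc$bond
  combos <- as.matrix(expand.grid(rep(list(1:3), 6)))
  ok <- apply(combos, 1, function(o) {
    val <- integer(6)
    for (k in 1:6) {
      val[bonds[k, "a"]] <- val[bonds[k, "a"]] + o[k]
      val[bonds[k, "b"]] <- val[bonds[k, "b"]] + o[k]
    }
    all(val <= 4) && any(o > 1)
  })
  oracle <- unique(stats::na.omit(smi_canonical(apply(
    combos[ok, ], 1, function(o) {
      m <- cyc; m$bond[, "order"] <- o
      mol_to_smiles(growspace:::mol_fill_h(m))
    }))))
  got <- introduce_unsaturations(cyc)
  expect_setequal(got, oracle)
  expect_true(smi_canonical("c1ccccc1") %in% got)
})

test_that("heteroatom mutation respects valence, symmetry, and forbidden motifs", {
  eth <- mol_from_smiles("CC")[[1]]
  expect_setequal(mutate_heteroatoms(eth),
                  smi_canonical(c("CN", "CO", "NO")))
  expect_setequal(mutate_heteroatoms(mol_from_smiles("C")[[1]]),
                  smi_canonical(c("N", "O")))
  # benzene: single mutation collapses to one product by symmetry
  benz <- mol_from_smiles("c1ccccc1")[[1]]
  prods <- mutate_heteroatoms(benz)
  single_n <- prods[vapply(prods, function(s) {
    h <- element_histogram(s); h[, "N"] == 1L && h[, "O"] == 0L
  }, logical(1))]
  expect_identical(single_n, smi_canonical("c1ccncc1"))
})

test_that("decoration applies the shipped transforms and rejects unknown ones", {
  ac <- mol_from_smiles("CC(=O)O")[[1]]
  expect_identical(decorate(ac), smi_canonical("CS(=O)(=O)O"))
  ph <- mol_from_smiles("Oc1ccccc1")[[1]]
  expect_setequal(decorate(ph),
                  smi_canonical(c("Fc1ccccc1", "Clc1ccccc1",
                                  "Brc1ccccc1", "Ic1ccccc1")))
  empty <- decorations_default()[0, ]
  expect_length(decorate(ac, empty), 0)
  bogus <- data.frame(name = "x", smirks = "[C:1]>>[N:1]")
  expect_error(decorate(ac, bogus), "unsupported")
})

test_that("space enumeration is exhaustive at one heavy atom and deterministic", {
  r <- enumerate_space(enumeration_config(1))
  expect_identical(r$molecules, c("C", "N", "O"))
  expect_identical(r$count_table$cumulative, 3L)
  r2 <- enumerate_space(enumeration_config(3))
  r3 <- enumerate_space(enumeration_config(3))
  expect_identical(r2$molecules, r3$molecules)
  expect_true(all(diff(r2$count_table$cumulative) >= 0))
  expect_identical(r2$count_table$cumulative,
                   as.integer(cumsum(r2$count_table$count)))
})

test_that("native forbidden-motif filtering equals the SMARTS route", {
  c_native <- enumeration_config(4)
  c_smarts <- enumeration_config(4)
  # same patterns, different object, forcing the generic SMARTS code path
  c_smarts$forbidden_motifs <- c(forbidden_motifs_default(), extra = "[Po]")
  r1 <- enumerate_space(c_native)
  r2 <- enumerate_space(c_smarts)
  expect_identical(r1$molecules, r2$molecules)
})
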