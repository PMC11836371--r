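test_that("atom distribution enumerates positive compositions", {
  expect_identical(distribute_atoms(3, 3), list(c(1L, 1L, 1L)))
  expect_length(distribute_atoms(5, 2), 4L)
  expect_identical(distribute_atoms(2, 3), list())
  for (n in 1:8) for (k in 1:4) {
    got <- distribute_atoms(n, k)
    expect_identical(length(got), as.integer(choose(n - 1, k - 1)),
                     info = paste(n, k))
    if (length(got)) {
      expect_true(all(vapply(got, sum, integer(1)) == n))
      expect_true(all(vapply(got, min, integer(1)) >= 1L))
      expect_false(any(duplicated(got)))
    }
  }
})

methyl_shelves <- function() build_shelves(activate_library("C", "single"))

test_that("growth attaches shelf substituents per mechanism", {
  cfg <- activate_scaffold("c1ccccc1", "single")
  one <- cfg$config_key[cfg$n_tags == 1L]
  expect_identical(grow(one, 1L, methyl_shelves()), smi_canonical("Cc1ccccc1"))
  two <- cfg$config_key[cfg$n_tags == 2L]
  xyl <- sort(unique(unlist(lapply(two, grow, composition = c(1L, 1L),
                                   shelves = methyl_shelves()))))
  expect_identical(xyl, sort(smi_canonical(c("Cc1ccccc1C", "Cc1cccc(C)c1",
                                             "Cc1ccc(C)cc1"))))
  # fusion and spiro rebuild shared-atom ring systems
  sh <- build_shelves(activate_library(c("C1CC1", "C1CCC1"),
                                       c("fusion", "spiro")))
  cfgf <- activate_scaffold("C1CCCCC1", c("fusion", "spiro"))
  fkey <- cfgf$config_key[cfgf$fusion == 1L & cfgf$n_tags == 1L][1]
  skey <- cfgf$config_key[cfgf$spiro == 1L & cfgf$n_tags == 1L][1]
  expect_identical(grow(fkey, 2L, sh), smi_canonical("C1CCC2CCC2C1"))
  expect_identical(grow(skey, 3L, sh), smi_canonical("C1CCC2(CC1)CCC2"))
  # empty compatible shelf -> no products
  expect_length(grow(fkey, 5L, sh), 0L)
})

test_that("superstructures contain their scaffold at the predicted size", {
  subs <- activate_library(c("C", "N", "O", "CC", "C=C"),
                           c("single", "double"))
  sh <- build_shelves(subs)
  res <- generate_superstructures("c1ccccc1", 2, sh,
                                  mechanisms = c("single", "double"))
  expect_setequal(res$molecules[[1]],
                  smi_canonical(c("Cc1ccccc1", "Nc1ccccc1", "Oc1ccccc1")))
  all_prods <- unlist(res$molecules)
  # substructure containment, exhaustively at this scale
  expect_true(all(substructure_search(all_prods, "c1ccccc1")))
  # heavy-atom bookkeeping: scaffold + added
  for (n_add in 1:2) {
    nh <- molecule_table(res$molecules[[n_add]])$n_heavy
    expect_true(all(nh == 6L + n_add))
  }
  # cumulative counts are monotone
  expect_true(all(diff(res$count_table$cumulative) >= 0))
})

test_that("toy-scale superstructures equal a brute-force attach-everywhere oracle", {
  # scaffold: furan; shelf: methyl only; 1 added atom, single bonds
  sh <- methyl_shelves()
  res <- generate_superstructures("c1ccoc1", 1, sh, mechanisms = "single")
  m <- mol_from_smiles(smi_canonical("c1ccoc1"))[[1]]
  brute <- character(0)
  for (i in which(m$hyd >= 1L)) {
    m2 <- m
    m2$elem <- c(m2$elem, "C")
    m2$hyd <- c(m2$hyd, 3L)
    m2$bond <- rbind(m2$bond, c(i, length(m2$elem), 1L))
    m2$hyd[i] <- m2$hyd[i] - 1L
    brute <- c(brute, mol_to_smiles(m2))
  }
  expect_setequal(res$molecules[[1]], unique(smi_canonical(brute)))
})

test_that("masked growth is a subset of unmasked growth", {
  sh <- methyl_shelves()
  m <- mol_from_smiles(smi_canonical("c1ccoc1"))[[1]]
  full <- generate_superstructures(m, 1, sh, mechanisms = "single")
  masked <- generate_superstructures(m, 1, sh, mechanisms = "single",
                                     allowed_vectors = which(m$elem == "C")[1])
  expect_true(all(unlist(masked$molecules) %in% unlist(full$molecules)))
  expect_lt(length(unlist(masked$molecules)), length(unlist(full$molecules)))
  # all vectors masked -> nothing grows
  none <- generate_superstructures(m, 1, sh, mechanisms = "single",
                                   allowed_vectors = integer(0))
  expect_identical(sum(none$count_table$count), 0L)
})
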