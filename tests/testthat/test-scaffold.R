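test_that("benzene single-bond activation yields the 12 necklace configurations", {
  cfg <- activate_scaffold("c1ccccc1", "single")
  expect_identical(nrow(cfg), 12L)
  expect_identical(attr(cfg, "raw_assignments"), 63L)
  expect_false(any(duplicated(cfg$config_key)))
})

test_that("scaffold configurations match brute-force subset enumeration with VF2 dedupe", {
  for (scaf in c("CC(C)O", "C1CCC1", "CCO", "CC=C")) {
    m <- mol_from_smiles(scaf)[[1]]
    cfg <- activate_scaffold(m, c("single", "double"))
    # oracle: enumerate the same hydrogen-feasible assignments but dedupe by
    # explicit pairwise VF2 isomorphism instead of canonical SMILES
    sites <- c(growspace:::raw_sites(m, "single"),
               growspace:::raw_sites(m, "double"))
    tagged <- list()
    rec <- function(i, cur) {
      if (i > length(sites)) {
        if (!is.null(cur)) tagged[[length(tagged) + 1L]] <<- cur
        return(invisible())
      }
      rec(i + 1L, cur)
      base <- if (is.null(cur)) m else cur
      mx <- growspace:::site_max_mult(m, sites[[i]])
      t <- base
      for (k in seq_len(mx)) {
        ok <- tryCatch({ t <- growspace:::attach_tag(t, sites[[i]]); TRUE },
                       error = function(e) FALSE)
        if (!ok) break
        rec(i + 1L, t)
      }
    }
    rec(1L, NULL)
    expect_identical(nrow(cfg), iso_dedupe_count(tagged), info = scaf)
  }
})

test_that("one viable site and one mechanism give exactly one configuration", {
  cfg <- activate_scaffold("C", "triple")
  expect_identical(nrow(cfg), 1L)
  expect_identical(cfg$n_tags, 1L)
})

test_that("masking growing vectors only removes configurations", {
  full <- activate_scaffold("Cc1ccccc1", "single")
  # allow tagging only on the methyl carbon (atom 1 in canonical order)
  m <- mol_from_smiles(smi_canonical("Cc1ccccc1"))[[1]]
  methyl <- which(m$elem == "C" & m$hyd == 3L)
  masked <- activate_scaffold(m, "single", allowed_vectors = methyl)
  expect_lt(nrow(masked), nrow(full))
  expect_true(all(masked$config_key %in% full$config_key))
  # no viable site -> empty frame, not an error
  none <- activate_scaffold("c1ccccc1", "single", allowed_vectors = integer(0))
  expect_identical(nrow(none), 0L)
})

test_that("the activation census reports convention sensitivity", {
  cen <- activation_census("c1ccccc1", c("single", "double"))
  expect_true(all(c("convention", "configurations") %in% names(cen)))
  expect_gte(nrow(cen), 3L)
  expect_identical(cen$configurations[1],
                   nrow(activate_scaffold("c1ccccc1", c("single", "double"))))
})
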