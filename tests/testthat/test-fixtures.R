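test_that("fixtures are byte-identical for a given seed", {
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  for (k in c("toy_library", "toy_blocks", "toy_counts", "toy_poses")) {
    p1 <- generate_fixtures(11, k, d1)
    p2 <- generate_fixtures(11, k, d2)
    expect_identical(readLines(p1), readLines(p2), info = k)
  }
  p3 <- generate_fixtures(12, "toy_library", d1)
  expect_false(identical(readLines(file.path(d1, "toy_library.smi")),
                         NULL))
  expect_error(generate_fixtures(1, "toy_nonsense", d1))
})

test_that("toy counts follow the closed form", {
  d <- tempfile()
  p <- generate_fixtures(1, "toy_counts", d, a = 1, b = 1, n_points = 3)
  tab <- read.delim(p)
  expect_identical(tab$cumulative, c(100L, 1000L, 10000L))
  expect_identical(tab$cumulative, as.integer(cumsum(tab$count)))
})

test_that("toy library plants eight benzene-ring matches", {
  d <- tempfile()
  lib <- read_smiles_file(generate_fixtures(3, "toy_library", d))
  expect_identical(nrow(lib), 20L)
  expect_identical(sum(substructure_search(lib$smiles, "c1ccccc1")), 8L)
})

test_that("planted poses drive the pose filter as designed", {
  d <- tempfile()
  generate_fixtures(5, "toy_poses", d)
  poses <- read_poses(file.path(d, "toy_poses.sdf"))
  ref <- read_poses(file.path(d, "toy_core_ref.sdf"))[[1]]$mol
  expect_length(poses, 5L)
  rmsds <- vapply(poses, function(p) core_rmsd(p$mol, ref), numeric(1))
  # one pose planted at exactly 3.0 A translation is rejected by the filter
  expect_true(any(abs(rmsds - 3.0) < 1e-6))
  sel <- core_rmsd_filter(poses, ref)
  expect_equal(sel$energy, -10)   # best energy (-12) sits at RMSD 3.0
  expect_equal(sel$rmsd, 1.5, tolerance = 1e-6)
})

test_that("the chained pipeline reconciles its manifest and is reproducible", {
  cfg <- list(n_max = 3, scaffold = "c1ccccc1", max_added = 1,
              mechanisms = "single", seed = 4, fit_range = c(1, 3),
              extrapolate_at = c(5L))
  r <- run_pipeline(cfg)
  expect_identical(r$manifest$tallies$molecules, length(r$space$molecules))
  expect_identical(r$manifest$tallies$activated_substituents,
                   nrow(r$substituents))
  expect_identical(r$manifest$tallies$scaffold_configurations, nrow(r$configs))
  expect_identical(r$manifest$tallies$superstructures,
                   sum(r$superstructures$count_table$count))
  expect_gte(r$manifest$tallies$activated_substituents,
             r$manifest$tallies$molecules)
  expect_s3_class(r$model, "growth_model")
  expect_identical(nrow(r$estimates), 1L)
  r2 <- run_pipeline(cfg)
  expect_identical(r$space$molecules, r2$space$molecules)
  expect_identical(r$superstructures$count_table, r2$superstructures$count_table)
})

test_that("growing with empty shelves succeeds with zero products", {
  empty <- build_shelves(activate_library(character(0)))
  res <- generate_superstructures("c1ccccc1", 1, empty, mechanisms = "single")
  expect_identical(sum(res$count_table$count), 0L)
})
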