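test_that("graph enumeration matches the exhaustive labeled-matrix oracle", {
  for (n in 1:5) {
    gs <- enumerate_graphs(n, planar = FALSE)
    got <- sum(vapply(gs, `[[`, integer(1), "n") == n)
    expect_identical(got, oracle_graph_classes(n), info = paste("n =", n))
  }
})

test_that("graph enumeration reproduces reference counts up to n = 7", {
  gs <- enumerate_graphs(7, planar = FALSE)
  gp <- enumerate_graphs(7, planar = TRUE)
  tab <- function(g) tabulate(vapply(g, `[[`, integer(1), "n"), nbins = 7)
  expect_identical(tab(gs), FROZEN_GRAPH_CLASSES$all)
  expect_identical(tab(gp), FROZEN_GRAPH_CLASSES$planar)
})

test_that("planarity test rejects Kuratowski graphs and their subdivisions", {
  k5 <- igraph::make_full_graph(5)
  k33 <- igraph::make_full_bipartite_graph(3, 3)
  expect_false(graph_is_planar(k5))
  expect_false(graph_is_planar(k33))
  # subdividing an edge must not restore planarity
  k33sub <- igraph::add_vertices(igraph::delete_edges(k33, 1), 1)
  k33sub <- igraph::add_edges(k33sub, c(1, 7, 7, 4))
  expect_false(graph_is_planar(k33sub))
  expect_true(graph_is_planar(igraph::make_ring(6)))
  expect_true(graph_is_planar(igraph::make_full_graph(4)))
  # planar but dense: octahedron reaches the 3n - 6 edge bound
  expect_true(graph_is_planar(igraph::make_graph("Octahedral")))
})

test_that("canonical keys are invariant under relabeling", {
  set.seed(42)
  gs <- enumerate_graphs(6, planar = TRUE)
  for (rec in sample(gs, 15)) {
    g <- igraph::make_empty_graph(rec$n, directed = FALSE)
    if (nrow(rec$edges)) g <- igraph::add_edges(g, t(rec$edges))
    p <- sample(rec$n)
    expect_identical(growspace:::graph_canonical_key(igraph::permute(g, p)),
                     rec$canonical_key)
  }
})

test_that("enumeration order is deterministic and n_max is validated", {
  expect_identical(enumerate_graphs(4), enumerate_graphs(4))
  expect_error(enumerate_graphs(0), "n_max")
})
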