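# Deterministic 3D embedding by distance geometry.
#
# The enumeration pipeline needs one reproducible conformer per saturated
# hydrocarbon, only to measure tetrahedral volumes at quaternary centers.
# Coordinates are produced by classical multidimensional scaling of the
# graph-distance matrix (scaled by ideal bond lengths) followed by BFGS
# refinement of a purely distance-based objective: harmonic terms for
# bonded (1-2) and geminal (1-3, tetrahedral-angle) distances plus a soft
# lower bound on all other pairs. Impossible constraint systems (fused
# small-ring cages) converge to collapsed geometries, which is precisely
# what the strain filter is meant to catch. The initial jitter that breaks
# planar degeneracies is drawn from the supplied seed, so embeddings are
# reproducible.

COVALENT_RADius <- c(C = 0.77, N = 0.75, O = 0.73, S = 1.04, P = 1.10,
                     F = 0.71, Cl = 0.99, Br = 1.14, I = 1.33, B = 0.82)

bond_length_ideal <- function(el1, el2, order = 1L) {
  r1 <- COVALENT_RADius[el1]; r2 <- COVALENT_RADius[el2]
  r1[is.na(r1)] <- 0.9; r2[is.na(r2)] <- 0.9
  shrink <- c(1, 0.87, 0.78)[pmin(order, 3L)]
  unname((r1 + r2) * shrink)
}

#' Deterministic 3D embedding of a molecular graph
#'
#' @param m a `gs_mol`.
#' @param seed integer; controls the symmetry-breaking jitter, making the
#'   embedding reproducible.
#' @param iterations maximum BFGS iterations.
#' @return the molecule with a `coords` matrix (n x 3, angstroms).
#' @export
embed_coords <- function(m, seed = 1L, iterations = 300L) {
  n <- length(m$elem)
  if (n == 1L) { m$coords <- matrix(0, 1, 3); return(m) }
  g <- igraph::graph_from_edgelist(m$bond[, 1:2, drop = FALSE], directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  blen <- bond_length_ideal(m$elem[m$bond[, "a"]], m$elem[m$bond[, "b"]],
                            m$bond[, "order"])
  gd <- igraph::distances(g)
  D <- gd * mean(blen)
  # classical MDS initialization
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (D * D) %*% J
  ev <- eigen(B, symmetric = TRUE)
  k <- min(3L, sum(ev$values > 1e-8))
  X <- matrix(0, n, 3)
  if (k > 0)
    X[, seq_len(k)] <- ev$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(ev$values[seq_len(k)]), k)
  set.seed(seed)
  X <- X + matrix(stats::rnorm(3 * n, sd = 0.1), n, 3)
  # distance constraints
  pairs12 <- m$bond[, 1:2, drop = FALSE]
  t12 <- blen
  # geminal pairs (1-3) at tetrahedral-type angles
  adj <- mol_adjlist(m)
  p13 <- NULL; t13 <- NULL
  for (j in seq_len(n)) {
    nb <- unique(unlist(lapply(adj[[j]], function(bi)
      setdiff(m$bond[bi, 1:2], j))))
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      for (cix in seq_len(ncol(cmb))) {
        a <- cmb[1, cix]; b <- cmb[2, cix]
        la <- bond_length_ideal(m$elem[a], m$elem[j])
        lb <- bond_length_ideal(m$elem[b], m$elem[j])
        p13 <- rbind(p13, c(a, b))
        t13 <- c(t13, sqrt(la^2 + lb^2 - 2 * la * lb * cos(109.47 * pi / 180)))
      }
    }
  }
  # soft repulsion floor for topologically distant pairs
  far <- which(gd >= 3, arr.ind = TRUE)
  far <- far[far[, 1] < far[, 2], , drop = FALSE]
  w12 <- 10; w13 <- 2; wrep <- 1; rep_floor <- 2.6
  energy_grad <- function(x) {
    X <- matrix(x, n, 3)
    E <- 0
    G <- matrix(0, n, 3)
    addterm <- function(p, t, w, lower_only = FALSE) {
      if (is.null(p) || !nrow(p)) return(invisible())
      d <- X[p[, 1], , drop = FALSE] - X[p[, 2], , drop = FALSE]
      r <- sqrt(rowSums(d * d)) + 1e-9
      dev <- r - t
      if (lower_only) dev <- pmin(dev, 0)
      E <<- E + w * sum(dev^2)
      f <- 2 * w * dev / r
      G2 <- d * f
      for (cc in 1:3) {
        G[, cc] <<- G[, cc] + tapply(c(G2[, cc], -G2[, cc]),
                                     factor(c(p[, 1], p[, 2]), levels = seq_len(n)),
                                     sum, default = 0)
      }
    }
    addterm(pairs12, t12, w12)
    addterm(p13, t13, w13)
    addterm(far, rep(rep_floor, nrow(far)), wrep, lower_only = TRUE)
    list(E = E, G = as.vector(G))
  }
  res <- stats::optim(as.vector(X),
                      fn = function(x) energy_grad(x)$E,
                      gr = function(x) energy_grad(x)$G,
                      method = "BFGS",
                      control = list(maxit = iterations, reltol = 1e-10))
  m$coords <- matrix(res$par, n, 3)
  m
}
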