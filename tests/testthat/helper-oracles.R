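# Brute-force oracles, independent of the generation paths they check.

# all permutations of 1..n (n <= 6 here)
perms_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perms_all(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# connected simple graphs on n labeled vertices with max degree <= 4,
# deduplicated by explicit permutation of adjacency matrices (no igraph,
# no canonical forms). Returns the count of isomorphism classes.
oracle_graph_classes <- function(n, max_degree = 4L) {
  if (n == 1L) return(1L)
  pairs <- t(utils::combn(n, 2))
  np <- nrow(pairs)
  P <- perms_all(n)
  seen <- character(0)
  reach_connected <- function(A) {
    vis <- logical(n); vis[1] <- TRUE; front <- 1L
    while (length(front)) {
      nxt <- which(colSums(A[front, , drop = FALSE]) > 0 & !vis)
      vis[nxt] <- TRUE; front <- nxt
    }
    all(vis)
  }
  for (mask in 0:(2^np - 1)) {
    A <- matrix(0L, n, n)
    bits <- bitwAnd(bitwShiftR(mask, seq_len(np) - 1L), 1L)
    if (sum(bits) < n - 1L) next
    for (e in which(bits == 1L)) {
      A[pairs[e, 1], pairs[e, 2]] <- 1L
      A[pairs[e, 2], pairs[e, 1]] <- 1L
    }
    if (max(rowSums(A)) > max_degree) next
    if (!reach_connected(A)) next
    # canonical label by explicit minimum over all permutations
    best <- NULL
    for (r in seq_len(nrow(P))) {
      p <- P[r, ]
      key <- paste(A[p, p][upper.tri(A)], collapse = "")
      if (is.null(best) || key < best) best <- key
    }
    seen <- union(seen, best)
  }
  length(seen)
}

# frozen counts of connected max-degree-4 graph classes per n, computed
# with an independent toolchain (exhaustive matrices / graph atlas plus a
# reference planarity test)
FROZEN_GRAPH_CLASSES <- data.frame(
  n = 1:7,
  all = c(1L, 1L, 2L, 6L, 21L, 78L, 353L),
  planar = c(1L, 1L, 2L, 6L, 20L, 74L, 321L))

# element-colored, bond-order-colored isomorphism via igraph VF2 on a
# bond-subdivided graph; used as the independent dedupe in activation tests
mol_iso_graph <- function(m) {
  n <- length(m$elem)
  nb <- nrow(m$bond)
  g <- igraph::make_empty_graph(n + nb, directed = FALSE)
  if (nb) {
    e <- rbind(cbind(m$bond[, "a"], n + seq_len(nb)),
               cbind(m$bond[, "b"], n + seq_len(nb)))
    g <- igraph::add_edges(g, t(e))
  }
  codes <- c(C = 1, N = 2, O = 3, S = 4, F = 5, Cl = 6, Br = 7, I = 8,
             Lu = 20, Hf = 21, Ta = 22, W = 23, Re = 24)
  vc <- c(unname(codes[m$elem]) + 100 * m$hyd, 50 + m$bond[, "order"])
  list(g = g, col = as.integer(vc))
}

mols_isomorphic <- function(m1, m2) {
  a <- mol_iso_graph(m1); b <- mol_iso_graph(m2)
  if (length(a$col) != length(b$col)) return(FALSE)
  if (!identical(sort(a$col), sort(b$col))) return(FALSE)
  igraph::isomorphic(a$g, b$g, method = "vf2",
                     vertex.color1 = a$col, vertex.color2 = b$col)
}

# dedupe a list of gs_mol by pairwise VF2 isomorphism
iso_dedupe_count <- function(mols) {
  reps <- list()
  for (m in mols) {
    dup <- any(vapply(reps, function(r) mols_isomorphic(r, m), logical(1)))
    if (!dup) reps[[length(reps) + 1L]] <- m
  }
  length(reps)
}
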