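# Generation of molecular skeleton graphs: connected simple graphs with
# maximum degree 4 (tetravalent carbon), one representative per isomorphism
# class, optionally restricted to planar graphs.
#
# Strategy: vertex augmentation. Every connected graph on n vertices arises
# from a connected graph on n-1 vertices (remove a non-cut vertex, which
# always exists) by adding one vertex joined to a non-empty subset of the
# old vertices. Duplicates are removed with a BLISS canonical form (igraph).
# Planarity can be enforced level-by-level because adding a vertex and edges
# never makes a non-planar graph planar.

graph_canonical_key <- function(g) {
  perm <- igraph::canonical_permutation(g)$labeling
  gc <- igraph::permute(g, perm)
  el <- igraph::as_edgelist(gc, names = FALSE)
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste0(igraph::vcount(g), ":", paste(el[, 1], el[, 2], sep = "-", collapse = ","))
}

#' Planarity test (Kuratowski subdivision search)
#'
#' Exact for the small graphs handled here. A graph is non-planar iff it
#' contains a subdivision of K5 or K3,3; the search enumerates candidate
#' branch vertices and looks for internally vertex-disjoint connecting
#' paths by backtracking. Cheap pre-checks (edge count bounds) short-circuit
#' most calls.
#'
#' @param g an igraph undirected graph.
#' @return logical.
#' @export
graph_is_planar <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n < 5L || m < 9L) return(TRUE)
  if (m > 3L * n - 6L) return(FALSE)
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  deg <- lengths(adj)
  # internally-disjoint path system between required pairs of branch vertices
  find_paths <- function(pairs, branch) {
    used <- logical(n)
    used[branch] <- TRUE
    connect <- function(k) {
      if (k > nrow(pairs)) return(TRUE)
      s <- pairs[k, 1]; t <- pairs[k, 2]
      # DFS over simple paths s..t with internal vertices unused & not branch
      path_dfs <- function(v, interior) {
        for (w in adj[[v]]) {
          if (w == t && (v != s || TRUE)) {
            # direct step to target
            if (connect(k + 1L)) return(TRUE)
          }
        }
        for (w in adj[[v]]) {
          if (w == t || used[w]) next
          used[w] <<- TRUE
          if (path_dfs(w, c(interior, w))) return(TRUE)
          used[w] <<- FALSE
        }
        FALSE
      }
      path_dfs(s, integer())
    }
    connect(1L)
  }
  # K5 subdivision: 5 branch vertices of degree >= 4
  cand5 <- which(deg >= 4L)
  if (length(cand5) >= 5L) {
    for (B in utils::combn(cand5, 5L, simplify = FALSE)) {
      pairs <- t(utils::combn(B, 2L))
      if (find_paths(pairs, B)) return(FALSE)
    }
  }
  # K3,3 subdivision: 6 branch vertices of degree >= 3, split 3 + 3
  cand33 <- which(deg >= 3L)
  if (length(cand33) >= 6L) {
    for (B in utils::combn(cand33, 6L, simplify = FALSE)) {
      for (L in utils::combn(seq_len(6L), 3L, simplify = FALSE)) {
        if (1L %in% L) {  # fix vertex 1 on the left to halve the work
          left <- B[L]; right <- B[-L]
          pairs <- as.matrix(expand.grid(left, right))
          if (find_paths(pairs, B)) return(FALSE)
        }
      }
    }
  }
  TRUE
}

#' Enumerate molecular skeleton graphs
#'
#' Generates exactly one representative per isomorphism class of connected
#' simple graphs with at most `n_max` nodes and maximum degree 4 (the
#' skeletons of tetravalent-carbon molecules), optionally restricted to
#' planar graphs. Output order is deterministic: by node count, then by
#' canonical key.
#'
#' @param n_max maximum number of nodes (>= 1).
#' @param planar if `TRUE` (default) keep only planar graphs.
#' @param max_degree maximum vertex degree (default 4).
#' @return list of graphs; each element is a list with `n` (nodes), `edges`
#'   (2-column matrix) and `canonical_key`.
#' @export
enumerate_graphs <- function(n_max, planar = TRUE, max_degree = 4L) {
  if (!is.numeric(n_max) || length(n_max) != 1L || n_max < 1L)
    stop("`n_max` must be a single integer >= 1")
  n_max <- as.integer(n_max)
  lvl <- list(list(igraph::make_empty_graph(1, directed = FALSE)))
  out <- list()
  emit <- function(gs, n) {
    keys <- vapply(gs, graph_canonical_key, character(1))
    ord <- order(keys)
    lapply(ord, function(i) {
      g <- gs[[i]]
      list(n = n, edges = igraph::as_edgelist(g, names = FALSE),
           canonical_key = keys[i])
    })
  }
  cur <- lvl[[1]]
  out <- c(out, emit(cur, 1L))
  n <- 1L
  while (n < n_max) {
    n <- n + 1L
    seen <- new.env(parent = emptyenv())
    nxt <- list()
    for (g in cur) {
      deg <- igraph::degree(g)
      attachable <- which(deg < max_degree)
      if (!length(attachable)) next
      for (k in seq_len(min(length(attachable), max_degree))) {
        subsets <- if (length(attachable) == 1L) list(attachable)
          else utils::combn(attachable, k, simplify = FALSE)
        for (S in subsets) {
          g2 <- igraph::add_vertices(g, 1L)
          g2 <- igraph::add_edges(g2, as.vector(rbind(S, n)))
          key <- graph_canonical_key(g2)
          if (!is.null(seen[[key]])) next
          if (planar && !graph_is_planar(g2)) { seen[[key]] <- FALSE; next }
          seen[[key]] <- TRUE
          nxt[[length(nxt) + 1L]] <- g2
        }
      }
    }
    cur <- nxt
    out <- c(out, emit(cur, n))
  }
  out
}

# igraph object from an enumerated graph record
graph_to_igraph <- function(rec) {
  g <- igraph::make_empty_graph(rec$n, directed = FALSE)
  if (nrow(rec$edges)) g <- igraph::add_edges(g, t(rec$edges))
  g
}
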