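# Automorphism-group machinery for orbit-level deduplication. Enumerating
# unsaturation patterns or heteroatom assignments over a fixed skeleton
# produces duplicates exactly when two assignments are related by a
# symmetry of the skeleton, so filtering to one orbit representative per
# class removes them without any canonicalization round-trips. (Aromatic
# Kekule forms that only collapse under aromaticity perception are merged
# later, at the final canonical-SMILES pass.)

# full automorphism group of a gs_mol graph as a matrix of permutations
# (one row per group element, acting on atom indices).
# use_orders: respect bond orders (edge colors, via subdivision vertices);
# use_elements: respect atom elements (vertex colors).
aut_group_perms <- function(m, use_orders = TRUE, use_elements = TRUE,
                            max_order = 200000L) {
  n <- length(m$elem)
  nb <- nrow(m$bond)
  nv <- n + nb
  g <- igraph::make_empty_graph(nv, directed = FALSE)
  if (nb) {
    e <- rbind(cbind(m$bond[, "a"], n + seq_len(nb)),
               cbind(m$bond[, "b"], n + seq_len(nb)))
    g <- igraph::add_edges(g, t(e))
  }
  ecode <- ELEM_CODE[m$elem]; ecode[is.na(ecode)] <- 12L
  vcol <- c(if (use_elements) ecode else rep(1L, n),
            if (use_orders) 100L + m$bond[, "order"] else rep(100L, nb))
  gens <- igraph::automorphism_group(g, colors = as.integer(vcol))
  gens <- lapply(gens, function(p) as.integer(p)[seq_len(n)])
  # close the generator set (BFS over composition)
  id <- seq_len(n)
  seen <- new.env(parent = emptyenv())
  key <- function(p) paste(p, collapse = ",")
  assign(key(id), TRUE, envir = seen)
  group <- list(id)
  frontier <- list(id)
  while (length(frontier)) {
    nxt <- list()
    for (p in frontier) for (q in gens) {
      r <- p[q]
      k <- key(r)
      if (is.null(seen[[k]])) {
        seen[[k]] <- TRUE
        group[[length(group) + 1L]] <- r
        nxt[[length(nxt) + 1L]] <- r
        if (length(group) > max_order)
          stop("automorphism group larger than ", max_order)
      }
    }
    frontier <- nxt
  }
  do.call(rbind, group)
}

# bond permutation induced by an atom permutation: row k of the result is
# the bond index that bond k maps to under the permutation.
bond_perms <- function(m, atom_perms) {
  nb <- nrow(m$bond)
  if (!nb) return(matrix(integer(), nrow = nrow(atom_perms), ncol = 0))
  bkey <- paste(pmin(m$bond[, "a"], m$bond[, "b"]),
                pmax(m$bond[, "a"], m$bond[, "b"]))
  idx <- stats::setNames(seq_len(nb), bkey)
  t(apply(atom_perms, 1, function(p) {
    a <- p[m$bond[, "a"]]; b <- p[m$bond[, "b"]]
    unname(idx[paste(pmin(a, b), pmax(a, b))])
  }))
}

# keep the rows of `mat` (assignments, one column per position) that are
# lexicographically minimal within their orbit under the permutations
# (rows of `perms`, acting by column re-indexing).
orbit_minimal <- function(mat, perms) {
  if (!nrow(mat)) return(logical(0))
  if (ncol(mat) == 0L) return(!duplicated(mat))
  self_key <- do.call(paste, c(as.data.frame(mat), sep = "\r"))
  keep <- rep(TRUE, nrow(mat))
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    if (all(p == seq_len(ncol(mat)))) next
    perm_key <- do.call(paste, c(as.data.frame(mat[, p, drop = FALSE]), sep = "\r"))
    keep <- keep & (self_key <= perm_key)
  }
  keep
}
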