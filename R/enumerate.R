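# Staged exhaustive enumeration of chemically stable molecules up to a
# heavy-atom limit: skeleton graphs -> saturated hydrocarbons -> strain
# filter (3D) -> unsaturation -> heteroatom mutation -> decoration.
# Deduplication is global, by canonical SMILES with aromaticity perception.

#' Enumeration configuration
#'
#' @param n_max heavy-atom limit (>= 1).
#' @param strain_volume_threshold minimum tetrahedral volume in cubic
#'   angstroms at a carbon with four heavy neighbors; smaller means a
#'   geometrically collapsed (strained) center and the hydrocarbon is
#'   discarded. Default 0.145.
#' @param mutation_elements elements carbons may be mutated into
#'   (default N and O).
#' @param forbidden_motifs character vector of SMARTS; molecules matching
#'   any are removed (defaults: acyclic N-N, acyclic O-O, cumulated double
#'   bonds).
#' @param decoration_table decoration transforms, see [decorations_default()].
#' @param embed_seed integer seed for the distance-geometry embedder's
#'   symmetry-breaking jitter ([embed_coords()]); embeddings, and with them
#'   strain-filter outcomes, are reproducible given the seed.
#' @param planar restrict skeleton graphs to planar graphs.
#' @return an `enumeration_config` list.
#' @export
enumeration_config <- function(n_max,
                               strain_volume_threshold = 0.145,
                               mutation_elements = c("N", "O"),
                               forbidden_motifs = forbidden_motifs_default(),
                               decoration_table = decorations_default(),
                               embed_seed = 1L,
                               planar = TRUE) {
  stopifnot(n_max >= 1, strain_volume_threshold > 0)
  structure(list(n_max = as.integer(n_max),
                 strain_volume_threshold = strain_volume_threshold,
                 mutation_elements = mutation_elements,
                 forbidden_motifs = forbidden_motifs,
                 decoration_table = decoration_table,
                 embed_seed = as.integer(embed_seed),
                 planar = isTRUE(planar)),
            class = "enumeration_config")
}

#' Default forbidden structural motifs
#'
#' Acyclic N-N (hydrazines, azo), acyclic O-O (peroxides) and cumulated
#' double bonds (allenes, ketenes). Matching molecules are rejected both
#' after heteroatom mutation and after substituent attachment.
#' @return named character vector of SMARTS.
#' @export
forbidden_motifs_default <- function() {
  c(hydrazine = "[#7]~!@[#7]",
    peroxide  = "[#8]~!@[#8]",
    allene    = "*=[*X2]=*")
}

#' Convert a skeleton graph to a saturated hydrocarbon
#'
#' Each node becomes a carbon; valences are completed with hydrogens.
#' @param rec a graph record from [enumerate_graphs()].
#' @return a `gs_mol`.
#' @export
saturate <- function(rec) {
  bond <- cbind(rec$edges, rep(1L, nrow(rec$edges)))
  if (!nrow(rec$edges)) bond <- matrix(integer(), ncol = 3)
  m <- gs_mol(rep("C", rec$n), integer(rec$n), bond)
  mol_fill_h(m)
}

#' Tetrahedral volumes at quaternary centers
#'
#' For every carbon with exactly four heavy-atom neighbors, the volume of
#' the tetrahedron spanned by the four neighbor coordinates. An ideal
#' center with C-C bonds of 1.54 A has a volume of about 1.87 cubic
#' angstroms; a collapsed (near-coplanar) arrangement approaches zero.
#'
#' @param m a `gs_mol` with 3D coordinates.
#' @return numeric vector (possibly empty), named by atom index.
#' @export
tetrahedron_volumes <- function(m) {
  if (is.null(m$coords)) stop("molecule has no 3D coordinates")
  deg <- mol_degree(m)
  centers <- which(deg == 4L & m$elem == "C")
  if (!length(centers)) return(stats::setNames(numeric(0), character(0)))
  vols <- vapply(centers, function(ci) {
    nb <- unique(c(m$bond[m$bond[, "a"] == ci, "b"],
                   m$bond[m$bond[, "b"] == ci, "a"]))
    p <- m$coords[nb, , drop = FALSE]
    v1 <- p[2, ] - p[1, ]; v2 <- p[3, ] - p[1, ]; v3 <- p[4, ] - p[1, ]
    abs(det(rbind(v1, v2, v3))) / 6
  }, numeric(1))
  stats::setNames(vols, centers)
}

#' Strain filter for embedded hydrocarbons
#'
#' Keeps a molecule iff every quaternary-center tetrahedral volume is at
#' least `threshold`. Molecules without such centers pass vacuously.
#'
#' @param m a `gs_mol` with coordinates.
#' @param threshold volume cutoff in cubic angstroms.
#' @return list with `keep` (logical) and `volumes`.
#' @export
strain_filter <- function(m, threshold = 0.145) {
  vols <- tetrahedron_volumes(m)
  list(keep = !length(vols) || all(vols >= threshold), volumes = vols)
}

## ---- template-based variant generation -------------------------------------

# Template of a molecule's SMILES with substitutable atom and bond slots.
# Variants differing only in element assignment and/or bond orders can then
# be written as strings without re-running the DFS writer.
smiles_template <- function(m) {
  n <- length(m$elem)
  pieces <- smiles_build_slots(m)
  inc <- matrix(0L, nrow = nrow(m$bond), ncol = n)
  if (nrow(m$bond)) for (i in seq_len(nrow(m$bond))) {
    inc[i, m$bond[i, "a"]] <- 1L
    inc[i, m$bond[i, "b"]] <- 1L
  }
  list(parts = pieces$parts, slots = pieces$slots, incidence = inc, n = n)
}

# Writer variant that records atom AND bond slots (bond symbol positions).
smiles_build_slots <- function(m) {
  n <- length(m$elem)
  adj <- mol_adjlist(m)
  visited <- logical(n)
  bond_used <- logical(nrow(m$bond))
  ring_num <- 0L
  closures <- vector("list", n)
  tree_children <- vector("list", n)
  visited[1L] <- TRUE
  stack <- c(1L)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (bi in adj[[v]]) {
      if (bond_used[bi]) next
      w <- if (m$bond[bi, "a"] == v) m$bond[bi, "b"] else m$bond[bi, "a"]
      if (!visited[w]) {
        visited[w] <- TRUE; bond_used[bi] <- TRUE
        tree_children[[v]] <- c(tree_children[[v]], list(c(w, bi)))
        stack <- c(stack, w)
      } else {
        bond_used[bi] <- TRUE
        ring_num <- ring_num + 1L
        closures[[v]] <- c(closures[[v]], list(c(ring_num, bi)))
        closures[[w]] <- c(closures[[w]], list(c(ring_num, bi)))
      }
    }
  }
  if (!all(visited)) stop("molecule is not connected")
  ring_digit <- function(k) if (k < 10) as.character(k) else paste0("%", k)
  out <- list()  # entries: list(type = "txt"/"atom"/"bond", value/index)
  push <- function(x) out[[length(out) + 1L]] <<- x
  emit <- function(v, bond_in) {
    if (!is.na(bond_in)) push(list(type = "bond", index = bond_in))
    push(list(type = "atom", index = v))
    for (cl in closures[[v]]) {
      push(list(type = "bond", index = cl[2]))
      push(list(type = "txt", value = ring_digit(cl[1])))
    }
    kids <- tree_children[[v]]
    for (k in seq_along(kids)) {
      w <- kids[[k]][1]; bi <- kids[[k]][2]
      if (k < length(kids)) {
        push(list(type = "txt", value = "(")); emit(w, bi)
        push(list(type = "txt", value = ")"))
      } else emit(w, bi)
    }
  }
  emit(1L, NA_integer_)
  # collapse consecutive txt, produce parts/slots
  types <- vapply(out, `[[`, character(1), "type")
  nslot <- sum(types != "txt")
  parts <- character(nslot + 1L)
  slots <- data.frame(type = character(nslot), index = integer(nslot),
                      stringsAsFactors = FALSE)
  si <- 0L
  for (e in out) {
    if (e$type == "txt") parts[si + 1L] <- paste0(parts[si + 1L], e$value)
    else {
      si <- si + 1L
      slots$type[si] <- e$type; slots$index[si] <- e$index
    }
  }
  list(parts = parts, slots = slots)
}

# Write all variants given an A x n element matrix and an A x nb order matrix.
template_render <- function(tpl, elem_mat, order_mat) {
  A <- nrow(elem_mat)
  bondsum <- if (ncol(tpl$incidence) && nrow(tpl$incidence))
    order_mat %*% tpl$incidence else matrix(0L, A, tpl$n)
  order_sym <- c("", "=", "#")
  cols <- vector("list", 2L * nrow(tpl$slots) + 1L)
  ci <- 1L
  cols[[ci]] <- tpl$parts[1L]
  for (s in seq_len(nrow(tpl$slots))) {
    ci <- ci + 1L
    if (tpl$slots$type[s] == "atom") {
      ai <- tpl$slots$index[s]
      el <- elem_mat[, ai]
      h <- implicit_h(el, bondsum[, ai])
      cols[[ci]] <- paste0("[", el,
                           ifelse(h == 1L, "H", ifelse(h > 1L, paste0("H", h), "")),
                           "]")
    } else {
      cols[[ci]] <- order_sym[order_mat[, tpl$slots$index[s]]]
    }
    ci <- ci + 1L
    cols[[ci]] <- tpl$parts[s + 1L]
  }
  do.call(paste0, cols)
}

## ---- unsaturation ----------------------------------------------------------

#' Introduce unsaturations into a saturated hydrocarbon
#'
#' Enumerates every assignment of double/triple orders to C-C bonds for
#' which both atoms can give up the required hydrogens (combinatorially,
#' multiple unsaturations allowed), and returns the unique resulting
#' molecules as canonical SMILES. The input (fully saturated) molecule is
#' not part of the result.
#'
#' @param m a `gs_mol` (saturated hydrocarbon).
#' @param canonical canonicalize and dedupe (set `FALSE` to obtain raw
#'   Kekule strings for caller-side batching).
#' @return character vector of canonical SMILES (possibly empty).
#' @export
introduce_unsaturations <- function(m, canonical = TRUE) {
  order_mat <- unsat_order_matrix(m)
  if (!nrow(order_mat)) return(character())
  tpl <- smiles_template(m)
  A <- nrow(order_mat)
  elem_mat <- matrix(rep(m$elem, each = A), nrow = A)
  smis <- template_render(tpl, elem_mat, order_mat)
  if (!canonical) return(smis)
  sort(unique(stats::na.omit(smi_canonical(smis))))
}

# orbit-unique bond-order assignments with at least one unsaturation
# (matrix with one column per bond; 0 rows if none)
unsat_order_matrix <- function(m) {
  nb <- nrow(m$bond)
  if (!nb) return(matrix(integer(), 0, 0))
  base <- mol_bondsum(m)
  cap <- STD_VALENCE[m$elem]; cap[is.na(cap)] <- 0L
  extra <- integer(nb)
  load <- integer(length(m$elem))  # extra order carried by each atom
  res <- list()
  assign_bond <- function(i) {
    if (i > nb) {
      if (any(extra > 0L)) res[[length(res) + 1L]] <<- extra
      return(invisible())
    }
    a <- m$bond[i, "a"]; b <- m$bond[i, "b"]
    # hydrogens available on each atom = cap - base - load (all-H periphery)
    avail <- min(cap[a] - base[a] - load[a], cap[b] - base[b] - load[b])
    for (e in 0:min(2L, max(avail, 0L))) {
      extra[i] <<- e; load[a] <<- load[a] + e; load[b] <<- load[b] + e
      assign_bond(i + 1L)
      load[a] <<- load[a] - e; load[b] <<- load[b] - e; extra[i] <<- 0L
    }
  }
  assign_bond(1L)
  if (!length(res)) return(matrix(integer(), 0, nb))
  order_mat <- matrix(1L + unlist(res), nrow = length(res), byrow = TRUE)
  aperm <- aut_group_perms(m, use_orders = FALSE, use_elements = FALSE)
  order_mat[orbit_minimal(order_mat, bond_perms(m, aperm)), , drop = FALSE]
}

# gs_mol variants for an order matrix (used by the space pipeline to avoid
# SMILES round-trips)
unsaturation_variants <- function(m, order_mat) {
  lapply(seq_len(nrow(order_mat)), function(k) {
    v <- m
    v$bond[, "order"] <- order_mat[k, ]
    mol_fill_h(v)
  })
}

## ---- heteroatom mutation ---------------------------------------------------

#' Mutate carbons into heteroatoms
#'
#' Combinatorially replaces carbon atoms by N and/or O wherever the
#' element's valence can carry the atom's bond orders (hydrogens adjust).
#' Molecules matching a forbidden motif are removed. The all-carbon input
#' itself is not part of the result.
#'
#' @param m a `gs_mol` (hydrocarbon, possibly unsaturated).
#' @param elements elements to mutate into.
#' @param forbidden_motifs SMARTS list applied to the products.
#' @param canonical canonicalize, dedupe and filter (set `FALSE` for raw
#'   strings; the forbidden-motif filter is then the caller's job).
#' @return character vector of canonical SMILES.
#' @export
mutate_heteroatoms <- function(m, elements = c("N", "O"),
                               forbidden_motifs = forbidden_motifs_default(),
                               canonical = TRUE) {
  n <- length(m$elem)
  bs <- mol_bondsum(m)
  choice <- lapply(seq_len(n), function(i) {
    if (m$elem[i] != "C") return(m$elem[i])
    ok <- elements[STD_VALENCE[elements] >= bs[i]]
    c("C", ok)
  })
  sizes <- lengths(choice)
  if (prod(sizes) <= 1) return(character())
  grid <- as.matrix(expand.grid(choice, stringsAsFactors = FALSE))
  grid <- grid[rowSums(grid != matrix(m$elem, nrow(grid), n, byrow = TRUE)) > 0L, ,
               drop = FALSE]
  if (!nrow(grid)) return(character())
  # one representative per symmetry orbit (bond orders respected)
  aperm <- aut_group_perms(m, use_orders = TRUE, use_elements = TRUE)
  grid <- grid[orbit_minimal(grid, aperm), , drop = FALSE]
  if (!nrow(grid)) return(character())
  tpl <- smiles_template(m)
  order_mat <- matrix(rep(m$bond[, "order"], each = nrow(grid)), nrow = nrow(grid))
  if (!nrow(m$bond)) order_mat <- matrix(integer(), nrow = nrow(grid), ncol = 0)
  smis <- template_render(tpl, grid, order_mat)
  if (!canonical) return(smis)
  out <- sort(unique(stats::na.omit(smi_canonical(smis))))
  filter_forbidden(out, forbidden_motifs)
}

# orbit-filtered element-assignment matrix for a skeleton, with the default
# acyclic N-N / O-O exclusions applied natively when requested
mutation_grid <- function(m, elements, native_motifs = TRUE) {
  n <- length(m$elem)
  bs <- mol_bondsum(m)
  choice <- lapply(seq_len(n), function(i) {
    if (m$elem[i] != "C") return(m$elem[i])
    ok <- elements[STD_VALENCE[elements] >= bs[i]]
    c("C", ok)
  })
  if (prod(lengths(choice)) <= 1) return(matrix(character(), 0, n))
  grid <- as.matrix(expand.grid(choice, stringsAsFactors = FALSE))
  grid <- grid[rowSums(grid != matrix(m$elem, nrow(grid), n, byrow = TRUE)) > 0L, ,
               drop = FALSE]
  if (!nrow(grid)) return(grid)
  if (native_motifs && nrow(m$bond)) {
    acyc <- which(!mol_ring_bonds(m))
    bad <- rep(FALSE, nrow(grid))
    for (r in acyc) {
      ea <- grid[, m$bond[r, "a"]]; eb <- grid[, m$bond[r, "b"]]
      bad <- bad | (ea == "N" & eb == "N") | (ea == "O" & eb == "O")
    }
    grid <- grid[!bad, , drop = FALSE]
    if (!nrow(grid)) return(grid)
  }
  aperm <- aut_group_perms(m, use_orders = TRUE, use_elements = TRUE)
  grid[orbit_minimal(grid, aperm), , drop = FALSE]
}

# graph-level test of the default forbidden motifs; TRUE means clean
motif_clean_native <- function(m) {
  if (!nrow(m$bond)) return(TRUE)
  mult <- m$bond[, "order"] >= 2L
  if (any(mult)) {
    cnt <- tabulate(c(m$bond[mult, "a"], m$bond[mult, "b"]),
                    nbins = length(m$elem))
    # cumulated center: two multiple bonds on a two-connection atom
    # (hypervalent sulfur in e.g. sulfonic acids is not cumulated)
    if (any(cnt >= 2L & mol_degree(m) == 2L)) return(FALSE)
  }
  acyc <- !mol_ring_bonds(m)
  if (any(acyc)) {
    ea <- m$elem[m$bond[acyc, "a"]]; eb <- m$elem[m$bond[acyc, "b"]]
    if (any(ea == "N" & eb == "N") || any(ea == "O" & eb == "O")) return(FALSE)
  }
  TRUE
}

# Remove molecules matching any forbidden motif.
filter_forbidden <- function(smiles, motifs) {
  if (!length(smiles) || !length(motifs)) return(smiles)
  bad <- logical(length(smiles))
  for (p in motifs) bad <- bad | (ob_smarts_count(smiles, p) > 0L)
  smiles[!bad]
}

## ---- decoration ------------------------------------------------------------

#' Default decoration transformations
#'
#' Functional-group decorations applied after heteroatom mutation:
#' carboxylic acids become sulfonic acids, and phenolic (sp2-ring-carbon)
#' hydroxyls become halogens. The SMIRKS strings name the transformations;
#' application is performed by equivalent graph rewrites.
#'
#' @param halogens halogen set for the phenol transform.
#' @return data.frame with columns `name` and `smirks`.
#' @export
decorations_default <- function(halogens = c("F", "Cl", "Br", "I")) {
  rbind(
    data.frame(name = "carboxylic_to_sulfonic",
               smirks = "[CX3:1](=[OX1:2])[OX2H:3]>>[S:1](=[O:2])(=O)[OH:3]",
               stringsAsFactors = FALSE),
    data.frame(name = paste0("phenol_to_", halogens),
               smirks = paste0("[c:1][OX2H]>>[c:1]", halogens),
               stringsAsFactors = FALSE))
}

# find carboxylic-acid carbons: C with =O (terminal O) and -OH
find_carboxyl <- function(m) {
  hits <- integer(0)
  deg <- mol_degree(m)
  for (i in which(m$elem == "C")) {
    dblO <- FALSE;ohO <- FALSE
    rows <- which(m$bond[, "a"] == i | m$bond[, "b"] == i)
    for (r in rows) {
      j <- if (m$bond[r, "a"] == i) m$bond[r, "b"] else m$bond[r, "a"]
      if (m$elem[j] == "O" && deg[j] == 1L) {
        if (m$bond[r, "order"] == 2L) dblO <- TRUE
        else if (m$hyd[j] >= 1L) ohO <- TRUE
      }
    }
    if (dblO && ohO) hits <- c(hits, i)
  }
  hits
}

# find phenolic hydroxyl oxygens: O-H whose single neighbor is a ring carbon
# carrying a double bond inside a ring (sp2 aromatic-type carbon)
find_phenolic_oh <- function(m) {
  deg <- mol_degree(m)
  ringb <- mol_ring_bonds(m)
  hits <- integer(0)
  for (i in which(m$elem == "O" & m$hyd >= 1L & deg == 1L)) {
    r <- which(m$bond[, "a"] == i | m$bond[, "b"] == i)
    if (length(r) != 1L || m$bond[r, "order"] != 1L) next
    j <- if (m$bond[r, "a"] == i) m$bond[r, "b"] else m$bond[r, "a"]
    if (m$elem[j] != "C") next
    rows <- which((m$bond[, "a"] == j | m$bond[, "b"] == j) & ringb &
                    m$bond[, "order"] == 2L)
    if (length(rows)) hits <- c(hits, i)
  }
  hits
}

#' Apply decoration transformations
#'
#' All single-site applications of each transformation in the table
#' (combinatorial over sites); products are canonicalized and deduplicated.
#'
#' @param m a `gs_mol`.
#' @param table decoration table, see [decorations_default()].
#' @param canonical canonicalize and dedupe the products.
#' @return character vector of canonical SMILES.
#' @export
decorate <- function(m, table = decorations_default(), canonical = TRUE) {
  if (is.null(table) || !nrow(table)) return(character())
  known <- decorations_default()
  bad <- setdiff(table$smirks, known$smirks)
  if (length(bad))
    stop("unsupported decoration SMIRKS: ", paste(bad, collapse = ", "))
  out <- vapply(decorate_mols(m, table), smiles_build, character(1))
  if (!canonical) return(out)
  sort(unique(stats::na.omit(smi_canonical(out))))
}

## ---- full enumeration ------------------------------------------------------

#' Exhaustively enumerate chemical space
#'
#' Runs all stages: skeleton graphs, saturation, strain filtering of the
#' 3D-embedded hydrocarbons, unsaturation, heteroatom mutation, forbidden
#' motif filtering, decoration; dedupes globally by canonical SMILES.
#'
#' @param config an [enumeration_config()].
#' @param progress emit per-stage messages.
#' @return list with `molecules` (sorted canonical SMILES), `count_table`
#'   (data.frame n_heavy / count / cumulative), and `manifest` (stage
#'   tallies, discards, config echo).
#' @export
enumerate_space <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "enumeration_config"))
  say <- function(...) if (progress) message(...)
  native <- identical(unname(config$forbidden_motifs),
                      unname(forbidden_motifs_default()))
  graphs <- enumerate_graphs(config$n_max, planar = config$planar)
  say(length(graphs), " skeleton graphs")
  hydro <- lapply(graphs, saturate)
  # 3D embedding only needed where a quaternary center exists
  need3d <- vapply(hydro, function(m) any(mol_degree(m) == 4L), logical(1))
  n_embed_fail <- 0L; n_strained <- 0L
  if (any(need3d)) {
    keep3d <- vapply(which(need3d), function(i) {
      em <- tryCatch(embed_coords(hydro[[i]], seed = config$embed_seed),
                     error = function(e) NULL)
      if (is.null(em) || is.null(em$coords) || anyNA(em$coords)) {
        n_embed_fail <<- n_embed_fail + 1L
        return(FALSE)
      }
      ok <- strain_filter(em, config$strain_volume_threshold)$keep
      if (!ok) n_strained <<- n_strained + 1L
      ok
    }, logical(1))
    drop <- which(need3d)[!keep3d]
    if (length(drop)) hydro <- hydro[-drop]
  }
  say(length(hydro), " hydrocarbons after strain filter (",
      n_strained, " strained, ", n_embed_fail, " embedding failures)")
  # hydrocarbon pool (saturated + orbit-unique unsaturated), as graphs
  pool_mols <- list()
  for (m in hydro) {
    pool_mols[[length(pool_mols) + 1L]] <- m
    om <- unsat_order_matrix(m)
    if (nrow(om))
      pool_mols <- c(pool_mols, unsaturation_variants(m, om))
  }
  n_pool_raw <- length(pool_mols)
  if (native) pool_mols <- Filter(motif_clean_native, pool_mols)
  say(length(pool_mols), " hydrocarbons incl. unsaturated")
  # mutation + decoration, skeleton by skeleton; strings are rendered from
  # templates and only canonicalized once, at the very end
  str_chunks <- list(); nh_chunks <- list()
  dec_chunks <- list()
  n_mutated <- 0L
  for (m in pool_mols) {
    n <- length(m$elem)
    tpl <- smiles_template(m)
    grid <- mutation_grid(m, config$mutation_elements, native_motifs = native)
    elem_mat <- rbind(matrix(m$elem, nrow = 1), grid)
    n_mutated <- n_mutated + nrow(grid)
    order_mat <- matrix(rep(m$bond[, "order"], each = nrow(elem_mat)),
                        nrow = nrow(elem_mat))
    if (!nrow(m$bond))
      order_mat <- matrix(integer(), nrow = nrow(elem_mat), ncol = 0)
    str_chunks[[length(str_chunks) + 1L]] <- template_render(tpl, elem_mat, order_mat)
    nh_chunks[[length(nh_chunks) + 1L]] <- rep.int(n, nrow(elem_mat))
    # decoration, vectorized over the grid: candidate sites depend only on
    # the skeleton topology, the element test is a row filter
    tab <- config$decoration_table
    if (!is.null(tab) && nrow(tab) && nrow(grid) && any(grid == "O")) {
      if ("carboxylic_to_sulfonic" %in% tab$name) {
        carb <- carboxyl_sites_topo(m)
        for (si in seq_len(nrow(carb))) {
          rel <- grid[, carb[si, 1]] == "C" & grid[, carb[si, 2]] == "O" &
            grid[, carb[si, 3]] == "O"
          if (!any(rel)) next
          m_aug <- m
          m_aug$elem <- c(m_aug$elem, "O"); m_aug$hyd <- c(m_aug$hyd, 0L)
          m_aug$bond <- rbind(m_aug$bond, c(carb[si, 1], n + 1L, 2L))
          tpl_aug <- smiles_template(m_aug)
          em <- cbind(grid[rel, , drop = FALSE], "O")
          em[, carb[si, 1]] <- "S"
          om <- matrix(rep(m_aug$bond[, "order"], each = nrow(em)), nrow = nrow(em))
          dec_chunks[[length(dec_chunks) + 1L]] <-
            list(template_render(tpl_aug, em, om), rep.int(n + 1L, nrow(em)))
        }
      }
      halogens <- sub("phenol_to_", "", grep("^phenol_to_", tab$name, value = TRUE))
      if (length(halogens)) {
        phen <- phenolic_sites_topo(m)
        for (si in seq_len(nrow(phen))) {
          rel <- grid[, phen[si, 1]] == "O" & grid[, phen[si, 2]] == "C"
          if (!any(rel)) next
          for (hal in halogens) {
            em <- grid[rel, , drop = FALSE]
            em[, phen[si, 1]] <- hal
            om <- matrix(rep(m$bond[, "order"], each = nrow(em)), nrow = nrow(em))
            dec_chunks[[length(dec_chunks) + 1L]] <-
              list(template_render(tpl, em, om), rep.int(n, nrow(em)))
          }
        }
      }
    }
  }
  raw_str <- unlist(str_chunks, use.names = FALSE)
  raw_nh <- unlist(nh_chunks, use.names = FALSE)
  n_decorated <- 0L
  if (length(dec_chunks)) {
    dstr <- unlist(lapply(dec_chunks, `[[`, 1), use.names = FALSE)
    dnh <- unlist(lapply(dec_chunks, `[[`, 2), use.names = FALSE)
    n_decorated <- length(dstr)
    raw_str <- c(raw_str, dstr)
    raw_nh <- c(raw_nh, dnh)
  }
  say(length(raw_str), " candidate molecules before canonical dedupe")
  can <- smi_canonical(raw_str)
  ok <- !is.na(can) & !duplicated(can) & raw_nh <= config$n_max
  all_smis <- can[ok]; nh <- raw_nh[ok]
  if (!native) {
    keep <- filter_forbidden(all_smis, config$forbidden_motifs)
    sel <- all_smis %in% keep
    all_smis <- all_smis[sel]; nh <- nh[sel]
  }
  ord <- order(nh, all_smis)
  all_smis <- all_smis[ord]; nh <- nh[ord]
  ct <- count_table(nh, config$n_max)
  manifest <- list(
    config = unclass(config),
    stages = list(graphs = length(graphs),
                  hydrocarbons = length(hydro),
                  strained_discarded = n_strained,
                  embedding_failures = n_embed_fail,
                  with_unsaturations = length(pool_mols),
                  unsaturated_motif_discards = n_pool_raw - length(pool_mols),
                  mutated = n_mutated,
                  decorated = n_decorated,
                  candidates = length(raw_str),
                  emitted = length(all_smis)))
  list(molecules = all_smis, count_table = ct, manifest = manifest)
}

# element-independent decoration site candidates on a skeleton:
# carboxyl-type center: atom with a double bond to a degree-1 neighbor and
# a single bond to another degree-1 neighbor -> rows (center, =X, -Y)
carboxyl_sites_topo <- function(m) {
  out <- matrix(integer(), 0, 3)
  deg <- mol_degree(m)
  for (ci in seq_along(m$elem)) {
    rows <- which(m$bond[, "a"] == ci | m$bond[, "b"] == ci)
    nb <- ifelse(m$bond[rows, "a"] == ci, m$bond[rows, "b"], m$bond[rows, "a"])
    xs <- nb[m$bond[rows, "order"] == 2L & deg[nb] == 1L]
    ys <- nb[m$bond[rows, "order"] == 1L & deg[nb] == 1L]
    for (x in xs) for (y in setdiff(ys, x)) out <- rbind(out, c(ci, x, y))
  }
  out
}

# phenol-type site: degree-1 atom single-bonded to a ring atom that
# carries an in-ring double bond -> rows (terminal, ring atom)
phenolic_sites_topo <- function(m) {
  out <- matrix(integer(), 0, 2)
  deg <- mol_degree(m)
  ringb <- mol_ring_bonds(m)
  for (oi in which(deg == 1L)) {
    r <- which(m$bond[, "a"] == oi | m$bond[, "b"] == oi)
    if (m$bond[r, "order"] != 1L) next
    j <- if (m$bond[r, "a"] == oi) m$bond[r, "b"] else m$bond[r, "a"]
    jr <- which((m$bond[, "a"] == j | m$bond[, "b"] == j) & ringb &
                  m$bond[, "order"] == 2L)
    if (length(jr)) out <- rbind(out, c(oi, j))
  }
  out
}

# decoration products as gs_mol objects (all single-site applications)
decorate_mols <- function(m, table) {
  out <- list()
  for (k in seq_len(nrow(table))) {
    nm <- table$name[k]
    if (nm == "carboxylic_to_sulfonic") {
      for (ci in find_carboxyl(m)) {
        m2 <- m
        m2$elem[ci] <- "S"
        m2$elem <- c(m2$elem, "O"); m2$hyd <- c(m2$hyd, 0L)
        m2$bond <- rbind(m2$bond, c(ci, length(m2$elem), 2L))
        out[[length(out) + 1L]] <- mol_fill_h(m2)
      }
    } else if (startsWith(nm, "phenol_to_")) {
      hal <- sub("phenol_to_", "", nm)
      for (oi in find_phenolic_oh(m)) {
        m2 <- m
        m2$elem[oi] <- hal
        m2$hyd[oi] <- 0L
        out[[length(out) + 1L]] <- m2
      }
    }
  }
  out
}

#' Cumulative molecule counts per heavy-atom number
#'
#' @param n_heavy integer vector of per-molecule heavy atom counts.
#' @param n_max table upper limit (defaults to observed maximum).
#' @return data.frame with columns `n_heavy`, `count`, `cumulative`.
#' @export
count_table <- function(n_heavy, n_max = max(n_heavy)) {
  cnt <- tabulate(n_heavy, nbins = n_max)
  data.frame(n_heavy = seq_len(n_max), count = as.integer(cnt),
             cumulative = as.integer(cumsum(cnt)))
}
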