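# Screening-support computations: circular fingerprints, greedy
# docking-rank leader clustering, (constrained) substructure search,
# structural-alert filters, common-core RMSD pose filtering, and
# reaction-based library enumeration from building blocks.

## ---- circular fingerprints -------------------------------------------------

# 31-bit deterministic integer hash of an integer vector
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  as.integer(h)
}

ELEM_CODE <- c(C = 1L, N = 2L, O = 3L, S = 4L, F = 5L, Cl = 6L, Br = 7L,
               I = 8L, P = 9L, B = 10L)

#' Circular (Morgan-type) fingerprint
#'
#' Iterative-neighborhood hashed fingerprint of radius 2 folded to 1024
#' bits: initial atom invariants (element, degree, hydrogens, bond-order
#' sum, ring membership) are refined twice by hashing with the sorted
#' (bond order, neighbor identifier) environment; every identifier at every
#' radius sets one bit. Deterministic for a given canonical SMILES.
#'
#' @param smiles character vector of SMILES.
#' @param nbits fingerprint width.
#' @param radius number of refinement iterations.
#' @return list of sorted integer vectors (set bit positions, 0-based).
#' @export
morgan_fingerprint <- function(smiles, nbits = 1024L, radius = 2L) {
  mols <- mol_from_smiles(smiles)
  lapply(mols, function(m) {
    if (is.null(m)) return(integer(0))
    n <- length(m$elem)
    deg <- mol_degree(m)
    bs <- mol_bondsum(m)
    ring <- mol_ring_atoms(m)
    code <- ELEM_CODE[m$elem]; code[is.na(code)] <- 11L
    ids <- vapply(seq_len(n), function(i)
      hash_ints(c(code[i], deg[i], m$hyd[i], bs[i], as.integer(ring[i]))),
      integer(1))
    all_ids <- ids
    adj <- mol_adjlist(m)
    for (r in seq_len(radius)) {
      new_ids <- ids
      for (i in seq_len(n)) {
        env <- lapply(adj[[i]], function(bi) {
          j <- if (m$bond[bi, "a"] == i) m$bond[bi, "b"] else m$bond[bi, "a"]
          c(m$bond[bi, "order"], ids[j])
        })
        if (length(env)) {
          ord <- order(vapply(env, `[[`, integer(1), 1),
                       vapply(env, `[[`, integer(1), 2))
          new_ids[i] <- hash_ints(c(r, ids[i], unlist(env[ord])))
        }
      }
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
    sort(unique(all_ids %% as.integer(nbits)))
  })
}

#' Tanimoto similarity of two bit sets
#' @param a,b sorted integer vectors of set bits.
#' @return numeric in `[0, 1]` (1 for two empty sets).
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

## ---- leader clustering -----------------------------------------------------

#' Greedy score-ranked leader clustering
#'
#' Molecules are ranked by docking score (lower is better; ties broken by
#' canonical SMILES). The best unassigned molecule founds a cluster and all
#' unassigned molecules with Tanimoto similarity strictly greater than the
#' threshold to the head join it; this repeats until all molecules are
#' assigned, producing a partition.
#'
#' @param ranked data.frame with columns `smiles` and `score`.
#' @param threshold Tanimoto threshold (default 0.5).
#' @param fingerprints optional precomputed list of bit sets aligned with
#'   `ranked` (default: [morgan_fingerprint()] of the SMILES).
#' @return `ranked` with additional columns `cluster` (1-based, in head
#'   score order) and `is_head`, ordered by cluster then score.
#' @export
leader_cluster <- function(ranked, threshold = 0.5, fingerprints = NULL) {
  stopifnot(all(c("smiles", "score") %in% names(ranked)))
  n <- nrow(ranked)
  if (!n) {
    ranked$cluster <- integer(0); ranked$is_head <- logical(0)
    return(ranked)
  }
  if (is.null(fingerprints)) fingerprints <- morgan_fingerprint(ranked$smiles)
  ord <- order(ranked$score, ranked$smiles)
  cluster <- integer(n); cl <- 0L
  for (i in ord) {
    if (cluster[i] > 0L) next
    cl <- cl + 1L
    cluster[i] <- cl
    for (j in ord) {
      if (cluster[j] > 0L) next
      if (tanimoto(fingerprints[[i]], fingerprints[[j]]) > threshold)
        cluster[j] <- cl
    }
  }
  ranked$cluster <- cluster
  heads <- vapply(split(seq_len(n), cluster), function(ix)
    ix[order(ranked$score[ix], ranked$smiles[ix])][1], integer(1))
  ranked$is_head <- seq_len(n) %in% heads
  ranked[order(ranked$cluster, ranked$score, ranked$smiles), , drop = FALSE]
}

## ---- substructure search ---------------------------------------------------

#' SMARTS substructure search over a molecule library
#'
#' @param library character vector of SMILES.
#' @param pattern a SMARTS string (may contain explicit-hydrogen and
#'   degree terms for constrained searches).
#' @return logical vector: does each molecule contain the pattern?
#' @export
substructure_search <- function(library, pattern) {
  if (!ob_smarts_valid(pattern)) stop("invalid SMARTS pattern: ", pattern)
  ob_smarts_count(library, pattern) > 0L
}

#' Build a (constrained) scaffold search pattern
#'
#' Converts a scaffold into a SMARTS pattern matching its superstructures.
#' In constrained mode every atom not listed in `open_atoms` receives
#' explicit hydrogen-count and heavy-degree terms, so growth is only
#' allowed at the open positions; unconstrained patterns allow substitution
#' anywhere.
#'
#' @param scaffold SMILES of the scaffold.
#' @param open_atoms integer indices (in canonical SMILES atom order) where
#'   substitution remains allowed in constrained mode.
#' @param constrained build the constrained variant.
#' @return a SMARTS string.
#' @export
scaffold_pattern <- function(scaffold, open_atoms = integer(0),
                             constrained = FALSE) {
  can <- smi_canonical(scaffold)
  if (is.na(can)) stop("scaffold could not be parsed")
  m <- mol_from_smiles(can)[[1]]
  deg <- mol_degree(m)
  # tokenize the canonical SMILES; atom order equals parse order
  rx <- "\\[[^]]*\\]|Cl|Br|[cnospb]|[CNOSPBFI]"
  starts <- gregexpr(rx, can)[[1]]
  lens <- attr(starts, "match.length")
  out <- character(0)
  pos <- 1L; ai <- 0L
  for (k in seq_along(starts)) {
    if (starts[k] > pos) out <- c(out, substr(can, pos, starts[k] - 1L))
    tok <- substr(can, starts[k], starts[k] + lens[k] - 1L)
    ai <- ai + 1L
    aromatic <- grepl("^\\[?[cnospb]", tok)
    el <- gsub("[^A-Za-z]", "", tok)
    el <- sub("H\\d*$", "", el)
    sym <- if (aromatic) tolower(el) else paste0("#", ELEM_NUM[[toupper_first(el)]])
    base <- if (aromatic) sym else sym
    if (constrained && !(ai %in% open_atoms)) {
      out <- c(out, sprintf("[%s;H%d;D%d]", base, m$hyd[ai], deg[ai]))
    } else {
      out <- c(out, sprintf("[%s]", base))
    }
    pos <- starts[k] + lens[k]
  }
  if (pos <= nchar(can)) out <- c(out, substr(can, pos, nchar(can)))
  paste0(out, collapse = "")
}

ELEM_NUM <- c(C = 6, N = 7, O = 8, S = 16, P = 15, B = 5, F = 9,
              Cl = 17, Br = 35, I = 53)
toupper_first <- function(s)
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))

## ---- structural filters ----------------------------------------------------

# read a SMARTS data file: "name<TAB>smarts", '#' comments
read_smarts_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(vapply(parts, `[[`, character(1), 2),
                  vapply(parts, `[[`, character(1), 1))
}

#' Structural alert filters
#'
#' Flags molecules matching pan-assay interference (PAINS) motifs or the
#' N-acylated six-membered arylamine exclusion. The shipped PAINS list is a
#' representative subset of well-known interference motifs, not the full
#' published catalog, so absolute pass/fail counts depend on the list
#' version recorded in run manifests.
#'
#' @param smiles character vector.
#' @param patterns named SMARTS vector (default: shipped alert lists).
#' @return data.frame with columns `smiles`, `pass`, `reason` (name of the
#'   first matching pattern, or `NA`).
#' @export
structural_filters <- function(smiles, patterns = NULL) {
  if (is.null(patterns)) {
    patterns <- c(
      read_smarts_file(system.file("extdata", "nacyl_arylamine.smarts",
                                   package = "growspace", mustWork = TRUE)),
      read_smarts_file(system.file("extdata", "pains_subset.smarts",
                                   package = "growspace", mustWork = TRUE)))
  }
  reason <- rep(NA_character_, length(smiles))
  for (nm in names(patterns)) {
    todo <- is.na(reason)
    if (!any(todo)) break
    hit <- ob_smarts_count(smiles[todo], patterns[[nm]]) > 0L
    reason[which(todo)[hit]] <- nm
  }
  data.frame(smiles = smiles, pass = is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}

## ---- pose IO and core-RMSD filtering ---------------------------------------

#' Read docked poses from an SDF file
#'
#' @param path SDF file (V2000) with 3D coordinates and a numeric energy
#'   data field.
#' @param energy_tag name of the SDF data field holding the docking energy.
#' @return list of poses: each a list with `mol` (a `gs_mol` with
#'   coordinates), `energy`, and `title`.
#' @export
read_poses <- function(path, energy_tag = "ENERGY") {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  blocks <- sdf_split(txt)
  lapply(blocks, function(bl) {
    m <- parse_molblock(bl, keep_coords = TRUE)
    fx <- grep(sprintf("^>\\s*<%s>", energy_tag), bl)
    en <- if (length(fx)) suppressWarnings(as.numeric(bl[fx[1] + 1L])) else NA_real_
    list(mol = m, energy = en, title = molblock_title(bl))
  })
}

# All subgraph-isomorphism mappings of the core's heavy atoms into the
# pose (element-colored VF2; bond orders deliberately ignored so kekule
# and protonation dialects in pose files do not break the mapping).
core_mappings <- function(core, pose) {
  colorize <- function(m) {
    cc <- ELEM_CODE[m$elem]; cc[is.na(cc)] <- 12L
    as.integer(cc)
  }
  gi <- function(m) {
    g <- igraph::make_empty_graph(length(m$elem), directed = FALSE)
    if (nrow(m$bond)) g <- igraph::add_edges(g, t(m$bond[, 1:2, drop = FALSE]))
    g
  }
  maps <- igraph::subgraph_isomorphisms(gi(core), gi(pose), method = "vf2",
                                        vertex.color1 = colorize(core),
                                        vertex.color2 = colorize(pose))
  lapply(maps, as.integer)
}

#' Common-core RMSD between a pose and a reference
#'
#' Heavy-atom RMSD of the core substructure, computed in the shared
#' (receptor) frame without refitting. Symmetry-equivalent mappings are
#' resolved by taking the minimum RMSD over all core-into-pose subgraph
#' isomorphisms.
#'
#' @param pose a `gs_mol` with coordinates.
#' @param ref reference core pose (`gs_mol` with coordinates).
#' @return RMSD in angstroms.
#' @export
core_rmsd <- function(pose, ref) {
  if (is.null(pose$coords) || is.null(ref$coords))
    stop("both structures need 3D coordinates")
  maps <- core_mappings(ref, pose)
  if (!length(maps)) stop("pose does not contain the reference core")
  min(vapply(maps, function(mp) {
    d <- pose$coords[mp, , drop = FALSE] - ref$coords
    sqrt(mean(rowSums(d * d)))
  }, numeric(1)))
}

#' Select the binding-mode-preserving pose
#'
#' Among the `top_k` lowest-energy poses, returns the lowest-energy one
#' whose common-core heavy-atom RMSD to the reference is below the
#' threshold; `NULL` if none qualifies.
#'
#' @param poses list of poses from [read_poses()].
#' @param ref reference core (`gs_mol` with coordinates).
#' @param threshold RMSD cutoff in angstroms (default 2).
#' @param top_k energy window (default 50 poses).
#' @return the selected pose augmented with `rmsd`, or `NULL`.
#' @export
core_rmsd_filter <- function(poses, ref, threshold = 2.0, top_k = 50L) {
  if (!length(poses)) return(NULL)
  en <- vapply(poses, `[[`, numeric(1), "energy")
  if (anyNA(en)) stop("all poses need a numeric energy")
  ord <- order(en)[seq_len(min(top_k, length(poses)))]
  for (i in ord) {
    r <- core_rmsd(poses[[i]]$mol, ref)
    if (r < threshold) {
      out <- poses[[i]]
      out$rmsd <- r
      out$rank <- match(i, ord)
      return(out)
    }
  }
  NULL
}

#' Write molecules with coordinates to an SDF file
#'
#' Minimal V2000 writer for fixtures and pose sets.
#'
#' @param mols list of `gs_mol` (coordinates optional; zeros written if
#'   absent).
#' @param path output path.
#' @param fields optional list (one element per molecule) of named data
#'   fields.
#' @param titles optional character vector of molecule titles.
#' @export
write_sdf <- function(mols, path, fields = NULL, titles = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    xyz <- if (is.null(m$coords)) matrix(0, length(m$elem), 3) else m$coords
    lines <- c(if (is.null(titles)) sprintf("mol%d", k) else titles[k],
               "  growspace", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       length(m$elem), nrow(m$bond)))
    for (i in seq_along(m$elem))
      lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                                xyz[i, 1], xyz[i, 2], xyz[i, 3], m$elem[i]))
    for (i in seq_len(nrow(m$bond)))
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                m$bond[i, "a"], m$bond[i, "b"], m$bond[i, "order"]))
    lines <- c(lines, "M  END")
    if (!is.null(fields) && length(fields) >= k && length(fields[[k]])) {
      for (nm in names(fields[[k]]))
        lines <- c(lines, sprintf(">  <%s>", nm), as.character(fields[[k]][[nm]]), "")
    }
    lines <- c(lines, "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}

## ---- reaction-based enumeration --------------------------------------------

#' Shipped coupling reactions
#'
#' The reaction templates used for building-block library enumeration,
#' keyed by their SMIRKS strings (see
#' `inst/extdata/reaction_smirks.txt`). Application is performed by graph
#' rewrites equivalent to the SMIRKS.
#' @return data.frame with columns `name` and `smirks`.
#' @export
reactions_default <- function() {
  path <- system.file("extdata", "reaction_smirks.txt",
                      package = "growspace", mustWork = TRUE)
  sm <- read_smarts_file(path)
  data.frame(name = names(sm), smirks = unname(sm), stringsAsFactors = FALSE)
}

# functional group finders (atom indices)
fg_carboxyl <- function(m) find_carboxyl(m)
fg_amine <- function(m) {
  # N-H not already acylated
  out <- integer(0)
  for (i in which(m$elem == "N" & m$hyd >= 1L)) {
    rows <- which(m$bond[, "a"] == i | m$bond[, "b"] == i)
    nb <- ifelse(m$bond[rows, "a"] == i, m$bond[rows, "b"], m$bond[rows, "a"])
    acyl <- any(vapply(nb, function(j) {
      jr <- which(m$bond[, "a"] == j | m$bond[, "b"] == j)
      m$elem[j] == "C" &&
        any(m$bond[jr, "order"] == 2L &
              m$elem[ifelse(m$bond[jr, "a"] == j, m$bond[jr, "b"], m$bond[jr, "a"])] == "O")
    }, logical(1)))
    if (!acyl) out <- c(out, i)
  }
  out
}
is_sp2_ring_c <- function(m, i) {
  rows <- which(m$bond[, "a"] == i | m$bond[, "b"] == i)
  m$elem[i] == "C" && mol_ring_atoms(m)[i] &&
    any(m$bond[rows, "order"] == 2L & mol_ring_bonds(m)[rows])
}
fg_aryl_halide <- function(m) {
  # returns matrix (halogen atom, aryl carbon)
  out <- NULL
  for (i in which(m$elem %in% c("Cl", "Br", "I"))) {
    r <- which(m$bond[, "a"] == i | m$bond[, "b"] == i)
    if (length(r) != 1L) next
    j <- if (m$bond[r, "a"] == i) m$bond[r, "b"] else m$bond[r, "a"]
    if (is_sp2_ring_c(m, j)) out <- rbind(out, c(i, j))
  }
  out
}
fg_boronic <- function(m) {
  # returns matrix (B atom, aryl carbon, O1, O2)
  out <- NULL
  for (b in which(m$elem == "B")) {
    rows <- which(m$bond[, "a"] == b | m$bond[, "b"] == b)
    nb <- ifelse(m$bond[rows, "a"] == b, m$bond[rows, "b"], m$bond[rows, "a"])
    os <- nb[m$elem[nb] == "O" & m$hyd[nb] >= 1L]
    cs <- nb[m$elem[nb] == "C"]
    if (length(os) == 2L && length(cs) == 1L && is_sp2_ring_c(m, cs))
      out <- rbind(out, c(b, cs, os))
  }
  out
}
fg_hydroxyl <- function(m) {
  deg <- mol_degree(m)
  which(m$elem == "O" & m$hyd >= 1L & deg == 1L)
}

# splice mol b after mol a; returns list(m, offset)
splice_mols <- function(a, b) {
  off <- length(a$elem)
  bb <- b$bond
  if (nrow(bb)) { bb[, "a"] <- bb[, "a"] + off; bb[, "b"] <- bb[, "b"] + off }
  list(m = gs_mol(c(a$elem, b$elem), c(a$hyd, b$hyd), rbind(a$bond, bb)),
       offset = off)
}

# couple two molecules: drop atoms `drop`, add bond (i, j, 1)
couple <- function(a, b, i_a, j_b, drop_a = integer(0), drop_b = integer(0)) {
  sp <- splice_mols(a, b)
  m <- sp$m
  m$bond <- rbind(m$bond, c(i_a, j_b + sp$offset, 1L))
  keep <- setdiff(seq_along(m$elem), c(drop_a, drop_b + sp$offset))
  mol_fill_h(subset_atoms(m, keep))
}

# apply one named reaction to an ordered reactant pair; list of product mols
apply_reaction <- function(name, r1, r2) {
  out <- list()
  if (name == "amide_coupling") {
    for (ci in fg_carboxyl(r1)) {
      # drop the acid OH oxygen
      rows <- which(r1$bond[, "a"] == ci | r1$bond[, "b"] == ci)
      nb <- ifelse(r1$bond[rows, "a"] == ci, r1$bond[rows, "b"], r1$bond[rows, "a"])
      oh <- nb[r1$elem[nb] == "O" & r1$hyd[nb] >= 1L &
                 r1$bond[rows, "order"] == 1L][1]
      for (ni in fg_amine(r2))
        out <- c(out, list(couple(r1, r2, ci, ni, drop_a = oh)))
    }
  } else if (name == "suzuki_coupling") {
    ah <- fg_aryl_halide(r1); bo <- fg_boronic(r2)
    if (!is.null(ah) && !is.null(bo))
      for (i in seq_len(nrow(ah))) for (j in seq_len(nrow(bo)))
        out <- c(out, list(couple(r1, r2, ah[i, 2], bo[j, 2],
                                  drop_a = ah[i, 1], drop_b = bo[j, c(1, 3, 4)])))
  } else if (name == "chan_lam_amination") {
    bo <- fg_boronic(r1)
    if (!is.null(bo))
      for (j in seq_len(nrow(bo))) for (ni in fg_amine(r2))
        out <- c(out, list(couple(r1, r2, bo[j, 2], ni,
                                  drop_a = bo[j, c(1, 3, 4)])))
  } else if (name == "ullmann_ether") {
    ah <- fg_aryl_halide(r1)
    if (!is.null(ah))
      for (i in seq_len(nrow(ah))) for (oi in fg_hydroxyl(r2))
        out <- c(out, list(couple(r1, r2, ah[i, 2], oi, drop_a = ah[i, 1])))
  } else stop("unknown reaction: ", name)
  out
}

#' Enumerate a reaction-based virtual library
#'
#' Couples building blocks to a parent scaffold in silico with the given
#' reactions (tried in both reactant orientations); products are
#' canonicalized and deduplicated. Blocks with no compatible functional
#' group are skipped and reported.
#'
#' @param blocks character vector of building-block SMILES.
#' @param reactions character vector of reaction SMIRKS from
#'   [reactions_default()] (or their names). Unknown SMIRKS raise a
#'   configuration error.
#' @param parent parent scaffold SMILES.
#' @return character vector of canonical product SMILES; attribute
#'   `skipped_blocks` lists blocks that never reacted.
#' @export
react_enumerate <- function(blocks, reactions, parent) {
  reg <- reactions_default()
  names_resolved <- vapply(reactions, function(r) {
    if (r %in% reg$name) return(r)
    i <- match(r, reg$smirks)
    if (is.na(i)) stop("unknown or malformed reaction SMIRKS: ", r)
    reg$name[i]
  }, character(1))
  pm <- mol_from_smiles(parent)[[1]]
  if (is.null(pm)) stop("parent could not be parsed")
  bmols <- mol_from_smiles(blocks)
  prods <- character(0)
  reacted <- logical(length(blocks))
  for (k in seq_along(bmols)) {
    bm <- bmols[[k]]
    if (is.null(bm)) next
    for (nm in names_resolved) {
      for (pair in list(list(pm, bm), list(bm, pm))) {
        ps <- apply_reaction(nm, pair[[1]], pair[[2]])
        if (length(ps)) {
          reacted[k] <- TRUE
          prods <- c(prods, vapply(ps, smiles_build, character(1)))
        }
      }
    }
  }
  out <- sort(unique(stats::na.omit(smi_canonical(prods))))
  attr(out, "skipped_blocks") <- unique(blocks[!reacted])
  out
}
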