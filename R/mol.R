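# Internal molecular-graph representation.
#
# A `gs_mol` is a Kekule-form heavy-atom graph:
#   elem   character vector of element symbols (heavy atoms only)
#   hyd    integer vector, hydrogens on each heavy atom
#   bond   integer matrix with columns a, b, order (1, 2, 3); 0 rows allowed
#   coords optional n x 3 matrix of 3D coordinates
# Aromatic systems are stored kekulized; aromaticity is perceived only at
# canonicalization time (OpenBabel), which is also where duplicates collapse.

STD_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
                 F = 1L, Cl = 1L, Br = 1L, I = 1L, B = 3L)

# Activation tag elements, one per connection mechanism.
TAG_ELEMENTS <- c(single = "Lu", double = "Hf", triple = "Ta",
                  fusion = "W", spiro = "Re")
MECHANISMS <- names(TAG_ELEMENTS)

gs_mol <- function(elem, hyd, bond, coords = NULL) {
  bond <- matrix(as.integer(bond), ncol = 3,
                 dimnames = list(NULL, c("a", "b", "order")))
  structure(list(elem = as.character(elem), hyd = as.integer(hyd),
                 bond = bond, coords = coords), class = "gs_mol")
}

#' @export
print.gs_mol <- function(x, ...) {
  cat("<gs_mol> ", length(x$elem), " heavy atoms, ",
      nrow(x$bond), " bonds: ", mol_to_smiles(x), "\n", sep = "")
  invisible(x)
}

mol_n_heavy <- function(m) sum(!(m$elem %in% TAG_ELEMENTS))

# per-atom sum of bond orders
mol_bondsum <- function(m) {
  bs <- integer(length(m$elem))
  if (nrow(m$bond)) {
    for (i in seq_len(nrow(m$bond))) {
      o <- m$bond[i, "order"]
      bs[m$bond[i, "a"]] <- bs[m$bond[i, "a"]] + o
      bs[m$bond[i, "b"]] <- bs[m$bond[i, "b"]] + o
    }
  }
  bs
}

# Implicit hydrogen count for an element carrying a given bond-order sum.
# S and P step up to their higher valence states (2/4/6 and 3/5) when the
# bond sum requires it; tag metals and unknown elements get no hydrogens.
implicit_h <- function(elem, bondsum) {
  v <- STD_VALENCE[elem]
  v[is.na(v)] <- 0L
  v <- as.integer(v)
  bondsum <- as.integer(bondsum)
  s <- elem == "S" & bondsum > 2L
  v[s] <- ifelse(bondsum[s] <= 4L, 4L, 6L)
  p <- elem == "P" & bondsum > 3L
  v[p] <- 5L
  pmax(0L, v - bondsum)
}

# Recompute implicit hydrogens from the valence model.
mol_fill_h <- function(m) {
  m$hyd <- implicit_h(m$elem, mol_bondsum(m))
  m
}

mol_adjlist <- function(m) {
  n <- length(m$elem)
  adj <- vector("list", n)
  if (nrow(m$bond)) for (i in seq_len(nrow(m$bond))) {
    a <- m$bond[i, "a"]; b <- m$bond[i, "b"]
    adj[[a]] <- c(adj[[a]], i); adj[[b]] <- c(adj[[b]], i)
  }
  adj
}

mol_degree <- function(m) {
  d <- integer(length(m$elem))
  if (nrow(m$bond)) {
    t1 <- tabulate(m$bond[, "a"], nbins = length(d))
    t2 <- tabulate(m$bond[, "b"], nbins = length(d))
    d <- t1 + t2
  }
  d
}

# Ring-membership flags for atoms and bonds (bond is in a ring iff removing
# it leaves its endpoints connected).
mol_ring_bonds <- function(m) {
  nb <- nrow(m$bond)
  if (!nb) return(logical(0))
  g <- igraph::graph_from_edgelist(m$bond[, 1:2, drop = FALSE], directed = FALSE)
  if (igraph::vcount(g) < length(m$elem))
    g <- igraph::add_vertices(g, length(m$elem) - igraph::vcount(g))
  bridges <- igraph::bridges(g)
  res <- rep(TRUE, nb)
  res[as.integer(bridges)] <- FALSE
  res
}

mol_ring_atoms <- function(m) {
  ra <- logical(length(m$elem))
  rb <- mol_ring_bonds(m)
  if (any(rb)) {
    idx <- which(rb)
    ra[unique(as.vector(m$bond[idx, 1:2]))] <- TRUE
  }
  ra
}

#' Element histogram of a molecule
#'
#' @param smiles character vector of SMILES.
#' @return integer matrix, one row per molecule, columns C, N, O, S, F, Cl,
#'   Br, I.
#' @export
element_histogram <- function(smiles) {
  mols <- mol_from_smiles(smiles)
  els <- c("C", "N", "O", "S", "F", "Cl", "Br", "I")
  out <- matrix(0L, nrow = length(smiles), ncol = length(els),
                dimnames = list(NULL, els))
  for (i in seq_along(mols)) {
    m <- mols[[i]]
    if (is.null(m)) next
    tb <- table(m$elem)
    keep <- intersect(names(tb), els)
    out[i, keep] <- as.integer(tb[keep])
  }
  out
}

#' Molecule records
#'
#' Builds the canonical structure record for a set of molecules: canonical
#' SMILES, heavy atom count and element histogram. Stereochemistry is not
#' represented (inputs are stripped by canonicalization without stereo
#' perception on the heavy-atom graph).
#'
#' @param smiles character vector of SMILES.
#' @return data.frame with columns `smiles` (canonical), `n_heavy`, and one
#'   column per element C, N, O, S, F, Cl, Br, I.
#' @export
molecule_table <- function(smiles) {
  can <- smi_canonical(smiles)
  keep <- !is.na(can)
  hist <- element_histogram(can[keep])
  df <- data.frame(smiles = can[keep],
                   n_heavy = as.integer(rowSums(hist)),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(hist))
}

## ---- SDF (V2000) parsing ---------------------------------------------------

# Split multi-molecule SDF text into V2000 blocks.
sdf_split <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ends <- which(lines == "$$$$")
  if (!length(ends)) return(list())
  starts <- c(1L, head(ends, -1L) + 1L)
  mapply(function(s, e) lines[s:(e - 1L)], starts, ends, SIMPLIFY = FALSE)
}

# Parse one V2000 block (explicit hydrogens expected) into a gs_mol with
# hydrogens folded into `hyd`. Returns NULL on malformed blocks.
parse_molblock <- function(lines, keep_coords = FALSE) {
  if (length(lines) < 4L) return(NULL)
  counts <- lines[4L]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || length(lines) < 4L + na + nb) return(NULL)
  at <- lines[4L + seq_len(na)]
  elem <- trimws(substr(at, 32, 34))
  xyz <- NULL
  if (keep_coords) {
    xyz <- cbind(as.numeric(substr(at, 1, 10)),
                 as.numeric(substr(at, 11, 20)),
                 as.numeric(substr(at, 21, 30)))
  }
  if (nb > 0L) {
    bl <- lines[4L + na + seq_len(nb)]
    bm <- cbind(as.integer(substr(bl, 1, 3)),
                as.integer(substr(bl, 4, 6)),
                as.integer(substr(bl, 7, 9)))
  } else bm <- matrix(integer(), ncol = 3)
  heavy <- elem != "H"
  newidx <- cumsum(heavy)
  hyd <- integer(sum(heavy))
  keep <- logical(nrow(bm))
  for (i in seq_len(nrow(bm))) {
    a <- bm[i, 1]; b <- bm[i, 2]
    if (heavy[a] && heavy[b]) keep[i] <- TRUE
    else if (heavy[a] && !heavy[b]) hyd[newidx[a]] <- hyd[newidx[a]] + 1L
    else if (!heavy[a] && heavy[b]) hyd[newidx[b]] <- hyd[newidx[b]] + 1L
  }
  bm <- bm[keep, , drop = FALSE]
  if (nrow(bm)) {
    bm[, 1] <- newidx[bm[, 1]]; bm[, 2] <- newidx[bm[, 2]]
    bm[, 3] <- pmin(pmax(bm[, 3], 1L), 3L)  # aromatic (4) never emitted by OB
  }
  gs_mol(elem[heavy], hyd, bm,
         coords = if (keep_coords) xyz[heavy, , drop = FALSE] else NULL)
}

# sdf block title (line 1); used to realign batched conversions
molblock_title <- function(lines) trimws(lines[1L])

#' Parse SMILES into internal molecular graphs
#'
#' Batched conversion through OpenBabel (kekulized, hydrogens counted).
#' Unparseable entries yield `NULL`.
#'
#' @param smiles character vector.
#' @param gen3d if `TRUE`, also generate one deterministic 3D conformer per
#'   molecule with the distance-geometry embedder ([embed_coords()]).
#' @param embed_seed seed for the embedder's symmetry-breaking jitter.
#' @return list of `gs_mol` (or `NULL`) of the same length as `smiles`.
#' @export
mol_from_smiles <- function(smiles, gen3d = FALSE, embed_seed = 1L) {
  n <- length(smiles)
  res <- vector("list", n)
  if (!n) return(res)
  todo <- seq_len(n)
  repeat {
    txt <- ob_sdf(smiles[todo])
    got <- logical(length(todo))
    for (bl in sdf_split(txt)) {
      id <- suppressWarnings(as.integer(molblock_title(bl)))
      if (is.na(id)) next
      res[[todo[id]]] <- parse_molblock(bl)
      got[id] <- TRUE
    }
    miss <- todo[!got]
    if (!length(miss)) break
    todo <- miss[-1L]  # fatal errors abort the stream; skip and retry rest
    if (!length(todo)) break
  }
  if (gen3d)
    res <- lapply(res, function(m)
      if (is.null(m)) m else embed_coords(m, seed = embed_seed))
  res
}

## ---- SMILES writing --------------------------------------------------------

# Emit a SMILES for a connected gs_mol. All atoms are written in brackets
# with explicit hydrogen counts derived from standard valences, so no
# implicit-valence model is involved. Rendering goes through the slot
# template machinery (see smiles_template) used by the enumeration stages.
smiles_build <- function(m) {
  tpl <- smiles_template(m)
  elem_mat <- matrix(m$elem, nrow = 1)
  order_mat <- matrix(m$bond[, "order"], nrow = 1)
  if (!nrow(m$bond)) order_mat <- matrix(integer(), nrow = 1, ncol = 0)
  template_render(tpl, elem_mat, order_mat)
}

#' Write SMILES for an internal molecular graph
#' @param m a `gs_mol`.
#' @param canonical canonicalize through OpenBabel.
#' @return SMILES string.
#' @export
mol_to_smiles <- function(m, canonical = FALSE) {
  s <- smiles_build(m)
  if (canonical) smi_canonical(s) else s
}
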