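# Superstructure generation: distribute added heavy atoms over a scaffold
# configuration's tagged sites and attach compatible shelf substituents.

#' Compositions of added heavy atoms over tagged sites
#'
#' All ordered compositions of `n_added` into `k_sites` positive parts
#' (every tagged site must receive at least one heavy atom; a site meant to
#' receive none belongs to a different configuration). There are
#' `choose(n_added - 1, k_sites - 1)` of them.
#'
#' @param n_added total heavy atoms to add (>= 0).
#' @param k_sites number of tagged sites (>= 1).
#' @return list of integer vectors (possibly empty).
#' @export
distribute_atoms <- function(n_added, k_sites) {
  stopifnot(n_added >= 0, k_sites >= 1)
  n_added <- as.integer(n_added); k_sites <- as.integer(k_sites)
  if (n_added < k_sites) return(list())
  if (k_sites == 1L) return(list(n_added))
  out <- list()
  rec <- function(prefix, rest, slots) {
    if (slots == 1L) {
      out[[length(out) + 1L]] <<- c(prefix, rest)
      return(invisible())
    }
    for (v in seq_len(rest - slots + 1L)) rec(c(prefix, v), rest - v, slots - 1L)
  }
  rec(integer(0), n_added, k_sites)
  out
}

## ---- tagged-structure slot extraction --------------------------------------

# Identify attachment slots in a tagged structure: one slot per tag atom.
# Returns list of slots: (mechanism, tag_atom, attach_atoms, chemotype).
# Chemotype is classified on the de-tagged parent structure.
tag_slots <- function(m) {
  parent_idx <- which(!(m$elem %in% TAG_ELEMENTS))
  parent <- mol_fill_h(subset_atoms(m, parent_idx))
  to_parent <- match(seq_along(m$elem), parent_idx)
  slots <- list()
  for (ti in which(m$elem %in% TAG_ELEMENTS)) {
    mech <- names(TAG_ELEMENTS)[match(m$elem[ti], TAG_ELEMENTS)]
    rows <- which(m$bond[, "a"] == ti | m$bond[, "b"] == ti)
    nb <- ifelse(m$bond[rows, "a"] == ti, m$bond[rows, "b"], m$bond[rows, "a"])
    ct <- if (mech == "fusion") "ring_bond_CHCH"
      else site_chemotype(parent, atom = to_parent[nb[1]])
    slots[[length(slots) + 1L]] <-
      list(mechanism = mech, tag_atom = ti, attach_atoms = nb, chemotype = ct)
  }
  slots
}

# Graft one activated substituent onto one slot of a tagged structure.
# Returns a list of resulting gs_mol (fusion can have two orientations;
# incompatible merges give an empty list). Remaining tags stay in place.
attach_substituent <- function(m, slot, sub) {
  stopifnot(inherits(sub, "gs_mol"))
  sub_slots <- tag_slots(sub)
  sub_slot <- NULL
  for (s in sub_slots) if (s$mechanism == slot$mechanism) sub_slot <- s
  if (is.null(sub_slot)) return(list())
  # splice substituent atoms into m (tags still present, removed below)
  off <- length(m$elem)
  comb <- m
  comb$elem <- c(comb$elem, sub$elem)
  comb$hyd <- c(comb$hyd, sub$hyd)
  sb <- sub$bond
  if (nrow(sb)) { sb[, "a"] <- sb[, "a"] + off; sb[, "b"] <- sb[, "b"] + off }
  comb$bond <- rbind(comb$bond, sb)
  comb$coords <- NULL
  t_sc <- slot$tag_atom
  t_sub <- sub_slot$tag_atom + off
  a_sc <- slot$attach_atoms
  a_sub <- sub_slot$attach_atoms + off
  mech <- slot$mechanism
  drop_and_fill <- function(mm, drop) mol_fill_h(subset_atoms(mm, setdiff(seq_along(mm$elem), drop)))
  if (mech %in% c("single", "double", "triple")) {
    order <- c(single = 1L, double = 2L, triple = 3L)[[mech]]
    comb$bond <- rbind(comb$bond, c(a_sc[1], a_sub[1], order))
    return(list(drop_and_fill(comb, c(t_sc, t_sub))))
  }
  if (mech == "spiro") {
    if (comb$elem[a_sc[1]] != comb$elem[a_sub[1]]) return(list())
    merged <- rewire_atom(comb, a_sub[1], a_sc[1])
    return(list(drop_and_fill(merged, c(t_sc, t_sub, a_sub[1]))))
  }
  # fusion: merge the two bond atoms pairwise, both orientations
  res <- list()
  for (orient in list(c(1L, 2L), c(2L, 1L))) {
    p <- a_sc; q <- a_sub[orient]
    if (comb$elem[p[1]] != comb$elem[q[1]] ||
        comb$elem[p[2]] != comb$elem[q[2]]) next
    m1 <- rewire_atom(comb, q[1], p[1])
    m1 <- rewire_atom(m1, q[2], p[2])
    res[[length(res) + 1L]] <- drop_and_fill(m1, c(t_sc, t_sub, q))
  }
  res
}

# redirect all bonds of atom j to atom i (self loops and duplicate bonds
# dropped); j is left in place, isolated, so indices stay stable until the
# caller removes dead atoms in one pass.
rewire_atom <- function(m, j, i) {
  b <- m$bond
  b[b[, "a"] == j, "a"] <- i
  b[b[, "b"] == j, "b"] <- i
  b <- b[b[, "a"] != b[, "b"], , drop = FALSE]
  key <- paste(pmin(b[, "a"], b[, "b"]), pmax(b[, "a"], b[, "b"]))
  b <- b[!duplicated(key), , drop = FALSE]
  m$bond <- b
  m
}

#' Grow substituents onto an activated scaffold configuration
#'
#' Attaches one compatible activated substituent of the prescribed size to
#' each tagged site (Cartesian over sites), eliminates the tags, applies
#' the forbidden-motif filter and dedupes canonically.
#'
#' @param config a tagged scaffold SMILES (a `config_key` from
#'   [activate_scaffold()]).
#' @param composition integer vector of heavy atoms per site; its length
#'   must equal the number of tags in `config`.
#' @param shelves a `substituent_shelves`.
#' @param forbidden_motifs SMARTS filter for products.
#' @param max_products guard for the Cartesian product.
#' @return character vector of canonical product SMILES.
#' @export
grow <- function(config, composition, shelves,
                 forbidden_motifs = forbidden_motifs_default(),
                 max_products = 200000L) {
  m <- if (is.character(config)) mol_from_smiles(config)[[1]] else config
  if (is.null(m)) stop("config could not be parsed")
  slots <- tag_slots(m)
  if (length(slots) != length(composition))
    stop("composition length ", length(composition),
         " does not match ", length(slots), " tagged sites")
  # a fused substituent shares two atoms with the scaffold and a spiro one
  # shares one, so the substituent serving `part` added atoms is larger
  shared <- c(single = 0L, double = 0L, triple = 0L, fusion = 2L, spiro = 1L)
  options_per_slot <- vector("list", length(slots))
  for (k in seq_along(slots)) {
    mech_k <- slots[[k]]$mechanism
    cand <- shelf_get(shelves, composition[k] + shared[[mech_k]], mech_k,
                      slots[[k]]$chemotype)
    if (!length(cand)) return(character())  # empty compatible shelf
    options_per_slot[[k]] <- cand
  }
  if (prod(lengths(options_per_slot)) > max_products)
    stop("more than ", max_products, " candidate products; raise `max_products`")
  subs_cache <- new.env(parent = emptyenv())
  get_sub <- function(s) {
    if (!exists(s, envir = subs_cache, inherits = FALSE))
      assign(s, mol_from_smiles(s)[[1]], envir = subs_cache)
    get(s, envir = subs_cache, inherits = FALSE)
  }
  partials <- list(m)
  for (k in seq_along(slots)) {
    nxt <- list()
    for (p in partials) {
      # slot tag atoms move as atoms are spliced/removed; re-derive slots on
      # the current partial and take the first remaining slot
      pslots <- tag_slots(p)
      if (!length(pslots)) next
      sl <- pslots[[1L]]
      for (s in options_per_slot[[k]]) {
        sub <- get_sub(s)
        if (is.null(sub)) next
        nxt <- c(nxt, attach_substituent(p, sl, sub))
      }
    }
    partials <- nxt
  }
  if (!length(partials)) return(character())
  smis <- vapply(partials, smiles_build, character(1))
  out <- sort(unique(stats::na.omit(smi_canonical(smis))))
  filter_forbidden(out, forbidden_motifs)
}

#' Generate all superstructures of a scaffold
#'
#' Full growth pipeline: enumerate activated scaffold configurations,
#' distribute 1..`max_added` heavy atoms over each configuration's tagged
#' sites, attach compatible shelf substituents, and count unique
#' superstructures per number of added heavy atoms.
#'
#' @param scaffold SMILES or `gs_mol`.
#' @param max_added maximum number of added heavy atoms (>= 1).
#' @param shelves a `substituent_shelves`.
#' @param mechanisms mechanism set.
#' @param allowed_vectors optional atom mask, see [activate_scaffold()].
#' @param forbidden_motifs product filter.
#' @return list with `molecules` (per added-atom list of canonical SMILES)
#'   and `count_table` (data.frame n_added / count / cumulative).
#' @export
generate_superstructures <- function(scaffold, max_added, shelves,
                                     mechanisms = MECHANISMS,
                                     allowed_vectors = NULL,
                                     forbidden_motifs = forbidden_motifs_default()) {
  stopifnot(max_added >= 1)
  configs <- activate_scaffold(scaffold, mechanisms, allowed_vectors)
  per_n <- rep(list(character(0)), max_added)
  for (i in seq_len(nrow(configs))) {
    key <- configs$config_key[i]
    k <- configs$n_tags[i]
    if (k > max_added) next
    for (n_add in k:max_added) {
      for (comp in distribute_atoms(n_add, k)) {
        prods <- grow(key, comp, shelves, forbidden_motifs)
        per_n[[n_add]] <- c(per_n[[n_add]], prods)
      }
    }
  }
  per_n <- lapply(per_n, function(x) sort(unique(x)))
  cnt <- lengths(per_n)
  list(molecules = per_n,
       count_table = data.frame(n_added = seq_len(max_added),
                                count = as.integer(cnt),
                                cumulative = as.integer(cumsum(cnt))))
}
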