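# Activation of substituents: attaching a growing-vector tag that records
# how a fragment connects to a scaffold. Five connection mechanisms are
# supported, each represented by a rare transition metal never produced by
# the enumeration stages:
#   single bond  Lu   (1 H consumed)
#   double bond  Hf   (2 H)
#   triple bond  Ta   (3 H, terminal atoms only)
#   ring fusion  W    (bridges a ring bond; 1 H from each bond atom)
#   spiro        Re   (double-bonded to a ring CH2-type atom; 2 H)
# The W tag bridges both atoms of the fused bond (a single tag atom bonded
# to both), which makes reconstruction at attachment time unambiguous even
# when adjacent bonds are fused.

#' Connection-site chemotypes
#'
#' Classifies the local chemical environment of a connection site. The
#' vocabulary drives shelf keys and compatibility rules: like-with-like
#' attachments of amine nitrogens or hydroxyl oxygens are forbidden because
#' they would create hydrazines / peroxides.
#'
#' @param m a `gs_mol`.
#' @param atom atom index (for atom sites).
#' @param bond bond row index (for fusion sites).
#' @return a chemotype label.
#' @export
site_chemotype <- function(m, atom = NULL, bond = NULL) {
  if (!is.null(bond)) return("ring_bond_CHCH")
  el <- m$elem[atom]
  if (el == "O") return("hydroxyl_O")
  if (el == "N") return("amine_N")
  if (el == "S") return("thiol_S")
  if (el != "C") return("other")
  ringa <- mol_ring_atoms(m)
  rows <- which(m$bond[, "a"] == atom | m$bond[, "b"] == atom)
  sp2ring <- ringa[atom] && any(m$bond[rows, "order"] == 2L & mol_ring_bonds(m)[rows])
  if (sp2ring) return("aromatic_CH")
  if (ringa[atom] && m$hyd[atom] >= 2L) return("ring_CH2")
  "aliphatic_CH"
}

# hydrogen cost per tag
mechanism_h_cost <- c(single = 1L, double = 2L, triple = 3L,
                      fusion = 1L, spiro = 2L)  # fusion: 1 H per bond atom

# raw viable sites for one mechanism: list of site records
raw_sites <- function(m, mechanism) {
  sites <- list()
  has_multiple <- function(i) {
    rows <- which(m$bond[, "a"] == i | m$bond[, "b"] == i)
    any(m$bond[rows, "order"] >= 2L)
  }
  if (mechanism %in% c("single", "double", "triple", "spiro")) {
    ringa <- if (mechanism == "spiro") mol_ring_atoms(m) else NULL
    deg <- mol_degree(m)
    for (i in seq_along(m$elem)) {
      if (m$elem[i] %in% TAG_ELEMENTS) next
      ok <- switch(mechanism,
        single = m$hyd[i] >= 1L,
        # a double-bond vector on an atom already in a multiple bond would
        # create a cumulated (allene-type) system
        double = m$hyd[i] >= 2L && !has_multiple(i),
        triple = m$hyd[i] >= 3L && deg[i] <= 1L,
        spiro  = m$hyd[i] >= 2L && ringa[i] && !has_multiple(i))
      if (ok)
        sites[[length(sites) + 1L]] <-
          list(mechanism = mechanism, atom = i,
               chemotype = site_chemotype(m, atom = i))
    }
  } else if (mechanism == "fusion") {
    rb <- mol_ring_bonds(m)
    for (r in which(rb)) {
      a <- m$bond[r, "a"]; b <- m$bond[r, "b"]
      if (m$bond[r, "order"] != 1L) next
      if (m$hyd[a] >= 1L && m$hyd[b] >= 1L &&
          !(m$elem[a] %in% TAG_ELEMENTS) && !(m$elem[b] %in% TAG_ELEMENTS))
        sites[[length(sites) + 1L]] <-
          list(mechanism = "fusion", bond = r,
               chemotype = site_chemotype(m, bond = r))
    }
  } else stop("unknown mechanism: ", mechanism)
  sites
}

# Attach one tag for `site` to a copy of m. Errors if hydrogens are missing.
attach_tag <- function(m, site) {
  mech <- site$mechanism
  tag <- TAG_ELEMENTS[[mech]]
  if (mech == "fusion") {
    r <- site$bond
    a <- m$bond[r, "a"]; b <- m$bond[r, "b"]
    if (m$hyd[a] < 1L || m$hyd[b] < 1L) stop("site violates hydrogen rule")
    m$elem <- c(m$elem, tag); m$hyd <- c(m$hyd, 0L)
    w <- length(m$elem)
    m$bond <- rbind(m$bond, c(a, w, 1L), c(b, w, 1L))
    m$hyd[a] <- m$hyd[a] - 1L; m$hyd[b] <- m$hyd[b] - 1L
    return(m)
  }
  i <- site$atom
  cost <- mechanism_h_cost[[mech]]
  if (m$hyd[i] < cost) stop("site violates hydrogen rule")
  order <- switch(mech, single = 1L, double = 2L, triple = 3L, spiro = 2L)
  m$elem <- c(m$elem, tag); m$hyd <- c(m$hyd, 0L)
  m$bond <- rbind(m$bond, c(i, length(m$elem), order))
  m$hyd[i] <- m$hyd[i] - cost
  m
}

#' Find symmetry-unique connection sites
#'
#' Viable sites for a mechanism, reduced to one representative per symmetry
#' orbit. Orbit equivalence is decided operationally: two sites are
#' equivalent iff tagging them yields the same canonical structure.
#'
#' @param m a `gs_mol` (or SMILES string).
#' @param mechanism one of `single`, `double`, `triple`, `fusion`, `spiro`.
#' @return list of site records (`mechanism`, `atom` or `bond`, `chemotype`).
#' @export
find_connection_sites <- function(m, mechanism) {
  if (is.character(m)) m <- mol_from_smiles(m)[[1]]
  mechanism <- match.arg(mechanism, MECHANISMS)
  sites <- raw_sites(m, mechanism)
  if (!length(sites)) return(sites)
  tagged <- vapply(sites, function(s) smiles_build(attach_tag(m, s)), character(1))
  keys <- smi_canonical(tagged)
  sites[!duplicated(keys) & !is.na(keys)]
}

#' Activate a substituent at a connection site
#'
#' @param m a `gs_mol` or SMILES string.
#' @param site a site record from [find_connection_sites()].
#' @return list with `tagged_smiles` (canonical), `n_heavy` (tag excluded),
#'   `mechanism` and `chemotype`.
#' @export
activate_substituent <- function(m, site) {
  if (is.character(m)) m <- mol_from_smiles(m)[[1]]
  t <- attach_tag(m, site)
  list(tagged_smiles = smi_canonical(smiles_build(t)),
       n_heavy = mol_n_heavy(t),
       mechanism = site$mechanism,
       chemotype = site$chemotype)
}

#' Remove activation tags
#'
#' Inverts activation: deletes all tag atoms and refills hydrogens. For a
#' substituent this recovers the original enumerated molecule.
#'
#' @param m a `gs_mol` or tagged SMILES string.
#' @return canonical SMILES of the untagged molecule.
#' @export
deactivate <- function(m) {
  if (is.character(m)) m <- mol_from_smiles(m)[[1]]
  keep <- !(m$elem %in% TAG_ELEMENTS)
  m2 <- subset_atoms(m, which(keep))
  smi_canonical(smiles_build(mol_fill_h(m2)))
}

# keep the given atoms (indices), drop all bonds touching removed atoms
subset_atoms <- function(m, keep_idx) {
  remap <- rep(NA_integer_, length(m$elem))
  remap[keep_idx] <- seq_along(keep_idx)
  b <- m$bond
  rows <- !is.na(remap[b[, "a"]]) & !is.na(remap[b[, "b"]])
  b <- b[rows, , drop = FALSE]
  if (nrow(b)) { b[, "a"] <- remap[b[, "a"]]; b[, "b"] <- remap[b[, "b"]] }
  gs_mol(m$elem[keep_idx], m$hyd[keep_idx], b,
         coords = if (!is.null(m$coords)) m$coords[keep_idx, , drop = FALSE])
}

#' Activate a whole molecule library
#'
#' Tags every symmetry-unique viable site of every molecule for the given
#' mechanisms and returns the deduplicated activated substituents.
#'
#' @param smiles character vector of molecule SMILES.
#' @param mechanisms subset of the five mechanisms.
#' @return data.frame with columns `tagged_smiles`, `source_smiles`,
#'   `n_heavy`, `mechanism`, `chemotype`.
#' @export
activate_library <- function(smiles, mechanisms = MECHANISMS) {
  mols <- mol_from_smiles(smiles)
  raw <- character(0); meta <- list()
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    if (is.null(m)) next
    nh <- mol_n_heavy(m)
    for (mech in mechanisms) {
      for (s in raw_sites(m, mech)) {
        raw[[length(raw) + 1L]] <- smiles_build(attach_tag(m, s))
        meta[[length(meta) + 1L]] <-
          data.frame(source_smiles = smiles[k], n_heavy = nh,
                     mechanism = mech, chemotype = s$chemotype,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(raw))
    return(data.frame(tagged_smiles = character(), source_smiles = character(),
                      n_heavy = integer(), mechanism = character(),
                      chemotype = character(), stringsAsFactors = FALSE))
  df <- cbind(data.frame(tagged_smiles = smi_canonical(raw),
                         stringsAsFactors = FALSE),
              do.call(rbind, meta))
  df <- df[!is.na(df$tagged_smiles), ]
  df <- df[!duplicated(df$tagged_smiles), ]
  df <- df[order(df$n_heavy, df$mechanism, df$tagged_smiles), ]
  rownames(df) <- NULL
  df
}

#' Default shelf compatibility rules
#'
#' Forbidden (scaffold-site chemotype, substituent chemotype) pairs. A
#' single-bond attachment of an amine substituent to an amine site would
#' form a hydrazine; hydroxyl onto hydroxyl a peroxide. (Cumulated double
#' bonds are prevented earlier, at site detection.)
#' @return data.frame with columns `site`, `shelf`.
#' @export
compatibility_default <- function() {
  data.frame(site  = c("amine_N", "hydroxyl_O"),
             shelf = c("amine_N", "hydroxyl_O"),
             stringsAsFactors = FALSE)
}

#' Build substituent shelves
#'
#' Indexes activated substituents by (heavy atoms, mechanism, chemotype)
#' and attaches the compatibility relation.
#'
#' @param substituents data.frame from [activate_library()].
#' @param compatibility forbidden chemotype pairs.
#' @return a `substituent_shelves` object.
#' @export
build_shelves <- function(substituents, compatibility = compatibility_default()) {
  idx <- new.env(parent = emptyenv())
  if (nrow(substituents)) {
    key <- paste(substituents$n_heavy, substituents$mechanism,
                 substituents$chemotype, sep = "|")
    sp <- split(substituents$tagged_smiles, key)
    for (k in names(sp)) assign(k, sort(unique(sp[[k]])), envir = idx)
  }
  structure(list(index = idx,
                 chemotypes = sort(unique(substituents$chemotype)),
                 compatibility = compatibility,
                 n_substituents = nrow(substituents)),
            class = "substituent_shelves")
}

#' @export
print.substituent_shelves <- function(x, ...) {
  cat("<substituent_shelves> ", x$n_substituents, " substituents in ",
      length(ls(x$index)), " shelves\n", sep = "")
  invisible(x)
}

# is a (site chemotype, shelf chemotype) pair allowed?
shelf_compatible <- function(shelves, site_chemotype, shelf_chemotype) {
  cc <- shelves$compatibility
  !any(cc$site == site_chemotype & cc$shelf == shelf_chemotype)
}

#' Retrieve compatible activated substituents
#'
#' @param shelves a `substituent_shelves`.
#' @param n_heavy substituent size.
#' @param mechanism connection mechanism.
#' @param site_chemotype chemotype of the scaffold site to be served.
#' @return character vector of tagged SMILES (possibly empty).
#' @export
shelf_get <- function(shelves, n_heavy, mechanism, site_chemotype) {
  out <- character(0)
  for (ct in shelves$chemotypes) {
    if (!shelf_compatible(shelves, site_chemotype, ct)) next
    k <- paste(n_heavy, mechanism, ct, sep = "|")
    if (exists(k, envir = shelves$index, inherits = FALSE))
      out <- c(out, get(k, envir = shelves$index))
  }
  sort(out)
}
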