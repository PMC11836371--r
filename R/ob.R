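# Bridge to OpenBabel (ChemmineOB). All calls are batched: conversion of a
# SMILES vector costs one round-trip regardless of length. Entries are keyed
# by a numeric title so that molecules OpenBabel rejects come back as NA
# instead of silently shifting the alignment.

ob_batch <- function(smiles, to, options = NULL) {
  n <- length(smiles)
  if (n == 0L) return(character())
  src <- paste0(paste0(smiles, "\t", seq_len(n)), "\n", collapse = "")
  if (is.null(options))  # avoid ChemmineOB's default gen2D (very slow)
    options <- data.frame(names = character(0), args = character(0))
  suppressWarnings(ChemmineOB::convertFormat("SMI", to, src, options = options))
}

#' Canonical SMILES via OpenBabel
#'
#' Canonicalizes a character vector of SMILES. Aromaticity is perceived, so
#' Kekule variants of the same aromatic system map to one string. Entries
#' that fail to parse are returned as `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of the same length with canonical SMILES or `NA`.
#' @export
smi_canonical <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character())
  res <- rep(NA_character_, n)
  todo <- seq_len(n)
  repeat {
    out <- ob_batch(smiles[todo], "CAN")
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    got <- rep(NA_character_, length(todo))
    for (p in strsplit(lines, "\t", fixed = TRUE)) {
      if (length(p) >= 2L) {
        id <- suppressWarnings(as.integer(p[[2L]]))
        if (!is.na(id)) got[id] <- p[[1L]]
      }
    }
    res[todo[!is.na(got)]] <- got[!is.na(got)]
    miss <- todo[is.na(got)]
    if (!length(miss)) break
    # a fatal parse error aborts the whole OpenBabel stream: give up on the
    # first unconverted entry and retry the remainder
    todo <- miss[-1L]
    if (!length(todo)) break
  }
  res
}

# SMILES -> SDF text with explicit hydrogens (one V2000 block per molecule).
ob_sdf <- function(smiles) {
  opts <- data.frame(names = "h", args = "", stringsAsFactors = FALSE)
  ob_batch(smiles, "SDF", options = opts)
}

# Count of unique SMARTS matches per molecule (0 for non-matching or
# unparseable molecules). Invalid SMARTS raises an error.
ob_smarts_count <- function(smiles, pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  n <- length(smiles)
  if (n == 0L) return(integer())
  src <- paste0(paste0(smiles, "\t", seq_len(n)), "\n", collapse = "")
  mols <- ChemmineOB::forEachMol("SMILES", src, identity)
  cnt <- ChemmineOB::smartsSearch_OB(mols, pattern, uniqueMatches = TRUE)
  res <- integer(n)
  # forEachMol drops unparseable entries; realign by title
  titles <- vapply(mols, function(m) {
    t <- try(ChemmineOB::prop_OB(m)$title, silent = TRUE)
    if (inherits(t, "try-error") || is.null(t)) NA_character_ else t
  }, character(1))
  ids <- suppressWarnings(as.integer(titles))
  if (anyNA(ids) || length(ids) != length(cnt)) {
    # fall back to positional alignment (all parsed)
    if (length(cnt) == n) return(as.integer(cnt))
    stop("SMARTS search could not align results to input molecules")
  }
  res[ids] <- as.integer(cnt)
  res
}

# Validate a SMARTS pattern (cheap probe against ethane).
ob_smarts_valid <- function(pattern) {
  ok <- try(suppressWarnings(ob_smarts_count("CC", pattern)), silent = TRUE)
  !inherits(ok, "try-error")
}
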