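# Deterministic fixture generation and the chained pipeline driver, so
# every module can be exercised without any external database.

#' Read / write SMILES files
#'
#' Tab-separated `smiles<TAB>id` lines; gzip transparently by `.gz` suffix.
#' @param path file path.
#' @return data.frame with columns `smiles`, `id`.
#' @export
read_smiles_file <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(smiles = vapply(parts, `[[`, character(1), 1),
             id = vapply(parts, function(p) if (length(p) > 1) p[[2]] else NA_character_,
                         character(1)),
             stringsAsFactors = FALSE)
}

#' @rdname read_smiles_file
#' @param smiles character vector.
#' @param ids identifiers (defaults to running numbers).
#' @export
write_smiles_file <- function(smiles, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("GS%06d", seq_along(smiles))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste(smiles, ids, sep = "\t"), con)
  invisible(path)
}

#' Generate deterministic test fixtures
#'
#' @param seed integer seed controlling the deterministic shuffles.
#' @param kind one of `toy_library` (20-molecule SMILES library with
#'   planted benzene-ring matches), `toy_poses` (5-pose SDF with planted
#'   core RMSDs and energies), `toy_blocks` (building blocks covering all
#'   shipped reactions plus an inert block), `toy_counts` (synthetic
#'   exponential count table with known intercept/slope).
#' @param dir output directory.
#' @param a,b intercept and slope for `toy_counts`
#'   (log10 cumulative = a + b * n).
#' @param n_points rows in `toy_counts`.
#' @param noise_sd log10-scale Gaussian noise added to `toy_counts`
#'   (0 = exact).
#' @return the generated file path (invisibly its content as attribute).
#' @export
generate_fixtures <- function(seed, kind, dir = tempdir(),
                              a = 1, b = 1, n_points = 6L, noise_sd = 0) {
  kind <- match.arg(kind, c("toy_library", "toy_poses", "toy_blocks", "toy_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  if (kind == "toy_library") {
    with_ring <- c("c1ccccc1", "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
                   "COc1ccccc1", "Cc1ccc(O)cc1", "Clc1ccccc1", "CCc1ccccc1")
    without <- c("C1CCCCC1", "c1ccncc1", "c1ccoc1", "C1CCOC1", "CCCCCC",
                 "CC(=O)O", "CC(=O)N", "C1CCCC1", "c1cc[nH]c1", "CO",
                 "CC(C)O", "CC(=O)C")
    smis <- c(with_ring, without)
    ord <- sample(length(smis))
    path <- file.path(dir, "toy_library.smi")
    write_smiles_file(smis[ord], path)
    return(invisible(path))
  }
  if (kind == "toy_blocks") {
    blocks <- c("CC(=O)O", "OC(=O)C1CC1", "NCc1ccccc1", "NC1CCC1",
                "OB(O)c1ccccc1", "OB(O)c1ccco1", "Brc1ccccc1",
                "Clc1ccc(C)cc1", "OCC", "CCCC")
    path <- file.path(dir, "toy_blocks.smi")
    write_smiles_file(blocks[sample(length(blocks))], path)
    return(invisible(path))
  }
  if (kind == "toy_counts") {
    n <- seq_len(n_points)
    l10 <- a + b * n + stats::rnorm(n_points, sd = noise_sd)
    cum <- round(10^l10)
    cnt <- diff(c(0, cum))
    path <- file.path(dir, "toy_counts.tsv")
    utils::write.table(data.frame(n_heavy = n, count = cnt, cumulative = cum),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  # toy_poses: the reference core plus translated copies with energies.
  # One pose is planted at exactly 3.0 A translation (must be rejected by a
  # 2 A filter); the best-energy pose is a rejected one, so the filter's
  # "lowest energy among passing" logic is exercised.
  core <- "O=CNC1=NOC2=C1CCCC2"
  ref <- mol_from_smiles(core, gen3d = TRUE)[[1]]
  if (is.null(ref$coords)) stop("3D embedding of the fixture core failed")
  shift <- function(m, dx) { m$coords <- sweep(m$coords, 2, c(dx, 0, 0), "+"); m }
  poses <- list(shift(ref, 3.0),   # E -12, rmsd 3.0 -> rejected
                shift(ref, 1.5),   # E -10, rmsd 1.5 -> selected
                shift(ref, 0.0),   # E -9,  rmsd 0
                shift(ref, 2.5),   # E -8,  rmsd 2.5
                shift(ref, 0.5))   # E -7,  rmsd 0.5
  energies <- c(-12, -10, -9, -8, -7)
  ord <- sample(length(poses))
  path <- file.path(dir, "toy_poses.sdf")
  write_sdf(poses[ord], path,
            fields = lapply(energies[ord], function(e) list(ENERGY = e)),
            titles = sprintf("pose%d", seq_along(poses)))
  refpath <- file.path(dir, "toy_core_ref.sdf")
  write_sdf(list(ref), refpath, titles = "core_ref")
  invisible(path)
}

#' Run the chained pipeline
#'
#' enumerate -> activate -> shelves -> activate scaffold -> grow ->
#' fit/extrapolate, with a reconciling run manifest.
#'
#' @param config list with elements `n_max`, optional `scaffold`,
#'   `max_added`, `mechanisms`, `fit_range`, `extrapolate_at`, `seed`,
#'   `out_dir`.
#' @return list with `space`, `substituents`, `shelves`, `configs`,
#'   `superstructures`, `model`, `estimates`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$n_max))
  mechanisms <- config$mechanisms %||% MECHANISMS
  ec <- enumeration_config(config$n_max, embed_seed = config$seed %||% 1L)
  space <- enumerate_space(ec)
  subs <- activate_library(space$molecules, mechanisms)
  shelves <- build_shelves(subs)
  configs <- NULL; superstructures <- NULL
  if (!is.null(config$scaffold)) {
    configs <- activate_scaffold(config$scaffold, mechanisms,
                                 allowed_vectors = config$allowed_vectors)
    if (!is.null(config$max_added) && config$max_added >= 1)
      superstructures <- generate_superstructures(
        config$scaffold, config$max_added, shelves, mechanisms,
        allowed_vectors = config$allowed_vectors)
  }
  model <- NULL; estimates <- NULL
  fit_range <- config$fit_range %||% NULL
  ok <- sum(space$count_table$cumulative > 0) >= 2
  if (ok) {
    model <- fit_growth_model(space$count_table, fit_range)
    if (!is.null(config$extrapolate_at))
      estimates <- extrapolate(model, config$extrapolate_at)
  }
  manifest <- list(
    config = config,
    seed = config$seed %||% 1L,
    data_files = list(pains = "growspace-pains-subset-1"),
    stages = space$manifest$stages,
    tallies = list(
      molecules = length(space$molecules),
      activated_substituents = nrow(subs),
      scaffold_configurations = if (is.null(configs)) NA_integer_ else nrow(configs),
      superstructures = if (is.null(superstructures)) NA_integer_
        else sum(superstructures$count_table$count)))
  out <- list(space = space, substituents = subs, shelves = shelves,
              configs = configs, superstructures = superstructures,
              model = model, estimates = estimates, manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_smiles_file(space$molecules,
                      file.path(config$out_dir, "space.smi.gz"))
    utils::write.table(space$count_table,
                       file.path(config$out_dir, "counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
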