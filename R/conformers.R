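# Conformer ensemble generation: seeded ETKDG distance-geometry embedding
# with MMFF94 relaxation, delegated to RDKit through the bundled python
# helper (inst/python/embed_conformers.py). Deterministic for a fixed seed;
# atom order of the input graph is preserved, so perceived features stay
# index-compatible across conformers.

find_python <- function() {
  p <- Sys.which(c("python", "python3"))
  p <- p[nzchar(p)]
  if (!length(p)) abort("no python interpreter on PATH (needed for conformer embedding)")
  p[[1]]
}

embed_script <- function() {
  sc <- system.file("python", "embed_conformers.py", package = "pharmfunnel")
  if (!nzchar(sc)) abort("bundled embedding helper not found")
  sc
}

#' Generate a conformer ensemble for a molecule
#'
#' Embeds up to `max_confs` conformers by seeded distance geometry (ETKDG)
#' followed by MMFF94 relaxation, then prunes near-duplicates (heavy-atom
#' RMSD < 0.5 angstrom after Kabsch superposition). Deterministic for a
#' fixed seed. Embedding failures flag the record (zero conformers,
#' `embed_failed` attribute) rather than erroring.
#'
#' @param m a `ph_mol` (the chemical graph is used; existing coordinates are
#'   not required).
#' @param max_confs maximum conformers to keep (default 50).
#' @param seed integer random seed for the embedding.
#' @return `m` with up to `max_confs` conformers.
#' @export
generate_conformers <- function(m, max_confs = 50L, seed = 1L) {
  stopifnot(inherits(m, "ph_mol"))
  assert_scalar_number(max_confs, "max_confs", lower = 1)
  dir <- tempfile("confs")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  fin <- file.path(dir, "in.sdf"); fout <- file.path(dir, "out.sdf")
  writeLines(mol_to_sdf(m), fin)
  status <- suppressWarnings(system2(
    find_python(), c(embed_script(), fin, fout, format(as.integer(max_confs)),
                     format(as.integer(seed))),
    stdout = FALSE, stderr = FALSE))
  confs <- list()
  if (status == 0 && file.exists(fout)) {
    for (rec in split_sdf_records(readLines(fout, warn = FALSE))) {
      cm <- tryCatch(mol_from_sdf_lines(rec, perceive_arom = FALSE), error = function(e) NULL)
      if (!is.null(cm) && nrow(cm$atoms) == nrow(m$atoms) && length(cm$conformers)) {
        confs[[length(confs) + 1L]] <- cm$conformers[[1]]
      }
    }
  }
  if (!length(confs)) {
    warn(sprintf("3D embedding failed for '%s'; record flagged", m$id))
    m$conformers <- list()
    attr(m, "embed_failed") <- TRUE
    return(m)
  }
  heavy <- m$atoms$element != "H"
  m$conformers <- prune_duplicate_conformers(confs, heavy, rmsd_cut = 0.5,
                                             max_confs = max_confs)
  attr(m, "conformer_seed") <- as.integer(seed)
  m
}

prune_duplicate_conformers <- function(confs, heavy, rmsd_cut = 0.5, max_confs = Inf) {
  kept <- list()
  for (cf in confs) {
    dup <- FALSE
    for (kf in kept) {
      fit <- kabsch(cf[heavy, , drop = FALSE], kf[heavy, , drop = FALSE])
      if (fit$rmsd < rmsd_cut) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1L]] <- cf
    if (length(kept) >= max_confs) break
  }
  kept
}

#' Perceive features for every conformer of a library
#'
#' Maps molecules to the per-conformer feature tables that the screening
#' funnel consumes.
#'
#' @param mols molecule tibble from [read_molecules()] (list column `mol`).
#' @param rules a `ph_ruleset`.
#' @param max_confs,seed passed to [generate_conformers()] for molecules
#'   without conformers.
#' @return tibble with columns `compound_id`, `conformer_id` and the feature
#'   columns, one row per feature.
#' @export
featurize_library <- function(mols, rules = ruleset(), max_confs = 50L, seed = 1L) {
  stopifnot(is.data.frame(mols), "mol" %in% names(mols))
  out <- list()
  for (i in seq_len(nrow(mols))) {
    m <- mols$mol[[i]]
    if (!length(m$conformers)) m <- generate_conformers(m, max_confs = max_confs, seed = seed)
    if (!length(m$conformers)) next
    for (k in seq_along(m$conformers)) {
      ft <- perceive_features(m, rules, conformer = k)
      if (nrow(ft)) {
        ft$compound_id <- m$id
        ft$conformer_id <- sprintf("%s/%d", m$id, k)
        out[[length(out) + 1L]] <- ft
      }
    }
  }
  if (!length(out)) {
    return(tibble(type = character(0), x = numeric(0), y = numeric(0), z = numeric(0),
                  dx = numeric(0), dy = numeric(0), dz = numeric(0),
                  ligand_id = character(0), atom_idx = list(),
                  compound_id = character(0), conformer_id = character(0)))
  }
  bind_rows(out)
}
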