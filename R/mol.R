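# Molecule container: chemical graph + zero or more conformers (angstrom).
# Parsing and chemistry perception are delegated to OpenBabel (ChemmineOB) and
# ChemmineR; this file only shapes their output into a light S3 record.

new_mol <- function(id, atoms, bonds, conformers = list(), source = "",
                    aromatic_rings = list(), smiles = NA_character_) {
  atoms <- as_tibble(atoms)
  bonds <- as_tibble(bonds)
  stopifnot(all(c("element", "charge", "aromatic") %in% names(atoms)))
  if (nrow(bonds)) {
    stopifnot(all(c("a1", "a2", "order") %in% names(bonds)))
    if (any(bonds$a1 < 1 | bonds$a1 > nrow(atoms) | bonds$a2 < 1 | bonds$a2 > nrow(atoms))) {
      abort("bond atom indices out of range")
    }
  }
  for (cf in conformers) {
    if (!is.matrix(cf) || nrow(cf) != nrow(atoms) || ncol(cf) != 3 || !all(is.finite(cf))) {
      abort("each conformer must be a finite N x 3 matrix matching the atom count")
    }
  }
  structure(
    list(id = id, atoms = atoms, bonds = bonds, conformers = conformers,
         aromatic_rings = aromatic_rings, source = source, smiles = smiles),
    class = "ph_mol"
  )
}

#' Construct a molecule record directly
#'
#' Low-level constructor used by the synthetic generators and tests; for real
#' input use [read_molecules()]. Aromaticity is supplied explicitly as a list
#' of atom-index rings rather than perceived.
#'
#' @param id record identifier.
#' @param elements character vector of element symbols (explicit hydrogens
#'   included where the perception rules need them).
#' @param bonds data frame with columns `a1`, `a2`, `order`.
#' @param conformer optional N x 3 coordinate matrix (angstrom).
#' @param charges integer formal charges (default all zero).
#' @param aromatic_rings list of integer vectors, each an aromatic ring.
#' @return a `ph_mol` object.
#' @export
mol <- function(id, elements, bonds = data.frame(a1 = integer(), a2 = integer(), order = integer()),
                conformer = NULL, charges = 0L, aromatic_rings = list()) {
  n <- length(elements)
  charges <- rep_len(as.integer(charges), n)
  arom <- rep(FALSE, n)
  for (r in aromatic_rings) arom[r] <- TRUE
  atoms <- tibble(element = elements, charge = charges, aromatic = arom)
  confs <- if (is.null(conformer)) list() else list(unname(as.matrix(conformer)))
  new_mol(id, atoms, as_tibble(bonds), confs, source = "constructed",
          aromatic_rings = aromatic_rings)
}

#' @export
print.ph_mol <- function(x, ...) {
  cat(sprintf("<ph_mol> %s: %d atoms (%d heavy), %d bonds, %d conformer(s)\n",
              x$id, nrow(x$atoms), n_heavy(x), nrow(x$bonds), length(x$conformers)))
  invisible(x)
}

#' Number of heavy (non-hydrogen) atoms
#' @param m a `ph_mol`.
#' @return integer count.
#' @export
n_heavy <- function(m) sum(m$atoms$element != "H")

ob_options <- function(...) {
  nm <- c(...)
  if (!length(nm)) return(NULL)
  data.frame(names = nm, args = rep("", length(nm)))
}

# OpenBabel format conversion; returns "" on failure instead of erroring
ob_convert <- function(from, to, text, options = NULL) {
  out <- tryCatch(
    suppressWarnings(
      if (is.null(options)) ChemmineOB::convertFormat(from, to, text)
      else ChemmineOB::convertFormat(from, to, text, options = options)
    ),
    error = function(e) ""
  )
  if (is.null(out) || !nzchar(out)) "" else out
}

split_sdf_records <- function(lines) {
  idx <- grep("^\\${4}", lines)
  if (!length(idx)) {
    if (!any(nzchar(trimws(lines)))) return(list())
    return(list(lines))
  }
  starts <- c(1L, head(idx, -1) + 1L)
  recs <- Map(function(s, e) lines[s:(e - 1L)], starts, idx)
  recs[vapply(recs, function(r) any(nzchar(trimws(r))), logical(1))]
}

parse_mchg <- function(lines, n_atoms) {
  charges <- integer(n_atoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    cnt <- toks[1]
    for (k in seq_len(cnt)) charges[toks[2 * k]] <- toks[2 * k + 1]
  }
  charges
}

# parse one V2000 record (character vector, no trailing $$$$) into a ph_mol
mol_from_sdf_lines <- function(lines, source = "", keep_conformer = TRUE,
                               perceive_arom = TRUE) {
  if (length(lines) < 4) abort("truncated SDF record")
  counts <- lines[4]
  n_at <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bd <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_at) || is.na(n_bd) || n_at < 1 || length(lines) < 4 + n_at + n_bd) {
    abort("malformed SDF counts line")
  }
  at_lines <- lines[5:(4 + n_at)]
  xyz <- matrix(NA_real_, n_at, 3)
  elem <- character(n_at)
  for (i in seq_len(n_at)) {
    ln <- at_lines[i]
    xyz[i, ] <- c(as.numeric(substr(ln, 1, 10)), as.numeric(substr(ln, 11, 20)),
                  as.numeric(substr(ln, 21, 30)))
    elem[i] <- trimws(substr(ln, 32, 34))
  }
  if (any(!nzchar(elem)) || any(!is.finite(xyz))) abort("malformed SDF atom block")
  bd <- tibble(a1 = integer(n_bd), a2 = integer(n_bd), order = integer(n_bd))
  if (n_bd > 0) {
    bd_lines <- lines[(5 + n_at):(4 + n_at + n_bd)]
    bd$a1 <- as.integer(substr(bd_lines, 1, 3))
    bd$a2 <- as.integer(substr(bd_lines, 4, 6))
    bd$order <- as.integer(substr(bd_lines, 7, 9))
    if (any(is.na(bd$a1) | is.na(bd$a2) | bd$a1 < 1 | bd$a2 < 1 | bd$a1 > n_at | bd$a2 > n_at)) {
      abort("malformed SDF bond block")
    }
  }
  charges <- parse_mchg(lines, n_at)
  id <- trimws(lines[1])
  if (!nzchar(id)) id <- "unnamed"
  arings <- if (perceive_arom) perceive_aromatic_rings(elem, bd) else list()
  arom <- rep(FALSE, n_at); for (r in arings) arom[r] <- TRUE
  confs <- if (keep_conformer && any(xyz != 0)) list(unname(xyz)) else list()
  new_mol(id, tibble(element = elem, charge = charges, aromatic = arom),
          bd, confs, source = source, aromatic_rings = arings)
}

# Aromatic ring perception on the kekulized graph: rings of size 5-6 whose
# atoms are all sp2-capable and whose ring bonds alternate / carry pi density.
# Delegated to ChemmineR's ring finder via a minimal in-memory SDF.
perceive_aromatic_rings <- function(elem, bonds) {
  if (nrow(bonds) == 0) return(list())
  sdf <- tryCatch(sdf_object_from_graph(elem, bonds), error = function(e) NULL)
  if (is.null(sdf)) return(list())
  r <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, upper = 6, type = "all", arom = TRUE)),
    error = function(e) NULL
  )
  if (is.null(r) || !length(r$RINGS)) return(list())
  keep <- which(as.logical(r$AROMATIC))
  rings <- lapply(r$RINGS[keep], function(at) {
    sort(as.integer(sub("^.*_", "", at)))
  })
  unique(rings)
}

# build a ChemmineR SDF object from graph + dummy coordinates
sdf_object_from_graph <- function(elem, bonds, xyz = NULL) {
  if (is.null(xyz)) xyz <- matrix(0, length(elem), 3)
  txt <- v2000_text("tmp", elem, bonds, xyz)
  set <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(txt))
  set[[1]]
}

fmt_coord <- function(x) formatC(x, format = "f", digits = 4, width = 10)

# minimal V2000 writer (plumbing for OpenBabel round trips)
v2000_text <- function(id, elem, bonds, xyz, charges = NULL) {
  n_at <- length(elem); n_bd <- nrow(bonds)
  hdr <- c(id, "  pharmfunnel", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_at, n_bd)
  at <- vapply(seq_len(n_at), function(i) {
    sprintf("%s%s%s %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            fmt_coord(xyz[i, 1]), fmt_coord(xyz[i, 2]), fmt_coord(xyz[i, 3]), elem[i])
  }, character(1))
  bd <- if (n_bd) sprintf("%3d%3d%3d  0  0  0  0", bonds$a1, bonds$a2, bonds$order) else character(0)
  chg <- character(0)
  if (!is.null(charges)) {
    ci <- which(charges != 0)
    if (length(ci)) {
      chg <- vapply(split(ci, ceiling(seq_along(ci) / 8)), function(grp) {
        paste0(sprintf("M  CHG%3d", length(grp)),
               paste0(sprintf("%4d%4d", grp, charges[grp]), collapse = ""))
      }, character(1))
    }
  }
  c(hdr, counts, at, bd, chg, "M  END", "$$$$")
}

#' Serialise a molecule to SDF (V2000) text
#'
#' @param m a `ph_mol` with at least one conformer (or none: zero coordinates
#'   are written).
#' @param conformer which conformer to write.
#' @return character vector of SDF lines (terminated by `$$$$`).
#' @export
mol_to_sdf <- function(m, conformer = 1L) {
  xyz <- if (length(m$conformers) >= conformer) m$conformers[[conformer]] else matrix(0, nrow(m$atoms), 3)
  v2000_text(m$id, m$atoms$element, m$bonds, xyz, m$atoms$charge)
}

#' Parse a single SMILES string into a molecule
#'
#' The chemical graph (with explicit hydrogens) comes from OpenBabel; the
#' record carries zero conformers — operations that need geometry state so.
#'
#' @param smiles SMILES string.
#' @param id record identifier.
#' @param gen3d embed one 3D conformer (OpenBabel force-field build).
#' @return a `ph_mol`, or `NULL` if the SMILES does not parse.
#' @export
mol_from_smiles <- function(smiles, id = smiles, gen3d = FALSE) {
  out <- ob_convert("SMI", "SDF", paste0(smiles, " ", id, "\n"), options = ob_options("h"))
  if (!nzchar(out)) return(NULL)
  m <- tryCatch(
    mol_from_sdf_lines(strsplit(out, "\n", fixed = TRUE)[[1]],
                       source = "smiles", keep_conformer = FALSE),
    error = function(e) NULL
  )
  if (is.null(m)) return(NULL)
  m$id <- id
  m$smiles <- smiles
  if (gen3d) m <- generate_conformers(m, max_confs = 1L, seed = 1L)
  m
}

#' Add explicit hydrogens with 3D positions
#'
#' Round-trips the molecule through OpenBabel's hydrogen-addition step. Heavy
#' atom coordinates are preserved to SDF precision (1e-4 angstrom).
#'
#' @param m a `ph_mol` with one conformer.
#' @return a `ph_mol` with explicit hydrogens.
#' @export
add_hydrogens <- function(m) {
  if (!length(m$conformers)) abort("add_hydrogens() requires a conformer")
  out <- ob_convert("SDF", "SDF", paste(mol_to_sdf(m), collapse = "\n"),
                    options = ob_options("h"))
  if (!nzchar(out)) abort("hydrogen addition failed")
  m2 <- mol_from_sdf_lines(strsplit(out, "\n", fixed = TRUE)[[1]], source = m$source)
  m2$id <- m$id
  m2$smiles <- m$smiles
  m2
}

mols_to_tbl <- function(mols) {
  tibble(
    id = map_chr(mols, "id"),
    n_atoms = map_int(mols, ~ nrow(.x$atoms)),
    n_heavy = map_int(mols, n_heavy),
    n_conformers = map_int(mols, ~ length(.x$conformers)),
    source = map_chr(mols, "source"),
    mol = mols
  )
}

#' Read molecules from a SMILES or SDF file
#'
#' One molecule per record; unparseable records are skipped with a warning and
#' counted in the `n_skipped` attribute. SMILES records carry zero conformers;
#' SDF records keep the file's coordinates as one conformer.
#'
#' @param path file path.
#' @param format `"smiles"` (one record per line, optional name after
#'   whitespace) or `"sdf"` (V2000).
#' @return tibble with columns `id`, `n_atoms`, `n_heavy`, `n_conformers`,
#'   `source` and list column `mol` (`ph_mol` objects), in record order.
#' @export
read_molecules <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), class = "pf_io_error")
  lines <- readLines(path, warn = FALSE)
  mols <- list()
  skipped <- 0L
  if (format == "smiles") {
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    for (i in seq_along(lines)) {
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      id <- if (length(toks) >= 2) paste(toks[-1], collapse = " ") else toks[1]
      m <- mol_from_smiles(toks[1], id = id)
      if (is.null(m)) skipped <- skipped + 1L else mols[[length(mols) + 1L]] <- m
    }
  } else {
    for (rec in split_sdf_records(lines)) {
      m <- tryCatch(mol_from_sdf_lines(rec, source = basename(path)), error = function(e) NULL)
      if (is.null(m)) skipped <- skipped + 1L else mols[[length(mols) + 1L]] <- m
    }
  }
  if (skipped > 0) warn(sprintf("skipped %d unparseable record(s) in %s", skipped, path))
  if (!length(mols)) abort(sprintf("no parseable records in %s", path), class = "pf_empty_input")
  out <- mols_to_tbl(mols)
  attr(out, "n_skipped") <- skipped
  out
}
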