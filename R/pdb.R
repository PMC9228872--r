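# Protein-ligand complex handling: ligand extraction from PDB files and
# rigid-body frame superposition on alpha-carbon anchors. PDB parsing is
# delegated to bio3d; small-molecule connectivity of the extracted ligand is
# perceived by OpenBabel from the HETATM coordinates (documented heuristic —
# PDB records carry no bond orders).

water_names <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")
ion_names <- c("NA", "K", "CL", "MG", "CA", "ZN", "MN", "FE", "CU", "NI",
               "CO", "CD", "IOD", "BR", "SO4", "PO4")

#' Extract a ligand from a protein-ligand complex
#'
#' Pulls the HETATM residue `het_code` out of a PDB file as a molecule with
#' one conformer in the crystal frame. Waters and common ions are never
#' returned. When the ligand is present in several chains and `chain` is not
#' given, the copy in the first chain (file order) is taken with a warning.
#'
#' @param pdb_path path to a PDB file (wwPDB v3.3 fixed width).
#' @param het_code 3-character HET residue name (e.g. `"BSU"`).
#' @param chain optional chain identifier selecting one copy.
#' @return a `ph_mol` with one conformer; coordinates are exactly the file's
#'   HETATM coordinates.
#' @export
extract_ligand <- function(pdb_path, het_code, chain = NULL) {
  if (!file.exists(pdb_path)) abort(sprintf("file not found: %s", pdb_path), class = "pf_io_error")
  het_code <- toupper(trimws(het_code))
  if (het_code %in% c(water_names, ion_names)) {
    abort(sprintf("'%s' is a water/ion residue, not a ligand", het_code), class = "pf_not_found")
  }
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  at <- pdb$atom
  sel <- at$type == "HETATM" & trimws(at$resid) == het_code
  # drop alternate locations other than blank/'A'
  if ("alt" %in% names(at)) sel <- sel & (is.na(at$alt) | at$alt %in% c("", "A"))
  if (!any(sel)) {
    abort(sprintf("HETATM residue '%s' not found in %s", het_code, basename(pdb_path)),
          class = "pf_not_found")
  }
  lig <- at[sel, , drop = FALSE]
  chains <- unique(lig$chain)
  if (is.null(chain)) {
    if (length(chains) > 1) {
      warn(sprintf("ligand %s present in chains %s; taking chain %s",
                   het_code, paste(chains, collapse = ","), chains[1]))
    }
    chain <- chains[1]
  } else if (!chain %in% chains) {
    abort(sprintf("ligand %s has no copy in chain %s", het_code, chain), class = "pf_not_found")
  }
  lig <- lig[lig$chain == chain, , drop = FALSE]
  # one residue copy: first resno within the chain
  lig <- lig[lig$resno == lig$resno[1], , drop = FALSE]
  elem <- trimws(lig$elesy)
  fix <- !nzchar(elem) | is.na(elem)
  if (any(fix)) elem[fix] <- sub("^[0-9]*", "", substr(trimws(lig$elety[fix]), 1, 1))
  elem <- paste0(substr(elem, 1, 1), tolower(substr(elem, 2, 2)))
  xyz <- cbind(lig$x, lig$y, lig$z)
  bonds <- perceive_bonds_ob(elem, xyz)
  arings <- perceive_aromatic_rings(elem, bonds)
  arom <- rep(FALSE, length(elem)); for (r in arings) arom[r] <- TRUE
  new_mol(
    id = het_code,
    atoms = tibble(element = elem, charge = rep(0L, length(elem)), aromatic = arom),
    bonds = bonds, conformers = list(unname(xyz)),
    source = basename(pdb_path), aromatic_rings = arings
  )
}

# bond perception from coordinates via OpenBabel (falls back to a covalent
# radius distance heuristic when the round trip fails)
perceive_bonds_ob <- function(elem, xyz) {
  pdb_lines <- vapply(seq_along(elem), function(i) {
    sprintf("HETATM%5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, paste0(elem[i], i), xyz[i, 1], xyz[i, 2], xyz[i, 3], toupper(elem[i]))
  }, character(1))
  out <- ob_convert("PDB", "SDF", paste(c(pdb_lines, "END"), collapse = "\n"))
  if (nzchar(out)) {
    m <- tryCatch(mol_from_sdf_lines(strsplit(out, "\n", fixed = TRUE)[[1]]),
                  error = function(e) NULL)
    if (!is.null(m) && nrow(m$atoms) == length(elem)) return(m$bonds)
  }
  covalent_bonds(elem, xyz)
}

covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07,
                    S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39)

covalent_bonds <- function(elem, xyz, slack = 1.25) {
  r <- covalent_radii[elem]
  r[is.na(r)] <- 0.77
  n <- length(elem)
  a1 <- integer(0); a2 <- integer(0)
  if (n >= 2) {
    dmat <- as.matrix(dist(xyz))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (dmat[i, j] <= slack * (r[i] + r[j])) { a1 <- c(a1, i); a2 <- c(a2, j) }
    }
  }
  tibble(a1 = a1, a2 = a2, order = rep(1L, length(a1)))
}

# --- frame superposition -----------------------------------------------------

anchor_coords <- function(x) {
  if (inherits(x, "pdb")) {
    at <- x$atom
    sel <- at$type == "ATOM" & trimws(at$elety) == "CA"
    if ("alt" %in% names(at)) sel <- sel & (is.na(at$alt) | at$alt %in% c("", "A"))
    at <- at[sel, , drop = FALSE]
    ins <- if ("insert" %in% names(at)) ifelse(is.na(at$insert), "", at$insert) else ""
    key <- paste(at$chain, at$resno, ins, sep = "_")
    keep <- !duplicated(key)
    m <- cbind(at$x, at$y, at$z)[keep, , drop = FALSE]
    rownames(m) <- key[keep]
    return(m)
  }
  if (is.matrix(x) && ncol(x) == 3) {
    if (is.null(rownames(x))) abort("anchor matrices need rownames as labels")
    return(x)
  }
  abort("superpose() accepts bio3d pdb objects or labeled n x 3 matrices")
}

#' Superpose a mobile structure onto a reference frame
#'
#' Least-squares rigid superposition on common anchor points. For protein
#' structures (bio3d `pdb` objects) anchors are alpha-carbons matched by
#' (chain, residue number, insertion code); alternate locations keep the 'A'
#' conformer. Labeled coordinate matrices are matched by rowname.
#'
#' @param mobile,reference bio3d `pdb` objects (from [bio3d::read.pdb()]) or
#'   n x 3 matrices with anchor labels as rownames.
#' @return list with `rotation` (3 x 3 proper rotation), `translation`,
#'   `rmsd` (angstrom, over the anchors after transformation) and
#'   `n_anchors`.
#' @export
superpose <- function(mobile, reference) {
  P <- anchor_coords(mobile)
  Q <- anchor_coords(reference)
  common <- intersect(rownames(P), rownames(Q))
  if (length(common) < 3) {
    abort(sprintf("need >= 3 common anchors, found %d", length(common)),
          class = "pf_insufficient_anchors")
  }
  fit <- kabsch(P[common, , drop = FALSE], Q[common, , drop = FALSE])
  fit$n_anchors <- length(common)
  fit
}
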