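# Pharmacophoric feature perception on a single 3D conformer.
#
# The default rule set is explicit and versioned (the feature grammars of
# commercial pharmacophore tools are proprietary, so reproducibility takes
# precedence over mimicry):
#   A (acceptor):   N/O with an available lone pair — carbonyl O, ether or
#                   hydroxyl O, pyridine-type aromatic N with no H, nitrile
#                   N; amide N and positively charged atoms excluded.
#                   Position at the atom; direction from the mean of bonded
#                   heavy atoms toward the atom.
#   D (donor):      N/O bearing >= 1 hydrogen; one feature per heavy atom,
#                   position at the heavy atom, direction toward the first
#                   hydrogen.
#   R (ring):       each aromatic ring; position at the ring-atom centroid,
#                   direction along the ring normal (axial, sign
#                   canonicalised).
#   H (hydrophobe): each maximal connected set of >= `hydrophobic_min`
#                   aliphatic carbons whose members bond only to C, H or
#                   halogen; position at the set centroid, no direction.
#                   Halogens count as compatible substituents but never seed
#                   a group alone.
#   N/P (ionizable, off by default): atoms with negative / positive formal
#                   charge, position at the atom.

halogens <- c("F", "Cl", "Br", "I")

#' Feature perception rule set
#'
#' @param hydrophobic_min minimum number of connected aliphatic carbons that
#'   form a hydrophobic group (default 3).
#' @param ionizable include negative/positive ionizable types `N`/`P`
#'   (default `FALSE`; the consensus models in this package use A, D, H, R).
#' @param patterns optional named list overriding perception per type: names
#'   are feature-type codes, values are character vectors of substructure
#'   patterns (restricted SMARTS, see package docs). For an overridden type
#'   the feature position is the centroid of each matched atom set and no
#'   direction is assigned.
#' @return a `ph_ruleset` object.
#' @export
ruleset <- function(hydrophobic_min = 3L, ionizable = FALSE, patterns = list()) {
  if (length(patterns)) {
    if (is.null(names(patterns)) || !all(names(patterns) %in% feature_type_codes)) {
      abort("pattern overrides must be named by feature type codes")
    }
    probe <- mol("probe", c("C", "C", "O", "N"),
                 data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4), order = c(1L, 2L, 1L)))
    for (p in unlist(patterns)) smarts_match(probe, p)  # compile check
  }
  structure(list(hydrophobic_min = as.integer(hydrophobic_min),
                 ionizable = isTRUE(ionizable), patterns = patterns),
            class = "ph_ruleset")
}

#' Read a rule-set pattern file
#'
#' One pattern per line, `<TYPE> <SMARTS>`, `#` comments. Listed types
#' replace the built-in perception for that type.
#'
#' @param path pattern file.
#' @param ... passed to [ruleset()].
#' @return a `ph_ruleset`.
#' @export
read_ruleset <- function(path, ...) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), class = "pf_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  pats <- list()
  for (ln in lines) {
    toks <- strsplit(ln, "\\s+")[[1]]
    if (length(toks) != 2 || !toks[1] %in% feature_type_codes) {
      abort(sprintf("rule-set file: malformed line '%s'", ln), class = "pf_format_error")
    }
    pats[[toks[1]]] <- c(pats[[toks[1]]], toks[2])
  }
  ruleset(patterns = pats, ...)
}

#' Perceive pharmacophoric features on a conformer
#'
#' Applies the rule set to one 3D coordinate set of a molecule and returns
#' the perceived features as a feature table (see [features()]). The output
#' is deterministic and canonically ordered; positions are equivariant under
#' rigid transforms of the conformer.
#'
#' @param m a `ph_mol` with at least one conformer and explicit hydrogens
#'   where donor perception matters.
#' @param rules a `ph_ruleset` (default [ruleset()]).
#' @param conformer index of the coordinate set to use.
#' @return feature tibble with `ligand_id = m$id`.
#' @export
#' @examples
#' benzene <- mol("benzene", rep("C", 6),
#'   data.frame(a1 = 1:6, a2 = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1)),
#'   conformer = cbind(cos(seq(0, 5) * pi / 3), sin(seq(0, 5) * pi / 3), 0),
#'   aromatic_rings = list(1:6))
#' perceive_features(benzene)
perceive_features <- function(m, rules = ruleset(), conformer = 1L) {
  stopifnot(inherits(m, "ph_mol"))
  if (length(m$conformers) < conformer) {
    abort(sprintf("molecule '%s' has no 3D coordinates; feature perception needs geometry", m$id),
          class = "pf_geometry_required")
  }
  xyz <- m$conformers[[conformer]]
  env <- mol_env(m)
  out <- list()
  emit <- function(type, pos, dir = NULL, atoms_idx = NA_integer_) {
    out[[length(out) + 1L]] <<- tibble(
      type = type, x = pos[1], y = pos[2], z = pos[3],
      dx = if (is.null(dir)) NA_real_ else dir[1],
      dy = if (is.null(dir)) NA_real_ else dir[2],
      dz = if (is.null(dir)) NA_real_ else dir[3],
      ligand_id = m$id, atom_idx = list(as.integer(atoms_idx))
    )
  }
  elem <- m$atoms$element
  arom <- m$atoms$aromatic
  chg <- m$atoms$charge
  heavy_nbrs <- function(i) env$adj[[i]][elem[env$adj[[i]]] != "H"]
  h_nbrs <- function(i) env$adj[[i]][elem[env$adj[[i]]] == "H"]
  bond_order_to <- function(i, j) {
    k <- which((m$bonds$a1 == i & m$bonds$a2 == j) | (m$bonds$a1 == j & m$bonds$a2 == i))
    if (length(k)) m$bonds$order[k[1]] else 0L
  }

  types_wanted <- c("A", "D", "H", "R", if (rules$ionizable) c("N", "P"))
  for (tp in types_wanted) {
    if (!is.null(rules$patterns[[tp]])) {
      for (p in rules$patterns[[tp]]) {
        for (hit in smarts_match(m, p)) {
          emit(tp, colMeans(xyz[hit, , drop = FALSE]), atoms_idx = hit)
        }
      }
      next
    }
    if (tp == "A") {
      for (i in which(elem %in% c("N", "O") & chg <= 0)) {
        is_acc <- FALSE
        if (elem[i] == "O" && !arom[i]) {
          # carbonyl, ether, hydroxyl (any non-aromatic O with a heavy neighbour)
          is_acc <- length(heavy_nbrs(i)) >= 1
        } else if (elem[i] == "N") {
          nH <- env$h_count[i]
          triple <- any(vapply(heavy_nbrs(i), function(j) bond_order_to(i, j) == 3L, logical(1)))
          if (arom[i] && nH == 0) is_acc <- TRUE          # pyridine-type
          if (triple) is_acc <- TRUE                      # nitrile
          # amide N: bonded to a carbonyl carbon
          amide <- any(vapply(heavy_nbrs(i), function(j) {
            elem[j] == "C" && any(vapply(heavy_nbrs(j), function(k2) {
              elem[k2] == "O" && bond_order_to(j, k2) == 2L
            }, logical(1)))
          }, logical(1)))
          if (amide) is_acc <- FALSE
        }
        if (is_acc) {
          hn <- heavy_nbrs(i)
          dir <- if (length(hn)) unitize(xyz[i, ] - colMeans(xyz[hn, , drop = FALSE])) else NULL
          emit("A", xyz[i, ], dir, i)
        }
      }
    } else if (tp == "D") {
      for (i in which(elem %in% c("N", "O"))) {
        hs <- sort(h_nbrs(i))
        if (length(hs) >= 1) {
          dir <- unitize(xyz[hs[1], ] - xyz[i, ])
          emit("D", xyz[i, ], dir, i)
        }
      }
    } else if (tp == "R") {
      for (ring in m$aromatic_rings) {
        pts <- xyz[ring, , drop = FALSE]
        ctr <- colMeans(pts)
        sv <- svd(sweep(pts, 2, ctr))
        nrm <- sv$v[, 3]
        pivot <- which(abs(nrm) > 1e-8)[1]
        if (!is.na(pivot) && nrm[pivot] < 0) nrm <- -nrm   # axial sign convention
        emit("R", ctr, unitize(nrm), ring)
      }
    } else if (tp == "H") {
      aliph <- which(elem == "C" & !arom &
                       vapply(seq_along(elem), function(i) {
                         all(elem[env$adj[[i]]] %in% c("C", "H", halogens))
                       }, logical(1)))
      if (length(aliph)) {
        sub_edges <- m$bonds[m$bonds$a1 %in% aliph & m$bonds$a2 %in% aliph, , drop = FALSE]
        g <- igraph::graph_from_data_frame(
          data.frame(from = as.character(sub_edges$a1), to = as.character(sub_edges$a2)),
          directed = FALSE, vertices = data.frame(name = as.character(aliph)))
        comp <- igraph::components(g)
        for (ci in seq_len(comp$no)) {
          members <- as.integer(names(comp$membership)[comp$membership == ci])
          if (length(members) >= rules$hydrophobic_min) {
            emit("H", colMeans(xyz[members, , drop = FALSE]), atoms_idx = sort(members))
          }
        }
      }
    } else if (tp == "N") {
      for (i in which(chg < 0)) emit("N", xyz[i, ], atoms_idx = i)
    } else if (tp == "P") {
      for (i in which(chg > 0)) emit("P", xyz[i, ], atoms_idx = i)
    }
  }
  if (!length(out)) {
    return(features(character(0), numeric(0), numeric(0), numeric(0),
                    ligand_id = character(0)))
  }
  arrange_features(bind_rows(out))
}

#' Tally perceived feature types
#'
#' @inheritParams perceive_features
#' @return named integer vector, count per feature type present.
#' @export
feature_counts <- function(m, rules = ruleset(), conformer = 1L) {
  ft <- perceive_features(m, rules, conformer)
  if (!nrow(ft)) return(setNames(integer(0), character(0)))
  tab <- table(ft$type)
  setNames(as.integer(tab), names(tab))
}
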