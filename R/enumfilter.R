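# Combinatorial amide library enumeration (carboxylic-acid scaffold x amine)
# and Lipinski drug-likeness filtering.
#
# Coupling is a SMILES splice: the scaffold's -C(=O)OH loses its hydroxyl
# and the acyl carbon is bonded to the amine's coupling nitrogen (the first
# primary or secondary, non-amide, non-aromatic N in SMILES atom order)
# through a dot-disconnected ring-closure pair (`C%99 ... N%99`). The
# scaffold SMILES must spell the acid as a leading "OC(=O)" or trailing
# "C(=O)O" group; records violating a convention are skipped with a
# warning. Amine ring-closure digits are renumbered so the splice is always
# a valid SMILES; products are canonicalised with OpenBabel and
# deduplicated.

# shift every ring-closure digit outside brackets by `offset` (to %nn form)
shift_ring_closures <- function(smiles, offset = 50L) {
  chars <- strsplit(smiles, "")[[1]]
  out <- character(0)
  i <- 1L
  mapping <- new.env()
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%") {
      num <- as.integer(paste0(chars[i + 1], chars[i + 2]))
      out <- c(out, sprintf("%%%d", num + offset))
      i <- i + 3L
    } else if (grepl("[0-9]", ch)) {
      out <- c(out, sprintf("%%%d", as.integer(ch) + offset))
      i <- i + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

# insert a ring-closure token right after the k-th atom token of a SMILES
insert_after_atom <- function(smiles, k, token = "%99") {
  chars <- strsplit(smiles, "")[[1]]
  count <- 0L
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      count <- count + 1L
      i <- j + 1L
    } else if (i < length(chars) && paste0(ch, chars[i + 1]) %in% c("Cl", "Br")) {
      count <- count + 1L
      i <- i + 2L
    } else if (grepl("[BCNOSPFIbcnops]", ch)) {
      count <- count + 1L
      i <- i + 1L
    } else {
      i <- i + 1L
      next
    }
    if (count == k) {
      return(paste0(paste(chars[seq_len(i - 1L)], collapse = ""), token,
                    paste(chars[seq(i, length(chars))[seq_len(max(0, length(chars) - i + 1L))]],
                          collapse = "")))
    }
  }
  NA_character_
}

# index of the first eligible coupling nitrogen (primary/secondary,
# non-aromatic, not amide) in SMILES atom order; 0 if none
first_amine_nitrogen <- function(m) {
  env <- mol_env(m)
  elem <- m$atoms$element
  for (i in seq_along(elem)) {
    if (elem[i] != "N" || m$atoms$aromatic[i]) next
    if (!env$h_count[i] %in% c(1L, 2L)) next
    nbrs <- env$adj[[i]][elem[env$adj[[i]]] != "H"]
    amide <- any(vapply(nbrs, function(j) {
      elem[j] == "C" && any(vapply(env$adj[[j]], function(k) {
        elem[k] == "O" && {
          b <- m$bonds[(m$bonds$a1 == j & m$bonds$a2 == k) | (m$bonds$a1 == k & m$bonds$a2 == j), ]
          nrow(b) > 0 && b$order[1] == 2L
        }
      }, logical(1)))
    }, logical(1)))
    if (!amide) return(i)
  }
  0L
}

# acyl fragment of the scaffold with an open %99 ring bond on the carbonyl C
scaffold_acyl <- function(scaffold_smiles) {
  if (startsWith(scaffold_smiles, "OC(=O)")) {
    return(paste0("O=C%99", substring(scaffold_smiles, nchar("OC(=O)") + 1L)))
  }
  if (endsWith(scaffold_smiles, "C(=O)O")) {
    prefix <- substring(scaffold_smiles, 1L, nchar(scaffold_smiles) - nchar("C(=O)O"))
    return(paste0(prefix, "C%99(=O)"))
  }
  NA_character_
}

splice_amide <- function(acyl, amine_marked) paste0(amine_marked, ".", acyl)

# parse many SMILES through one OpenBabel invocation; NULL where unparseable
parse_smiles_batch <- function(smiles) {
  res <- vector("list", length(smiles))
  if (!length(smiles)) return(res)
  src <- paste0(smiles, " m", seq_along(smiles), collapse = "\n")
  out <- ob_convert("SMI", "SDF", paste0(src, "\n"), options = ob_options("h"))
  if (!nzchar(out)) return(res)
  # aromatic-ring perception is only needed when an aromatic N could be the
  # (ineligible) coupling site; plain lowercase-n-free SMILES skip it
  arom_needed <- grepl("n", smiles, fixed = TRUE)
  for (rec in split_sdf_records(strsplit(out, "\n", fixed = TRUE)[[1]])) {
    id0 <- trimws(rec[1])
    if (!grepl("^m[0-9]+$", id0)) next
    idx <- as.integer(substring(id0, 2))
    m <- tryCatch(mol_from_sdf_lines(rec, source = "smiles", keep_conformer = FALSE,
                                     perceive_arom = arom_needed[idx]),
                  error = function(e) NULL)
    if (is.null(m)) next
    m$id <- smiles[idx]
    m$smiles <- smiles[idx]
    res[[idx]] <- m
  }
  res
}

# batch canonicalisation through OpenBabel; returns NA for failures
canonical_smiles <- function(smiles) {
  if (!length(smiles)) return(character(0))
  src <- paste0(smiles, " m", seq_along(smiles), collapse = "\n")
  out <- ob_convert("SMI", "CAN", paste0(src, "\n"))
  res <- rep(NA_character_, length(smiles))
  if (!nzchar(out)) return(res)
  for (ln in strsplit(out, "\n", fixed = TRUE)[[1]]) {
    if (!nzchar(trimws(ln))) next
    toks <- strsplit(trimws(ln), "\t|\\s+")[[1]]
    if (length(toks) >= 2 && grepl("^m[0-9]+$", toks[2])) {
      res[as.integer(substring(toks[2], 2))] <- toks[1]
    }
  }
  res
}

as_smiles_tbl <- function(x, what) {
  if (is.character(x)) {
    return(tibble(id = if (!is.null(names(x)) && all(nzchar(names(x)))) names(x)
                  else paste0(what, seq_along(x)),
                  smiles = unname(x)))
  }
  stopifnot(is.data.frame(x), all(c("id", "smiles") %in% names(x)))
  as_tibble(x[, c("id", "smiles")])
}

#' Enumerate a combinatorial amide library
#'
#' One amide product per (scaffold, amine) pair, coupling the scaffold's
#' single carboxylic acid to the amine's first eligible nitrogen (primary or
#' secondary, non-aromatic, not already an amide). Products are
#' canonicalised and duplicates collapsed with a logged count, so the
#' expected cardinality is `nrow(scaffolds) * nrow(amines) - duplicates -
#' failures`.
#'
#' @param scaffolds scaffold acids: data frame with `id`, `smiles`, or a
#'   character vector of SMILES.
#' @param amines amine building blocks, same forms.
#' @return tibble with `product_id`, `scaffold_id`, `amine_id`, `smiles`
#'   (canonical); attributes `n_duplicates` and `n_failures`.
#' @export
#' @examples
#' enumerate_products("OC(=O)CC", c(aniline = "Nc1ccccc1"))
enumerate_products <- function(scaffolds, amines) {
  scaffolds <- as_smiles_tbl(scaffolds, "scaffold")
  amines <- as_smiles_tbl(amines, "amine")
  if (nrow(amines) == 0 || nrow(scaffolds) == 0) {
    out <- tibble(product_id = character(0), scaffold_id = character(0),
                  amine_id = character(0), smiles = character(0))
    attr(out, "n_duplicates") <- 0L; attr(out, "n_failures") <- 0L
    return(out)
  }
  # locate each amine's coupling nitrogen and mark it with an open ring bond
  mols <- parse_smiles_batch(amines$smiles)
  marked <- rep(NA_character_, nrow(amines))
  for (i in seq_len(nrow(amines))) {
    m <- mols[[i]]
    if (is.null(m)) next
    fn <- first_amine_nitrogen(m)
    if (fn > 0L) marked[i] <- insert_after_atom(shift_ring_closures(amines$smiles[i], 50L), fn)
  }
  ok_amine <- !is.na(marked)
  if (any(!ok_amine)) {
    warn(sprintf("skipping %d amine record(s) without a usable primary/secondary amine nitrogen",
                 sum(!ok_amine)))
  }
  acyls <- vapply(scaffolds$smiles, scaffold_acyl, character(1))
  if (any(is.na(acyls))) {
    warn(sprintf("skipping %d scaffold(s) without a recognisable carboxylic acid", sum(is.na(acyls))))
  }
  n_fail <- as.integer(sum(!ok_amine)) * sum(!is.na(acyls)) +
    as.integer(sum(is.na(acyls))) * nrow(amines)
  si <- which(!is.na(acyls)); ai <- which(ok_amine)
  if (!length(si) || !length(ai)) {
    warn("no products could be formed")
    out <- tibble(product_id = character(0), scaffold_id = character(0),
                  amine_id = character(0), smiles = character(0))
    attr(out, "n_duplicates") <- 0L; attr(out, "n_failures") <- n_fail
    return(out)
  }
  grid_s <- rep(si, each = length(ai)); grid_a <- rep(ai, times = length(si))
  prods <- tibble(
    product_id = paste0(scaffolds$id[grid_s], "_", amines$id[grid_a]),
    scaffold_id = scaffolds$id[grid_s], amine_id = amines$id[grid_a],
    smiles = paste0(marked[grid_a], ".", acyls[grid_s]))
  can <- canonical_smiles(prods$smiles)
  bad <- is.na(can)
  if (any(bad)) n_fail <- n_fail + sum(bad)
  prods <- prods[!bad, , drop = FALSE]
  prods$smiles <- can[!bad]
  dup <- duplicated(prods$smiles)
  n_dup <- sum(dup)
  if (n_dup > 0) inform(sprintf("collapsed %d duplicate product(s)", n_dup))
  out <- prods[!dup, , drop = FALSE]
  attr(out, "n_duplicates") <- n_dup
  attr(out, "n_failures") <- n_fail
  out
}

#' Generate a deterministic set of distinct aromatic amines
#'
#' Substituted anilines enumerated over a fixed substituent alphabet at the
#' five ring positions, canonicalised and deduplicated, in a fixed order.
#' Commercial building-block lists are proprietary; this generator provides
#' an equally sized, fully reproducible stand-in for exercising
#' combinatorial enumeration at realistic scale.
#'
#' @param n number of distinct amines required (default 2924, a typical
#'   commercial aromatic-amine catalogue size).
#' @return tibble with `id` (`am00001`, ...) and canonical `smiles`;
#'   exactly `n` rows, all distinct.
#' @export
generate_amines <- function(n = 2924L) {
  groups <- c("", "C", "CC", "F", "Cl", "Br", "I", "OC", "C(F)(F)F", "C=C")
  g <- length(groups)
  decode <- function(k) {
    # base-g digits of k over the five ring positions (ortho, meta, para, meta', ortho')
    digs <- integer(5)
    for (p in 1:5) { digs[p] <- k %% g; k <- k %/% g }
    subs <- groups[digs + 1L]
    paste0("Nc1c", ifelse(nzchar(subs[1]), paste0("(", subs[1], ")"), ""),
           "c", ifelse(nzchar(subs[2]), paste0("(", subs[2], ")"), ""),
           "c", ifelse(nzchar(subs[3]), paste0("(", subs[3], ")"), ""),
           "c", ifelse(nzchar(subs[4]), paste0("(", subs[4], ")"), ""),
           "c1", subs[5])
  }
  seen <- character(0)
  k <- 0L
  chunk <- 4096L
  while (length(seen) < n && k < g^5) {
    idx <- k:min(k + chunk - 1L, g^5 - 1L)
    can <- canonical_smiles(vapply(idx, decode, character(1)))
    can <- can[!is.na(can)]
    seen <- c(seen, setdiff(can, seen))
    k <- k + chunk
  }
  if (length(seen) < n) abort("substituent alphabet exhausted before reaching n amines")
  tibble(id = sprintf("am%05d", seq_len(n)), smiles = seen[seq_len(n)])
}

#' Lipinski descriptors and rule-of-five violations
#'
#' Molecular weight (average isotope) and logP (OpenBabel atom-contribution
#' estimate) come from OpenBabel; donor/acceptor counts are taken from the
#' molecular graph — `hbd` = number of N/O atoms bearing at least one
#' hydrogen, `hba` = number of N plus O atoms. `violations` counts rules
#' broken among {MW > 500, logP > 5, HBD > 5, HBA > 10}.
#'
#' @param mols molecule tibble ([read_molecules()]), a data frame with a
#'   `smiles` column, or a character vector of SMILES.
#' @return input ids with `mw`, `logp`, `hbd`, `hba`, `violations`.
#' @export
lipinski <- function(mols) {
  if (is.character(mols)) {
    mols <- tibble(id = if (!is.null(names(mols))) names(mols) else mols, smiles = unname(mols))
  }
  stopifnot(is.data.frame(mols))
  if (!"mol" %in% names(mols)) {
    stopifnot("smiles" %in% names(mols))
    if (!"id" %in% names(mols)) mols$id <- mols$smiles
    mols$mol <- lapply(seq_len(nrow(mols)), function(i) {
      mol_from_smiles(mols$smiles[i], id = mols$id[i])
    })
  }
  valid <- !vapply(mols$mol, is.null, logical(1))
  # graph-based donor/acceptor counts
  hbd <- hba <- rep(NA_integer_, nrow(mols))
  for (i in which(valid)) {
    m <- mols$mol[[i]]
    env <- mol_env(m)
    no <- which(m$atoms$element %in% c("N", "O"))
    hbd[i] <- sum(env$h_count[no] >= 1L)
    hba[i] <- length(no)
  }
  # MW / logP in one OpenBabel batch
  mw <- logp <- rep(NA_real_, nrow(mols))
  if (any(valid)) {
    txt <- unlist(lapply(which(valid), function(i) mol_to_sdf(mols$mol[[i]])))
    set <- tryCatch(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(txt)),
                    error = function(e) NULL)
    if (!is.null(set)) {
      pr <- tryCatch(suppressWarnings(ChemmineR::propOB(set)), error = function(e) NULL)
      if (!is.null(pr) && nrow(pr) == sum(valid)) {
        mw[valid] <- as.numeric(pr$MW)
        logp[valid] <- as.numeric(pr$logP)
      }
    }
  }
  viol <- ifelse(valid,
                 (!is.na(mw) & mw > 500) + (!is.na(logp) & logp > 5) +
                   (hbd > 5) + (hba > 10),
                 NA_integer_)
  tibble(id = mols$id, mw = mw, logp = logp, hbd = hbd, hba = hba,
         violations = as.integer(viol))
}

#' Filter a library to drug-like members
#'
#' Keeps molecules with at most `max_violations` Lipinski violations
#' (default 0, strict); order is preserved and pass/fail counts are logged.
#'
#' @param mols as in [lipinski()].
#' @param max_violations maximum rule-of-five violations tolerated.
#' @return the passing subset with the [lipinski()] columns attached.
#' @export
filter_druglike <- function(mols, max_violations = 0L) {
  rec <- lipinski(mols)
  keep <- !is.na(rec$violations) & rec$violations <= max_violations
  inform(sprintf("drug-likeness filter: %d of %d pass (max_violations = %d)",
                 sum(keep), nrow(rec), max_violations))
  rec[keep, , drop = FALSE]
}
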