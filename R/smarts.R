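# Restricted SMARTS subset matcher.
#
# No installed R package exposes atom-level SMARTS matches (only match
# counts), so rule-set pattern overrides are matched with this small
# backtracking matcher. Supported subset:
#   atoms:   C N O S P F Cl Br I B (aliphatic), c n o s p (aromatic), *,
#            A (aliphatic any), a (aromatic any);
#            bracket atoms with primitives joined by ';'/'&' (AND) or ','
#            (OR), each optionally negated with '!':
#            element symbols, #<num>, H<n> (total H count), +<n>/-<n>
#            (formal charge, bare +/- = 1), X<n> (total connections),
#            R (in ring of size <= 6), a, A, *
#   bonds:   - (single), = (double), # (triple), : (aromatic),
#            ~ (any), default bond = single-or-aromatic
#   grammar: branches with parentheses, ring closures 1-9 and %nn
# Not supported: stereo, recursive SMARTS, 2-digit charge, D/v primitives.

parse_smarts <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  atoms <- list()       # each: list of OR-groups, each group = list(neg, prim, arg)
  bonds <- list()       # list(a1, a2, type)
  i <- 1L
  prev_stack <- integer(0)
  prev <- 0L
  pending_bond <- NA_character_
  ring_open <- list()
  two_letter <- c("Cl", "Br")

  add_atom <- function(spec) {
    atoms[[length(atoms) + 1L]] <<- spec
    cur <- length(atoms)
    if (prev > 0L) {
      bonds[[length(bonds) + 1L]] <<- list(a1 = prev, a2 = cur,
                                           type = if (is.na(pending_bond)) "default" else pending_bond)
    }
    pending_bond <<- NA_character_
    prev <<- cur
  }
  # split a bracket AND-group into juxtaposed primitives (implicit '&')
  tokenize_prims <- function(grp) {
    toks <- character(0)
    while (nzchar(grp)) {
      mt <- regmatches(grp, regexpr(
        "^(!*)(Cl|Br|#[0-9]+|H[0-9]*|X[0-9]+|\\+[0-9]*|-[0-9]*|R|a|A|\\*|[A-Z][a-z]?|[cnops])",
        grp))
      if (!length(mt)) abort(sprintf("unsupported SMARTS primitive near '%s' in pattern '%s'",
                                     grp, pattern))
      toks <- c(toks, mt)
      grp <- substring(grp, nchar(mt) + 1L)
    }
    toks
  }
  parse_bracket <- function(body) {
    ors <- strsplit(body, ",", fixed = TRUE)[[1]]
    lapply(ors, function(grp) {
      prims <- unlist(lapply(strsplit(grp, "[;&]")[[1]], tokenize_prims))
      lapply(prims, function(p) {
        neg <- FALSE
        while (startsWith(p, "!")) { neg <- !neg; p <- substring(p, 2) }
        if (grepl("^#[0-9]+$", p)) return(list(neg = neg, prim = "anum", arg = as.integer(substring(p, 2))))
        if (grepl("^H[0-9]*$", p)) {
          n <- if (nchar(p) == 1) 1L else as.integer(substring(p, 2))
          return(list(neg = neg, prim = "hcount", arg = n))
        }
        if (grepl("^X[0-9]+$", p)) return(list(neg = neg, prim = "degree", arg = as.integer(substring(p, 2))))
        if (grepl("^\\+[0-9]*$", p)) {
          n <- if (nchar(p) == 1) 1L else as.integer(substring(p, 2))
          return(list(neg = neg, prim = "charge", arg = n))
        }
        if (grepl("^-[0-9]*$", p)) {
          n <- if (nchar(p) == 1) 1L else as.integer(substring(p, 2))
          return(list(neg = neg, prim = "charge", arg = -n))
        }
        if (p == "R") return(list(neg = neg, prim = "ring", arg = NA))
        if (p == "a") return(list(neg = neg, prim = "arom", arg = TRUE))
        if (p == "A") return(list(neg = neg, prim = "arom", arg = FALSE))
        if (p == "*") return(list(neg = neg, prim = "any", arg = NA))
        if (grepl("^[A-Z][a-z]?$", p)) return(list(neg = neg, prim = "elem", arg = p, arom = NA))
        if (grepl("^[cnops]$", p)) return(list(neg = neg, prim = "elem", arg = toupper(p), arom = TRUE))
        abort(sprintf("unsupported SMARTS primitive '%s' in pattern '%s'", p, pattern))
      })
    })
  }

  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(j)) abort(sprintf("unclosed bracket in SMARTS '%s'", pattern))
      add_atom(parse_bracket(paste(chars[(i + 1):(j - 1)], collapse = "")))
      i <- j + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pending_bond <- ch; i <- i + 1L
    } else if (ch == "(") {
      prev_stack <- c(prev_stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      num <- if (ch == "%") { n <- paste0(chars[i + 1], chars[i + 2]); i <- i + 3L; n } else { i <- i + 1L; ch }
      if (!is.null(ring_open[[num]])) {
        bonds[[length(bonds) + 1L]] <- list(a1 = ring_open[[num]], a2 = prev,
                                            type = if (is.na(pending_bond)) "default" else pending_bond)
        ring_open[[num]] <- NULL
      } else ring_open[[num]] <- prev
      pending_bond <- NA_character_
    } else {
      sym2 <- if (i < length(chars)) paste0(ch, chars[i + 1]) else ""
      if (sym2 %in% two_letter) {
        add_atom(list(list(list(neg = FALSE, prim = "elem", arg = sym2, arom = FALSE))))
        i <- i + 2L
      } else if (grepl("^[BCNOSPFI]$", ch)) {
        add_atom(list(list(list(neg = FALSE, prim = "elem", arg = ch, arom = FALSE))))
        i <- i + 1L
      } else if (grepl("^[cnops]$", ch)) {
        add_atom(list(list(list(neg = FALSE, prim = "elem", arg = toupper(ch), arom = TRUE))))
        i <- i + 1L
      } else if (ch == "*") {
        add_atom(list(list(list(neg = FALSE, prim = "any", arg = NA))))
        i <- i + 1L
      } else {
        abort(sprintf("unsupported character '%s' in SMARTS '%s'", ch, pattern))
      }
    }
  }
  if (length(ring_open)) abort(sprintf("unclosed ring bond in SMARTS '%s'", pattern))
  list(atoms = atoms, bonds = bonds)
}

atomic_numbers <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
                    Cl = 17, Br = 35, I = 53)

# per-molecule environment tables used by the matcher
mol_env <- function(m) {
  n <- nrow(m$atoms)
  adj <- vector("list", n)
  btype <- matrix(0L, 0, 0)
  h_count <- integer(n)
  degree <- integer(n)
  bond_key <- new.env(hash = TRUE)
  if (nrow(m$bonds)) {
    for (k in seq_len(nrow(m$bonds))) {
      a <- m$bonds$a1[k]; b <- m$bonds$a2[k]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
      arom_bond <- m$atoms$aromatic[a] && m$atoms$aromatic[b] &&
        any(vapply(m$aromatic_rings, function(r) all(c(a, b) %in% r), logical(1)))
      assign(paste(min(a, b), max(a, b)),
             if (arom_bond) ":" else c("-", "=", "#", "-")[min(m$bonds$order[k], 4)],
             envir = bond_key)
      if (m$atoms$element[a] == "H") h_count[b] <- h_count[b] + 1L
      if (m$atoms$element[b] == "H") h_count[a] <- h_count[a] + 1L
    }
  }
  degree <- lengths(adj)
  in_ring <- rep(FALSE, n)
  for (r in m$aromatic_rings) in_ring[r] <- TRUE
  # non-aromatic rings too: cycle atoms of the bond graph
  if (nrow(m$bonds)) {
    g <- igraph::graph_from_data_frame(m$bonds[, c("a1", "a2")], directed = FALSE,
                                       vertices = data.frame(name = seq_len(n)))
    core <- igraph::coreness(g)
    in_ring <- in_ring | core >= 2
  }
  list(adj = adj, bond_key = bond_key, h_count = h_count, degree = degree,
       in_ring = in_ring)
}

match_atom_spec <- function(spec, m, env, ai) {
  at <- m$atoms[ai, ]
  if (at$element == "H") return(FALSE)
  one <- function(p) {
    ok <- switch(p$prim,
      any = TRUE,
      elem = {
        e_ok <- at$element == p$arg
        ar <- p$arom %||% NA
        if (e_ok && !is.na(ar)) e_ok <- at$aromatic == ar
        e_ok
      },
      anum = { an <- atomic_numbers[at$element]; !is.na(an) && an == p$arg },
      hcount = env$h_count[ai] == p$arg,
      degree = (env$degree[ai]) == p$arg,
      charge = at$charge == p$arg,
      ring = env$in_ring[ai],
      arom = at$aromatic == p$arg,
      FALSE)
    if (p$neg) !ok else ok
  }
  any(vapply(spec, function(grp) all(vapply(grp, one, logical(1))), logical(1)))
}

match_bond_spec <- function(type, m, env, ai, aj) {
  actual <- get0(paste(min(ai, aj), max(ai, aj)), envir = env$bond_key, ifnotfound = NA)
  if (is.na(actual)) return(FALSE)
  switch(type,
         "~" = TRUE,
         "default" = actual %in% c("-", ":"),
         actual == type)
}

# all matches of a parsed pattern; returns list of integer vectors (atom
# indices, one per pattern atom), unique as unordered atom sets
smarts_match <- function(m, pattern) {
  pat <- if (is.character(pattern)) parse_smarts(pattern) else pattern
  np <- length(pat$atoms)
  if (np == 0) return(list())
  env <- mol_env(m)
  heavy <- which(m$atoms$element != "H")
  # adjacency of pattern
  pat_adj <- vector("list", np)
  for (b in pat$bonds) {
    pat_adj[[b$a1]] <- c(pat_adj[[b$a1]], list(b))
    pat_adj[[b$a2]] <- c(pat_adj[[b$a2]], list(list(a1 = b$a2, a2 = b$a1, type = b$type)))
  }
  results <- list()
  assign_vec <- integer(np)
  recurse <- function(k) {
    if (k > np) {
      results[[length(results) + 1L]] <<- assign_vec
      return(invisible())
    }
    for (cand in heavy) {
      if (cand %in% assign_vec[seq_len(k - 1)]) next
      if (!match_atom_spec(pat$atoms[[k]], m, env, cand)) next
      ok <- TRUE
      for (b in pat_adj[[k]]) {
        other <- if (b$a1 == k) b$a2 else b$a1
        if (other < k) {
          if (!match_bond_spec(b$type, m, env, cand, assign_vec[other])) { ok <- FALSE; break }
        }
      }
      if (ok) {
        assign_vec[k] <<- cand
        recurse(k + 1L)
        assign_vec[k] <<- 0L
      }
    }
  }
  recurse(1L)
  if (!length(results)) return(list())
  sets <- vapply(results, function(v) paste(sort(v), collapse = "-"), character(1))
  results[!duplicated(sets)]
}
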