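# Matching a feature set against a hypothesis.
#
# In-place mode: the features already sit in the hypothesis frame (a docking
# pose); the best injective type-respecting assignment with every pair
# distance inside the site radius is found exactly by dynamic programming
# over site subsets (maximum cardinality, then minimum total distance).
#
# Aligned mode: the conformer frame is arbitrary; candidate assignments come
# from a correspondence graph whose nodes are type-compatible (feature,
# site) pairs and whose edges require the inter-feature distance to agree
# with the inter-site distance within the sum of the two site radii (a
# triangle-inequality bound, so no verifying assignment is pruned). All
# cliques of size >= min_match are enumerated (not only maximal ones — a
# maximal clique can fail post-alignment verification while a sub-clique
# verifies), each is Kabsch-superposed onto the sites and verified against
# the radii.

match_eps <- 1e-9

new_match <- function(assignment, rotation, translation, rmsd, hyp, mode, feat,
                      conformer_id = NA_character_) {
  attr(assignment, "feature_dirs") <-
    cbind(feat$dx, feat$dy, feat$dz)[assignment$feature, , drop = FALSE]
  res <- structure(
    list(assignment = assignment, rotation = rotation, translation = translation,
         matched_count = nrow(assignment), rmsd_match = rmsd,
         fit_score = NA_real_, mode = mode, conformer_id = conformer_id),
    class = "ph_match"
  )
  res$fit_score <- fit_score(res, hyp)
  res
}

#' @export
print.ph_match <- function(x, ...) {
  cat(sprintf("<ph_match> %s: %d site(s) matched, rmsd %.3f A, fit score %.3f\n",
              x$mode, x$matched_count, x$rmsd_match, x$fit_score))
  invisible(x)
}

#' @rdname match_inplace
#' @param x a `ph_match`.
#' @param ... unused.
#' @export
tidy.ph_match <- function(x, ...) x$assignment

#' @rdname match_inplace
#' @export
glance.ph_match <- function(x, ...) {
  tibble(mode = x$mode, matched_count = x$matched_count,
         rmsd_match = x$rmsd_match, fit_score = x$fit_score,
         conformer_id = x$conformer_id)
}

site_radius_ok <- function(d, radius) d <= radius + match_eps

# pairwise feature/site distance matrix with Inf where types differ or the
# distance exceeds the site radius (in-place feasibility)
inplace_cost <- function(feat, h) {
  fx <- feat_xyz(feat); sx <- site_xyz(h)
  n <- nrow(feat); m <- nrow(h$sites)
  cost <- matrix(Inf, n, m)
  for (j in seq_len(m)) {
    same <- feat$type == h$sites$type[j]
    if (!any(same)) next
    d <- sqrt(rowSums(sweep(fx[same, , drop = FALSE], 2, sx[j, ])^2))
    ok <- site_radius_ok(d, h$sites$radius[j])
    cost[which(same)[ok], j] <- d[ok]
  }
  cost
}

#' Match a pose in place against a hypothesis
#'
#' The features must already be in the hypothesis frame (e.g. a docking
#' pose): no conformational search, no realignment. Finds the
#' maximum-cardinality injective type-respecting assignment in which every
#' feature lies inside its site's tolerance sphere; among
#' maximum-cardinality assignments the one of minimum total distance is
#' returned (ties broken deterministically).
#'
#' @param feat feature tibble (hypothesis frame).
#' @param h a `ph_hypothesis`.
#' @param min_match minimum matched sites to report a hit (default: all
#'   sites).
#' @param conformer_id identifier carried into the result.
#' @return a `ph_match` (transform = identity), or `NULL` when fewer than
#'   `min_match` sites can be matched.
#' @export
match_inplace <- function(feat, h, min_match = nrow(h$sites),
                          conformer_id = NA_character_) {
  validate_features(feat)
  stopifnot(inherits(h, "ph_hypothesis"))
  m <- nrow(h$sites)
  if (min_match > m) abort("min_match cannot exceed the number of sites")
  if (m > 12) abort("in-place matcher supports at most 12 sites")
  n <- nrow(feat)
  if (n == 0) return(NULL)
  cost <- inplace_cost(feat, h)
  n_masks <- bitwShiftL(1L, m)
  NEG <- -1L
  cnt <- rep(NEG, n_masks); tot <- rep(Inf, n_masks)
  cnt[1] <- 0L; tot[1] <- 0
  layers_cnt <- vector("list", n); layers_tot <- vector("list", n)
  for (i in seq_len(n)) {
    new_cnt <- cnt; new_tot <- tot
    usable <- which(is.finite(cost[i, ]))
    for (j in usable) {
      bit <- bitwShiftL(1L, j - 1L)
      from <- which(cnt >= 0L & bitwAnd(seq_len(n_masks) - 1L, bit) == 0L)
      for (msk in from) {
        to <- msk + bit
        c2 <- cnt[msk] + 1L; t2 <- tot[msk] + cost[i, j]
        if (c2 > new_cnt[to] || (c2 == new_cnt[to] && t2 < new_tot[to] - match_eps)) {
          new_cnt[to] <- c2; new_tot[to] <- t2
        }
      }
    }
    cnt <- new_cnt; tot <- new_tot
    layers_cnt[[i]] <- cnt; layers_tot[[i]] <- tot
  }
  best_mask <- order(-cnt, tot, seq_len(n_masks))[1]
  best_cnt <- cnt[best_mask]
  if (best_cnt < min_match || best_cnt == 0L) return(NULL)
  # backtrack deterministically (smallest site index at each step)
  pairs <- list()
  msk <- best_mask
  for (i in rev(seq_len(n))) {
    prev_cnt <- if (i > 1) layers_cnt[[i - 1]] else c(0L, rep(NEG, n_masks - 1L))
    prev_tot <- if (i > 1) layers_tot[[i - 1]] else c(0, rep(Inf, n_masks - 1L))
    here_cnt <- layers_cnt[[i]][msk]; here_tot <- layers_tot[[i]][msk]
    if (prev_cnt[msk] == here_cnt && abs(prev_tot[msk] - here_tot) <= match_eps) next
    found <- FALSE
    for (j in seq_len(m)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(msk - 1L, bit) == 0L || !is.finite(cost[i, j])) next
      pm <- msk - bit
      if (prev_cnt[pm] == here_cnt - 1L &&
          abs(prev_tot[pm] + cost[i, j] - here_tot) <= 1e-7) {
        pairs[[length(pairs) + 1L]] <- tibble(feature = i, site = j, dist = cost[i, j])
        msk <- pm; found <- TRUE; break
      }
    }
    if (!found) next
  }
  assignment <- dplyr::arrange(bind_rows(pairs), .data$feature)
  new_match(assignment, diag(3), c(0, 0, 0),
            sqrt(mean(assignment$dist^2)), h, mode = "inplace", feat = feat,
            conformer_id = conformer_id)
}

# correspondence-graph nodes and edges for aligned matching
correspondence_graph <- function(feat, h) {
  nodes <- which(outer(feat$type, h$sites$type, `==`), arr.ind = TRUE)
  colnames(nodes) <- c("feature", "site")
  K <- nrow(nodes)
  if (K == 0) return(list(nodes = nodes, graph = NULL))
  fd <- as.matrix(dist(feat_xyz(feat)))
  sd_ <- as.matrix(dist(site_xyz(h)))
  rad <- h$sites$radius
  ei <- integer(0); ej <- integer(0)
  for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
    i1 <- nodes[a, 1]; j1 <- nodes[a, 2]; i2 <- nodes[b, 1]; j2 <- nodes[b, 2]
    if (i1 == i2 || j1 == j2) next
    if (abs(fd[i1, i2] - sd_[j1, j2]) <= rad[j1] + rad[j2] + match_eps) {
      ei <- c(ei, a); ej <- c(ej, b)
    }
  }
  g <- igraph::make_empty_graph(n = K, directed = FALSE)
  if (length(ei)) g <- igraph::add_edges(g, rbind(ei, ej))
  list(nodes = nodes, graph = g)
}

verify_aligned <- function(feat, h, fi, si) {
  P <- feat_xyz(feat)[fi, , drop = FALSE]
  Q <- site_xyz(h)[si, , drop = FALSE]
  fit <- kabsch(P, Q)
  d <- sqrt(rowSums((apply_rigid(P, fit$rotation, fit$translation) - Q)^2))
  if (!all(site_radius_ok(d, h$sites$radius[si]))) return(NULL)
  list(fit = fit, dists = d)
}

#' Match a conformer to a hypothesis with rigid alignment
#'
#' Correspondence-graph clique search followed by Kabsch superposition of
#' the candidate feature subset onto the sites and verification against the
#' tolerance radii. Returns the verified assignment with the highest
#' `(matched_count, fit_score)`; deterministic tie-breaking.
#'
#' @param feat feature tibble in any frame.
#' @param h a `ph_hypothesis`.
#' @param min_match minimum matched sites (>= 3; rigid superposition needs
#'   three points). Default: all sites.
#' @param conformer_id identifier carried into the result.
#' @return a `ph_match` carrying the fitted rotation/translation, or `NULL`.
#' @export
match_aligned <- function(feat, h, min_match = nrow(h$sites),
                          conformer_id = NA_character_) {
  validate_features(feat)
  stopifnot(inherits(h, "ph_hypothesis"))
  if (min_match < 3) abort("min_match must be >= 3 in aligned mode")
  if (min_match > nrow(h$sites)) abort("min_match cannot exceed the number of sites")
  if (nrow(feat) == 0) return(NULL)
  cg <- correspondence_graph(feat, h)
  if (is.null(cg$graph) || nrow(cg$nodes) < min_match) return(NULL)
  cliques <- igraph::cliques(cg$graph, min = min_match)
  if (!length(cliques)) return(NULL)
  sizes <- lengths(cliques)
  best <- NULL
  best_key <- NULL
  for (s in sort(unique(sizes), decreasing = TRUE)) {
    if (!is.null(best)) break  # larger size already verified
    for (ci in which(sizes == s)) {
      v <- as.integer(cliques[[ci]])
      fi <- cg$nodes[v, 1]; si <- cg$nodes[v, 2]
      ord <- order(si)
      fi <- fi[ord]; si <- si[ord]
      ver <- verify_aligned(feat, h, fi, si)
      if (is.null(ver)) next
      assignment <- tibble(feature = fi, site = si, dist = ver$dists)
      cand <- new_match(assignment, ver$fit$rotation, ver$fit$translation,
                        ver$fit$rmsd, h, mode = "aligned", feat = feat,
                        conformer_id = conformer_id)
      key <- list(-cand$matched_count, -cand$fit_score,
                  paste(fi, si, collapse = ";"))
      if (is.null(best) || match_key_less(key, best_key)) {
        best <- cand; best_key <- key
      }
    }
  }
  best
}

match_key_less <- function(k1, k2) {
  if (k1[[1]] != k2[[1]]) return(k1[[1]] < k2[[1]])
  if (abs(k1[[2]] - k2[[2]]) > match_eps) return(k1[[2]] < k2[[2]])
  k1[[3]] < k2[[3]]
}

#' Fit score of a match
#'
#' Open, documented replacement for proprietary screen scores:
#' `score = 0.5 * max(0, 1 - rmsd/tolerance) + 0.5 * V`, where `V` is the
#' mean of `max(0, cos theta)` over matched pairs in which both the feature
#' and the site carry a direction (`theta` the angle between them after the
#' match transform), and `V = 1` when no such pair exists. Lies in [0, 1].
#'
#' @param result a `ph_match`.
#' @param h the matched `ph_hypothesis`.
#' @return numeric score in `[0, 1]`.
#' @export
fit_score <- function(result, h) {
  tol <- h$build_params$tolerance
  pos <- 0.5 * max(0, 1 - result$rmsd_match / tol)
  V <- 1
  fd <- attr(result$assignment, "feature_dirs")
  if (!is.null(fd)) {
    sd_ <- cbind(h$sites$dx, h$sites$dy, h$sites$dz)[result$assignment$site, , drop = FALSE]
    both <- !is.na(fd[, 1]) & !is.na(sd_[, 1])
    if (any(both)) {
      fr <- fd[both, , drop = FALSE] %*% result$rotation
      cosv <- rowSums(fr * sd_[both, , drop = FALSE])
      V <- mean(pmax(0, cosv))
    }
  }
  pos + 0.5 * V
}

#' Brute-force matching oracle
#'
#' Exhaustive enumeration of injective type-respecting feature-to-site
#' assignments, used as ground truth in equivalence tests. In-place mode
#' requires every pair distance within the site radius; aligned mode runs a
#' Kabsch superposition per assignment (size >= 3) before the radius check.
#'
#' @param feat feature tibble (at most 7 features).
#' @param h a `ph_hypothesis` (at most 6 sites).
#' @param min_match minimum assignment size counted as a match.
#' @param mode `"inplace"` or `"aligned"`.
#' @return the best verified matched count (0 when nothing reaches
#'   `min_match`).
#' @export
brute_force_match <- function(feat, h, min_match = 3L, mode = c("inplace", "aligned")) {
  mode <- match.arg(mode)
  validate_features(feat)
  if (nrow(feat) > 7 || nrow(h$sites) > 6) {
    abort("brute_force_match() is limited to <= 7 features and <= 6 sites")
  }
  n <- nrow(feat); m <- nrow(h$sites)
  if (n == 0) return(0L)
  lower <- if (mode == "aligned") max(3L, min_match) else max(1L, min_match)
  fx <- feat_xyz(feat); sx <- site_xyz(h)
  hi <- min(n, m)
  if (hi < lower) return(0L)
  for (s in hi:lower) {
    found <- FALSE
    site_sets <- utils::combn(m, s, simplify = FALSE)
    for (ss in site_sets) {
      cand <- lapply(ss, function(j) which(feat$type == h$sites$type[j]))
      if (any(lengths(cand) == 0)) next
      assign_rec <- function(k, used) {
        if (found) return(invisible())
        if (k > s) {
          fi <- used
          if (mode == "inplace") {
            d <- sqrt(rowSums((fx[fi, , drop = FALSE] - sx[ss, , drop = FALSE])^2))
            if (all(site_radius_ok(d, h$sites$radius[ss]))) found <<- TRUE
          } else {
            if (!is.null(verify_aligned(feat, h, fi, ss))) found <<- TRUE
          }
          return(invisible())
        }
        for (f in cand[[k]]) {
          if (f %in% used) next
          assign_rec(k + 1L, c(used, f))
          if (found) return(invisible())
        }
      }
      assign_rec(1L, integer(0))
      if (found) break
    }
    if (found) return(s)
  }
  0L
}
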