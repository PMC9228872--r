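# Consensus hypothesis construction: cluster same-type features across
# prealigned ligands (average-linkage agglomerative clustering cut at the
# tolerance) and keep clusters supported by at least a minimum fraction of
# the ligands. Average linkage is used rather than single linkage so that
# features cannot chain across the binding pocket into one sprawling site.

#' Cluster same-type features at a distance tolerance
#'
#' Average-linkage agglomerative clustering on the Euclidean distances of
#' feature positions, cut so that no merge occurs at a linkage distance
#' greater than `tolerance`. Deterministic under input order: features are
#' put in canonical order before clustering.
#'
#' @param feat feature tibble, all rows of one type.
#' @param tolerance clustering tolerance (angstrom, > 0).
#' @return tibble with one row per cluster: `cluster`, `type`, centroid
#'   `x,y,z`, `n_members`, `n_ligands` (distinct supporting ligands) and a
#'   list column `members` holding the member features.
#' @export
cluster_features <- function(feat, tolerance) {
  assert_scalar_number(tolerance, "tolerance", lower = 1e-12)
  if (nrow(feat) == 0) {
    return(tibble(cluster = integer(0), type = character(0), x = numeric(0),
                  y = numeric(0), z = numeric(0), n_members = integer(0),
                  n_ligands = integer(0), members = list()))
  }
  if (length(unique(feat$type)) > 1) abort("cluster_features() expects a single feature type")
  feat <- arrange_features(feat)
  cl <- if (nrow(feat) == 1) 1L else {
    hc <- hclust(dist(feat_xyz(feat)), method = "average")
    cutree(hc, h = tolerance)
  }
  out <- lapply(sort(unique(cl)), function(k) {
    mem <- feat[cl == k, , drop = FALSE]
    ctr <- unname(colMeans(feat_xyz(mem)))
    tibble(cluster = k, type = mem$type[1], x = ctr[1], y = ctr[2], z = ctr[3],
           n_members = nrow(mem), n_ligands = n_distinct(mem$ligand_id),
           members = list(mem))
  })
  dplyr::arrange(bind_rows(out), desc(.data$n_ligands), .data$x, .data$y, .data$z)
}

# direction consensus: normalized mean of member directions when at least
# half the members carry one
cluster_direction <- function(members) {
  has <- !is.na(members$dx)
  if (sum(has) * 2 < nrow(members)) return(rep(NA_real_, 3))
  d <- unitize(colMeans(cbind(members$dx[has], members$dy[has], members$dz[has])))
  if (is.null(d)) rep(NA_real_, 3) else d
}

#' Build a consensus pharmacophore hypothesis from prealigned ligands
#'
#' For each feature type, features pooled across all ligands are clustered
#' with [cluster_features()]; a cluster becomes a site when the fraction of
#' distinct supporting ligands reaches `min_fraction` (a ligand contributes
#' at most one vote per cluster, so two nearby donors on one ligand cannot
#' double-count). Site position is the member centroid, radius the build
#' tolerance, support the ligand fraction. Overlapping same-type sites
#' (centroids closer than the tolerance) are merged keeping the higher
#' support. Output sites are canonically ordered, so ligand input order is
#' irrelevant.
#'
#' @param feat feature tibble carrying a `ligand_id` column (the prealigned
#'   ligand set, one common frame).
#' @param min_fraction minimum ligand-support fraction in (0, 1].
#' @param tolerance clustering tolerance and site radius (angstrom).
#' @param max_sites optional cap: keep the top `max_sites` by support.
#' @param n_ligands number of ligands in the set; defaults to the distinct
#'   `ligand_id` count (supply explicitly if some ligands contributed no
#'   features).
#' @param id,frame identifiers stored on the hypothesis.
#' @return a `ph_hypothesis`.
#' @export
#' @examples
#' ligs <- dplyr::bind_rows(
#'   features("A", 0, 0, 0, ligand_id = "l1"),
#'   features("A", 0.5, 0, 0, ligand_id = "l2"))
#' build_hypothesis(ligs, min_fraction = 1, tolerance = 2)
build_hypothesis <- function(feat, min_fraction = 0.5, tolerance = 2.0,
                             max_sites = NULL, n_ligands = NULL,
                             id = "consensus", frame = "unspecified") {
  validate_features(feat)
  if (nrow(feat) == 0) abort("empty ligand set: no features to cluster")
  if (min_fraction > 1 || min_fraction <= 0) {
    abort("min_fraction must be in (0, 1]", class = "pf_parameter_error")
  }
  assert_scalar_number(tolerance, "tolerance", lower = 1e-12)
  n_ligands <- n_ligands %||% n_distinct(feat$ligand_id)
  if (n_ligands < 1) abort("empty ligand set")

  sites <- list()
  for (tp in sort(unique(feat$type))) {
    cl <- cluster_features(feat[feat$type == tp, , drop = FALSE], tolerance)
    for (i in seq_len(nrow(cl))) {
      support <- cl$n_ligands[i] / n_ligands
      if (support + 1e-12 < min_fraction) next
      dir <- cluster_direction(cl$members[[i]])
      sites[[length(sites) + 1L]] <- tibble(
        type = tp, x = cl$x[i], y = cl$y[i], z = cl$z[i],
        radius = tolerance, support = min(support, 1),
        dx = dir[1], dy = dir[2], dz = dir[3]
      )
    }
  }
  if (!length(sites)) {
    abort(sprintf("no cluster reaches min_fraction %.3g (N = %d ligands)", min_fraction, n_ligands),
          class = "pf_no_sites")
  }
  sites <- canonical_site_order(bind_rows(sites))
  sites <- merge_overlapping_sites(sites, tolerance)
  if (!is.null(max_sites) && nrow(sites) > max_sites) {
    sites <- canonical_site_order(sites)[seq_len(max_sites), , drop = FALSE]
  }
  hypothesis(sites, id = id, frame = frame,
             min_fraction = min_fraction, tolerance = tolerance)
}

# same-type sites with centroids closer than the tolerance collapse to the
# higher-support one (sites arrive support-descending)
merge_overlapping_sites <- function(sites, tolerance) {
  keep <- rep(TRUE, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (!keep[i]) next
    if (i < nrow(sites)) for (j in (i + 1):nrow(sites)) {
      if (!keep[j] || sites$type[j] != sites$type[i]) next
      d <- sqrt(sum((c(sites$x[i], sites$y[i], sites$z[i]) -
                     c(sites$x[j], sites$y[j], sites$z[j]))^2))
      if (d < tolerance) keep[j] <- FALSE
    }
  }
  sites[keep, , drop = FALSE]
}
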