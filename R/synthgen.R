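# Synthetic fixtures: planted hypotheses, jittered prealigned ligand feature
# sets with controlled per-site ligand support, guaranteed-non-matching
# decoys and toy screening libraries. Fixtures operate at the feature-cloud
# level so algorithmic behaviour (clustering, matching, the funnel) is
# testable independently of chemistry perception. They emulate the
# statistical structure of a co-crystal ligand panel: a few anchor sites
# shared by most ligands, peripheral sites contributed by a minority,
# Gaussian positional jitter.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Specification for a planted synthetic study
#'
#' Defines the conditions a synthetic ligand panel emulates: number and
#' types of consensus sites, panel size, which ligand supports which site,
#' positional jitter and per-ligand noise features.
#'
#' @param n_sites number of planted sites.
#' @param types feature-type multiset of the sites (default the five-point
#'   acceptor/acceptor/donor/hydrophobe/ring pattern `A A D H R`).
#' @param n_ligands number of ligands in the panel.
#' @param support per-site ligand-support fractions (recycled to
#'   `n_sites`), or a full `n_ligands x n_sites` logical matrix.
#' @param jitter_sigma isotropic Gaussian jitter of supported features
#'   (angstrom).
#' @param n_noise number of random off-site noise features per ligand.
#' @param tolerance build tolerance the panel is designed for (sets site
#'   radii and the noise exclusion zone).
#' @param box edge length of the cubic placement box (angstrom).
#' @param min_separation minimum pairwise site separation (angstrom); must
#'   exceed `2 * jitter_sigma + tolerance` so planted sites cannot blur into
#'   one another.
#' @param seed integer seed; every derived quantity is deterministic in it.
#' @return a `ph_plantspec` list.
#' @export
plant_spec <- function(n_sites = 5L, types = c("A", "A", "D", "H", "R"),
                       n_ligands = 20L, support = 1.0, jitter_sigma = 0.3,
                       n_noise = 0L, tolerance = 2.5, box = 20,
                       min_separation = 6, seed = 1L) {
  stopifnot(length(types) == n_sites, all(types %in% feature_type_codes))
  assert_scalar_number(jitter_sigma, "jitter_sigma", lower = 0)
  assert_scalar_number(tolerance, "tolerance", lower = 1e-12)
  if (min_separation <= 2 * jitter_sigma + tolerance) {
    abort("min_separation must exceed 2 * jitter_sigma + tolerance")
  }
  if (is.matrix(support)) {
    stopifnot(nrow(support) == n_ligands, ncol(support) == n_sites)
    smat <- support
  } else {
    fr <- rep_len(support, n_sites)
    stopifnot(all(fr > 0 & fr <= 1))
    smat <- with_seed(seed + 1000L, {
      vapply(seq_len(n_sites), function(j) {
        k <- max(1L, round(fr[j] * n_ligands))
        seq_len(n_ligands) %in% sample.int(n_ligands, k)
      }, logical(n_ligands))
    })
    if (n_ligands == 1L) smat <- matrix(smat, nrow = 1L)
  }
  structure(list(n_sites = as.integer(n_sites), types = types,
                 n_ligands = as.integer(n_ligands), support = smat,
                 jitter_sigma = jitter_sigma, n_noise = as.integer(n_noise),
                 tolerance = tolerance, box = box,
                 min_separation = min_separation, seed = as.integer(seed)),
            class = "ph_plantspec")
}

#' Plant a synthetic hypothesis
#'
#' Places `n_sites` typed sites uniformly in the box by rejection sampling
#' until all pairwise separations reach `min_separation`; directed types
#' (A, D, R) receive random unit directions. Deterministic in the spec
#' seed.
#'
#' @param spec a [plant_spec()].
#' @return a `ph_hypothesis` with `frame = "synthetic"`; site supports are
#'   the design fractions of the spec's support matrix.
#' @export
plant_hypothesis <- function(spec) {
  stopifnot(inherits(spec, "ph_plantspec"))
  with_seed(spec$seed, {
    pos <- NULL
    for (try in seq_len(5000L)) {
      cand <- matrix(runif(3 * spec$n_sites, 0, spec$box), ncol = 3)
      if (spec$n_sites < 2 || min(dist(cand)) >= spec$min_separation) { pos <- cand; break }
    }
    if (is.null(pos)) {
      abort("could not place sites at the requested separation inside the box")
    }
    dirs <- matrix(NA_real_, spec$n_sites, 3)
    for (j in seq_len(spec$n_sites)) {
      if (spec$types[j] %in% c("A", "D", "R")) {
        dirs[j, ] <- unitize(rnorm(3))
      }
    }
    sites <- tibble(
      type = spec$types, x = pos[, 1], y = pos[, 2], z = pos[, 3],
      radius = spec$tolerance,
      support = pmin(1, colMeans(matrix(spec$support, ncol = spec$n_sites))),
      dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3]
    )
    hypothesis(sites, id = sprintf("planted_seed%d", spec$seed), frame = "synthetic",
               min_fraction = 0.25, tolerance = spec$tolerance)
  })
}

# rotate a unit vector by a small random angle (sd_deg) about a random axis
perturb_direction <- function(d, sd_deg = 10) {
  ang <- rnorm(1, 0, sd_deg * pi / 180)
  axis <- unitize(rnorm(3))
  # Rodrigues rotation
  d * cos(ang) + pracma_cross(axis, d) * sin(ang) + axis * sum(axis * d) * (1 - cos(ang))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Sample a jittered prealigned ligand set from a planted hypothesis
#'
#' Each ligand contributes one feature per supported site at the site
#' position plus isotropic Gaussian jitter, with the site direction
#' perturbed by a small angular noise; `n_noise` additional features of
#' random type are placed at least `2 * tolerance` away from every site.
#'
#' @param hyp the planted `ph_hypothesis` (site order must match the spec's
#'   support matrix columns, i.e. come from [plant_hypothesis()] of the same
#'   spec).
#' @param spec the matching [plant_spec()].
#' @return feature tibble (ligands `lig01`, `lig02`, ...) with attribute
#'   `n_ligands`.
#' @export
sample_ligandset <- function(hyp, spec) {
  stopifnot(inherits(hyp, "ph_hypothesis"), inherits(spec, "ph_plantspec"))
  if (nrow(hyp$sites) != spec$n_sites) abort("hypothesis/spec site count mismatch")
  sx <- site_xyz(hyp)
  with_seed(spec$seed + 1L, {
    out <- list()
    for (i in seq_len(spec$n_ligands)) {
      lid <- sprintf("lig%02d", i)
      for (j in seq_len(spec$n_sites)) {
        if (!spec$support[i, j]) next
        p <- unname(sx[j, ]) + rnorm(3, 0, spec$jitter_sigma)
        d <- rep(NA_real_, 3)
        if (!is.na(hyp$sites$dx[j])) {
          d <- perturb_direction(c(hyp$sites$dx[j], hyp$sites$dy[j], hyp$sites$dz[j]))
          d <- unitize(d)
        }
        out[[length(out) + 1L]] <- tibble(
          type = hyp$sites$type[j], x = p[1], y = p[2], z = p[3],
          dx = d[1], dy = d[2], dz = d[3], ligand_id = lid,
          atom_idx = list(NA_integer_))
      }
      if (spec$n_noise > 0) {
        for (k in seq_len(spec$n_noise)) {
          repeat {
            p <- runif(3, -0.5 * spec$box, 1.5 * spec$box)
            if (min(sqrt(rowSums(sweep(sx, 2, p)^2))) >= 2 * spec$tolerance) break
          }
          out[[length(out) + 1L]] <- tibble(
            type = sample(spec$types, 1), x = p[1], y = p[2], z = p[3],
            dx = NA_real_, dy = NA_real_, dz = NA_real_, ligand_id = lid,
            atom_idx = list(NA_integer_))
        }
      }
    }
    ft <- arrange_features(bind_rows(out))
    attr(ft, "n_ligands") <- spec$n_ligands
    ft
  })
}

# one synthetic compound that matches every site (features at the sites with
# small in-radius jitter), as a feature table in the hypothesis frame
matching_feature_set <- function(hyp, id, jitter = 0.2) {
  sx <- site_xyz(hyp)
  p <- sx + matrix(rnorm(length(sx), 0, jitter), ncol = 3)
  tibble(type = hyp$sites$type, x = p[, 1], y = p[, 2], z = p[, 3],
         dx = hyp$sites$dx, dy = hyp$sites$dy, dz = hyp$sites$dz,
         ligand_id = id, atom_idx = rep(list(NA_integer_), nrow(sx)))
}

#' Generate feature sets guaranteed not to match a hypothesis
#'
#' Decoys are built from a full matcher either by deleting every feature of
#' one type (pigeonhole: at most `n_sites - 1` can match) or by displacing
#' one feature far outside every same-type tolerance sphere. Every decoy is
#' verified non-matching (best matched count < number of sites) by the
#' brute-force oracle before being emitted.
#'
#' @param hyp a `ph_hypothesis` with at most 6 sites (oracle bound).
#' @param n number of decoys.
#' @param seed integer seed.
#' @return list of `n` feature tibbles, named `decoy1 ... decoyn`.
#' @export
make_decoy_set <- function(hyp, n, seed = 1L) {
  stopifnot(inherits(hyp, "ph_hypothesis"))
  m <- nrow(hyp$sites)
  if (m > 6) abort("decoy verification needs <= 6 sites (brute-force oracle bound)")
  sx <- site_xyz(hyp)
  with_seed(seed, {
    out <- vector("list", n)
    for (k in seq_len(n)) {
      id <- sprintf("decoy%d", k)
      for (try in seq_len(200L)) {
        base <- matching_feature_set(hyp, id, jitter = 0.15)
        if (k %% 2 == 1L) {
          # displacement decoy: push one feature outside every same-type sphere
          j <- ((k - 1L) %/% 2L) %% m + 1L
          same <- which(hyp$sites$type == hyp$sites$type[j])
          repeat {
            p <- sx[j, ] + unitize(rnorm(3)) * (2.5 * max(hyp$sites$radius))
            if (min(sqrt(rowSums(sweep(sx[same, , drop = FALSE], 2, p)^2))) >
                2 * max(hyp$sites$radius)) break
          }
          base$x[j] <- p[1]; base$y[j] <- p[2]; base$z[j] <- p[3]
          cand <- base
        } else {
          # deletion decoy: remove an entire feature type
          tp <- hyp$sites$type[((k - 1L) %/% 2L) %% m + 1L]
          cand <- base[base$type != tp, , drop = FALSE]
        }
        ok_in <- brute_force_match(cand, hyp, min_match = 1L, mode = "inplace") < m
        ok_al <- brute_force_match(cand, hyp, min_match = 3L, mode = "aligned") < m
        if (ok_in && ok_al) { out[[k]] <- cand; break }
      }
      if (is.null(out[[k]])) abort("failed to construct a verified decoy")
    }
    names(out) <- sprintf("decoy%d", seq_len(n))
    out
  })
}

#' Build a synthetic screening library around a hypothesis
#'
#' `n_match` compounds that satisfy every site (each handed to stage 1 in a
#' random rigid frame, with the in-frame copy kept as its docking pose) and
#' `n_decoy` verified decoys. Used to exercise the funnel end to end without
#' chemistry.
#'
#' @param hyp a `ph_hypothesis` (<= 6 sites).
#' @param n_match,n_decoy library composition.
#' @param seed integer seed.
#' @return list with `library` (flat feature table with `compound_id`,
#'   `conformer_id` columns, frames randomised), `poses` (flat feature
#'   table in the hypothesis frame, `pose_id` column) and `truth` (tibble of
#'   compound ids and planted labels).
#' @export
synth_screen_library <- function(hyp, n_match = 3L, n_decoy = 7L, seed = 1L) {
  decoys <- make_decoy_set(hyp, n_decoy, seed = seed + 7L)
  with_seed(seed, {
    lib <- list(); poses <- list(); truth <- list()
    for (i in seq_len(n_match)) {
      id <- sprintf("hit%d", i)
      ft <- matching_feature_set(hyp, id, jitter = 0.2)
      pose <- ft
      moved <- transform_features(ft, random_rotation(), runif(3, -20, 20))
      moved$compound_id <- id; moved$conformer_id <- paste0(id, "/1")
      pose$compound_id <- id; pose$pose_id <- paste0(id, "#1")
      lib[[length(lib) + 1L]] <- moved
      poses[[length(poses) + 1L]] <- pose
      truth[[length(truth) + 1L]] <- tibble(compound_id = id, planted_match = TRUE)
    }
    for (k in seq_along(decoys)) {
      id <- names(decoys)[k]
      ft <- decoys[[k]]
      pose <- ft
      moved <- transform_features(ft, random_rotation(), runif(3, -20, 20))
      moved$compound_id <- id; moved$conformer_id <- paste0(id, "/1")
      pose$compound_id <- id; pose$pose_id <- paste0(id, "#1")
      lib[[length(lib) + 1L]] <- moved
      poses[[length(poses) + 1L]] <- pose
      truth[[length(truth) + 1L]] <- tibble(compound_id = id, planted_match = FALSE)
    }
    list(library = bind_rows(lib), poses = bind_rows(poses), truth = bind_rows(truth))
  })
}

#' Synthetic co-crystal panel emulating the published study conditions
#'
#' A 20-ligand prealigned panel over a five-site A/A/D/H/R hypothesis whose
#' per-site ligand supports follow the narrative of structure-based
#' consensus modelling on soluble epoxide hydrolase co-crystal ligands: the
#' urea-mimicking acceptor/donor anchors present in nearly all binders
#' (supports 0.95 and 0.85), an aromatic stacking feature in a majority
#' (0.60), and peripheral acceptor/hydrophobe features in a minority (0.45,
#' 0.35). Building a consensus model on this panel yields five sites at the
#' permissive parameters (min_fraction 0.25, tolerance 2.5) and three at
#' the defaults (0.5, 2.0).
#'
#' @param seed integer seed.
#' @return list with `spec`, the planted `hypothesis`, and the `ligands`
#'   feature table.
#' @export
synth_cocrystal_panel <- function(seed = 1L) {
  spec <- plant_spec(
    n_sites = 5L, types = c("A", "D", "R", "A", "H"), n_ligands = 20L,
    support = c(0.95, 0.85, 0.60, 0.45, 0.35),
    jitter_sigma = 0.3, n_noise = 1L, tolerance = 2.5, seed = seed
  )
  hyp <- plant_hypothesis(spec)
  list(spec = spec, hypothesis = hyp, ligands = sample_ligandset(hyp, spec))
}
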