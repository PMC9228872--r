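test_that("Kabsch superposition recovers transforms and refuses reflections", {
  set.seed(1)
  P <- matrix(rnorm(15), 5, 3)
  f0 <- kabsch(P, P)
  expect_equal(f0$rmsd, 0, tolerance = 1e-12)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-9)

  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  f1 <- kabsch(P, P %*% Rz)
  expect_lt(f1$rmsd, 1e-9)
  expect_equal(f1$rotation, Rz, tolerance = 1e-6)

  # chiral tetrahedron vs its mirror image: proper rotations cannot fix it
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.2, 0), c(0, 0, 1.7))
  f2 <- kabsch(tet, tet %*% diag(c(-1, 1, 1)))
  expect_gt(f2$rmsd, 0.1)
  expect_equal(det(f2$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch(P[1:2, ], P[1:2, ]), "n >= 3")
})

test_that("in-place matching finds exact hits and respects the tolerance boundary", {
  spec <- plant_spec(n_sites = 5, n_ligands = 4, support = 1, jitter_sigma = 0.1,
                     tolerance = 2.0, seed = 11)
  h <- plant_hypothesis(spec)
  exact <- features(h$sites$type, h$sites$x, h$sites$y, h$sites$z,
                    dx = h$sites$dx, dy = h$sites$dy, dz = h$sites$dz,
                    ligand_id = "exact")
  r <- match_inplace(exact, h, min_match = 5)
  expect_equal(r$matched_count, 5L)
  expect_equal(r$rmsd_match, 0, tolerance = 1e-12)
  expect_equal(r$fit_score, 1.0, tolerance = 1e-9)
  expect_true(all(tidy(r)$dist <= tidy(h)$radius[tidy(r)$site] + 1e-9))

  # push one feature just past its radius: that site becomes unmatchable
  off <- exact
  j <- which(off$type == "D")[1]
  off$x[j] <- off$x[j] + h$sites$radius[1] + 0.1  # only one D site exists
  r_off <- match_inplace(off, h, min_match = 1)
  expect_equal(r_off$matched_count, 4L)
  expect_null(match_inplace(off, h, min_match = 5))
})

test_that("aligned matching is invariant to rigid motion of the query", {
  spec <- plant_spec(n_sites = 5, n_ligands = 4, support = 1, jitter_sigma = 0.1,
                     tolerance = 2.0, seed = 21)
  h <- plant_hypothesis(spec)
  base <- pharmfunnel:::with_seed(5, pharmfunnel:::matching_feature_set(h, "q", jitter = 0.3))
  r0 <- match_aligned(base, h, min_match = 3)
  expect_equal(r0$matched_count, 5L)
  for (s in 1:10) {
    set.seed(s)
    moved <- transform_features(base, random_rotation(), rnorm(3, sd = 15))
    r <- match_aligned(moved, h, min_match = 3)
    expect_equal(r$matched_count, r0$matched_count)
    expect_equal(r$rmsd_match, r0$rmsd_match, tolerance = 1e-6)
  }
})

test_that("a chiral four-point arrangement does not match its mirror image", {
  sites <- tibble::tibble(
    type = c("A", "D", "H", "R"),
    x = c(0, 4, 0, 0), y = c(0, 0, 5, 0), z = c(0, 0, 0, 6),
    radius = 0.5, support = 1)
  h <- hypothesis(sites, tolerance = 0.5)
  mirror <- features(sites$type, -sites$x, sites$y, sites$z, ligand_id = "mirror")
  r <- match_aligned(mirror, h, min_match = 3)
  expect_lt(matched_or_zero(r), 4L)
  straight <- features(sites$type, sites$x, sites$y, sites$z, ligand_id = "ok")
  expect_equal(match_aligned(straight, h, min_match = 4)$matched_count, 4L)
})

test_that("both matchers agree with brute-force enumeration on random instances", {
  for (s in 1:100) {
    inst <- random_instance(s)
    bf_in <- brute_force_match(inst$ft, inst$h, min_match = 1, mode = "inplace")
    expect_equal(matched_or_zero(match_inplace(inst$ft, inst$h, min_match = 1)),
                 bf_in, info = paste("inplace seed", s))
    bf_al <- brute_force_match(inst$ft, inst$h, min_match = 3, mode = "aligned")
    expect_equal(matched_or_zero(match_aligned(inst$ft, inst$h, min_match = 3)),
                 bf_al, info = paste("aligned seed", s))
  }
})

test_that("brute-force oracle handles its stated edge cases and bounds", {
  h <- hypothesis(tibble::tibble(type = c("A", "D", "R"), x = c(0, 5, 0),
                                 y = c(0, 0, 5), z = 0, radius = 1, support = 1))
  empty <- features(character(0), numeric(0), numeric(0), numeric(0),
                    ligand_id = character(0))
  expect_equal(brute_force_match(empty, h, 1, "inplace"), 0L)
  same <- features(c("A", "D", "R"), c(0, 5, 0), c(0, 0, 5), 0, ligand_id = "x")
  expect_equal(brute_force_match(same, h, 3, "inplace"), 3L)
  big <- features(rep("A", 8), 1:8, 0, 0, ligand_id = "x")
  expect_error(brute_force_match(big, h, 1, "inplace"), "7 features")
})

test_that("inflating site radii never decreases the matched count", {
  for (s in 1:100) {
    inst <- random_instance(s + 300)
    h_big <- inst$h
    h_big$sites$radius <- h_big$sites$radius * runif(1, 1.1, 2)
    for (mode in c("inplace", "aligned")) {
      mm <- if (mode == "aligned") 3L else 1L
      fn <- if (mode == "aligned") match_aligned else match_inplace
      expect_gte(matched_or_zero(fn(inst$ft, h_big, min_match = mm)),
                 matched_or_zero(fn(inst$ft, inst$h, min_match = mm)))
    }
  }
})

test_that("an in-place k-site match implies an aligned match of at least k", {
  for (s in 1:60) {
    inst <- random_instance(s + 700)
    k <- matched_or_zero(match_inplace(inst$ft, inst$h, min_match = 1))
    if (k < 3) next
    expect_gte(matched_or_zero(match_aligned(inst$ft, inst$h, min_match = 3)), k)
  }
  succeed()  # the loop itself finding no >=3 in-place matches is not a failure
})

test_that("every reported pair distance sits inside its tolerance sphere", {
  for (s in 1:40) {
    inst <- random_instance(s + 1100)
    for (r in list(match_inplace(inst$ft, inst$h, min_match = 1),
                   match_aligned(inst$ft, inst$h, min_match = 3))) {
      if (is.null(r)) next
      expect_true(all(tidy(r)$dist <= inst$h$sites$radius[tidy(r)$site] + 1e-9))
      expect_equal(r$matched_count, nrow(tidy(r)))
      expect_false(any(duplicated(tidy(r)$feature)))
      expect_false(any(duplicated(tidy(r)$site)))
      expect_true(all(inst$ft$type[tidy(r)$feature] == inst$h$sites$type[tidy(r)$site]))
    }
  }
})

test_that("the fit score follows its published formula", {
  h <- hypothesis(tibble::tibble(type = c("A", "D", "H"), x = c(0, 6, 0),
                                 y = c(0, 0, 6), z = 0, radius = 2, support = 1),
                  tolerance = 2)
  # rmsd = tolerance, no directional pairs -> 0.5
  ft <- features(c("A", "D", "H"), c(2, 8, 2), c(0, 0, 6), 0, ligand_id = "q")
  r <- match_inplace(ft, h, min_match = 3)
  expect_equal(r$rmsd_match, 2, tolerance = 1e-9)
  expect_equal(r$fit_score, 0.5, tolerance = 1e-9)

  # rmsd = tolerance/2 and one directional pair at 60 degrees:
  # 0.5*0.5 + 0.5*0.5 = 0.5
  h2 <- hypothesis(tibble::tibble(type = c("A", "D", "H"), x = c(0, 6, 0),
                                  y = c(0, 0, 6), z = 0, radius = 2, support = 1,
                                  dx = c(1, NA, NA), dy = c(0, NA, NA), dz = c(0, NA, NA)),
                   tolerance = 2)
  ft2 <- features(c("A", "D", "H"), c(1, 7, 1), c(0, 0, 6), 0,
                  dx = c(cos(pi / 3), NA, NA), dy = c(sin(pi / 3), NA, NA),
                  dz = c(0, NA, NA), ligand_id = "q")
  r2 <- match_inplace(ft2, h2, min_match = 3)
  expect_equal(r2$rmsd_match, 1, tolerance = 1e-9)
  expect_equal(r2$fit_score, 0.5, tolerance = 1e-9)
})

test_that("conformer ensembles are capped, deterministic and duplicate-free", {
  b <- generate_conformers(mol_from_smiles("c1ccccc1", "benzene"), max_confs = 50, seed = 7)
  expect_equal(length(b$conformers), 1)  # rigid molecule collapses to one

  c5a <- generate_conformers(mol_from_smiles(compound5_smiles, "cmpd5"), 50, seed = 7)
  c5b <- generate_conformers(mol_from_smiles(compound5_smiles, "cmpd5"), 50, seed = 7)
  expect_gt(length(c5a$conformers), 1)
  expect_lte(length(c5a$conformers), 50)
  expect_identical(c5a$conformers, c5b$conformers)

  # pairwise heavy-atom RMSD of kept conformers stays >= the pruning cutoff
  heavy <- c5a$atoms$element != "H"
  n <- length(c5a$conformers)
  for (i in seq_len(min(n, 5))) for (j in seq_len(min(n, 5))) {
    if (i >= j) next
    expect_gte(kabsch(c5a$conformers[[i]][heavy, ], c5a$conformers[[j]][heavy, ])$rmsd, 0.5)
  }

  bad <- suppressWarnings(generate_conformers(mol("impossible", "C"), 10, 1))
  expect_equal(length(bad$conformers), 0)
  expect_true(isTRUE(attr(bad, "embed_failed")))
})
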