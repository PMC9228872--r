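# independent average-linkage oracle: full dendrogram by exhaustive merging,
# cut so no merge exceeds the tolerance
brute_average_linkage <- function(xyz, tolerance) {
  clusters <- as.list(seq_len(nrow(xyz)))
  repeat {
    if (length(clusters) == 1) break
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- mean(as.matrix(dist(xyz))[clusters[[i]], clusters[[j]]])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    if (best_d > tolerance) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  clusters
}

test_that("feature clustering honours the tolerance cut", {
  two <- features("A", c(0, 1), 0, 0, ligand_id = c("l1", "l2"))
  cl <- cluster_features(two, tolerance = 2.5)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$x, cl$y, cl$z), c(0.5, 0, 0))
  expect_equal(cl$n_ligands, 2L)

  far <- features("A", c(0, 6), 0, 0, ligand_id = c("l1", "l2"))
  expect_equal(nrow(cluster_features(far, tolerance = 2.5)), 2)

  expect_equal(nrow(cluster_features(two[0, ], 2.5)), 0)
  expect_error(cluster_features(features(c("A", "D"), 1:2, 0, 0), 2.5),
               "single feature type")
})

test_that("clustering agrees with an exhaustive average-linkage oracle", {
  # collinear points at 2 A spacing, tolerance 2.5 — the chaining trap
  line <- features("A", c(0, 2, 4, 6, 8), 0, 0,
                   ligand_id = paste0("l", 1:5))
  cl <- cluster_features(line, 2.5)
  oracle <- brute_average_linkage(feat_xyz(line), 2.5)
  expect_equal(sort(cl$n_members), sort(lengths(oracle)))
  expect_setequal(
    lapply(cl$members, function(m) sort(m$x)),
    lapply(oracle, function(idx) sort(line$x[idx])))

  for (s in 1:20) {
    set.seed(s)
    n <- sample(3:9, 1)
    pool <- features("D", runif(n, 0, 10), runif(n, 0, 10), runif(n, 0, 10),
                     ligand_id = paste0("l", seq_len(n)))
    tol <- runif(1, 1, 4)
    cl <- cluster_features(pool, tol)
    oracle <- brute_average_linkage(feat_xyz(pool), tol)
    expect_equal(sort(cl$n_members), sort(lengths(oracle)), info = paste("seed", s))
  }
})

test_that("a single ligand yields one full-support site per feature", {
  ft <- dplyr::bind_rows(
    features("A", 0, 0, 0, ligand_id = "only"),
    features("D", 8, 0, 0, ligand_id = "only"),
    features("R", 0, 8, 0, ligand_id = "only"))
  h <- build_hypothesis(ft, min_fraction = 1.0, tolerance = 2.0)
  expect_equal(nrow(h$sites), 3)
  expect_true(all(h$sites$support == 1.0))
  expect_true(all(h$sites$radius == 2.0))
})

test_that("ligand support controls which clusters survive", {
  # a planted acceptor present in 2 of 4 ligands
  ft <- dplyr::bind_rows(
    features("A", c(0.1, -0.1), 0, 0, ligand_id = c("l1", "l2")),
    features("D", 10, c(0, 0.2, -0.2, 0.1), 0, ligand_id = paste0("l", 1:4)))
  h <- build_hypothesis(ft, min_fraction = 0.25, tolerance = 2.5, n_ligands = 4)
  a_site <- h$sites[h$sites$type == "A", ]
  expect_equal(nrow(a_site), 1)
  expect_equal(a_site$support, 0.5)
  h2 <- build_hypothesis(ft, min_fraction = 0.6, tolerance = 2.5, n_ligands = 4)
  expect_false("A" %in% h2$sites$type)
  # a ligand with two nearby donors cannot double-vote
  dd <- dplyr::bind_rows(
    features("D", c(0, 0.3), 0, 0, ligand_id = "l1"),
    features("D", 0.1, 0.1, 0, ligand_id = "l2"))
  h3 <- build_hypothesis(dd, min_fraction = 0.5, tolerance = 2.0, n_ligands = 4)
  expect_equal(h3$sites$support, 0.5)
})

test_that("support threshold is monotone: higher min_fraction, nested site sets", {
  for (s in 1:30) {
    spec <- plant_spec(n_sites = 4, types = c("A", "D", "H", "R"), n_ligands = 10,
                       support = runif(4, 0.2, 1), jitter_sigma = 0.2,
                       tolerance = 2.0, min_separation = 6, seed = s)
    ligs <- sample_ligandset(plant_hypothesis(spec), spec)
    sites_at <- function(f) {
      tryCatch(tidy(build_hypothesis(ligs, f, 2.0, n_ligands = 10))[, c("type", "x")],
               error = function(e) NULL)
    }
    lo <- sites_at(0.25); hi <- sites_at(0.6)
    n_lo <- if (is.null(lo)) 0L else nrow(lo)
    n_hi <- if (is.null(hi)) 0L else nrow(hi)
    expect_lte(n_hi, n_lo)
    if (n_hi > 0) {
      expect_true(all(round(hi$x, 9) %in% round(lo$x, 9)), info = paste("seed", s))
    }
  }
})

test_that("larger tolerance never increases the cluster count", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(2:20, 1)
    pool <- features("H", runif(n, 0, 15), runif(n, 0, 15), runif(n, 0, 15),
                     ligand_id = paste0("l", seq_len(n)))
    t1 <- runif(1, 0.5, 3); t2 <- t1 + runif(1, 0.1, 2)
    expect_lte(nrow(cluster_features(pool, t2)), nrow(cluster_features(pool, t1)))
  }
})

test_that("planted five-site models are recovered from 20 jittered ligands", {
  hits <- 0L
  for (s in 1:50) {
    spec <- plant_spec(n_sites = 5, types = c("A", "A", "D", "H", "R"),
                       n_ligands = 20, support = runif(5, 0.5, 1),
                       jitter_sigma = 0.3, tolerance = 2.5, seed = s)
    hyp <- plant_hypothesis(spec)
    ligs <- sample_ligandset(hyp, spec)
    rebuilt <- tryCatch(build_hypothesis(ligs, 0.25, 2.5, n_ligands = 20),
                        error = function(e) NULL)
    if (is.null(rebuilt) || nrow(rebuilt$sites) != 5) next
    devs <- vapply(seq_len(5), function(j) {
      same <- which(rebuilt$sites$type == hyp$sites$type[j])
      min(sqrt((rebuilt$sites$x[same] - hyp$sites$x[j])^2 +
               (rebuilt$sites$y[same] - hyp$sites$y[j])^2 +
               (rebuilt$sites$z[same] - hyp$sites$z[j])^2))
    }, numeric(1))
    if (max(devs) <= 0.5) hits <- hits + 1L
  }
  expect_gte(hits, 48L)  # >= 95% of 50 seeds
})

test_that("ligand input order is irrelevant to the built model", {
  spec <- plant_spec(n_sites = 5, n_ligands = 12, support = 0.8,
                     jitter_sigma = 0.3, tolerance = 2.5, seed = 4)
  ligs <- sample_ligandset(plant_hypothesis(spec), spec)
  h1 <- build_hypothesis(ligs, 0.25, 2.5, n_ligands = 12)
  set.seed(99)
  shuf <- ligs[sample.int(nrow(ligs)), ]
  h2 <- build_hypothesis(shuf, 0.25, 2.5, n_ligands = 12)
  expect_equal(h1$sites, h2$sites, tolerance = 1e-12)
})

test_that("degenerate build inputs raise typed errors", {
  expect_error(build_hypothesis(features(character(0), numeric(0), numeric(0),
                                         numeric(0), ligand_id = character(0))),
               "empty")
  ft <- features("A", 0, 0, 0, ligand_id = "l1")
  expect_error(build_hypothesis(ft, min_fraction = 1.5), class = "pf_parameter_error")
  # max_sites caps by support
  spec <- plant_spec(n_sites = 5, n_ligands = 10, support = c(1, 0.9, 0.8, 0.7, 0.6),
                     jitter_sigma = 0.1, tolerance = 2.0, seed = 2)
  ligs <- sample_ligandset(plant_hypothesis(spec), spec)
  h <- build_hypothesis(ligs, 0.25, 2.0, max_sites = 3, n_ligands = 10)
  expect_equal(nrow(h$sites), 3)
  expect_true(all(h$sites$support >= 0.7 - 1e-9))
})
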