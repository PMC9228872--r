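test_that("SMILES files read one molecule per record, skipping bad records", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines("c1ccccc1 benzene", f)
  tb <- read_molecules(f, "smiles")
  expect_equal(nrow(tb), 1)
  expect_equal(tb$id, "benzene")
  expect_equal(tb$n_heavy, 6L)
  expect_equal(tb$n_conformers, 0L)

  writeLines(c("CCO ethanol", "xx((bad", "CC(=O)O acetic"), f)
  expect_warning(tb2 <- read_molecules(f, "smiles"), "skipped 1")
  expect_equal(nrow(tb2), 2)
  expect_equal(attr(tb2, "n_skipped"), 1L)

  expect_error(read_molecules(file.path(tempdir(), "absent.smi"), "smiles"),
               class = "pf_io_error")
  writeLines("notasmiles((", f)
  expect_error(suppressWarnings(read_molecules(f, "smiles")), class = "pf_empty_input")
})

test_that("the three scaffold acids parse with the expected composition", {
  f <- system.file("extdata", "scaffolds.smi", package = "pharmfunnel")
  tb <- read_molecules(f, "smiles")
  expect_equal(tb$id, c("2a", "2b", "2c"))
  # quinazoline-2,4-dione core (12 heavy) + acid CO2 (3) + 4/5/6 chain carbons
  expect_equal(tb$n_heavy, c(19L, 20L, 21L))
  for (m in tb$mol) {
    expect_equal(sum(m$atoms$element == "N"), 2L)
    expect_equal(sum(m$atoms$element == "O"), 4L)
  }
})

test_that("SDF reading preserves coordinates and skips corrupt records", {
  b <- benzene_fixture()
  good <- mol_to_sdf(b)
  corrupt <- c("broken", " x", "", "  not a counts line", "$$$$")
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(good, corrupt, good), f)
  expect_warning(tb <- read_molecules(f, "sdf"), "skipped 1")
  expect_equal(nrow(tb), 2)
  expect_equal(attr(tb, "n_skipped"), 1L)
  expect_equal(tb$mol[[1]]$conformers[[1]], unname(hexagon_xyz()), tolerance = 1e-4)
})

test_that("ligand extraction returns the crystal-frame HETATM copy requested", {
  f <- withr::local_tempfile(fileext = ".pdb")
  fx <- synthetic_complex_pdb(f, chains = c("A", "B"))
  expect_warning(m <- extract_ligand(f, "BSU"), "chains A,B")
  expect_equal(n_heavy(m), 16L)  # 1,3-diphenylurea: C13 + N2 + O1
  expect_equal(length(m$conformers), 1)

  # coordinates bit-equal to the file's printed HETATM values
  ref <- round(fx$mol$conformers[[1]][fx$heavy, ], 3)
  expect_identical(m$conformers[[1]], unname(ref))

  mB <- extract_ligand(f, "BSU", chain = "B")
  expect_equal(mB$conformers[[1]][, 1] - m$conformers[[1]][, 1],
               rep(25, n_heavy(m)))

  expect_error(extract_ligand(f, "XYZ"), class = "pf_not_found")
  expect_error(extract_ligand(f, "HOH"), class = "pf_not_found")

  # a file with no HETATM at all
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    EMPTY", "END"), f2)
  expect_error(extract_ligand(f2, "BSU"), class = "pf_not_found")
})

test_that("superposition recovers rigid transforms on alpha-carbon anchors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  synthetic_complex_pdb(f)
  p1 <- bio3d::read.pdb(f)
  s0 <- superpose(p1, p1)
  expect_equal(s0$rmsd, 0, tolerance = 1e-9)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)

  # 90 degrees about z plus a shift
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  p2 <- p1
  p2$atom[, c("x", "y", "z")] <-
    as.matrix(p1$atom[, c("x", "y", "z")]) %*% Rz +
    matrix(c(1, 2, 3), nrow(p1$atom), 3, byrow = TRUE)
  s <- superpose(p1, p2)
  expect_lt(s$rmsd, 1e-9)
  expect_equal(s$rotation, Rz, tolerance = 1e-6)
  expect_equal(s$translation, c(1, 2, 3), tolerance = 1e-6)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)

  # anchors matched by (chain, resno): 10 of 20 shared
  set.seed(3)
  A <- matrix(rnorm(60), 20, 3); rownames(A) <- paste0("A_", 1:20, "_")
  B <- matrix(rnorm(60), 20, 3); rownames(B) <- paste0("A_", 11:30, "_")
  s2 <- superpose(A, B)
  expect_equal(s2$n_anchors, 10L)
  expect_error(superpose(A[1:2, , drop = FALSE], A[1:2, , drop = FALSE]),
               class = "pf_insufficient_anchors")
})

test_that("superpose always returns a proper rotation, even on degenerate anchors", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(3:8, 1)
    P <- matrix(rnorm(3 * n), n, 3)
    if (s %% 2 == 0) P[, 3] <- 0          # planar sets
    Q <- P %*% diag(c(-1, 1, 1))          # mirrored target
    rownames(P) <- rownames(Q) <- paste0("A_", seq_len(n), "_")
    fit <- superpose(P, Q)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("hypothesis JSON round-trips exactly and rejects schema violations", {
  for (s in 1:100) {
    set.seed(s)
    m <- sample(1:7, 1)
    dirs <- matrix(NA_real_, m, 3)
    has <- runif(m) < 0.5
    for (i in which(has)) {
      v <- rnorm(3); dirs[i, ] <- v / sqrt(sum(v^2))
    }
    h <- hypothesis(
      tibble::tibble(type = sample(c("A", "D", "H", "N", "P", "R"), m, replace = TRUE),
                     x = rnorm(m, sd = 10), y = rnorm(m, sd = 10), z = rnorm(m, sd = 10),
                     radius = runif(m, 0.5, 3), support = runif(m, 0.05, 1),
                     dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3]),
      id = sprintf("h%d", s), frame = "synthetic",
      min_fraction = runif(1, 0.1, 1), tolerance = runif(1, 0.5, 3))
    f <- tempfile(fileext = ".json")
    write_hypothesis(h, f)
    h2 <- read_hypothesis(f)
    expect_equal(h2$sites, h$sites, tolerance = 1e-12)
    expect_identical(h2$id, h$id)
    expect_equal(h2$build_params, h$build_params, tolerance = 1e-12)
    unlink(f)
  }
})

test_that("hypothesis JSON errors name the offending field", {
  h <- hypothesis(tibble::tibble(type = "A", x = 1, y = 2, z = 3,
                                 radius = 2, support = 0.5))
  f <- withr::local_tempfile(fileext = ".json")
  write_hypothesis(h, f)
  doc <- jsonlite::read_json(f)
  doc$sites[[1]]$radius <- NULL
  jsonlite::write_json(doc, f, auto_unbox = TRUE, null = "null")
  expect_error(read_hypothesis(f), "radius", class = "pf_format_error")

  doc$sites <- list()
  jsonlite::write_json(doc, f, auto_unbox = TRUE, null = "null")
  expect_error(read_hypothesis(f), class = "pf_format_error")
})
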