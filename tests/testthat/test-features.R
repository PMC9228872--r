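test_that("reference molecules yield the documented feature counts", {
  # benzene as a regular hexagon: exactly one ring feature at the origin
  ft <- perceive_features(benzene_fixture())
  expect_equal(nrow(ft), 1)
  expect_equal(ft$type, "R")
  expect_equal(c(ft$x, ft$y, ft$z), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(abs(c(ft$dx, ft$dy, ft$dz)), c(0, 0, 1), tolerance = 1e-9)

  counts <- function(smi, id) feature_counts(mol_from_smiles(smi, id, gen3d = TRUE))
  # 1,3-diphenylurea: carbonyl O acceptor, two N-H donors, two phenyls,
  # no aliphatic group (urea N excluded from acceptors as amide-type N)
  expect_equal(counts("O=C(Nc1ccccc1)Nc1ccccc1", "BSU"),
               c(A = 1L, D = 2L, R = 2L))
  expect_equal(counts("CO", "methanol"), c(A = 1L, D = 1L))
  expect_equal(counts("c1ccncc1", "pyridine"), c(A = 1L, R = 1L))
  expect_equal(length(counts("C", "methane")), 0L)

  # n-hexane: one maximal aliphatic set of all six carbons, at their centroid
  hx <- mol_from_smiles("CCCCCC", "hexane", gen3d = TRUE)
  ft_h <- perceive_features(hx)
  expect_equal(ft_h$type, "H")
  carbons <- which(hx$atoms$element == "C")
  expect_equal(sort(ft_h$atom_idx[[1]]), carbons)
  expect_equal(c(ft_h$x, ft_h$y, ft_h$z),
               unname(colMeans(hx$conformers[[1]][carbons, ])), tolerance = 1e-9)
})

test_that("molecules without geometry are rejected, with a clear error", {
  m <- mol_from_smiles("CCO", "ethanol")
  expect_error(perceive_features(m), class = "pf_geometry_required")
})

test_that("feature positions and directions are equivariant under rigid motion", {
  bsu <- mol_from_smiles("O=C(Nc1ccccc1)Nc1ccccc1", "BSU", gen3d = TRUE)
  f0 <- perceive_features(bsu)
  for (s in 1:5) {
    set.seed(s)
    R <- random_rotation(); tv <- rnorm(3, sd = 5)
    m2 <- bsu
    m2$conformers[[1]] <- bsu$conformers[[1]] %*% R +
      matrix(tv, nrow(bsu$atoms), 3, byrow = TRUE)
    f1 <- perceive_features(m2)
    # expected: transform the original features, then canonical re-sort
    fx <- pharmfunnel:::arrange_features(transform_features(f0, R, tv))
    expect_equal(feat_xyz(f1), feat_xyz(fx), tolerance = 1e-9)
    expect_equal(f1$type, fx$type)
    for (i in seq_len(nrow(fx))) {
      if (is.na(fx$dx[i])) next
      d0 <- c(fx$dx[i], fx$dy[i], fx$dz[i])
      d1 <- c(f1$dx[i], f1$dy[i], f1$dz[i])
      # ring normals are axial: equality up to sign
      if (fx$type[i] == "R") {
        expect_lt(min(sum((d0 - d1)^2), sum((d0 + d1)^2)), 1e-16)
      } else {
        expect_equal(d0, d1, tolerance = 1e-9)
      }
    }
  }
})

test_that("perception is deterministic and atom sets obey the type contracts", {
  m <- mol_from_smiles("O=C(Nc1ccc(CCCC)cc1)CCCCO", "amide", gen3d = TRUE)
  f1 <- perceive_features(m)
  f2 <- perceive_features(m)
  expect_identical(f1, f2)
  for (i in seq_len(nrow(f1))) {
    idx <- f1$atom_idx[[i]]
    if (f1$type[i] %in% c("A", "D")) expect_length(idx, 1)
    if (f1$type[i] == "R") expect_length(idx, 6)
    if (f1$type[i] == "H") expect_gte(length(idx), 3)
  }
  # donors: one feature per heavy atom even with two hydrogens
  fN <- perceive_features(mol_from_smiles("NCC", "ethylamine", gen3d = TRUE))
  expect_equal(sum(fN$type == "D"), 1)
})

test_that("hydrophobic groups respect the C/H/halogen-only membership rule", {
  # chain carbons bonded to N or carbonyl C are excluded; the butyl tail
  # attached to an aromatic ring still qualifies (aromatic C is carbon)
  m <- mol_from_smiles("CCCCc1ccccc1", "butylbenzene", gen3d = TRUE)
  fc <- feature_counts(m)
  expect_equal(fc[["H"]], 1L)
  expect_equal(fc[["R"]], 1L)
  # halogens never seed a group alone
  expect_false("H" %in% names(feature_counts(
    mol_from_smiles("FC(F)(F)F", "cf4", gen3d = TRUE))))
})

test_that("ionizable types are off by default and toggle on", {
  m <- mol_from_smiles("[NH3+]CCCC([O-])=O", "gaba_zwitterion", gen3d = TRUE)
  expect_false(any(perceive_features(m)$type %in% c("N", "P")))
  ft <- perceive_features(m, ruleset(ionizable = TRUE))
  expect_equal(sum(ft$type == "P"), 1)
  expect_equal(sum(ft$type == "N"), 1)
})

test_that("rule-set pattern files override built-in perception per type", {
  f <- system.file("extdata", "ruleset_example.txt", package = "pharmfunnel")
  rs <- read_ruleset(f)
  # acetone: built-in A sees the carbonyl O; the pattern override agrees
  m <- mol_from_smiles("CC(=O)C", "acetone", gen3d = TRUE)
  expect_equal(feature_counts(m, rs)[["A"]], 1L)
  # glycol: no carbonyl, so the A override finds nothing (built-in finds 2)
  g <- mol_from_smiles("OCCO", "glycol", gen3d = TRUE)
  expect_false("A" %in% names(feature_counts(g, rs)))
  expect_equal(feature_counts(g)[["A"]], 2L)
  # malformed pattern file and uncompilable pattern both error
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("A", bad)
  expect_error(read_ruleset(bad), class = "pf_format_error")
  writeLines("A [Qq", bad)
  expect_error(read_ruleset(bad))
})

test_that("the restricted SMARTS matcher handles the documented subset", {
  m <- mol_from_smiles("Nc1ccc(Cl)cc1", "chloroaniline", gen3d = TRUE)
  hits <- function(p) length(pharmfunnel:::smarts_match(m, p))
  expect_equal(hits("c1ccccc1"), 1)      # unique as an atom set
  expect_equal(hits("[NH2]c"), 1)
  expect_equal(hits("Cl"), 1)
  expect_equal(hits("[#7]"), 1)
  expect_equal(hits("[!C;!H0;NX3]"), 1)
  expect_equal(hits("[OX2]"), 0)
  expect_equal(hits("[F,Cl,Br,I]"), 1)
  expect_equal(hits("[NX3]-c1ccccc1"), 1)
})
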