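# Shared fixtures, all built in code.

hexagon_xyz <- function(radius = 1.39, z = 0) {
  ang <- seq(0, 5) * pi / 3
  cbind(radius * cos(ang), radius * sin(ang), z)
}

benzene_fixture <- function() {
  mol("benzene", rep("C", 6),
      data.frame(a1 = 1:6, a2 = c(2:6, 1), order = c(2L, 1L, 2L, 1L, 2L, 1L)),
      conformer = hexagon_xyz(),
      aromatic_rings = list(1:6))
}

# a small random matching instance: typed sites + a random feature cloud
random_instance <- function(seed, n_sites_rng = 3:6, n_feat_rng = 3:7, span = 12) {
  set.seed(seed)
  m <- sample(n_sites_rng, 1); n <- sample(n_feat_rng, 1)
  types <- c("A", "D", "H", "R")
  sites <- tibble::tibble(
    type = sample(types, m, replace = TRUE),
    x = runif(m, 0, span), y = runif(m, 0, span), z = runif(m, 0, span),
    radius = runif(m, 0.8, 2.5), support = runif(m, 0.3, 1)
  )
  list(
    h = hypothesis(sites, tolerance = 2.0),
    ft = features(type = sample(types, n, replace = TRUE),
                  x = runif(n, 0, span), y = runif(n, 0, span), z = runif(n, 0, span),
                  ligand_id = "query")
  )
}

matched_or_zero <- function(r) if (is.null(r)) 0L else r$matched_count

# synthetic protein-ligand complex in PDB format: a BSU copy per requested
# chain (offset along x) plus a handful of CA anchors; geometry from the
# package's own embedding, so the fixture is fully synthetic
synthetic_complex_pdb <- function(path, chains = c("A"), n_ca = 10, ca_seed = 1) {
  bsu <- mol_from_smiles("O=C(Nc1ccccc1)Nc1ccccc1", "BSU", gen3d = TRUE)
  stopifnot(length(bsu$conformers) == 1)
  xyz <- bsu$conformers[[1]]
  heavy <- which(bsu$atoms$element != "H")
  lines <- "HEADER    SYNTHETIC TEST COMPLEX"
  ser <- 0L
  set.seed(ca_seed)
  ca <- matrix(rnorm(3 * n_ca, sd = 5), n_ca, 3)
  for (i in seq_len(n_ca)) {
    ser <- ser + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      ser, "A", i, ca[i, 1], ca[i, 2], ca[i, 3]))
  }
  for (ch in chains) {
    off <- (match(ch, LETTERS) - 1) * 25
    for (i in heavy) {
      ser <- ser + 1L
      lines <- c(lines, sprintf(
        "HETATM%5d  %-3s BSU %s 401    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        ser, paste0(bsu$atoms$element[i], i), ch,
        xyz[i, 1] + off, xyz[i, 2], xyz[i, 3], toupper(bsu$atoms$element[i])))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(list(mol = bsu, heavy = heavy, ca = ca))
}

scaffold_fixture <- function() {
  tibble::tibble(
    id = c("2a", "2b", "2c"),
    smiles = c("OC(=O)CCCCN1C(=O)Nc2ccccc2C1=O",
               "OC(=O)CCCCCN1C(=O)Nc2ccccc2C1=O",
               "OC(=O)CCCCCCN1C(=O)Nc2ccccc2C1=O"))
}

# quinazolinedione negative-control analogue (flexible amide chain)
compound5_smiles <- "O=C(Nc1ccc2OCCOc2c1)CCCCN1C(=O)Nc2ccccc2C1=O"
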