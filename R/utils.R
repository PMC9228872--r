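# internal geometry / misc helpers

vec_norm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vec_norm(v)
  if (!is.finite(n) || n < 1e-12) return(NULL)
  v / n
}

# apply rigid transform x %*% R + t to an N x 3 matrix
apply_rigid <- function(xyz, rotation, translation) {
  sweep(xyz %*% rotation, 2, translation, `+`)
}

# random proper rotation (QR of a Gaussian matrix, det corrected)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

feature_type_codes <- c("A", "D", "H", "N", "P", "R")

# canonical feature ordering used everywhere results must be order-stable
arrange_features <- function(feat) {
  dplyr::arrange(feat, .data$type, .data$x, .data$y, .data$z)
}

#' Assemble a pharmacophore feature table
#'
#' Features are the currency of the package: perceived chemical points
#' (acceptor `A`, donor `D`, hydrophobic `H`, negative/positive ionizable
#' `N`/`P`, aromatic ring `R`) with 3D positions in angstroms and an optional
#' unit direction. Most functions accept and return this table.
#'
#' @param type character vector of feature type codes (`A D H N P R`).
#' @param x,y,z numeric coordinates (angstrom).
#' @param dx,dy,dz optional unit direction components (`NA` when the feature
#'   has no direction, e.g. hydrophobic centroids).
#' @param ligand_id identifier of the parent ligand.
#' @param atom_idx optional list column of supporting atom indices.
#' @return a tibble with one row per feature, ordered canonically by
#'   `(type, x, y, z)`.
#' @export
#' @examples
#' features(type = c("A", "D"), x = c(0, 3), y = 0, z = 0, ligand_id = "lig1")
features <- function(type, x, y, z, dx = NA_real_, dy = NA_real_, dz = NA_real_,
                     ligand_id = "lig", atom_idx = NULL) {
  ft <- tibble(
    type = as.character(type), x = as.numeric(x), y = as.numeric(y),
    z = as.numeric(z), dx = as.numeric(dx), dy = as.numeric(dy),
    dz = as.numeric(dz), ligand_id = as.character(ligand_id)
  )
  ft$atom_idx <- if (is.null(atom_idx)) vector("list", nrow(ft)) else atom_idx
  validate_features(ft)
  arrange_features(ft)
}

validate_features <- function(feat) {
  stopifnot(is.data.frame(feat))
  need <- c("type", "x", "y", "z", "ligand_id")
  miss <- setdiff(need, names(feat))
  if (length(miss)) abort(paste0("feature table missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(feat) == 0) return(invisible(feat))
  if (!all(feat$type %in% feature_type_codes)) {
    abort("feature types must be drawn from {A, D, H, N, P, R}")
  }
  if (!all(is.finite(feat$x) & is.finite(feat$y) & is.finite(feat$z))) {
    abort("feature positions must be finite")
  }
  has_dir <- !is.na(feat$dx)
  if (any(has_dir)) {
    nrm <- sqrt(feat$dx[has_dir]^2 + feat$dy[has_dir]^2 + feat$dz[has_dir]^2)
    if (any(abs(nrm - 1) > 1e-6)) abort("feature directions must have unit norm")
  }
  invisible(feat)
}

feat_xyz <- function(feat) {
  cbind(x = feat$x, y = feat$y, z = feat$z)
}

# transform a feature table rigidly (positions and directions)
transform_features <- function(feat, rotation, translation = c(0, 0, 0)) {
  if (nrow(feat) == 0) return(feat)
  p <- apply_rigid(feat_xyz(feat), rotation, translation)
  feat$x <- p[, 1]; feat$y <- p[, 2]; feat$z <- p[, 3]
  has_dir <- !is.na(feat$dx)
  if (any(has_dir)) {
    d <- cbind(feat$dx[has_dir], feat$dy[has_dir], feat$dz[has_dir]) %*% rotation
    feat$dx[has_dir] <- d[, 1]; feat$dy[has_dir] <- d[, 2]; feat$dz[has_dir] <- d[, 3]
  }
  feat
}
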