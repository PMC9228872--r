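#' Kabsch superposition
#'
#' Least-squares rigid transform (proper rotation + translation) minimizing
#' the RMSD of `P` onto `Q`. Reflections are never returned: the smallest
#' singular direction is flipped when the raw solution is improper, so
#' enantiomeric point sets cannot be superposed exactly.
#'
#' @param P,Q n x 3 coordinate matrices (n >= 3), row i of `P` corresponding
#'   to row i of `Q`.
#' @return list with `rotation` (3 x 3, det = +1), `translation` (length 3)
#'   such that `P %*% rotation + translation` best fits `Q`, and `rmsd`.
#' @export
#' @examples
#' P <- matrix(rnorm(12), 4, 3)
#' kabsch(P, P)$rmsd
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) < 3 || ncol(P) != 3 || !all(dim(P) == dim(Q))) {
    abort("kabsch() needs matching n x 3 matrices with n >= 3")
  }
  if (!all(is.finite(P)) || !all(is.finite(Q))) abort("kabsch() needs finite coordinates")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)   # Pc %*% R ~ Qc, det +1
  tr <- as.numeric(cq - cp %*% R)
  diff <- apply_rigid(P, R, tr) - Q
  list(rotation = R, translation = tr, rmsd = sqrt(mean(rowSums(diff^2))))
}
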