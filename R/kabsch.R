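# Weighted Kabsch superposition (SVD form, reflection-corrected).

#' Optimal rigid superposition of two point sets
#'
#' Finds the proper rigid transform `T` minimizing the (weighted) RMSD of
#' `T(X)` against `Y`. This is the superposition primitive underlying every
#' RMSD metric in the package (ligand RMSD, interface RMSD, C-alpha RMSD).
#'
#' @param X,Y n x 3 coordinate matrices (n >= 3), row i of `X` corresponding
#'   to row i of `Y`.
#' @param weights optional non-negative per-point weights.
#' @return list with `transform` (a [rigid_transform]) and `rmsd` (Angstrom).
#' @export
kabsch <- function(X, Y, weights = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3L || nrow(Y) != n || ncol(X) != 3L || ncol(Y) != 3L)
    stop("degenerate point set: need matched n x 3 matrices with n >= 3")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0)
    stop("invalid weights")
  w <- w / sum(w)
  xc <- colSums(X * w)
  yc <- colSums(Y * w)
  Xc <- sweep(X, 2, xc)
  Yc <- sweep(Y, 2, yc)
  H <- t(Xc * w) %*% Yc
  sv <- svd(H)
  # rank < 2 leaves the rotation under-determined (collinear/coincident points)
  if (sv$d[2] <= 1e-10 * max(sv$d[1], 1e-300))
    stop("degenerate point set: rank-deficient configuration")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tt <- yc - as.numeric(R %*% xc)
  tf <- rigid_transform(R, tt)
  dev <- rt_apply(tf, X) - Y
  rmsd <- sqrt(sum(w * rowSums(dev * dev)))
  list(transform = tf, rmsd = rmsd)
}

# Plain RMSD of two matched coordinate sets (no superposition).
rmsd_raw <- function(X, Y) {
  d <- X - Y
  sqrt(sum(d * d) / nrow(X))
}

# RMSD after optimal superposition of X onto Y.
rmsd_superposed <- function(X, Y, weights = NULL) kabsch(X, Y, weights)$rmsd
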