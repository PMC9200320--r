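# Internal utilities the tests lean on (the suite runs against the installed
# package, where these are not exported).
vnorm <- flexidock:::vnorm
deg2rad <- flexidock:::deg2rad
rad2deg <- flexidock:::rad2deg
lj_split <- flexidock:::lj_split
random_rotation <- flexidock:::random_rotation
rotation_about_point <- flexidock:::rotation_about_point

# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (quaternion superposition instead of SVD,
# brute-force O(N^2) scans instead of the vectorized selections).

# Horn's quaternion-method superposition: rotation + translation minimizing
# RMSD of X onto Y. Second-algorithm oracle for kabsch().
quaternion_superpose <- function(X, Y) {
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  S <- t(Xc) %*% Yc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  eig <- eigen(K, symmetric = TRUE)
  q <- eig$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  moved <- sweep(Xc %*% t(R), 2, yc, `+`)
  list(R = R, rmsd = sqrt(mean(rowSums((moved - Y)^2))))
}

# Brute-force interface selection: residue indices of each partner with any
# coarse-atom pair within cutoff, by explicit double loop.
brute_interface <- function(pose, cutoff) {
  rec <- integer(0); lig <- integer(0)
  for (i in seq_len(pose$receptor$n)) {
    xi <- pose$receptor$xyz[(i - 1) * 6 + 1:6, , drop = FALSE]
    for (j in seq_len(pose$ligand$n)) {
      xj <- pose$ligand$xyz[(j - 1) * 6 + 1:6, , drop = FALSE]
      dmin <- min(sqrt(outer(rowSums(xi^2), rowSums(xj^2), `+`) -
                         2 * xi %*% t(xj)))
      if (is.finite(dmin) && dmin <= cutoff) {
        rec <- union(rec, i); lig <- union(lig, j)
      }
    }
  }
  list(receptor = sort(rec), ligand = sort(lig))
}

# Brute-force ligand RMSD: superpose receptors with the quaternion oracle,
# then plain backbone RMSD of the ligand.
brute_lrmsd <- function(pred, native) {
  fit <- quaternion_superpose(backbone_xyz(pred$receptor),
                              backbone_xyz(native$receptor))
  xc <- colMeans(backbone_xyz(pred$receptor))
  yc <- colMeans(backbone_xyz(native$receptor))
  L <- backbone_xyz(pred$ligand)
  moved <- sweep(sweep(L, 2, xc) %*% t(fit$R), 2, yc, `+`)
  sqrt(mean(rowSums((moved - backbone_xyz(native$ligand))^2)))
}

# Brute-force CAPRI rank from the rule table.
brute_capri_rank <- function(fn, lr, ir) {
  if (fn >= 0.5 && (lr <= 1 || ir <= 1)) return(3L)
  if (fn >= 0.3 && (lr <= 5 || ir <= 2)) return(2L)
  if (fn >= 0.1 && (lr <= 10 || ir <= 4)) return(1L)
  0L
}

# Apply one global rigid motion to a whole pose (both chains), preserving
# the jump bookkeeping.
transform_pose <- function(pose, tf) {
  pose$receptor$xyz <- rt_apply(tf, pose$receptor$xyz)
  pose_set_ligand_xyz(pose, rt_apply(tf, pose$ligand$xyz))
}

# A deterministic random rigid transform.
random_rigid <- function(seed) {
  set.seed(seed)
  rigid_transform(random_rotation(), stats::rnorm(3, 0, 10))
}

# Shared small fixtures (built once per test file load).
toy36 <- function(seed = 3L, unbound_angle = 15) {
  make_toy_complex(rec_helix = 9L, loop_len = 4L, lig_len = 14L,
                   unbound_angle = unbound_angle, seed = seed)
}
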