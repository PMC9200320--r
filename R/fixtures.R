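# Synthetic structure and decoy generation.
#
# Everything here is built from internal coordinates with ideal bond geometry
# (NeRF chain extension), so fixtures are exactly reproducible, free of hard
# clashes, and carry known dihedrals -- which turns them into oracles for the
# dihedral extraction, secondary-structure and mobile-residue machinery.

IDEAL_BB <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5
)

# Canonical (phi, psi) used by the segment builder.
SS_DIHEDRALS <- list(
  H = c(phi = -57, psi = -47),
  E = c(phi = -120, psi = 130),
  # two alternating loop conformers chosen to sit outside both the helix and
  # strand dihedral boxes while keeping helix-loop-helix builds clash-free
  L1 = c(phi = -80, psi = 60),
  L2 = c(phi = 100, psi = 40)
)

#' Build a chain from per-residue dihedrals
#'
#' Extends an ideal-geometry backbone residue by residue: given phi(i),
#' psi(i) and omega(i) the atoms N, CA, C are placed by internal-coordinate
#' (NeRF) construction, O anti to the next amide nitrogen, CB at ideal
#' tetrahedral geometry and the sidechain centroid at CB (CA for glycine).
#'
#' @param phi,psi,omega numeric vectors (degrees), one entry per residue.
#'   `phi[1]` and the last `psi`/`omega` only orient terminal O/CB atoms.
#' @param aa one-letter sequence (recycled); default polyalanine.
#' @param chain_id chain identifier.
#' @param seq_start first author residue number.
#' @return `coarse_chain`.
#' @export
make_chain_from_dihedrals <- function(phi, psi, omega = NULL, aa = "A",
                                      chain_id = "A", seq_start = 1L) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  if (is.null(omega)) omega <- rep(180, n)
  aa <- rep_len(strsplit(paste(aa, collapse = ""), "")[[1]], n)
  g <- IDEAL_BB
  N <- matrix(0, n, 3); CA <- matrix(0, n, 3); C <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  ang <- deg2rad(g$ang_n_ca_c)
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1L)) {
    N[i + 1L, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], g$c_n, g$ang_ca_c_n, psi[i])
    CA[i + 1L, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1L, ], g$n_ca, g$ang_c_n_ca, omega[i])
    C[i + 1L, ] <- nerf_place(C[i, ], N[i + 1L, ], CA[i + 1L, ], g$ca_c, g$ang_n_ca_c, phi[i + 1L])
  }
  xyz <- matrix(0, 6L * n, 3)
  cbv <- rep(FALSE, n)
  for (i in seq_len(n)) {
    O <- if (i < n) {
      nerf_place(N[i + 1L, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o, 180)
    } else {
      nerf_place(N[i, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o, psi[i] + 180)
    }
    CB <- ideal_cb(N[i, ], CA[i, ], C[i, ])
    cbv[i] <- aa[i] == "G"
    CEN <- if (aa[i] == "G") CA[i, ] else CB
    xyz[(i - 1L) * 6L + 1:6, ] <- rbind(N[i, ], CA[i, ], C[i, ], O, CB, CEN)
  }
  coarse_chain(rep(chain_id, n), seq(seq_start, length.out = n), aa, xyz, cbv)
}

#' Ideal alpha-helix fixture
#'
#' @param n_res number of residues (>= 4).
#' @param aa sequence (recycled), default polyalanine.
#' @param chain_id,seq_start passed through.
#' @return `coarse_chain` with phi = -57, psi = -47, omega = 180.
#' @export
make_helix <- function(n_res, aa = "A", chain_id = "A", seq_start = 1L) {
  stopifnot(n_res >= 4L)
  make_chain_from_dihedrals(rep(-57, n_res), rep(-47, n_res), rep(180, n_res),
                            aa, chain_id, seq_start)
}

#' Build a chain from a secondary-structure segment recipe
#'
#' @param segments list of `list(ss, len)` entries with `ss` in
#'   {"H", "E", "L"}; loops alternate between two fixed coil conformers.
#' @param aa,chain_id,seq_start passed through.
#' @return `coarse_chain`.
#' @export
make_segmented_chain <- function(segments, aa = "A", chain_id = "A",
                                 seq_start = 1L) {
  phi <- numeric(0); psi <- numeric(0)
  for (s in segments) {
    if (s$ss %in% c("H", "E")) {
      d <- SS_DIHEDRALS[[s$ss]]
      phi <- c(phi, rep(d["phi"], s$len))
      psi <- c(psi, rep(d["psi"], s$len))
    } else {
      alt <- rep(c("L1", "L2"), length.out = s$len)
      phi <- c(phi, vapply(alt, function(k) SS_DIHEDRALS[[k]]["phi"], 0))
      psi <- c(psi, vapply(alt, function(k) SS_DIHEDRALS[[k]]["psi"], 0))
    }
  }
  make_chain_from_dihedrals(phi, psi, NULL, aa, chain_id, seq_start)
}

#' Synthetic two-body complex with controllable unbound-bound deviation
#'
#' Builds a bound mini-complex (helix-loop-helix receptor docked against a
#' single-helix ligand) plus "unbound" monomers in which the receptor loop
#' has been displaced by a Backrub rotation of known angle, so the
#' unbound-to-bound backbone deviation is controlled by `unbound_angle` and
#' localized to known residues.
#'
#' @param rec_helix,loop_len,lig_len segment lengths (residues).
#' @param unbound_angle Backrub angle (degrees) applied to the receptor loop
#'   to create the unbound receptor; 0 gives identical monomers.
#' @param seed RNG seed for the docking orientation.
#' @return list with `bound` (`coarse_pose`), `receptor`, `ligand` (unbound
#'   `coarse_chain`s), and `loop` (dense receptor indices of the displaced
#'   loop interior).
#' @export
make_toy_complex <- function(rec_helix = 9L, loop_len = 4L, lig_len = 14L,
                             unbound_angle = 15, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rec <- make_segmented_chain(list(list(ss = "H", len = rec_helix),
                                   list(ss = "L", len = loop_len),
                                   list(ss = "H", len = rec_helix)),
                              aa = "AVLKDESTFM", chain_id = "A")
  lig <- make_helix(lig_len, aa = "LKAEVFDSTM", chain_id = "B")
  # dock the ligand: random orientation, placed along a random direction and
  # slid into contact
  Rm <- random_rotation()
  lc <- colMeans(atom_xyz(lig, "CA"))
  lig$xyz <- rt_apply(rotation_about_point(Rm, lc), lig$xyz)
  rc <- colMeans(atom_xyz(rec, "CA"))
  u <- random_unit_vector()
  shift <- rc + u * 40 - lc
  lig$xyz <- sweep(lig$xyz, 2, shift, `+`)
  bound <- slide_into_contact(coarse_pose(rec, lig))
  loop <- (rec_helix + 1L):(rec_helix + loop_len)
  rec_unbound <- bound$receptor
  if (unbound_angle != 0) {
    rec_unbound <- backrub_rotate(rec_unbound, rec_helix, rec_helix + loop_len + 1L,
                                  unbound_angle)
  }
  list(bound = bound, receptor = rec_unbound, ligand = bound$ligand, loop = loop)
}

#' Synthetic scored decoy set
#'
#' Generates `(score, near-native flag, serial)` rows with a controllable
#' association between score and flag: `score_signal = 1` makes every
#' near-native decoy score better than every other decoy (perfect
#' separation); `score_signal = 0` makes scores independent of the flags.
#'
#' @param n number of decoys (>= 5).
#' @param near_native_fraction fraction flagged near-native.
#' @param score_signal association strength in `[0, 1]`.
#' @param seed RNG seed.
#' @return data.frame with columns `serial`, `score`, `near_native`.
#' @export
make_decoy_set <- function(n, near_native_fraction, score_signal, seed = 1L) {
  stopifnot(n >= 5L, near_native_fraction >= 0, near_native_fraction <= 1,
            score_signal >= 0, score_signal <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  k <- round(near_native_fraction * n)
  flag <- sample(rep(c(TRUE, FALSE), c(k, n - k)))
  noise <- stats::rnorm(n)
  # signal term separates the two groups by 4 units (|noise| is O(1))
  score <- (1 - score_signal) * noise +
    score_signal * (ifelse(flag, -4, 0) + 0.1 * stats::runif(n))
  data.frame(serial = seq_len(n), score = score, near_native = flag)
}

#' Funnel-shaped surrogate energy around a native pose
#'
#' Returns an energy callable usable wherever the docking score is: zero at
#' the native placement, rising to `depth` as the ligand RMSD grows on the
#' scale `width`, plus a weak quadratic tether in lrmsd and a soft CA-CA
#' clash penalty. Used as an integration stand-in for the full
#' low-resolution score so replica-exchange runs can be verified to descend
#' a known funnel. Strictly increasing in lrmsd on a clash-free ray; zero at
#' the native placement.
#'
#' Defaults are chosen for that diagnostic role: the funnel curvature
#' (`depth / width^2`) puts the equilibrium ligand RMSD of the coldest
#' ladder temperature (1.5 energy units) below the 2 Angstrom near-native
#' boundary, and the tether keeps the hottest replica within local-docking
#' range instead of diffusing over the flat plateau.
#'
#' @param native_pose `coarse_pose` at the funnel minimum.
#' @param width lrmsd scale of the funnel (Angstrom).
#' @param depth plateau height (energy units).
#' @param tether prefactor of the long-range `tether * lrmsd^2` term.
#' @param clash_dist,clash_k CA-CA soft-clash threshold (Angstrom) and
#'   quadratic prefactor.
#' @return function(pose) -> energy.
#' @export
funnel_energy_factory <- function(native_pose, width = 4, depth = 25,
                                  tether = 0.02, clash_dist = 3.0,
                                  clash_k = 2) {
  nat_rec_bb <- backbone_xyz(native_pose$receptor)
  nat_lig_bb <- backbone_xyz(native_pose$ligand)
  rec_rows <- backbone_rows(seq_len(native_pose$receptor$n))
  lig_rows <- backbone_rows(seq_len(native_pose$ligand$n))
  rec_ca <- atom_rows(seq_len(native_pose$receptor$n), "CA")
  lig_ca <- atom_rows(seq_len(native_pose$ligand$n), "CA")
  n_lig_bb <- length(lig_rows)
  cd2 <- clash_dist^2
  # cache the receptor superposition: under rigid-body-only sampling the
  # receptor never moves, so the fit is recomputed only when its coordinates
  # actually change
  cache <- new.env(parent = emptyenv())
  cache$rec <- NULL
  function(pose) {
    rec_bb <- pose$receptor$xyz[rec_rows, , drop = FALSE]
    if (is.null(cache$rec) || !identical(cache$rec, rec_bb)) {
      cache$rec <- rec_bb
      cache$fit <- kabsch(rec_bb, nat_rec_bb)
    }
    tf <- cache$fit$transform
    lig <- pose$ligand$xyz[lig_rows, , drop = FALSE] %*% t(tf$R)
    dx <- lig[, 1] + tf$t[1] - nat_lig_bb[, 1]
    dy <- lig[, 2] + tf$t[2] - nat_lig_bb[, 2]
    dz <- lig[, 3] + tf$t[3] - nat_lig_bb[, 3]
    lr2 <- sum(dx * dx + dy * dy + dz * dz) / n_lig_bb
    ca_r <- pose$receptor$xyz[rec_ca, , drop = FALSE]
    ca_l <- pose$ligand$xyz[lig_ca, , drop = FALSE]
    d2 <- outer(rowSums(ca_r * ca_r), rowSums(ca_l * ca_l), `+`) -
      2 * tcrossprod(ca_r, ca_l)
    viol <- d2[d2 < cd2]
    clash <- if (length(viol)) sum((clash_dist - sqrt(pmax(viol, 0)))^2) else 0
    depth * (1 - exp(-lr2 / width^2)) + tether * lr2 + clash_k * clash
  }
}

# Save/restore the global RNG state so seeded fixture builders do not disturb
# the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
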