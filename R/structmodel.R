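# Coarse structure model and PDB input/output.
#
# A chain is held in a reduced representation: the four backbone heavy atoms
# (N, CA, C, O), a beta carbon (synthesized from ideal geometry when absent,
# e.g. glycine) and a sidechain centroid CEN (mean of sidechain heavy atoms;
# CB for alanine-like residues, CA for glycine). Atom coordinates live in a
# single (6 n) x 3 matrix with a fixed atom order per residue, which keeps
# move proposals and scoring fully vectorized.

COARSE_ATOMS <- c("N", "CA", "C", "O", "CB", "CEN")

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "C"
)

#' Construct a coarse chain
#'
#' @param chain per-residue chain identifier (single letters).
#' @param seq per-residue author sequence number (integer, strictly increasing
#'   within a chain).
#' @param aa per-residue one-letter amino-acid code.
#' @param xyz (6 n) x 3 coordinate matrix, atom order per residue
#'   N, CA, C, O, CB, CEN.
#' @param cb_virtual logical per residue: TRUE when CB was synthesized from
#'   ideal geometry rather than read from file (such CBs are not written out).
#' @return object of class `coarse_chain`.
#' @export
coarse_chain <- function(chain, seq, aa, xyz, cb_virtual = NULL) {
  n <- length(seq)
  stopifnot(length(chain) == n, length(aa) == n,
            is.matrix(xyz), nrow(xyz) == 6L * n, ncol(xyz) == 3L)
  if (is.null(cb_virtual)) cb_virtual <- rep(FALSE, n)
  structure(list(n = n, chain = as.character(chain), seq = as.integer(seq),
                 aa = as.character(aa), xyz = unname(xyz),
                 cb_virtual = cb_virtual),
            class = "coarse_chain")
}

#' Row indices of one atom type for residues `i` (dense 1-based indices)
#' @param i residue indices.
#' @param atom coarse atom name.
#' @export
atom_rows <- function(i, atom) (i - 1L) * 6L + match(atom, COARSE_ATOMS)

#' Extract coordinates of one atom type
#'
#' @param ch `coarse_chain`.
#' @param atom one of `"N"`, `"CA"`, `"C"`, `"O"`, `"CB"`, `"CEN"`.
#' @param i residue indices (dense, 1-based); default all.
#' @return length(i) x 3 matrix.
#' @export
atom_xyz <- function(ch, atom, i = seq_len(ch$n)) {
  ch$xyz[atom_rows(i, atom), , drop = FALSE]
}

# Rows of the backbone atoms (N, CA, C, O) for residues i, in residue order.
#' @rdname backbone_xyz
#' @export
backbone_rows <- function(i) {
  as.vector(t(outer((i - 1L) * 6L, 1:4, `+`)))
}

#' Backbone (N, CA, C, O) coordinates of residues
#' @param ch `coarse_chain`.
#' @param i residue indices (default all).
#' @return 4 length(i) x 3 matrix in residue order.
#' @export
backbone_xyz <- function(ch, i = seq_len(ch$n)) {
  ch$xyz[backbone_rows(i), , drop = FALSE]
}

# Per-atom residue index vector for a chain (length 6 n).
atom_res_index <- function(ch) rep(seq_len(ch$n), each = 6L)

#' @export
print.coarse_chain <- function(x, ...) {
  cat(sprintf("<coarse_chain> %d residues, chain(s) %s\n",
              x$n, paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

#' Construct a two-body docking pose
#'
#' The pose couples a fixed receptor with a mobile ligand whose placement is
#' carried by a rigid "jump" transform: the ligand's stored local coordinates
#' mapped through `jump` reproduce its global coordinates. Rigid-body moves
#' update the jump; backbone moves update coordinates and re-derive the local
#' frame.
#'
#' @param receptor,ligand `coarse_chain` objects (disjoint chain ids).
#' @param jump `rigid_transform` placing the ligand frame in the receptor
#'   frame; defaults to identity with local = global coordinates.
#' @return object of class `coarse_pose`.
#' @export
coarse_pose <- function(receptor, ligand, jump = rt_identity()) {
  stopifnot(inherits(receptor, "coarse_chain"), inherits(ligand, "coarse_chain"))
  if (length(intersect(unique(receptor$chain), unique(ligand$chain))) > 0)
    stop("receptor and ligand chains must be disjoint")
  structure(list(receptor = receptor, ligand = ligand, jump = jump,
                 ligand_local = rt_apply(rt_invert(jump), ligand$xyz)),
            class = "coarse_pose")
}

#' @export
print.coarse_pose <- function(x, ...) {
  cat(sprintf("<coarse_pose> receptor %d res (%s) | ligand %d res (%s)\n",
              x$receptor$n, paste(unique(x$receptor$chain), collapse = ","),
              x$ligand$n, paste(unique(x$ligand$chain), collapse = ",")))
  invisible(x)
}

#' Update the ligand placement of a pose
#'
#' `pose_set_jump()` replaces the jump outright, `pose_perturb_jump()`
#' composes a delta transform onto it (ligand global coordinates follow from
#' the stored local frame), and `pose_set_ligand_xyz()` replaces the global
#' ligand coordinates, re-deriving the local frame (backbone moves).
#'
#' @param pose `coarse_pose`.
#' @param jump,delta `rigid_transform`.
#' @param xyz ligand coordinate matrix.
#' @return the updated pose.
#' @export
pose_set_jump <- function(pose, jump) {
  pose$jump <- jump
  pose$ligand$xyz <- rt_apply(jump, pose$ligand_local)
  pose
}

#' @rdname pose_set_jump
#' @export
pose_perturb_jump <- function(pose, delta) {
  pose_set_jump(pose, rt_compose(delta, pose$jump))
}

#' @rdname pose_set_jump
#' @export
pose_set_ligand_xyz <- function(pose, xyz) {
  pose$ligand$xyz <- xyz
  pose$ligand_local <- rt_apply(rt_invert(pose$jump), xyz)
  pose
}

# --- PDB parsing -----------------------------------------------------------

# Ideal-geometry CB from backbone N, CA, C (also used for glycine's virtual
# CB). Internal coordinates: CA-CB 1.521 A, N-CA-CB 110.5 deg, improper
# torsion C-N-CA-CB +122.5 deg (L-configuration).
ideal_cb <- function(N, CA, C) {
  nerf_place(C, N, CA, 1.521, 110.5, 122.5)
}

# Place atom D bonded to C given positions A, B, C, the bond length C-D, the
# angle B-C-D (degrees) and the torsion A-B-C-D (degrees). Standard
# internal-coordinate (NeRF) construction.
nerf_place <- function(A, B, C, bond, angle_deg, torsion_deg) {
  ang <- deg2rad(angle_deg)
  tor <- deg2rad(torsion_deg)
  bc <- unit(C - B)
  n <- unit(cross3(B - A, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Read a two-body pose from a PDB file
#'
#' Parses ATOM records of MODEL 1 (waters and HETATM records skipped, first
#' alternate location kept), builds the coarse representation and splits the
#' chains into receptor and ligand according to `chain_spec`.
#'
#' @param path PDB file.
#' @param chain_spec string `"A_B"`: receptor chain letters before the
#'   underscore, ligand letters after (e.g. `"AB_C"`).
#' @return [coarse_pose()] with residues ordered by chain then residue number.
#' @details Residues missing any of N/CA/C are dropped with a warning. A
#'   missing O or CB is synthesized from ideal geometry; the sidechain
#'   centroid is the mean of sidechain heavy atoms (CB for alanine, CA for
#'   glycine).
#' @export
read_pdb <- function(path, chain_spec) {
  parts <- strsplit(chain_spec, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("chain_spec must look like 'A_B'")
  rec_chains <- strsplit(parts[1], "")[[1]]
  lig_chains <- strsplit(parts[2], "")[[1]]
  parsed <- parse_pdb_atoms(path)
  for (ch in c(rec_chains, lig_chains))
    if (!any(parsed$chain == ch)) stop("chain not found: ", ch)
  rec <- build_coarse_chain(parsed, rec_chains)
  lig <- build_coarse_chain(parsed, lig_chains)
  if (is.null(rec) || is.null(lig))
    stop("zero parseable residues in a chain group")
  coarse_pose(rec, lig)
}

#' Read one chain group from a PDB file as a `coarse_chain`
#'
#' @param path PDB file.
#' @param chains chain letters, e.g. `"A"` or `"AB"`.
#' @export
read_pdb_chain <- function(path, chains) {
  chv <- strsplit(chains, "")[[1]]
  parsed <- parse_pdb_atoms(path)
  for (ch in chv)
    if (!any(parsed$chain == ch)) stop("chain not found: ", ch)
  out <- build_coarse_chain(parsed, chv)
  if (is.null(out)) stop("zero parseable residues in a chain group")
  out
}

# Parse the ATOM records of MODEL 1 into parallel vectors.
parse_pdb_atoms <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  at <- lines[startsWith(lines, "ATOM")]
  if (!length(at)) stop("no ATOM records in ", path)

  f <- function(a, b) trimws(substr(at, a, b))
  name <- f(13, 16)
  altloc <- substr(at, 17, 17)
  resname <- f(18, 20)
  chain <- substr(at, 22, 22)
  resseq <- suppressWarnings(as.integer(f(23, 26)))
  x <- as.numeric(f(31, 38)); y <- as.numeric(f(39, 46)); z <- as.numeric(f(47, 54))
  elem <- f(77, 78)

  keep <- altloc %in% c(" ", "", "A") &
    !(resname %in% c("HOH", "WAT", "DOD")) &
    !(elem %in% c("H", "D")) & !grepl("^[0-9]*H", name) &
    !is.na(resseq) & is.finite(x)
  list(name = name[keep], resname = resname[keep], chain = chain[keep],
       resseq = resseq[keep], xyz = cbind(x[keep], y[keep], z[keep]))
}

# Build the coarse chain of one chain group from parsed atoms.
build_coarse_chain <- function(parsed, chs) {
  name <- parsed$name; resname <- parsed$resname; chain <- parsed$chain
  resseq <- parsed$resseq; xyz <- parsed$xyz
  idx <- which(chain %in% chs)
  if (!length(idx)) return(NULL)
  key <- paste(chain[idx], resseq[idx], sep = "|")
  groups <- split(idx, factor(key, levels = unique(key)))
  # order residues by chain (order given in the spec string) then seq number
  gchain <- vapply(groups, function(g) chain[g[1]], character(1))
  gseq <- vapply(groups, function(g) resseq[g[1]], integer(1))
  ord <- order(match(gchain, chs), gseq)
  groups <- groups[ord]

  res_chain <- character(0); res_seq <- integer(0); res_aa <- character(0)
  coords <- list(); cbv <- logical(0); dropped <- character(0)
  for (g in groups) {
    nm <- name[g]
    get1 <- function(a) {
      j <- which(nm == a)
      if (!length(j)) return(NULL)
      xyz[g[j[1]], ]
    }
    N <- get1("N"); CA <- get1("CA"); C <- get1("C")
    if (is.null(N) || is.null(CA) || is.null(C)) {
      dropped <- c(dropped, paste0(chain[g[1]], resseq[g[1]]))
      next
    }
    O <- get1("O")
    if (is.null(O)) O <- nerf_place(N, CA, C, 1.231, 120.5, 180)
    aa <- unname(AA3TO1[resname[g[1]]])
    if (is.na(aa)) aa <- "X"
    CB <- get1("CB")
    virt <- is.null(CB)
    if (virt) CB <- ideal_cb(N, CA, C)
    side <- setdiff(unique(nm), c("N", "CA", "C", "O", "OXT"))
    if (length(side)) {
      j <- g[nm %in% side]
      CEN <- colMeans(xyz[j, , drop = FALSE])
    } else {
      CEN <- if (aa == "G") CA else CB
    }
    res_chain <- c(res_chain, chain[g[1]])
    res_seq <- c(res_seq, resseq[g[1]])
    res_aa <- c(res_aa, aa)
    cbv <- c(cbv, virt)
    coords[[length(coords) + 1L]] <- rbind(N, CA, C, O, CB, CEN)
  }
  if (length(dropped))
    warning("dropped residue(s) missing backbone atoms: ",
            paste(dropped, collapse = ", "))
  if (!length(coords)) return(NULL)
  coarse_chain(res_chain, res_seq, res_aa, do.call(rbind, coords), cbv)
}

#' Write a pose or chain as PDB ATOM records
#'
#' Writes N, CA, C, O and (non-virtual) CB atoms in fixed-column PDB format
#' with a TER record between chains. Sidechain centroids and synthesized CBs
#' are representation artifacts and are not written.
#'
#' @param x `coarse_pose` or `coarse_chain`.
#' @param path output file path.
#' @export
write_pdb <- function(x, path) {
  chains <- if (inherits(x, "coarse_pose")) list(x$receptor, x$ligand) else list(x)
  if (sum(vapply(chains, function(c) c$n, integer(1))) == 0L)
    stop("empty pose")
  aa1to3 <- stats::setNames(names(AA3TO1)[1:20], unname(AA3TO1[1:20]))
  out <- character(0)
  serial <- 0L
  for (ch in chains) {
    for (i in seq_len(ch$n)) {
      res3 <- aa1to3[ch$aa[i]]
      if (is.na(res3)) res3 <- "UNK"
      atoms <- c("N", "CA", "C", "O", if (!ch$cb_virtual[i]) "CB")
      for (a in atoms) {
        serial <- serial + 1L
        p <- ch$xyz[atom_rows(i, a), ]
        out <- c(out, sprintf(
          "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, a, res3, ch$chain[i], ch$seq[i], p[1], p[2], p[3], 1, 0,
          substr(a, 1, 1)))
      }
    }
    serial <- serial + 1L
    last <- ch$n
    res3 <- aa1to3[ch$aa[last]]; if (is.na(res3)) res3 <- "UNK"
    out <- c(out, sprintf("TER   %5d      %3s %1s%4d",
                          serial, res3, ch$chain[last], ch$seq[last]))
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

# --- dihedrals -------------------------------------------------------------

# Torsion angle (degrees, (-180, 180]) for rows of four coordinate matrices.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
              b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
              b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
              b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
              b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  m1 <- cbind(n1[, 2] * b2[, 3] - n1[, 3] * b2[, 2],
              n1[, 3] * b2[, 1] - n1[, 1] * b2[, 3],
              n1[, 1] * b2[, 2] - n1[, 2] * b2[, 1])
  b2n <- sqrt(rowSums(b2 * b2))
  xcomp <- rowSums(n1 * n2)
  ycomp <- rowSums(m1 * n2) / b2n
  ang <- -rad2deg(atan2(ycomp, xcomp))
  ifelse(ang <= -180, ang + 360, ang)
}

#' Backbone dihedral angles of a chain
#'
#' phi(i) from C(i-1),N(i),CA(i),C(i); psi(i) from N(i),CA(i),C(i),N(i+1);
#' omega(i) from CA(i),C(i),N(i+1),CA(i+1). Angles across chain termini,
#' chain-id changes or chain breaks (C(i)-N(i+1) > 2 Angstrom) are `NA`.
#'
#' @param ch `coarse_chain`.
#' @return data.frame with columns `phi`, `psi`, `omega` (degrees).
#' @export
backbone_dihedrals <- function(ch) {
  n <- ch$n
  if (n < 2L) {
    return(data.frame(phi = rep(NA_real_, n), psi = NA_real_, omega = NA_real_))
  }
  N <- atom_xyz(ch, "N"); CA <- atom_xyz(ch, "CA"); C <- atom_xyz(ch, "C")
  # linked(i): residue i+1 follows residue i (same chain id, peptide bond)
  gap <- sqrt(rowSums((N[-1, , drop = FALSE] - C[-n, , drop = FALSE])^2))
  linked <- (ch$chain[-n] == ch$chain[-1]) & gap <= 2.0
  phi <- psi <- omega <- rep(NA_real_, n)
  i <- which(linked)          # transitions i -> i+1
  if (length(i)) {
    phi[i + 1L] <- dihedral_angle(C[i, , drop = FALSE], N[i + 1L, , drop = FALSE],
                                  CA[i + 1L, , drop = FALSE], C[i + 1L, , drop = FALSE])
    psi[i] <- dihedral_angle(N[i, , drop = FALSE], CA[i, , drop = FALSE],
                             C[i, , drop = FALSE], N[i + 1L, , drop = FALSE])
    omega[i] <- dihedral_angle(CA[i, , drop = FALSE], C[i, , drop = FALSE],
                               N[i + 1L, , drop = FALSE], CA[i + 1L, , drop = FALSE])
  }
  data.frame(phi = phi, psi = psi, omega = omega)
}

# --- secondary structure ---------------------------------------------------

#' Dihedral-box secondary-structure assignment
#'
#' A deliberately simple loop/non-loop split: H where (phi, psi) falls in the
#' helical box for a run of at least `min_h` residues, E in the strand box for
#' a run of at least `min_e`, otherwise L. Termini (undefined dihedrals) are
#' L. Box bounds are exposed for tuning.
#'
#' @param ch `coarse_chain` (or a data.frame of dihedrals).
#' @param helix_box,strand_box numeric bounds, see defaults.
#' @param min_h,min_e minimum run lengths.
#' @return character vector of labels in {"H", "E", "L"}.
#' @export
assign_secstruct <- function(ch,
                             helix_box = c(phi_min = -100, phi_max = -30,
                                           psi_min = -80, psi_max = -5),
                             strand_box = c(phi_min = -180, phi_max = -40,
                                            psi_min = 90, psi_max = 180,
                                            psi_min2 = -180, psi_max2 = -170),
                             min_h = 4L, min_e = 3L) {
  dih <- if (is.data.frame(ch)) ch else backbone_dihedrals(ch)
  phi <- dih$phi; psi <- dih$psi
  ok <- !is.na(phi) & !is.na(psi)
  in_h <- ok & phi >= helix_box["phi_min"] & phi <= helix_box["phi_max"] &
    psi >= helix_box["psi_min"] & psi <= helix_box["psi_max"]
  in_e <- ok & phi >= strand_box["phi_min"] & phi <= strand_box["phi_max"] &
    ((psi >= strand_box["psi_min"] & psi <= strand_box["psi_max"]) |
       (psi >= strand_box["psi_min2"] & psi <= strand_box["psi_max2"]))
  lab <- rep("L", length(phi))
  keep_runs <- function(flag, minlen) {
    r <- rle(flag)
    r$values <- r$values & r$lengths >= minlen
    inverse.rle(r)
  }
  lab[keep_runs(in_e, min_e)] <- "E"
  lab[keep_runs(in_h, min_h)] <- "H"   # helix takes precedence
  lab
}
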