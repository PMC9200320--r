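# Mobile-residue selection and the Monte Carlo move set.

#' Move-proposal schedule
#'
#' @param p_rigid probability that a trial is a rigid-body move (otherwise a
#'   backbone move); 0.5 by default so both move families occur each sweep.
#' @param rigid_trans_sigma Gaussian sigma per axis of the rigid translation
#'   (Angstrom).
#' @param rigid_rot_sigma Gaussian sigma of the rigid rotation angle
#'   (degrees) about a uniform random axis through the ligand centroid.
#' @param backrub_max_angle Backrub angles are drawn uniformly in
#'   `[-backrub_max_angle, backrub_max_angle]` (degrees).
#' @export
move_schedule <- function(p_rigid = 0.5, rigid_trans_sigma = 0.7,
                          rigid_rot_sigma = 5, backrub_max_angle = 20) {
  stopifnot(p_rigid >= 0, p_rigid <= 1, rigid_trans_sigma > 0,
            rigid_rot_sigma > 0, backrub_max_angle >= 0)
  list(p_rigid = p_rigid, rigid_trans_sigma = rigid_trans_sigma,
       rigid_rot_sigma = rigid_rot_sigma, backrub_max_angle = backrub_max_angle)
}

#' Interface residues of a pose
#'
#' A residue is selected iff any of its coarse atoms lies within `cutoff` of
#' any coarse atom of the other partner. Recomputable on demand as the pose
#' changes.
#'
#' @param pose `coarse_pose`.
#' @param cutoff distance cutoff (Angstrom): 5.5 for the conservative patch,
#'   8 for the broad patch.
#' @return list with `receptor` and `ligand` dense residue index vectors.
#' @export
select_interface <- function(pose, cutoff = 8) {
  stopifnot(cutoff > 0)
  D <- cross_dist(pose$receptor$xyz, pose$ligand$xyz)
  hit <- D <= cutoff
  ri <- atom_res_index(pose$receptor)
  li <- atom_res_index(pose$ligand)
  rec <- sort(unique(ri[rowSums(hit) > 0]))
  lig <- sort(unique(li[colSums(hit) > 0]))
  list(receptor = rec, ligand = lig)
}

#' Add all loop residues of a chain to a selection
#'
#' @param selection dense residue indices.
#' @param labels secondary-structure labels of the chain
#'   (from [assign_secstruct()]).
#' @return union of `selection` with all residues labeled `"L"`.
#' @export
add_loop_residues <- function(selection, labels) {
  sort(unique(c(selection, which(labels == "L"))))
}

#' Contiguous fragments (with pivots) of a residue selection
#'
#' Maximal runs of consecutive author residue numbers within one chain; runs
#' shorter than `min_len` are dropped (a Backrub needs at least one interior
#' residue between the two pivots). Pivots are the first and last residue of
#' each run.
#'
#' @param idx dense residue indices of the selection.
#' @param ch `coarse_chain` the indices refer to.
#' @param min_len minimum run length (default 3).
#' @return list of `list(first, last)` dense-index pivot pairs.
#' @export
contiguous_fragments <- function(idx, ch, min_len = 3L) {
  if (!length(idx)) return(list())
  idx <- sort(idx)
  brk <- c(TRUE, diff(ch$seq[idx]) != 1L | ch$chain[idx][-1] != ch$chain[idx][-length(idx)])
  run <- cumsum(brk)
  out <- list()
  for (r in unique(run)) {
    members <- idx[run == r]
    if (length(members) >= min_len)
      out[[length(out) + 1L]] <- list(first = members[1],
                                      last = members[length(members)])
  }
  out
}

#' Mobile-residue selection for backbone sampling
#'
#' Builds the residue set allowed to move in backbone space and its
#' contiguous fragments with pivot residues. Modes: interface patches at
#' 5.5 or 8 Angstrom, optionally augmented with all loop residues of the
#' monomers, or a user-directed list.
#'
#' @param pose `coarse_pose`.
#' @param mode one of `"interface_5.5"`, `"interface_8"`,
#'   `"interface_5.5_plus_loops"`, `"interface_8_plus_loops"`, `"directed"`.
#' @param directed for `mode = "directed"`: data.frame with columns `chain`
#'   and `seq` (author numbering), or a character vector of `"A:12"` /
#'   `"A:3-9"` entries.
#' @param min_len minimum fragment length.
#' @return object of class `mobile_selection`: `residues` (data.frame with
#'   `partner`, `chain`, `seq`, `idx`) and `fragments`
#'   (list of `list(partner, first, last)`).
#' @export
mobile_selection <- function(pose,
                             mode = c("interface_8", "interface_5.5",
                                      "interface_8_plus_loops",
                                      "interface_5.5_plus_loops", "directed"),
                             directed = NULL, min_len = 3L) {
  mode <- match.arg(mode)
  if (mode == "directed") {
    if (is.null(directed)) stop("directed mode requires a residue list")
    if (is.character(directed)) directed <- parse_residue_list(directed)
    if (!nrow(directed)) stop("directed mode requires a non-empty residue list")
    pick <- function(ch) which(paste(ch$chain, ch$seq) %in%
                                 paste(directed$chain, directed$seq))
    sel <- list(receptor = pick(pose$receptor), ligand = pick(pose$ligand))
  } else {
    cutoff <- if (grepl("5.5", mode, fixed = TRUE)) 5.5 else 8
    sel <- select_interface(pose, cutoff)
    if (grepl("plus_loops", mode)) {
      sel$receptor <- add_loop_residues(sel$receptor,
                                        assign_secstruct(pose$receptor))
      sel$ligand <- add_loop_residues(sel$ligand,
                                      assign_secstruct(pose$ligand))
    }
  }
  frags <- c(
    lapply(contiguous_fragments(sel$receptor, pose$receptor, min_len),
           function(f) c(list(partner = "receptor"), f)),
    lapply(contiguous_fragments(sel$ligand, pose$ligand, min_len),
           function(f) c(list(partner = "ligand"), f))
  )
  res <- rbind(
    if (length(sel$receptor))
      data.frame(partner = "receptor", chain = pose$receptor$chain[sel$receptor],
                 seq = pose$receptor$seq[sel$receptor], idx = sel$receptor),
    if (length(sel$ligand))
      data.frame(partner = "ligand", chain = pose$ligand$chain[sel$ligand],
                 seq = pose$ligand$seq[sel$ligand], idx = sel$ligand)
  )
  structure(list(mode = mode, residues = res, fragments = frags),
            class = "mobile_selection")
}

#' Parse a directed mobile-residue list
#'
#' Accepts lines of the form `"A:12"` or `"A:3-9"`.
#' @param lines character vector (or path of a file of such lines via
#'   [readLines()] by the caller).
#' @return data.frame with columns `chain`, `seq`.
#' @export
parse_residue_list <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9]):([0-9]+)(-([0-9]+))?$", ln))[[1]]
    if (!length(m)) stop("cannot parse residue spec: ", ln)
    from <- as.integer(m[3])
    to <- if (nzchar(m[5])) as.integer(m[5]) else from
    out[[length(out) + 1L]] <- data.frame(chain = m[2], seq = from:to)
  }
  do.call(rbind, out)
}

#' Rigid-body move proposal
#'
#' Perturbs the ligand jump by a Gaussian translation (`rigid_trans_sigma`
#' per axis) and a rotation about a uniform random axis through the ligand
#' centroid with Gaussian angle (`rigid_rot_sigma`). Symmetric proposal;
#' the receptor never moves.
#'
#' @param pose `coarse_pose`.
#' @param schedule [move_schedule()].
#' @return proposed `coarse_pose`.
#' @export
rigid_move <- function(pose, schedule = move_schedule()) {
  ang <- stats::rnorm(1, 0, schedule$rigid_rot_sigma)
  axis <- random_unit_vector()
  tr <- stats::rnorm(3, 0, schedule$rigid_trans_sigma)
  ctr <- colMeans(atom_xyz(pose$ligand, "CA"))
  delta <- rotation_about_point(axis_angle_matrix(axis, ang), ctr)
  delta$t <- delta$t + tr
  pose_perturb_jump(pose, delta)
}

#' Backbone (Backrub) move proposal
#'
#' Chooses one fragment of the selection uniformly and applies a Backrub
#' rotation with angle drawn uniformly in the schedule's range. Residues
#' outside the chosen fragment never move.
#'
#' @param pose `coarse_pose`.
#' @param selection [mobile_selection()].
#' @param schedule [move_schedule()].
#' @return proposed `coarse_pose`.
#' @export
backbone_move <- function(pose, selection, schedule = move_schedule()) {
  frags <- selection$fragments
  if (!length(frags)) stop("no mobile fragments")
  f <- frags[[sample.int(length(frags), 1L)]]
  ang <- stats::runif(1, -schedule$backrub_max_angle, schedule$backrub_max_angle)
  if (f$partner == "receptor") {
    pose$receptor <- backrub_rotate(pose$receptor, f$first, f$last, ang)
  } else {
    moved <- backrub_rotate(pose$ligand, f$first, f$last, ang)
    pose <- pose_set_ligand_xyz(pose, moved$xyz)
  }
  pose
}

#' Randomized global-docking start pose
#'
#' Both partners are independently rotated by uniform random rotations about
#' their centroids, the ligand is placed at a uniform random direction from
#' the receptor at a non-overlapping distance, and the partners are slid
#' into contact.
#'
#' @param receptor,ligand `coarse_chain` monomers.
#' @return `coarse_pose` in surface contact.
#' @export
init_global <- function(receptor, ligand) {
  rc <- colMeans(atom_xyz(receptor, "CA"))
  receptor$xyz <- rt_apply(rotation_about_point(random_rotation(), rc),
                           receptor$xyz)
  lc <- colMeans(atom_xyz(ligand, "CA"))
  ligand$xyz <- rt_apply(rotation_about_point(random_rotation(), lc), ligand$xyz)
  rad <- function(ch, c0) max(sqrt(rowSums(sweep(ch$xyz, 2, c0)^2)))
  u <- random_unit_vector()
  target <- rc + u * (rad(receptor, rc) + rad(ligand, lc) + 10)
  ligand$xyz <- sweep(ligand$xyz, 2, target - lc, `+`)
  slide_into_contact(coarse_pose(receptor, ligand))
}

#' Local-docking start pose (separate-and-rotate setup)
#'
#' If a bound reference is given, both unbound monomers are first superposed
#' onto their bound counterparts (backbone Kabsch). The ligand is then
#' translated 15 Angstrom along the receptor-to-ligand centroid axis and
#' rotated 45 degrees about that axis (through the ligand centroid). With
#' `perturb`, an additional Gaussian perturbation (1 Angstrom translation per
#' axis, 1 degree rotation about a random axis) differentiates trajectory
#' starts; with `perturb = FALSE` the 15 Angstrom / 45 degree offsets are
#' exact.
#'
#' @param receptor,ligand unbound `coarse_chain` monomers.
#' @param bound_reference optional bound `coarse_pose` to superpose onto.
#' @param perturb apply the Gaussian start perturbation.
#' @param separation,rotation offsets (Angstrom, degrees).
#' @return `coarse_pose`.
#' @export
init_local <- function(receptor, ligand, bound_reference = NULL,
                       perturb = TRUE, separation = 15, rotation = 45) {
  if (!is.null(bound_reference)) {
    receptor <- superpose_chain(receptor, bound_reference$receptor)
    ligand <- superpose_chain(ligand, bound_reference$ligand)
  }
  rc <- colMeans(atom_xyz(receptor, "CA"))
  lc <- colMeans(atom_xyz(ligand, "CA"))
  sep <- lc - rc
  if (vnorm(sep) < 1e-6) stop("undefined separation axis")
  u <- unit(sep)
  tf <- rotation_about_point(axis_angle_matrix(u, rotation), lc)
  tf$t <- tf$t + separation * u
  ligand$xyz <- rt_apply(tf, ligand$xyz)
  if (perturb) {
    dtr <- stats::rnorm(3, 0, 1)
    dang <- stats::rnorm(1, 0, 1)
    dax <- random_unit_vector()
    lc2 <- colMeans(atom_xyz(ligand, "CA"))
    ptf <- rotation_about_point(axis_angle_matrix(dax, dang), lc2)
    ptf$t <- ptf$t + dtr
    ligand$xyz <- rt_apply(ptf, ligand$xyz)
  }
  coarse_pose(receptor, ligand)
}

# Superpose a chain onto a reference chain (backbone Kabsch over residues
# matched by chain id + author number); returns the moved chain.
superpose_chain <- function(ch, ref) {
  key <- paste(ch$chain, ch$seq)
  rkey <- paste(ref$chain, ref$seq)
  common <- intersect(key, rkey)
  i <- match(common, key)
  j <- match(common, rkey)
  if (length(i) < 3L) stop("insufficient residue correspondence for superposition")
  fit <- kabsch(backbone_xyz(ch, i), backbone_xyz(ref, j))
  ch$xyz <- rt_apply(fit$transform, ch$xyz)
  ch
}

#' Slide partners into surface contact
#'
#' Translates the ligand along the centroid axis in fixed small steps until
#' the closest inter-chain coarse-atom distance first falls inside
#' `[contact_lo, contact_hi]`, backing off one step if it lands below
#' `contact_lo`. Poses already within `contact_hi` are returned unchanged.
#'
#' @param pose `coarse_pose` with separated chains.
#' @param contact_lo,contact_hi target closest-distance window (Angstrom).
#' @param step step size (Angstrom).
#' @param max_travel error out after this much travel (Angstrom).
#' @return `coarse_pose` in contact.
#' @export
slide_into_contact <- function(pose, contact_lo = 3.5, contact_hi = 4.5,
                               step = 0.2, max_travel = 200) {
  min_dist <- function(p) min(cross_dist(p$receptor$xyz, p$ligand$xyz))
  d <- min_dist(pose)
  if (d <= contact_hi) return(pose)
  rc <- colMeans(atom_xyz(pose$receptor, "CA"))
  lc <- colMeans(atom_xyz(pose$ligand, "CA"))
  sep <- lc - rc
  if (vnorm(sep) < 1e-6) stop("undefined separation axis")
  u <- unit(sep)
  travel <- 0
  while (travel <= max_travel) {
    pose <- pose_perturb_jump(pose, rigid_transform(diag(3), -step * u))
    travel <- travel + step
    d <- min_dist(pose)
    if (d <= contact_hi) {
      if (d < contact_lo)
        pose <- pose_perturb_jump(pose, rigid_transform(diag(3), step * u))
      return(pose)
    }
  }
  stop("no contact achievable within ", max_travel, " Angstrom of travel")
}
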