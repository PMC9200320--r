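# Low-resolution composite score (Motif-Updated-Dock-Score analogue).
#
# Terms:
#   e_motif          knowledge-based residue-pair-transform term (inter-chain)
#   e_lj_rep/e_attr  soft 6-12 Lennard-Jones clash/contact terms over coarse
#                    atoms, inter-chain plus long-range intra-chain pairs
#   e_rama           -log p(phi, psi | residue class), analytic surrogate
#   e_omega          planarity penalty on the omega torsion
#   e_aa_propensity  -log p(class | phi, psi), same surface normalized the
#                    other way
#
# The genuine PDB-mined motif table is not shipped; the module provides the
# exact binned-lookup machinery plus a builder (train on any structure set)
# and a smooth analytic surrogate well as the offline default.

#' Weights of the composite low-resolution score
#'
#' Defaults follow the "0.1X" weighting of the non-motif terms relative to
#' the pair-transform term.
#' @param w_motif,w_lj_rep,w_lj_attr,w_rama,w_omega,w_aa_propensity
#'   dimensionless multipliers.
#' @export
muds_weights <- function(w_motif = 1, w_lj_rep = 0.1, w_lj_attr = 0.1,
                         w_rama = 0.1, w_omega = 0.1, w_aa_propensity = 0.1) {
  w <- c(w_motif = w_motif, w_lj_rep = w_lj_rep, w_lj_attr = w_lj_attr,
         w_rama = w_rama, w_omega = w_omega, w_aa_propensity = w_aa_propensity)
  stopifnot(all(is.finite(w)))
  w
}

#' Refinement-stage weights (no motif term)
#' @export
refine_weights <- function() muds_weights(w_motif = 0, w_lj_rep = 0.1,
                                          w_lj_attr = 0.1, w_rama = 0.1,
                                          w_omega = 0.1, w_aa_propensity = 0.1)

#' Lennard-Jones parameters for coarse atoms
#'
#' One homogeneous atom type: `r_min` is the pair-minimum distance, `eps`
#' the well depth, `cutoff` the truncation distance. Below `cap_frac * r_min`
#' the repulsive branch continues linearly (value and slope matched) so
#' deep overlaps stay finite.
#' @export
lj_params <- function(r_min = 3.2, eps = 0.2, cutoff = 8.0, cap_frac = 0.6,
                      intra_min_sep = 4L) {
  list(r_min = r_min, eps = eps, cutoff = cutoff, cap_frac = cap_frac,
       intra_min_sep = intra_min_sep)
}

# Split 6-12 LJ: repulsive branch (r < r_min, shifted to 0 at r_min,
# linearly capped below cap_frac * r_min) and attractive branch
# (r_min <= r < cutoff). Vectorized over r.
lj_split <- function(r, p) {
  lj <- function(rr) p$eps * ((p$r_min / rr)^12 - 2 * (p$r_min / rr)^6)
  rep_e <- numeric(length(r))
  attr_e <- numeric(length(r))
  rcap <- p$cap_frac * p$r_min
  lo <- r < rcap
  mid <- !lo & r < p$r_min
  hi <- r >= p$r_min & r < p$cutoff
  if (any(mid)) rep_e[mid] <- lj(r[mid]) + p$eps
  if (any(lo)) {
    f0 <- lj(rcap) + p$eps
    # d/dr of eps((rm/r)^12 - 2 (rm/r)^6) at rcap
    slope <- p$eps * (-12 * p$r_min^12 / rcap^13 + 12 * p$r_min^6 / rcap^7)
    rep_e[lo] <- f0 + slope * (r[lo] - rcap)
  }
  if (any(hi)) attr_e[hi] <- lj(r[hi])
  list(rep = rep_e, attr = attr_e)
}

# Flat pairwise distances between two coordinate matrices.
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * (A %*% t(B))
  sqrt(pmax(d2, 0))
}

#' Lennard-Jones clash/contact terms of a pose
#'
#' Sums the split LJ over all inter-chain coarse-atom pairs and over
#' intra-chain pairs more than `intra_min_sep` residues apart (both chains).
#'
#' @param pose `coarse_pose`.
#' @param params [lj_params()].
#' @return named numeric `c(e_rep, e_attr)` with `e_rep >= 0`,
#'   `e_attr <= 0`.
#' @export
lj_terms <- function(pose, params = lj_params()) {
  intra <- function(ch) {
    if (ch$n < 2L) return(c(0, 0))
    D <- cross_dist(ch$xyz, ch$xyz)
    ri <- atom_res_index(ch)
    sep_ok <- abs(outer(ri, ri, `-`)) > params$intra_min_sep
    same_chain <- outer(ch$chain[ri], ch$chain[ri], `==`)
    m <- upper.tri(D) & sep_ok & same_chain & D < params$cutoff
    s <- lj_split(D[m], params)
    c(sum(s$rep), sum(s$attr))
  }
  D <- cross_dist(pose$receptor$xyz, pose$ligand$xyz)
  m <- D < params$cutoff
  s <- lj_split(D[m], params)
  tot <- c(sum(s$rep), sum(s$attr)) + intra(pose$receptor) + intra(pose$ligand)
  c(e_rep = tot[1], e_attr = tot[2])
}

# --- backbone torsion statistics ------------------------------------------

# Analytic Ramachandran surrogate: per residue class, a mixture of products
# of von Mises densities in phi and psi. Classes: general, glycine, proline,
# pre-proline. These are stand-ins preserving the scoring roles (low energy
# in the canonical basins, high outside), not fits to PDB statistics.
RAMA_BASINS <- list(
  general = data.frame(
    mu_phi = c(-63, -120, 55), mu_psi = c(-43, 130, 45),
    kappa_phi = c(8, 5, 8), kappa_psi = c(8, 4, 8),
    w = c(0.45, 0.45, 0.10)),
  gly = data.frame(
    mu_phi = c(-80, 80, -150, 100), mu_psi = c(-30, 30, 160, -160),
    kappa_phi = c(3, 3, 3, 3), kappa_psi = c(3, 3, 3, 3),
    w = c(0.3, 0.3, 0.2, 0.2)),
  pro = data.frame(
    mu_phi = c(-62, -62), mu_psi = c(-35, 145),
    kappa_phi = c(14, 14), kappa_psi = c(8, 8),
    w = c(0.5, 0.5)),
  prepro = data.frame(
    mu_phi = c(-63, -125, 50), mu_psi = c(-40, 135, 45),
    kappa_phi = c(7, 6, 7), kappa_psi = c(7, 5, 7),
    w = c(0.30, 0.60, 0.10))
)

vm_density <- function(x_deg, mu_deg, kappa) {
  exp(kappa * cos(deg2rad(x_deg - mu_deg))) / (2 * pi * besselI(kappa, 0))
}

#' Ramachandran surrogate density
#'
#' @param phi,psi angles in degrees (vectorized).
#' @param class one of `"general"`, `"gly"`, `"pro"`, `"prepro"`.
#' @return density value(s) of the packaged surface (radian^-2 measure).
#' @export
rama_density <- function(phi, psi, class = "general") {
  b <- RAMA_BASINS[[match.arg(class, names(RAMA_BASINS))]]
  out <- 0
  for (k in seq_len(nrow(b))) {
    out <- out + b$w[k] * vm_density(phi, b$mu_phi[k], b$kappa_phi[k]) *
      vm_density(psi, b$mu_psi[k], b$kappa_psi[k])
  }
  out
}

# Residue torsion class vector for a chain.
rama_class <- function(ch) {
  cls <- rep("general", ch$n)
  cls[ch$aa == "G"] <- "gly"
  cls[ch$aa == "P"] <- "pro"
  nextp <- c(ch$aa[-1] == "P" & ch$chain[-1] == ch$chain[-ch$n], FALSE)
  cls[nextp & cls == "general"] <- "prepro"
  cls
}

#' Backbone torsion-statistics terms of a chain
#'
#' `e_rama` sums -log p(phi, psi | class) over the packaged surrogate
#' surface; `e_omega` penalizes deviation from planar omega (trans or cis)
#' as `k * min((omega - 180)^2, omega^2)` in degrees; `e_aa_propensity` sums
#' -log p(class | phi, psi) with a uniform prior over the four classes.
#' Residues with undefined dihedrals contribute nothing.
#'
#' @param ch `coarse_chain`.
#' @param omega_k prefactor of the omega penalty (per squared degree).
#' @return named numeric `c(e_rama, e_omega, e_aa_propensity)`.
#' @export
torsion_stats <- function(ch, omega_k = 0.005) {
  dih <- backbone_dihedrals(ch)
  cls <- rama_class(ch)
  ok <- !is.na(dih$phi) & !is.na(dih$psi)
  e_rama <- 0; e_aa <- 0
  if (any(ok)) {
    dens <- matrix(0, sum(ok), length(RAMA_BASINS))
    colnames(dens) <- names(RAMA_BASINS)
    for (cl in names(RAMA_BASINS))
      dens[, cl] <- rama_density(dih$phi[ok], dih$psi[ok], cl)
    own <- dens[cbind(seq_len(nrow(dens)), match(cls[ok], colnames(dens)))]
    e_rama <- sum(-log(pmax(own, 1e-300)))
    e_aa <- sum(-log(pmax(own / rowSums(dens), 1e-300)))
  }
  om <- dih$omega[!is.na(dih$omega)]
  dev180 <- pmin(abs(om - 180), abs(om + 180))
  e_omega <- omega_k * sum(pmin(dev180^2, om^2))
  c(e_rama = e_rama, e_omega = e_omega, e_aa_propensity = e_aa)
}

# --- residue-pair-transform term ------------------------------------------

# Coarse amino-acid classes used to key the pair table (keeps trainable
# tables dense enough for small training sets).
aa_pair_class <- function(aa) {
  cls <- rep("p", length(aa))
  cls[aa %in% c("A", "V", "L", "I", "M", "F", "W", "C")] <- "h"
  cls[aa %in% c("K", "R", "H")] <- "+"
  cls[aa %in% c("D", "E")] <- "-"
  cls[aa == "G"] <- "g"
  cls[aa == "P"] <- "P"
  cls
}

#' Smooth analytic surrogate for the pair-transform score
#'
#' The offline default standing in for a PDB-mined table: a distance- and
#' orientation-dependent well. Each inter-chain residue pair within `range`
#' contributes `-depth * exp(-(d - d0)^2 / (2 sigma^2)) * f_orient`, where
#' `d` is the CA-CA distance and `f_orient` in `[0, 1]` favors sidechains
#' (CA->CB vectors) pointing at each other. Smooth, and invariant to global
#' rigid motion.
#' @param depth,d0,sigma,range well parameters (Angstrom; energy units).
#' @export
pair_surrogate <- function(depth = 1, d0 = 6, sigma = 1.5, range = 10) {
  structure(list(depth = depth, d0 = d0, sigma = sigma, range = range),
            class = c("pair_surrogate", "pair_score_model"))
}

#' Binned 6-D residue-pair-transform score table
#'
#' Histogram-derived log-odds score over the 6 coordinates of
#' [pair_transform()]: translation components binned on `t_edges` (Angstrom)
#' and rotation-vector components on `r_edges` (radians), keyed additionally
#' by the (receptor class, ligand class) pair. Sparse storage: only observed
#' bins are kept; a bin absent from both foreground and background scores 0.
#'
#' @param counts,expected named count vectors (bin keys).
#' @param t_edges,r_edges bin edges.
#' @param range CA-CA distance range (Angstrom) of the term.
#' @param pseudocount additive smoothing count.
#' @param meta free-form training-set description.
#' @export
pair_table <- function(counts, expected, t_edges, r_edges, range = 10,
                       pseudocount = 1, meta = "") {
  structure(list(counts = counts, expected = expected, t_edges = t_edges,
                 r_edges = r_edges, range = range, pseudocount = pseudocount,
                 meta = meta),
            class = c("pair_table", "pair_score_model"))
}

# Bin key of one pair transform, or NA when out of range.
pair_bin_key <- function(clsA, clsB, tr, table) {
  it <- findInterval(tr$t, table$t_edges, rightmost.closed = TRUE)
  ir <- findInterval(tr$rv, table$r_edges, rightmost.closed = TRUE)
  if (any(it < 1L) || any(it >= length(table$t_edges)) ||
      any(ir < 1L) || any(ir >= length(table$r_edges))) return(NA_character_)
  paste(clsA, clsB, it[1], it[2], it[3], ir[1], ir[2], ir[3], sep = ":")
}

pair_table_lookup <- function(table, key) {
  if (is.na(key)) return(0)
  cnt <- unname(table$counts[key])
  exp_ <- unname(table$expected[key])
  if (is.na(cnt)) cnt <- 0
  if (is.na(exp_)) exp_ <- 0
  if (cnt == 0 && exp_ == 0) return(0)
  -log((cnt + table$pseudocount) / (exp_ + table$pseudocount))
}

# Inter-chain residue pairs with CA-CA distance <= range.
contact_pairs <- function(pose, range) {
  D <- cross_dist(atom_xyz(pose$receptor, "CA"), atom_xyz(pose$ligand, "CA"))
  which(D <= range, arr.ind = TRUE)
}

#' Residue-pair-transform score of a pose
#'
#' Sum over inter-chain residue pairs within the model's range of the pair
#' score, either from a trained [pair_table()] or the analytic
#' [pair_surrogate()]. Invariant to global rigid motion of the complex.
#'
#' @param pose `coarse_pose`.
#' @param model `pair_table` or `pair_surrogate`.
#' @return scalar `e_motif`.
#' @export
pair_transform_score <- function(pose, model = pair_surrogate()) {
  UseMethod("pair_transform_score", model)
}

#' @export
pair_transform_score.pair_surrogate <- function(pose, model = pair_surrogate()) {
  idx <- contact_pairs(pose, model$range)
  if (!nrow(idx)) return(0)
  ca_r <- atom_xyz(pose$receptor, "CA", idx[, 1])
  ca_l <- atom_xyz(pose$ligand, "CA", idx[, 2])
  cb_r <- atom_xyz(pose$receptor, "CB", idx[, 1])
  cb_l <- atom_xyz(pose$ligand, "CB", idx[, 2])
  v <- ca_l - ca_r
  d <- sqrt(rowSums(v * v))
  un <- v / pmax(d, 1e-12)
  dir_r <- cb_r - ca_r
  dir_l <- cb_l - ca_l
  nr <- sqrt(rowSums(dir_r^2)); nl <- sqrt(rowSums(dir_l^2))
  ca_ <- rowSums(dir_r * un) / pmax(nr, 1e-12)
  cb_ <- rowSums(dir_l * (-un)) / pmax(nl, 1e-12)
  fo <- 0.25 * (1 + ca_) * (1 + cb_)
  -model$depth * sum(exp(-(d - model$d0)^2 / (2 * model$sigma^2)) * fo)
}

#' @export
pair_transform_score.pair_table <- function(pose, model) {
  idx <- contact_pairs(pose, model$range)
  if (!nrow(idx)) return(0)
  cls_r <- aa_pair_class(pose$receptor$aa)
  cls_l <- aa_pair_class(pose$ligand$aa)
  tot <- 0
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    tr <- pair_transform(pose$receptor, i, pose$ligand, j)
    tot <- tot + pair_table_lookup(model, pair_bin_key(cls_r[i], cls_l[j], tr, model))
  }
  tot
}

#' Train a pair-transform table from complexes
#'
#' Tallies the binned 6-D transforms of all inter-chain contacts in the
#' training complexes (foreground) against a shuffled-orientation background
#' (random rigid re-orientations of each ligand about its centroid) and
#' scores each bin as `-log((count + pc) / (expected + pc))`, with the
#' background rescaled to the foreground total.
#'
#' @param complexes list of `coarse_pose`.
#' @param t_bin,r_bin_deg bin widths (Angstrom; degrees).
#' @param range CA-CA range (Angstrom).
#' @param pseudocount additive smoothing count.
#' @param n_shuffle background orientations per complex.
#' @param seed RNG seed for the background shuffle.
#' @return [pair_table()].
#' @export
build_pair_table <- function(complexes, t_bin = 1, r_bin_deg = 30, range = 10,
                             pseudocount = 1, n_shuffle = 20, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  t_edges <- seq(-range, range, by = t_bin)
  r_edges <- seq(-pi, pi, by = deg2rad(r_bin_deg))
  if (r_edges[length(r_edges)] < pi) r_edges <- c(r_edges, pi)
  tmpl <- list(t_edges = t_edges, r_edges = r_edges, range = range)

  tally <- function(pose, env) {
    idx <- contact_pairs(pose, range)
    if (!nrow(idx)) return(0L)
    cls_r <- aa_pair_class(pose$receptor$aa)
    cls_l <- aa_pair_class(pose$ligand$aa)
    n <- 0L
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      tr <- pair_transform(pose$receptor, i, pose$ligand, j)
      key <- pair_bin_key(cls_r[i], cls_l[j], tr, tmpl)
      if (is.na(key)) next
      env[[key]] <- (if (is.null(env[[key]])) 0 else env[[key]]) + 1
      n <- n + 1L
    }
    n
  }

  fg <- new.env(parent = emptyenv()); bg <- new.env(parent = emptyenv())
  n_fg <- 0L; n_bg <- 0L
  for (pose in complexes) {
    n_fg <- n_fg + tally(pose, fg)
    lc <- colMeans(atom_xyz(pose$ligand, "CA"))
    for (s in seq_len(n_shuffle)) {
      shuf <- pose_perturb_jump(pose, rotation_about_point(random_rotation(), lc))
      n_bg <- n_bg + tally(shuf, bg)
    }
  }
  if (n_fg == 0L) stop("no contacts in training set")
  counts <- unlist(as.list(fg))
  expected <- unlist(as.list(bg))
  if (length(expected)) expected <- expected * (n_fg / max(n_bg, 1L))
  if (!length(counts)) counts <- stats::setNames(numeric(0), character(0))
  if (!length(expected)) expected <- stats::setNames(numeric(0), character(0))
  pair_table(counts, expected, t_edges, r_edges, range, pseudocount,
             meta = sprintf("trained on %d complex(es), %d contacts",
                            length(complexes), n_fg))
}

#' Serialize / load a pair table (JSON container)
#' @param table [pair_table()].
#' @param path file path.
#' @export
save_pair_table <- function(table, path) {
  jsonlite::write_json(
    list(counts = as.list(table$counts), expected = as.list(table$expected),
         t_edges = table$t_edges, r_edges = table$r_edges,
         range = table$range, pseudocount = table$pseudocount,
         meta = table$meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_pair_table
#' @export
load_pair_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$t_edges) || is.null(x$r_edges))
    stop("malformed pair table: ", path)
  cnt <- unlist(x$counts); if (is.null(cnt)) cnt <- stats::setNames(numeric(0), character(0))
  exp_ <- unlist(x$expected); if (is.null(exp_)) exp_ <- stats::setNames(numeric(0), character(0))
  pair_table(cnt, exp_, x$t_edges, x$r_edges, x$range, x$pseudocount, x$meta)
}

# --- composite -------------------------------------------------------------

#' Composite low-resolution score of a pose
#'
#' @param pose `coarse_pose`.
#' @param weights [muds_weights()].
#' @param model pair-score model ([pair_surrogate()] default, or a trained
#'   [pair_table()]).
#' @param params [lj_params()].
#' @return object of class `score_breakdown`: per-term energies and the
#'   weighted `total`.
#' @export
muds <- function(pose, weights = muds_weights(), model = pair_surrogate(),
                 params = lj_params()) {
  e_motif <- if (weights["w_motif"] != 0) pair_transform_score(pose, model) else 0
  lj <- lj_terms(pose, params)
  ts <- torsion_stats(pose$receptor) + torsion_stats(pose$ligand)
  terms <- c(e_motif = e_motif, e_lj_rep = unname(lj["e_rep"]),
             e_lj_attr = unname(lj["e_attr"]), e_rama = unname(ts["e_rama"]),
             e_omega = unname(ts["e_omega"]),
             e_aa_propensity = unname(ts["e_aa_propensity"]))
  total <- sum(unname(weights) * unname(terms))
  structure(c(as.list(terms), list(total = total, weights = weights)),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  for (k in c("e_motif", "e_lj_rep", "e_lj_attr", "e_rama", "e_omega",
              "e_aa_propensity"))
    cat(sprintf("  %-16s %10.4f\n", k, x[[k]]))
  cat(sprintf("  %-16s %10.4f\n", "total", x$total))
  invisible(x)
}

# Refinement-style score of a single chain (LJ intra + torsion terms).
chain_score_total <- function(ch, weights = refine_weights(),
                              params = lj_params()) {
  D <- cross_dist(ch$xyz, ch$xyz)
  ri <- atom_res_index(ch)
  sep_ok <- abs(outer(ri, ri, `-`)) > params$intra_min_sep
  same_chain <- outer(ch$chain[ri], ch$chain[ri], `==`)
  m <- upper.tri(D) & sep_ok & same_chain & D < params$cutoff
  s <- lj_split(D[m], params)
  ts <- torsion_stats(ch)
  sum(unname(weights[c("w_lj_rep", "w_lj_attr", "w_rama", "w_omega",
                       "w_aa_propensity")]) *
        c(sum(s$rep), sum(s$attr), unname(ts)))
}

#' Interface (binding) score of a pose
#'
#' `total(complex) - total(receptor alone) - total(ligand alone)` under the
#' refinement score (LJ + torsion terms, no motif term): a binding-energy-like
#' ranking quantity that vanishes for separated chains.
#'
#' @param pose `coarse_pose`.
#' @param weights weight set (default [refine_weights()]).
#' @param params [lj_params()].
#' @return scalar energy.
#' @export
interface_score <- function(pose, weights = refine_weights(),
                            params = lj_params()) {
  complex_total <- muds(pose, weights, model = NULL, params = params)$total
  complex_total - chain_score_total(pose$receptor, weights, params) -
    chain_score_total(pose$ligand, weights, params)
}
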