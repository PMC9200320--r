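# CAPRI-style evaluation: fnat, ligand/interface/C-alpha RMSDs, quality
# ranks, target difficulty, mobile-residue identification, enrichment and
# the bootstrapped expected-N5 success statistic.

#' CAPRI thresholds and cutoffs
#'
#' Contact cutoff for fnat, native-interface cutoff for the interface RMSD,
#' and the nested rank boundaries (acceptable / medium / high).
#' @export
capri_thresholds <- function(contact_cutoff = 5, interface_cutoff = 10) {
  list(contact_cutoff = contact_cutoff, interface_cutoff = interface_cutoff,
       acceptable = list(fnat = 0.1, lrmsd = 10, irmsd = 4),
       medium = list(fnat = 0.3, lrmsd = 5, irmsd = 2),
       high = list(fnat = 0.5, lrmsd = 1, irmsd = 1))
}

# Residue correspondence between two poses: dense indices (pred, native) per
# partner, matched on chain id + author residue number.
pose_correspondence <- function(pred, native) {
  one <- function(a, b) {
    ka <- paste(a$chain, a$seq); kb <- paste(b$chain, b$seq)
    common <- intersect(ka, kb)
    if (!length(common)) stop("no residue correspondence between poses")
    list(pred = match(common, ka), native = match(common, kb))
  }
  list(receptor = one(pred$receptor, native$receptor),
       ligand = one(pred$ligand, native$ligand))
}

# Inter-chain residue contact keys of a pose (any coarse-atom pair within
# cutoff), restricted to given residue index subsets.
contact_keys <- function(pose, cutoff, rec_idx = seq_len(pose$receptor$n),
                         lig_idx = seq_len(pose$ligand$n)) {
  rows_r <- as.vector(t(outer((rec_idx - 1L) * 6L, 1:6, `+`)))
  rows_l <- as.vector(t(outer((lig_idx - 1L) * 6L, 1:6, `+`)))
  D <- cross_dist(pose$receptor$xyz[rows_r, , drop = FALSE],
                  pose$ligand$xyz[rows_l, , drop = FALSE])
  hit <- which(D <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(character(0))
  ri <- rec_idx[(hit[, 1] - 1L) %/% 6L + 1L]
  li <- lig_idx[(hit[, 2] - 1L) %/% 6L + 1L]
  unique(paste(pose$receptor$chain[ri], pose$receptor$seq[ri],
               pose$ligand$chain[li], pose$ligand$seq[li], sep = "|"))
}

#' Fraction of native contacts
#'
#' Native contacts are inter-chain residue pairs with any coarse-atom pair
#' within `cutoff` in the native complex; fnat is the fraction recovered by
#' the prediction.
#'
#' @param pred,native `coarse_pose` objects sharing residue identity
#'   (chain id + author number).
#' @param cutoff contact cutoff (Angstrom).
#' @return fraction in `[0, 1]`.
#' @export
fnat <- function(pred, native, cutoff = 5) {
  corr <- pose_correspondence(pred, native)
  nat <- contact_keys(native, cutoff, corr$receptor$native, corr$ligand$native)
  if (!length(nat)) stop("no native interface")
  prd <- contact_keys(pred, cutoff, corr$receptor$pred, corr$ligand$pred)
  length(intersect(prd, nat)) / length(nat)
}

#' Ligand RMSD
#'
#' Backbone RMSD of the ligand after superposing the receptors.
#' @param pred,native `coarse_pose` objects.
#' @return Angstrom.
#' @export
lrmsd <- function(pred, native) {
  corr <- pose_correspondence(pred, native)
  fit <- kabsch(backbone_xyz(pred$receptor, corr$receptor$pred),
                backbone_xyz(native$receptor, corr$receptor$native))
  lig <- rt_apply(fit$transform, backbone_xyz(pred$ligand, corr$ligand$pred))
  rmsd_raw(lig, backbone_xyz(native$ligand, corr$ligand$native))
}

#' Interface RMSD
#'
#' Backbone RMSD over the native-interface residues (any coarse atom within
#' `interface_cutoff` of the partner in the native complex) after optimal
#' superposition on those same residues.
#' @param pred,native `coarse_pose` objects.
#' @param interface_cutoff native-interface definition cutoff (Angstrom).
#' @return Angstrom.
#' @export
irmsd <- function(pred, native, interface_cutoff = 10) {
  corr <- pose_correspondence(pred, native)
  sel <- select_interface(native, interface_cutoff)
  ri <- intersect(sel$receptor, corr$receptor$native)
  li <- intersect(sel$ligand, corr$ligand$native)
  if (length(ri) + length(li) < 1L) stop("no native interface")
  pr <- corr$receptor$pred[match(ri, corr$receptor$native)]
  pl <- corr$ligand$pred[match(li, corr$ligand$native)]
  X <- rbind(backbone_xyz(pred$receptor, pr), backbone_xyz(pred$ligand, pl))
  Y <- rbind(backbone_xyz(native$receptor, ri), backbone_xyz(native$ligand, li))
  rmsd_superposed(X, Y)
}

#' Whole-complex C-alpha RMSD
#'
#' CA RMSD over both chains after whole-complex superposition.
#' @param pred,native `coarse_pose` objects.
#' @return Angstrom.
#' @export
ca_rmsd <- function(pred, native) {
  corr <- pose_correspondence(pred, native)
  X <- rbind(atom_xyz(pred$receptor, "CA", corr$receptor$pred),
             atom_xyz(pred$ligand, "CA", corr$ligand$pred))
  Y <- rbind(atom_xyz(native$receptor, "CA", corr$receptor$native),
             atom_xyz(native$ligand, "CA", corr$ligand$native))
  rmsd_superposed(X, Y)
}

#' All docking metrics of a prediction
#'
#' @param pred,native `coarse_pose` objects.
#' @param thresholds [capri_thresholds()].
#' @return object of class `dock_metrics` with `fnat`, `irmsd`, `lrmsd`,
#'   `ca_rmsd` and `capri_rank`.
#' @export
dock_metrics <- function(pred, native, thresholds = capri_thresholds()) {
  m <- list(fnat = fnat(pred, native, thresholds$contact_cutoff),
            irmsd = irmsd(pred, native, thresholds$interface_cutoff),
            lrmsd = lrmsd(pred, native),
            ca_rmsd = ca_rmsd(pred, native))
  m$capri_rank <- capri_rank(m, thresholds)
  structure(m, class = "dock_metrics")
}

#' @export
print.dock_metrics <- function(x, ...) {
  cat(sprintf("fnat %.3f | irmsd %.2f A | lrmsd %.2f A | CA rmsd %.2f A | rank %d\n",
              x$fnat, x$irmsd, x$lrmsd, x$ca_rmsd, x$capri_rank))
  invisible(x)
}

#' CAPRI quality rank of a set of metrics
#'
#' Highest rank whose boundary conditions all hold: 3 = high, 2 = medium,
#' 1 = acceptable, 0 = incorrect.
#' @param metrics list with `fnat`, `lrmsd`, `irmsd`.
#' @param thresholds [capri_thresholds()].
#' @return integer rank in 0:3.
#' @export
capri_rank <- function(metrics, thresholds = capri_thresholds()) {
  meets <- function(b) metrics$fnat >= b$fnat &&
    (metrics$lrmsd <= b$lrmsd || metrics$irmsd <= b$irmsd)
  if (meets(thresholds$high)) return(3L)
  if (meets(thresholds$medium)) return(2L)
  if (meets(thresholds$acceptable)) return(1L)
  0L
}

#' Target difficulty from the unbound-to-bound deviation
#'
#' rigid for RMSD_BU < 1.2 Angstrom, medium for 1.2 <= RMSD_BU <= 2.2,
#' difficult above (the shared boundary 2.2 is assigned to medium).
#' @param rmsd_bu unbound-to-bound backbone RMSD (Angstrom, >= 0).
#' @return `"rigid"`, `"medium"` or `"difficult"`.
#' @export
classify_difficulty <- function(rmsd_bu) {
  if (rmsd_bu < 0) stop("RMSD must be non-negative")
  if (rmsd_bu < 1.2) "rigid" else if (rmsd_bu <= 2.2) "medium" else "difficult"
}

#' Mobile residues of an unbound monomer
#'
#' Superposes the unbound chain onto its bound counterpart (backbone Kabsch
#' over matched residues) and flags residues whose backbone RMSD after the
#' superposition exceeds `threshold`.
#'
#' @param unbound,bound `coarse_chain` objects of the same monomer.
#' @param threshold Angstrom (default 0.5).
#' @return data.frame with columns `chain`, `seq`, `rmsd` of mobile residues.
#' @export
identify_mobile_residues <- function(unbound, bound, threshold = 0.5) {
  ka <- paste(unbound$chain, unbound$seq)
  kb <- paste(bound$chain, bound$seq)
  common <- intersect(ka, kb)
  i <- match(common, ka); j <- match(common, kb)
  fit <- kabsch(backbone_xyz(unbound, i), backbone_xyz(bound, j))
  X <- rt_apply(fit$transform, backbone_xyz(unbound, i))
  Y <- backbone_xyz(bound, j)
  d2 <- rowSums((X - Y)^2)
  per_res <- sqrt(colMeans(matrix(d2, nrow = 4L)))
  mob <- which(per_res > threshold)
  data.frame(chain = unbound$chain[i[mob]], seq = unbound$seq[i[mob]],
             rmsd = per_res[mob])
}

#' Enrichment of good candidates among the top-scoring fraction
#'
#' Counts acceptable-or-better candidates among the lowest-scoring
#' `ceil(top_fraction * n)` models.
#'
#' @param scores candidate scores (lower is better).
#' @param quality_flags logical: acceptable-or-better.
#' @param top_fraction fraction of the set considered "top-scoring".
#' @param serial tie-break order (default input order).
#' @return integer count.
#' @export
enrichment <- function(scores, quality_flags, top_fraction = 0.10,
                       serial = seq_along(scores)) {
  n <- length(scores)
  stopifnot(n >= 10L, length(quality_flags) == n)
  k <- ceiling(top_fraction * n)
  top <- order(scores, serial)[seq_len(k)]
  sum(quality_flags[top])
}

#' Bootstrapped expected N5
#'
#' Per replicate, draws `n_draw` candidates with replacement, sorts by score
#' (ascending, serial tie-break) and counts near-native models among the
#' five top-scoring (N5). The expectation over `n_rep` replicates is the
#' expected N5; success is declared at expected N5 >= 3. Near-native flags
#' are supplied by the caller (low-resolution convention: C-alpha RMSD <= 5
#' Angstrom; high-resolution: CAPRI rank >= 1).
#'
#' @param scores candidate scores (lower is better).
#' @param near_native logical flags.
#' @param serial stable tie-break ids (default input order).
#' @param n_draw bootstrap sample size (default 1000).
#' @param n_rep bootstrap replicates (default 1000).
#' @return object of class `n5_result`: `samples` (integer in 0:5),
#'   `expected`, `success`.
#' @export
n5_bootstrap <- function(scores, near_native, serial = seq_along(scores),
                         n_draw = 1000L, n_rep = 1000L) {
  n <- length(scores)
  if (n < 5L) stop("need at least 5 candidates")
  stopifnot(length(near_native) == n, length(serial) == n)
  samples <- integer(n_rep)
  for (r in seq_len(n_rep)) {
    idx <- sample.int(n, n_draw, replace = TRUE)
    ord <- order(scores[idx], serial[idx])
    top5 <- idx[ord[1:5]]
    samples[r] <- sum(near_native[top5])
  }
  expected <- mean(samples)
  structure(list(samples = samples, expected = expected,
                 success = expected >= 3),
            class = "n5_result")
}

#' @export
print.n5_result <- function(x, ...) {
  cat(sprintf("<N5> = %.3f over %d bootstrap replicates -> %s\n",
              x$expected, length(x$samples),
              if (x$success) "SUCCESS (>= 3)" else "no success"))
  invisible(x)
}

#' Low-resolution near-native call
#'
#' @param ca_rmsd_value C-alpha RMSD to the native complex (Angstrom).
#' @param cutoff near-native boundary, 5 Angstrom for the low-resolution
#'   stage.
#' @export
near_native_lowres <- function(ca_rmsd_value, cutoff = 5) ca_rmsd_value <= cutoff
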