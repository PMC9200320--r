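# Refinement: zero-temperature quench with fine rigid-body moves, optional
# coordinate-descent minimization over the six jump parameters, and
# interface-score ranking. Stands in for all-atom refinement: side-chain
# packing is out of scope, so the stage's roles are reduced to clash relief
# and re-ranking under the LJ + torsion score.

#' Refinement configuration
#'
#' @param trans_sigma Gaussian sigma of fine rigid translations (Angstrom).
#' @param rot_sigma Gaussian sigma of fine rigid rotations (degrees).
#' @param n_quench_trials greedy quench proposals.
#' @param minimize follow the quench with coordinate-descent line searches
#'   over the six rigid-body jump parameters.
#' @param backrub_angle if a mobile selection is supplied to [refine()],
#'   small Backrub moves up to this angle are mixed into the quench.
#' @export
refine_config <- function(trans_sigma = 0.1, rot_sigma = 3,
                          n_quench_trials = 300L, minimize = TRUE,
                          backrub_angle = 3) {
  stopifnot(trans_sigma > 0, rot_sigma > 0, n_quench_trials >= 0)
  list(trans_sigma = trans_sigma, rot_sigma = rot_sigma,
       n_quench_trials = as.integer(n_quench_trials), minimize = minimize,
       backrub_angle = backrub_angle)
}

# Delta transform moving the ligand along one of the six jump coordinates:
# dims 1-3 translation (Angstrom) along the global axes, dims 4-6 rotation
# (degrees) about the global axes through the ligand centroid.
jump_delta <- function(pose, dim, value) {
  if (dim <= 3L) {
    t <- c(0, 0, 0); t[dim] <- value
    rigid_transform(diag(3), t)
  } else {
    ax <- c(0, 0, 0); ax[dim - 3L] <- 1
    rotation_about_point(axis_angle_matrix(ax, value),
                         colMeans(atom_xyz(pose$ligand, "CA")))
  }
}

#' Refine one candidate pose
#'
#' Greedy zero-temperature quench: fine rigid-body proposals (plus small
#' Backrub moves on the mobile fragments when a selection is given) are
#' accepted only if the refinement score (LJ + torsion terms) decreases.
#' Optionally followed by golden-section coordinate descent over the six
#' rigid-body jump parameters. Deterministic for a fixed seed; the returned
#' refinement score never exceeds the input score.
#'
#' @param pose `coarse_pose` (a low-resolution candidate).
#' @param config [refine_config()].
#' @param weights refinement weight set.
#' @param selection optional [mobile_selection()] enabling backbone moves.
#' @param seed optional seed (quench proposals use the session RNG).
#' @return list with `pose`, `interface_score`, `score` (refinement total),
#'   `breakdown` and the accepted-score `trace`.
#' @export
refine <- function(pose, config = refine_config(), weights = refine_weights(),
                   selection = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sched <- move_schedule(rigid_trans_sigma = config$trans_sigma,
                         rigid_rot_sigma = config$rot_sigma,
                         backrub_max_angle = max(config$backrub_angle, 1e-6))
  score_fn <- function(p) muds(p, weights, model = NULL)$total
  cur <- score_fn(pose)
  trace <- cur
  for (t in seq_len(config$n_quench_trials)) {
    use_bb <- !is.null(selection) && length(selection$fragments) &&
      stats::runif(1) < 0.5
    prop <- if (use_bb) backbone_move(pose, selection, sched)
            else rigid_move(pose, sched)
    s <- score_fn(prop)
    if (s < cur) {
      pose <- prop; cur <- s
      trace <- c(trace, cur)
    }
  }
  if (config$minimize) {
    for (sweep in 1:2) {
      for (dim in 1:6) {
        span <- if (dim <= 3L) 0.5 else 5
        f <- function(v) score_fn(pose_perturb_jump(pose, jump_delta(pose, dim, v)))
        opt <- stats::optimize(f, c(-span, span), tol = 1e-3)
        if (opt$objective < cur) {
          pose <- pose_perturb_jump(pose, jump_delta(pose, dim, opt$minimum))
          cur <- opt$objective
          trace <- c(trace, cur)
        }
      }
    }
  }
  list(pose = pose, interface_score = interface_score(pose, weights),
       score = cur, breakdown = muds(pose, weights, model = NULL),
       trace = trace)
}

#' Rank refined candidates by interface score
#'
#' Ascending interface score; ties broken by candidate serial (stable total
#' order).
#'
#' @param refined data.frame with columns `interface_score` and `serial`.
#' @return the data.frame reordered.
#' @export
rank_candidates <- function(refined) {
  if (!nrow(refined)) stop("no candidates to rank")
  refined[order(refined$interface_score, refined$serial), , drop = FALSE]
}
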