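# Temperature replica-exchange Monte Carlo scheduler.
#
# The scheduler is generic over an "MC system" (energy + symmetric proposal
# over some state), so the same machinery drives the docking engine and the
# 1-D toy systems used to verify Boltzmann correctness. Energies are treated
# as kcal/mol-compatible with the Boltzmann constant folded into the inverse
# temperatures.

#' Replica temperature ladder
#'
#' @param betas inverse temperatures (kcal^-1 mol), stored cold to hot
#'   (strictly decreasing). Default `c(1/1.5, 1/3, 1/5)`.
#' @param swap_interval MC trials between exchange attempts (default 1000).
#' @export
replica_ladder <- function(betas = c(1 / 1.5, 1 / 3, 1 / 5),
                           swap_interval = 1000L) {
  stopifnot(length(betas) >= 1L, all(betas > 0), swap_interval >= 1L)
  if (length(betas) > 1L && any(diff(betas) > 0))
    stop("betas must be non-increasing (cold to hot)")
  list(betas = betas, swap_interval = as.integer(swap_interval))
}

#' Run configuration
#'
#' Defaults follow the local-docking protocol: 8 trajectories of 2.5e5 MC
#' trials over 3 replicas with exchange attempts every 1000 trials.
#'
#' @param n_trajectories independent trajectories (seeded `seed + k`).
#' @param n_trials MC trials per replica per trajectory (2.5e5 local;
#'   use 1e6 or more for global searches).
#' @param ladder [replica_ladder()].
#' @param schedule [move_schedule()].
#' @param flex mobile-residue selection mode (see [mobile_selection()]).
#' @param directed residue list for `flex = "directed"`.
#' @param p_rigid probability of a rigid-body move per trial.
#' @param seed master seed.
#' @param store_all store snapshots of every replica at an accepted exchange
#'   round (default: coldest replica only).
#' @param refresh_selection recompute the interface selection every exchange
#'   round ("on-the-fly" at swap granularity).
#' @export
run_config <- function(n_trajectories = 8L, n_trials = 250000L,
                       ladder = replica_ladder(), schedule = move_schedule(),
                       flex = "interface_8", directed = NULL, p_rigid = NULL,
                       seed = 1L, store_all = FALSE,
                       refresh_selection = TRUE) {
  stopifnot(n_trajectories >= 1L, n_trials >= 1L)
  if (!is.null(p_rigid)) schedule$p_rigid <- p_rigid
  list(n_trajectories = as.integer(n_trajectories),
       n_trials = as.integer(n_trials), ladder = ladder, schedule = schedule,
       flex = flex, directed = directed, seed = as.integer(seed),
       store_all = store_all, refresh_selection = refresh_selection)
}

#' Metropolis acceptance for a move
#'
#' Accepts with probability `min(1, exp(-beta * delta_e))` using a single
#' uniform draw (taken even for downhill moves, keeping the RNG stream
#' aligned across code paths).
#'
#' @param delta_e energy change of the proposal.
#' @param beta inverse temperature (> 0).
#' @return logical.
#' @export
metropolis_accept <- function(delta_e, beta) {
  stopifnot(beta > 0)
  stats::runif(1) < exp(-beta * delta_e)
}

#' Replica-exchange swap acceptance probability
#'
#' The standard temperature-REMC Metropolis criterion
#' `min(1, exp((beta_i - beta_j) * (e_i - e_j)))`: symmetric under relabeling
#' of the pair, equal to 1 when the energies or the temperatures coincide,
#' and the unique form satisfying detailed balance across the ladder.
#'
#' @param e_i,e_j replica energies.
#' @param beta_i,beta_j inverse temperatures (> 0).
#' @return probability in `[0, 1]`.
#' @export
swap_accept_prob <- function(e_i, e_j, beta_i, beta_j) {
  stopifnot(beta_i > 0, beta_j > 0)
  min(1, exp((beta_i - beta_j) * (e_i - e_j)))
}

#' Generic MC system
#'
#' @param energy function(state) -> scalar energy.
#' @param propose function(state) -> proposed state (symmetric proposal
#'   density; uses the session RNG).
#' @param snapshot function(state) -> what to store in candidate records.
#' @param refresh optional function(state) -> NULL called once per exchange
#'   round (e.g. to recompute an interface selection held in the closure).
#' @export
mc_system <- function(energy, propose, snapshot = identity, refresh = NULL) {
  structure(list(energy = energy, propose = propose, snapshot = snapshot,
                 refresh = refresh), class = "mc_system")
}

#' One-dimensional quadratic toy system
#'
#' State is a scalar x with E(x) = x^2 / 2 and Gaussian step proposals; the
#' Boltzmann marginal at inverse temperature beta is Gaussian with variance
#' 1/beta and mean energy 1/(2 beta) (equipartition), giving closed-form
#' oracles for the scheduler.
#'
#' @param step_sigma proposal step standard deviation.
#' @export
toy_quadratic_system <- function(step_sigma = 1) {
  mc_system(energy = function(x) 0.5 * x * x,
            propose = function(x) x + stats::rnorm(1, 0, step_sigma))
}

#' Run one replica-exchange trajectory
#'
#' All replicas start from (a copy of) the state returned by `init`. Each
#' exchange round consists of `swap_interval` Metropolis trials per replica
#' followed by one exchange attempt per adjacent pair, alternating even and
#' odd pairs between rounds (deterministic even-odd scheme). On an accepted
#' swap the two replicas exchange configurations and energies; the inverse
#' temperatures stay with the ladder slots. After every round in which at
#' least one swap was accepted, a snapshot of the coldest replica (all
#' replicas with `store_all`) is stored as a candidate record.
#'
#' @param system [mc_system()].
#' @param init starting state, or a function() returning one (called after
#'   seeding, so stochastic starts are reproducible per trajectory).
#' @param ladder [replica_ladder()].
#' @param n_trials MC trials per replica.
#' @param seed trajectory seed.
#' @param store_all store all replicas' snapshots at accepted rounds.
#' @param record_every optionally record each replica's energy every this
#'   many trials (diagnostics; NULL to disable).
#' @return list with `candidates` (list of records with `state`, `energy`,
#'   `replica`, `round`, `trial`, `serial`), `diagnostics` (per-pair swap
#'   attempt/accept counts, per-round energy traces, optional energy
#'   samples) and `final_states`.
#' @export
run_trajectory <- function(system, init, ladder = replica_ladder(),
                           n_trials = 1000L, seed = 1L, store_all = FALSE,
                           record_every = NULL) {
  set.seed(seed)
  betas <- ladder$betas
  K <- length(betas)
  start <- if (is.function(init)) init() else init
  states <- rep(list(start), K)
  energies <- rep(system$energy(start), K)
  n_rounds <- n_trials %/% ladder$swap_interval
  sw_att <- integer(max(K - 1L, 1L))
  sw_acc <- integer(max(K - 1L, 1L))
  etrace <- matrix(NA_real_, n_rounds, K)
  esamples <- if (!is.null(record_every)) vector("list", K) else NULL
  candidates <- list()
  serial <- 0L
  trial <- 0L

  run_block <- function(k, nt) {
    st <- states[[k]]; en <- energies[k]; beta <- betas[k]
    if (is.null(record_every)) {
      for (t in seq_len(nt)) {
        prop <- system$propose(st)
        ep <- system$energy(prop)
        if (stats::runif(1) < exp(-beta * (ep - en))) {
          st <- prop; en <- ep
        }
      }
    } else {
      buf <- numeric(0)
      for (t in seq_len(nt)) {
        prop <- system$propose(st)
        ep <- system$energy(prop)
        if (stats::runif(1) < exp(-beta * (ep - en))) {
          st <- prop; en <- ep
        }
        if (t %% record_every == 0L) buf <- c(buf, en)
      }
      esamples[[k]] <<- c(esamples[[k]], buf)
    }
    states[[k]] <<- st
    energies[k] <<- en
  }

  for (round in seq_len(n_rounds)) {
    if (!is.null(system$refresh)) system$refresh(states[[1L]])
    for (k in seq_len(K)) run_block(k, ladder$swap_interval)
    trial <- trial + ladder$swap_interval
    # exchange attempts: even/odd adjacent pairs, alternating per round
    first <- if (round %% 2L == 1L) 1L else 2L
    any_acc <- FALSE
    if (K >= 2L && first <= K - 1L) {
      for (i in seq(first, K - 1L, by = 2L)) {
        j <- i + 1L
        sw_att[i] <- sw_att[i] + 1L
        p <- swap_accept_prob(energies[i], energies[j], betas[i], betas[j])
        if (stats::runif(1) < p) {
          sw_acc[i] <- sw_acc[i] + 1L
          tmp <- states[[i]]; states[[i]] <- states[[j]]; states[[j]] <- tmp
          te <- energies[i]; energies[i] <- energies[j]; energies[j] <- te
          any_acc <- TRUE
        }
      }
    }
    etrace[round, ] <- energies
    if (any_acc) {
      which_store <- if (store_all) seq_len(K) else 1L
      for (k in which_store) {
        serial <- serial + 1L
        candidates[[serial]] <- list(state = system$snapshot(states[[k]]),
                                     energy = energies[k], replica = k,
                                     round = round, trial = trial,
                                     serial = serial)
      }
      # drift trap: the cached energy must match a fresh evaluation
      e_chk <- system$energy(states[[1L]])
      if (abs(e_chk - energies[1L]) > 1e-4)
        stop(sprintf("energy drift detected: cached %.8g vs recomputed %.8g",
                     energies[1L], e_chk))
    }
  }
  rem <- n_trials - n_rounds * ladder$swap_interval
  if (rem > 0L) for (k in seq_len(K)) run_block(k, rem)

  list(candidates = candidates,
       diagnostics = list(swap_attempts = sw_att, swap_accepts = sw_acc,
                          energy_trace = etrace, energy_samples = esamples),
       final_states = states)
}

# Build the docking MC system for a pose + energy function.
docking_system <- function(energy_fn, schedule, flex = "interface_8",
                           directed = NULL, refresh_selection = TRUE) {
  env <- new.env(parent = emptyenv())
  env$selection <- NULL
  get_selection <- function(pose) {
    if (is.null(env$selection))
      env$selection <- mobile_selection(pose, flex, directed)
    env$selection
  }
  propose <- function(pose) {
    sel <- get_selection(pose)
    if (length(sel$fragments) == 0L || stats::runif(1) < schedule$p_rigid) {
      rigid_move(pose, schedule)
    } else {
      backbone_move(pose, sel, schedule)
    }
  }
  refresh <- if (refresh_selection && flex != "directed") {
    function(pose) {
      env$selection <- mobile_selection(pose, flex, directed)
      invisible(NULL)
    }
  } else NULL
  mc_system(energy = energy_fn, propose = propose, refresh = refresh)
}

#' Run a full docking simulation
#'
#' Drives `n_trajectories` independent replica-exchange trajectories (seeds
#' `seed + k`), each from a freshly perturbed start pose, and merges the
#' stored candidates with provenance. The default energy is the composite
#' low-resolution score with the analytic pair surrogate; any callable
#' `function(pose) -> energy` can be substituted (e.g. a
#' [funnel_energy_factory()] stand-in or a trained-table score).
#'
#' @param receptor,ligand unbound `coarse_chain` monomers.
#' @param config [run_config()].
#' @param energy optional energy callable; default `muds(...)$total`.
#' @param native optional bound `coarse_pose`: used as the superposition
#'   reference for the local start pose.
#' @param mode `"local"` (separate-and-rotate start) or `"global"`
#'   (randomized start).
#' @return object of class `dock_run`: `candidates` (data.frame with
#'   trajectory, replica, round, trial, serial, energy), `poses` (list of
#'   stored pose snapshots, parallel to the rows), `diagnostics` (per-pair
#'   exchange acceptance rates, per-replica energy traces) and `config`.
#' @export
run_simulation <- function(receptor, ligand, config = run_config(),
                           energy = NULL, native = NULL,
                           mode = c("local", "global")) {
  mode <- match.arg(mode)
  if (is.null(energy)) {
    model <- pair_surrogate()
    w <- muds_weights()
    energy <- function(pose) muds(pose, w, model)$total
  }
  all_rows <- list()
  all_poses <- list()
  diag_list <- list()
  for (k in seq_len(config$n_trajectories)) {
    tseed <- config$seed + k
    system <- docking_system(energy, config$schedule, config$flex,
                             config$directed, config$refresh_selection)
    init <- function() {
      if (mode == "local") {
        init_local(receptor, ligand, bound_reference = native, perturb = TRUE)
      } else {
        init_global(receptor, ligand)
      }
    }
    res <- run_trajectory(system, init, config$ladder, config$n_trials,
                          seed = tseed, store_all = config$store_all)
    for (cand in res$candidates) {
      all_rows[[length(all_rows) + 1L]] <- data.frame(
        trajectory = k, replica = cand$replica, round = cand$round,
        trial = cand$trial, traj_serial = cand$serial, energy = cand$energy)
      all_poses[[length(all_poses) + 1L]] <- cand$state
    }
    diag_list[[k]] <- res$diagnostics
  }
  candidates <- if (length(all_rows)) do.call(rbind, all_rows) else
    data.frame(trajectory = integer(0), replica = integer(0),
               round = integer(0), trial = integer(0),
               traj_serial = integer(0), energy = numeric(0))
  if (nrow(candidates)) candidates$serial <- seq_len(nrow(candidates))
  att <- Reduce(`+`, lapply(diag_list, function(d) d$swap_attempts))
  acc <- Reduce(`+`, lapply(diag_list, function(d) d$swap_accepts))
  structure(list(candidates = candidates, poses = all_poses,
                 diagnostics = list(swap_attempts = att, swap_accepts = acc,
                                    acceptance_rate = ifelse(att > 0, acc / att, NA),
                                    per_trajectory = diag_list),
                 config = config),
            class = "dock_run")
}

#' @export
print.dock_run <- function(x, ...) {
  cat(sprintf("<dock_run> %d candidates from %d trajectories\n",
              nrow(x$candidates), x$config$n_trajectories))
  if (length(x$diagnostics$acceptance_rate))
    cat("  exchange acceptance per adjacent pair:",
        sprintf("%.3f", x$diagnostics$acceptance_rate), "\n")
  invisible(x)
}
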