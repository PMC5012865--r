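#' Parameter grid for the homeostatic-network search
#'
#' The default grid scans the rule-sampling parameters: label counts `N`,
#' adaptor counts `A`, loading propensities `g` and fusion propensities
#' `f`, with `g` on a 0.05 grid and `f` additionally probed at 0.025,
#' 0.075 and 1. With `N = 4:7` this yields 8360 distinct combinations; the
#' reduced default (`N = 7` only) yields 2090.
#'
#' @param N,A,g,f vectors of parameter values.
#' @param replicates rule sets sampled per combination.
#' @return a data.frame with one row per (N, A, g, f) combination and the
#'   replication count as an attribute.
#' @export
sweep_grid <- function(N = 7L,
                       A = 1:5,
                       g = seq(0.05, 0.95, by = 0.05),
                       f = sort(c(seq(0.05, 0.95, by = 0.05), 0.025, 0.075, 1)),
                       replicates = 2L) {
  grid <- expand.grid(N = N, A = A, g = g, f = f,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$N, grid$A, grid$g, grid$f), , drop = FALSE]
  rownames(grid) <- NULL
  attr(grid, "replicates") <- as.integer(replicates)
  grid
}

#' Sample rules across a parameter grid and collect homeostatic networks
#'
#' For every parameter combination and replicate: draw a rule set, draw a
#' random initial condition, and iterate the Boolean dynamics up to
#' `max_steps` updates. Period-1 non-degenerate outcomes (homeostatic
#' states) are kept, together with their typed traffic networks when
#' `build_networks = TRUE`. All randomness flows through a per-run seed
#' stream derived from `seed`, so any single run can be replayed in
#' isolation via [replay_run()].
#'
#' @param grid a [sweep_grid()] data.frame.
#' @param seed master integer seed.
#' @param max_steps update cap per run (default 1024).
#' @param build_networks build a [build_network()] object for each
#'   homeostatic run (default TRUE).
#' @param progress print a progress line every 500 runs.
#' @return an object of class `traffic_sweep`: list with
#'   * `runs`: data.frame of per-run outcomes (parameters, `run_seed`,
#'     `reached`, `period`, `steps`, `degenerate`, `homeostatic`,
#'     `n_compartments`, `n_vesicle_types`, `n_homotypic`),
#'   * `networks`: list of `traffic_network` objects for the homeostatic
#'     runs (named by run row index),
#'   * `grid`, `seed`, `max_steps`.
#' @export
run_sweep <- function(grid = sweep_grid(), seed = 1L, max_steps = 1024L,
                      build_networks = TRUE, progress = FALSE) {
  replicates <- attr(grid, "replicates")
  if (is.null(replicates)) replicates <- 1L
  ncombo <- nrow(grid)
  nruns <- ncombo * replicates
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, nruns)

  combo_idx <- rep(seq_len(ncombo), each = replicates)
  runs <- data.frame(
    run = seq_len(nruns),
    N = grid$N[combo_idx], A = grid$A[combo_idx],
    g = grid$g[combo_idx], f = grid$f[combo_idx],
    replicate = rep(seq_len(replicates), times = ncombo),
    run_seed = run_seeds,
    reached = NA, period = NA_integer_, steps = NA_integer_,
    degenerate = NA, homeostatic = NA,
    n_compartments = NA_integer_, n_vesicle_types = NA_integer_,
    n_homotypic = NA_integer_
  )
  networks <- vector("list", nruns)

  for (r in seq_len(nruns)) {
    res <- replay_run(runs$N[r], runs$A[r], runs$g[r], runs$f[r],
                      run_seeds[r], max_steps = max_steps)
    orb <- res$orbit
    runs$reached[r] <- orb$reached
    runs$period[r] <- orb$period
    runs$steps[r] <- orb$steps_to_orbit
    runs$degenerate[r] <- orb$degenerate
    hom <- is_homeostatic(orb)
    runs$homeostatic[r] <- hom
    if (hom) {
      st <- orb$states[[1L]]
      runs$n_compartments[r] <- length(st)
      runs$n_vesicle_types[r] <- length(budded_vesicles(st, res$rules))
      runs$n_homotypic[r] <- length(orb$homotypic_types)
      if (build_networks) networks[[r]] <- build_network(res$rules, orb)
    }
    if (progress && r %% 500L == 0L) {
      message(sprintf("run %d / %d", r, nruns))
    }
  }
  keep <- !vapply(networks, is.null, logical(1))
  networks <- networks[keep]
  names(networks) <- as.character(which(keep))
  structure(
    list(runs = runs, networks = networks, grid = grid,
         seed = seed, max_steps = max_steps),
    class = "traffic_sweep"
  )
}

#' Replay a single sweep run from its seed
#'
#' Re-samples the rule set and initial condition from a recorded per-run
#' seed and re-runs the dynamics, reproducing the stored outcome exactly.
#'
#' @param N,A,g,f sampler parameters of the run.
#' @param run_seed the per-run seed recorded in the sweep table.
#' @param max_steps update cap.
#' @return list with `rules`, `initial` and `orbit`.
#' @export
replay_run <- function(N, A, g, f, run_seed, max_steps = 1024L) {
  set.seed(run_seed)
  rules <- sample_rules(N, A, g, f)
  rules$seed <- as.integer(run_seed)
  initial <- sample_initial_state(N)
  list(rules = rules, initial = initial,
       orbit = run_to_orbit(rules, initial, max_steps = max_steps))
}

#' @export
print.traffic_sweep <- function(x, ...) {
  r <- x$runs
  cat(sprintf(
    "<traffic_sweep> %d runs (%d combos); %.1f%% reached an orbit; %.1f%% of orbits homeostatic; %d networks stored\n",
    nrow(r), nrow(x$grid), 100 * mean(r$reached),
    100 * sum(r$homeostatic) / sum(r$reached), length(x$networks)
  ))
  invisible(x)
}

#' Summary counters of a sweep
#'
#' @param object a `traffic_sweep`.
#' @param ... unused.
#' @return list with run counts and the orbit-reached and homeostatic
#'   fractions (the latter over reached orbits, excluding the degenerate
#'   empty state from the numerator).
#' @export
summary.traffic_sweep <- function(object, ...) {
  r <- object$runs
  list(
    n_runs = nrow(r),
    n_reached = sum(r$reached),
    n_homeostatic = sum(r$homeostatic),
    frac_reached = mean(r$reached),
    frac_homeostatic = sum(r$homeostatic) / sum(r$reached)
  )
}
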