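ssa_args <- function(scenario) {
  net <- scenario$network
  sig <- signal_core_args(net, scenario$signal, scenario$ctx)
  init <- scenario$init[net$species]
  if (any(is.na(init))) stop("scenario initial counts must name every species")
  list(x0 = as.integer(init), stoich = net$stoich, react = net$reactants,
       rates = as.numeric(molecule_rates(net, scenario$ctx)), sig = sig,
       t0 = scenario$signal$t_start[1], species = net$species)
}

new_count_trajectory <- function(times, counts, species, scenario, seed) {
  colnames(counts) <- species
  structure(list(times = times, counts = counts, species = species,
                 scenario = scenario$name, seed = seed, unit = "molecules"),
            class = "count_trajectory")
}

#' @export
print.count_trajectory <- function(x, ...) {
  cat(sprintf("<count_trajectory> %s: %d records on [%g, %g], seed %d\n",
              paste(x$species, collapse = ","), length(x$times),
              x$times[1], x$times[length(x$times)], x$seed))
  invisible(x)
}

#' Exact stochastic (Gillespie) trajectory of a scenario
#'
#' Direct-method SSA for the scenario's network under its piecewise-constant
#' input. Propensities are recomputed after every reaction firing and the
#' next-reaction time is re-drawn at every signal switch (exact by
#' memorylessness of the exponential clock). With `record = "events"` every
#' reaction event is stored (queryable at arbitrary times by left-hold via
#' [trajectory_at()]); with `record = "grid"` only the scenario's output grid
#' (or `times`) is stored, which is what ensemble runs use.
#'
#' @param scenario A [scenario()].
#' @param record `"events"` or `"grid"`.
#' @param times Optional explicit record times for `record = "grid"`.
#' @param seed RNG seed; defaults to the scenario's master seed.
#' @param max_events Guard on the size of an event record.
#' @return A `count_trajectory`.
#' @export
ssa_run <- function(scenario, record = c("events", "grid"), times = NULL,
                    seed = scenario$seed, max_events = 5e6) {
  record <- match.arg(record)
  a <- ssa_args(scenario)
  set.seed(seed)
  if (record == "events") {
    out <- ssa_events_cpp(a$x0, a$stoich, a$react, a$rates,
                          a$sig$sig_scaled, a$sig$sig_species, a$sig$sig_t,
                          a$sig$sig_level, a$sig$sig_level_mol, a$t0,
                          signal_t_end(scenario$signal), as.integer(max_events))
    new_count_trajectory(out$times, out$counts, a$species, scenario, seed)
  } else {
    if (is.null(times)) times <- scenario$grid
    counts <- ssa_sample_cpp(a$x0, a$stoich, a$react, a$rates,
                             a$sig$sig_scaled, a$sig$sig_species, a$sig$sig_t,
                             a$sig$sig_level, a$sig$sig_level_mol, a$t0, times)
    new_count_trajectory(times, counts, a$species, scenario, seed)
  }
}

#' Query a trajectory at arbitrary times (left-hold)
#'
#' @param traj A `count_trajectory`.
#' @param times Query times at or after the first record.
#' @return Matrix `length(times) x n_species` of counts.
#' @export
trajectory_at <- function(traj, times) {
  stopifnot(inherits(traj, "count_trajectory"))
  if (any(times < traj$times[1])) stop("query before trajectory start")
  idx <- findInterval(times, traj$times)
  out <- traj$counts[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ensemble mean and variance over a simulated cell population
#'
#' Runs `n_cells` independent SSA trajectories (per-cell seeds derived as
#' `master seed + cell index`) and accumulates the per-time mean and
#' variance of every species at the scenario grid times. Deterministic given
#' the master seed, independent of how cells are chunked.
#'
#' @param scenario A [scenario()].
#' @param n_cells Population size; defaults to the scenario's.
#' @param times Record times (default the scenario grid).
#' @return An `ensemble_summary`: list with `times`, `mean`, `var`
#'   (times x species matrices), `n_cells`.
#' @export
ensemble_mean <- function(scenario, n_cells = scenario$n_cells, times = NULL) {
  stopifnot(n_cells >= 1)
  if (is.null(times)) times <- scenario$grid
  a <- ssa_args(scenario)
  s <- matrix(0, length(times), length(a$species))
  s2 <- matrix(0, length(times), length(a$species))
  for (cell in seq_len(n_cells)) {
    set.seed(scenario$seed + cell)
    x <- ssa_sample_cpp(a$x0, a$stoich, a$react, a$rates, a$sig$sig_scaled,
                        a$sig$sig_species, a$sig$sig_t, a$sig$sig_level,
                        a$sig$sig_level_mol, a$t0, times)
    s <- s + x
    s2 <- s2 + x * x
  }
  mean <- s / n_cells
  var <- if (n_cells > 1) (s2 - n_cells * mean^2) / (n_cells - 1) else s2 * 0
  var[var < 0] <- 0
  colnames(mean) <- colnames(var) <- a$species
  structure(list(times = times, mean = mean, var = var, n_cells = n_cells,
                 scenario = scenario$name, seed = scenario$seed,
                 unit = "molecules"),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %d cells, %d times, species %s\n",
              x$n_cells, length(x$times), paste(colnames(x$mean),
                                                collapse = ", ")))
  invisible(x)
}

#' Population snapshot sample at one time point
#'
#' Scheme A of the ergodicity comparison: `n_cells` independent runs, each
#' observed once at the same time `t_star` (a flow-cytometry-style snapshot).
#'
#' @param scenario A [scenario()].
#' @param n_cells Number of independent cells.
#' @param t_star Observation time (caller must ensure it lies beyond the
#'   relaxation time if a stationary sample is intended).
#' @return Matrix `n_cells x n_species` of copy numbers.
#' @export
snapshot_sample <- function(scenario, n_cells, t_star) {
  a <- ssa_args(scenario)
  if (t_star > signal_t_end(scenario$signal) || t_star < a$t0)
    stop("t_star outside scenario support")
  out <- matrix(0L, n_cells, length(a$species),
                dimnames = list(NULL, a$species))
  for (cell in seq_len(n_cells)) {
    set.seed(scenario$seed + cell)
    out[cell, ] <- ssa_sample_cpp(a$x0, a$stoich, a$react, a$rates,
                                  a$sig$sig_scaled, a$sig$sig_species,
                                  a$sig$sig_t, a$sig$sig_level,
                                  a$sig$sig_level_mol, a$t0, t_star)
  }
  out
}

#' Single-cell time-series sample
#'
#' Scheme B of the ergodicity comparison: one run observed at `n_points`
#' equally spaced times `t_star + k dt`, all beyond `t_star`.
#'
#' @param scenario A [scenario()]; its signal support must cover
#'   `t_star + (n_points - 1) dt`. For stationary sampling use a
#'   constant-signal scenario (e.g. via `overrides`).
#' @param t_star First observation time.
#' @param dt Spacing between observations.
#' @param n_points Number of observations.
#' @return Matrix `n_points x n_species` of copy numbers.
#' @export
timeseries_sample <- function(scenario, t_star, dt, n_points) {
  stopifnot(dt > 0, n_points >= 1)
  times <- t_star + dt * (seq_len(n_points) - 1)
  if (times[n_points] > signal_t_end(scenario$signal))
    stop("t_star + n_points * dt outside scenario support")
  traj <- ssa_run(scenario, record = "grid", times = times)
  traj$counts
}

#' Chemical Langevin (Euler-Maruyama) trajectory
#'
#' Diffusion approximation of the jump process in molecule units: each
#' reaction contributes drift `nu_r a_r(x)` and an independent noise channel
#' with amplitude `sqrt(a_r(x))` times its stoichiometric vector, matching
#' the SDE formulation of the motif (six channels for the linear model).
#' Propensity arguments are clamped at zero on negative excursions. Since
#' the drift of the linear model is affine, the path mean equals the ODE
#' solution up to the Euler discretization error.
#'
#' @param scenario A [scenario()].
#' @param dt Euler-Maruyama step (time units). A warning is issued when
#'   `dt` exceeds a tenth of the fastest relaxation timescale.
#' @param times Record times (default the scenario grid).
#' @param seed RNG seed; defaults to the scenario's master seed.
#' @return A `count_trajectory`-shaped object with real-valued states.
#' @export
cle_run <- function(scenario, dt = 1e-3, times = NULL,
                    seed = scenario$seed) {
  stopifnot(dt > 0)
  a <- ssa_args(scenario)
  first_order <- a$rates[colSums(scenario$network$reactants) == 1L]
  fastest <- max(c(first_order, 0),
                 max(scenario$signal$level) * scenario$network$rates["ka"],
                 na.rm = TRUE)
  if (fastest > 0 && dt > 0.1 / fastest)
    warning(sprintf("dt = %g exceeds 0.1/(fastest rate %.3g); refine dt",
                    dt, fastest))
  if (is.null(times)) times <- scenario$grid
  set.seed(seed)
  x <- cle_cpp(as.numeric(a$x0), a$stoich, a$react, a$rates,
               a$sig$sig_scaled, a$sig$sig_species, a$sig$sig_t,
               a$sig$sig_level, a$sig$sig_level_mol, a$t0, dt, times)
  colnames(x) <- a$species
  structure(list(times = times, counts = x, species = a$species,
                 scenario = scenario$name, seed = seed, unit = "molecules"),
            class = "count_trajectory")
}
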