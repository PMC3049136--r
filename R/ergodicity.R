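# Evaluate one species of any trajectory-like object on a regular grid:
# left-hold for SSA/CLE records, exact closed form for ODE trajectories,
# linear interpolation for ensemble means.
series_at <- function(obj, times, species = "Pm") {
  if (inherits(obj, "count_trajectory")) {
    as.numeric(trajectory_at(obj, times)[, species])
  } else if (inherits(obj, "conc_trajectory")) {
    as.numeric(eval_solution(obj, times)[, species])
  } else if (inherits(obj, "ensemble_summary")) {
    stats::approx(obj$times, obj$mean[, species], xout = times,
                  rule = 2)$y
  } else stop("unsupported trajectory object")
}

series_start <- function(obj, signal) {
  if (inherits(obj, "count_trajectory")) obj$times[1] else signal$t_start[1]
}

#' Fluctuation noise floor of a trajectory
#'
#' `k` standard deviations of the species' sampled values, the scale against
#' which responses are judged. Calibrate on an unstimulated (signal = 0) run
#' of the same kind and length as the trajectory under study: for a
#' single-cell SSA run of the linear motif the result approximates
#' `k * sqrt(mean)` (Poisson fluctuations); for an ensemble mean of `n`
#' cells it shrinks by `sqrt(n)`.
#'
#' @param traj A `count_trajectory`, `conc_trajectory` or
#'   `ensemble_summary`.
#' @param signal The [step_signal()] the run was driven with (defines the
#'   sampled time range).
#' @param species Species name.
#' @param dt Sampling spacing (time units).
#' @param k Number of standard deviations (default 2).
#' @return A single non-negative number in the trajectory's units.
#' @export
noise_floor <- function(traj, signal, species = "Pm", dt = 0.5, k = 2) {
  t0 <- series_start(traj, signal)
  tt <- seq(t0, signal_t_end(signal), by = dt)
  k * stats::sd(series_at(traj, tt, species))
}

#' Per-interval sensitivity and precision of an adaptive response
#'
#' Sensitivity is the absolute difference between the peak response within a
#' signal interval and the pre-stimulus level; precision is measured by the
#' gap between the post- and pre-stimulus equilibria (zero for perfect
#' adaptation of a deterministic trajectory). To make the metrics
#' comparable between noisy single-cell records and smooth means, all
#' quantities are computed on a trailing moving average of the sampled
#' trajectory: equilibria are trailing-window means at the interval
#' boundaries, the peak is the extreme windowed value inside the interval.
#' The default window is 20% of a 50-unit interval (10 time units): longer
#' than the slowest relaxation time of the stimulated motif (~6.4 time
#' units at the reference signal level), so the windowed peak integrates
#' the whole transient excess rather than an instantaneous extreme that is
#' shot-noise-dominated for Poisson-level copy numbers, yet short relative
#' to an interval so equilibrium estimates stay quasi-stationary. The
#' sampling step `window / 40` resolves the fast onset bursts that a
#' coarser Riemann sum of the windowed average would clip.
#'
#' @param traj A `count_trajectory`, `conc_trajectory` or
#'   `ensemble_summary` covering the whole signal.
#' @param signal The driving [step_signal()].
#' @param species Species name (default `"Pm"`, the output of the motif).
#' @param window Averaging window (time units); must not exceed the
#'   shortest interval.
#' @param dt Sampling spacing within the window (default `window / 10`).
#' @return An `adaptation_metrics` data frame, one row per signal interval:
#'   `interval`, `t_start`, `t_end`, `level`, `is_stim` (level increased at
#'   the interval start), `pre`, `peak`, `end`, `sensitivity`,
#'   `precision_gap`.
#' @export
adaptation_metrics <- function(traj, signal, species = "Pm", window = 10,
                               dt = window / 40) {
  widths <- signal$t_end - signal$t_start
  if (window > min(widths)) stop("window exceeds the shortest interval")
  t0 <- series_start(traj, signal)
  tt <- seq(t0, signal_t_end(signal), by = dt)
  x <- series_at(traj, tt, species)
  kw <- max(1L, as.integer(round(window / dt)))
  roll <- as.numeric(stats::filter(x, rep(1 / kw, kw), sides = 1))

  n <- length(signal$level)
  res <- data.frame(interval = seq_len(n), t_start = signal$t_start,
                    t_end = signal$t_end, level = signal$level,
                    is_stim = c(FALSE, diff(signal$level) > 0),
                    pre = NA_real_, peak = NA_real_, end = NA_real_,
                    sensitivity = NA_real_, precision_gap = NA_real_)
  roll_near <- function(t) {
    i <- which.min(abs(tt - t))
    v <- roll[i]
    if (is.na(v)) roll[which(!is.na(roll))[1]] else v
  }
  for (i in seq_len(n)) {
    pre <- roll_near(res$t_start[i])
    endv <- roll_near(res$t_end[i])
    sel <- which(tt > res$t_start[i] & tt <= res$t_end[i] & !is.na(roll))
    vals <- roll[sel]
    k <- which.max(abs(vals - pre))
    res$pre[i] <- pre
    res$peak[i] <- vals[k]
    res$end[i] <- endv
    res$sensitivity[i] <- abs(vals[k] - pre)
    res$precision_gap[i] <- abs(endv - pre)
  }
  attr(res, "species") <- species
  attr(res, "window") <- window
  class(res) <- c("adaptation_metrics", "data.frame")
  res
}

#' Adaptation verdict of a trajectory against a noise floor
#'
#' Each stimulation interval (one whose level increased) is labeled
#' `adaptive` when the sensitivity exceeds the noise floor and the precision
#' gap stays at or below it, `responsive-non-adapting` when the response
#' exceeds the floor but the trajectory does not return, and
#' `non-responsive` otherwise. The overall label is `adaptive` if any
#' stimulation interval is adaptive (the motif provably loses sensitivity
#' under repeated stimulation, so adaptation is demonstrated by the
#' intervals with a sizeable fold change), else `responsive-non-adapting`
#' if any interval responds, else `non-responsive`.
#'
#' @param metrics An [adaptation_metrics()] data frame.
#' @param noise_floor Background fluctuation scale in the same units,
#'   typically from [noise_floor()] on an unstimulated run.
#' @return List with `labels` (per stimulation interval) and `overall`.
#' @export
adaptation_verdict <- function(metrics, noise_floor) {
  stopifnot(inherits(metrics, "adaptation_metrics"), noise_floor >= 0)
  m <- metrics[metrics$is_stim, , drop = FALSE]
  if (nrow(m) == 0L)
    return(list(labels = character(0), overall = "non-responsive"))
  labels <- ifelse(m$sensitivity > noise_floor,
                   ifelse(m$precision_gap <= noise_floor, "adaptive",
                          "responsive-non-adapting"),
                   "non-responsive")
  names(labels) <- m$interval
  overall <- if (any(labels == "adaptive")) "adaptive"
  else if (any(labels == "responsive-non-adapting")) "responsive-non-adapting"
  else "non-responsive"
  list(labels = labels, overall = overall)
}

#' Compare snapshot and time-series sampling of a stochastic scenario
#'
#' Builds the two observation schemes whose disagreement exposes rupture of
#' biological ergodicity: (A) a population snapshot - `n` independent cells
#' observed once at `t_star` - and (B) a single-cell time series - one run
#' observed at `n` times `t_star + k dt`. Both samples are histogrammed on a
#' common copy-number support and compared by total-variation distance.
#' Under a constant (time-homogeneous) signal both converge to the same
#' stationary law; under the stepping protocol they need not.
#'
#' @param scenario A [scenario()] whose signal covers
#'   `t_star + (n - 1) dt`.
#' @param t_star Observation start; the caller supplies a value beyond the
#'   relaxation time when a stationary sample is intended.
#' @param n Sample size for both schemes.
#' @param dt Spacing of the time-series observations.
#' @param species Species to histogram (default `"Pm"`).
#' @return An `ergodicity_report`: list with `snapshot`, `timeseries`
#'   (counts), `support`, `snapshot_hist`, `timeseries_hist` (proportions),
#'   `tv_distance` and the parameters used.
#' @export
compare_sampling_schemes <- function(scenario, t_star, n, dt,
                                     species = "Pm") {
  snap <- snapshot_sample(scenario, n, t_star)[, species]
  ts <- timeseries_sample(scenario, t_star, dt, n)[, species]
  support <- 0:max(snap, ts)
  h1 <- tabulate(snap + 1L, nbins = length(support)) / n
  h2 <- tabulate(ts + 1L, nbins = length(support)) / n
  structure(list(snapshot = snap, timeseries = ts, support = support,
                 snapshot_hist = h1, timeseries_hist = h2,
                 tv_distance = 0.5 * sum(abs(h1 - h2)),
                 t_star = t_star, n = n, dt = dt, species = species,
                 scenario = scenario$name, seed = scenario$seed),
            class = "ergodicity_report")
}

#' @export
print.ergodicity_report <- function(x, ...) {
  cat(sprintf(paste0("<ergodicity_report> %s, n = %d: TV(snapshot, ",
                     "time series) = %.4f\n"), x$scenario, x$n,
              x$tv_distance))
  invisible(x)
}
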