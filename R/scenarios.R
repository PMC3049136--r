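#' Piecewise-constant input signal
#'
#' A signal is an ordered set of half-open intervals `[t_start, t_end)` with a
#' constant level (micromolar) on each; intervals are contiguous and cover
#' `[breaks[1], breaks[length(breaks)])`.
#'
#' @param breaks Strictly increasing numeric vector of interval boundaries
#'   (length `n + 1` for `n` intervals).
#' @param levels Non-negative level per interval (micromolar).
#' @return An object of class `step_signal`.
#' @examples
#' sig <- step_signal(c(0, 50, 100), c(0, 1))
#' signal_level(sig, c(25, 75)) # 0 1
#' @export
step_signal <- function(breaks, levels) {
  breaks <- as.numeric(breaks); levels <- as.numeric(levels)
  if (length(breaks) != length(levels) + 1L)
    stop("`breaks` must have one more element than `levels`")
  if (any(diff(breaks) <= 0)) stop("`breaks` must be strictly increasing")
  if (any(levels < 0)) stop("signal levels must be >= 0")
  structure(list(t_start = breaks[-length(breaks)], t_end = breaks[-1L],
                 level = levels),
            class = "step_signal")
}

#' @export
print.step_signal <- function(x, ...) {
  cat(sprintf("<step_signal> %d intervals on [%g, %g)\n", length(x$level),
              x$t_start[1], x$t_end[length(x$t_end)]))
  print(data.frame(t_start = x$t_start, t_end = x$t_end, level = x$level),
        row.names = FALSE)
  invisible(x)
}

#' Query a step signal at arbitrary times
#'
#' @param signal A [step_signal()].
#' @param t Times within the signal support `[t0, T_end)`; the endpoint
#'   `T_end` is allowed and returns the last level.
#' @return Numeric vector of levels (micromolar).
#' @export
signal_level <- function(signal, t) {
  stopifnot(inherits(signal, "step_signal"))
  n <- length(signal$level)
  if (any(t < signal$t_start[1] | t > signal$t_end[n]))
    stop("time outside signal support")
  idx <- findInterval(t, c(signal$t_start, signal$t_end[n]),
                      rightmost.closed = TRUE)
  signal$level[idx]
}

signal_t_end <- function(signal) signal$t_end[length(signal$t_end)]

#' The study's repeated step-stimulation protocol
#'
#' The input is `A(t) = S(t) * F_i` micromolar with the step function S equal
#' to 0 on `[0,50)` and `[100,150)`, 1 on `[50,100)` and `[150,200)`, then 2,
#' 3, 4 on successive 50-unit intervals up to `t = 350`. The scale factor
#' `F_i` is drawn from `(0.01, 0.1, 1, 10, 100)` in the study but any
#' positive value is accepted.
#'
#' @param F_i Positive signal scale factor.
#' @return A [step_signal()] over `[0, 350)`.
#' @export
adaptation_signal <- function(F_i = 1) {
  stopifnot(is.numeric(F_i), length(F_i) == 1L, F_i > 0)
  step_signal(seq(0, 350, by = 50), c(0, 1, 0, 1, 2, 3, 4) * F_i)
}

#' Fold-change stimulation profiles A1 and A2
#'
#' A1 steps through levels `2^0, 2^1, ..., 2^10` micromolar on consecutive
#' 50-unit intervals; A2 is `2 * A1` level-wise on identical time points.
#' The first interval of each profile sits at the profile's background level
#' (no step), so every subsequent interval starts with a fold-2 change; runs
#' should be initialized at the equilibrium of the background level (the
#' presets in [scenario()] do this). An optional relaxation `gap` at level 0
#' can be inserted between fold steps.
#'
#' @param n_levels Number of fold levels (default 11).
#' @param interval Length of each stimulation interval (time units).
#' @param gap Length of a level-0 relaxation interval inserted between
#'   consecutive fold steps (default 0, i.e. back-to-back steps).
#' @return List with elements `A1` and `A2`, both [step_signal()]s.
#' @export
fold_profiles <- function(n_levels = 11, interval = 50, gap = 0) {
  stopifnot(n_levels >= 2, interval > 0, gap >= 0)
  lev1 <- 2^(seq_len(n_levels) - 1)
  build <- function(lev) {
    if (gap > 0) {
      levels <- as.vector(rbind(lev, 0))
      levels <- levels[-length(levels)]
      widths <- as.vector(rbind(rep(interval, n_levels), gap))
      widths <- widths[-length(widths)]
    } else {
      levels <- lev
      widths <- rep(interval, n_levels)
    }
    step_signal(cumsum(c(0, widths)), levels)
  }
  list(A1 = build(lev1), A2 = build(2 * lev1))
}

#' Output time grid used for the study's solution comparisons
#'
#' Within each stimulation interval of length `interval`, the solution is
#' reported at offsets `interval * c(2^-14, 2^-12, ..., 2^-2, 1/2, 1)` from
#' the interval start: a dyadic refinement that resolves the fast transient
#' right after each signal switch plus the midpoint and the endpoint. Nine
#' points per interval; interval endpoints are included, the initial time is
#' not.
#'
#' @param n_intervals Number of consecutive intervals.
#' @param interval Interval length (time units, default 50).
#' @param t0 Start of the first interval.
#' @return Strictly increasing numeric vector of `9 * n_intervals` times.
#' @export
output_time_grid <- function(n_intervals = 7, interval = 50, t0 = 0) {
  offsets <- interval * c(2^-14, 2^-12, 2^-10, 2^-8, 2^-6, 2^-4, 2^-2, 0.5, 1)
  starts <- t0 + interval * (seq_len(n_intervals) - 1)
  as.vector(outer(offsets, starts, `+`))
}

#' Bundled study scenarios
#'
#' Returns the full configuration for one of the named analysis settings:
#' network variant, rates, input signal, output grid, initial copy numbers,
#' volume context, FSP state-space bounds, RNG seed and population size.
#'
#' Presets:
#' \describe{
#'   \item{`perfect_adaptation`}{Linear model, `dP = 0`, repeated step
#'     protocol scaled by `F_i`, initial (P, Pm) = (60, 6) molecules.}
#'   \item{`near_perfect`}{As above with `dP = 0.01`.}
#'   \item{`unstimulated`}{Linear model, `dP = 0`, signal identically zero on
#'     `[0, 350)`; used to calibrate fluctuation noise floors.}
#'   \item{`fcd_A1`, `fcd_A2`}{Perfect-adaptation model under the fold
#'     profiles of [fold_profiles()], initialized at the equilibrium of the
#'     profile's background level.}
#'   \item{`mediator_kinase`}{Mediated model; the signal sets the unbound
#'     kinase copy number; phosphatase starts at 0.1 uM, (P, Pm) at the
#'     kinase-free equilibrium of the linear part, complexes empty.}
#'   \item{`mediator_trapping`}{As `mediator_kinase` with
#'     `(ka1, ka2, ka3) = (1e3, 0.1, 0.1)`, the variant in which a high
#'     `ka1/ka2` ratio traps P in kinase complexes and the response
#'     correlates negatively with the signal.}
#' }
#'
#' @param name Scenario name.
#' @param F_i Signal scale factor (ignored by the fcd presets).
#' @param seed Master RNG seed; per-cell streams are derived as
#'   `seed + cell`.
#' @param n_cells Population size for ensemble runs.
#' @param ctx A [volume_context()].
#' @param space FSP bounds, a [state_space()] (linear model only).
#' @param overrides Named list of fields to replace in the returned scenario
#'   (e.g. `list(rates = two_state_rates(dP = 0.005))`).
#' @return An object of class `scenario`.
#' @examples
#' sc <- scenario("perfect_adaptation", F_i = 1)
#' sc$init
#' @export
scenario <- function(name = c("perfect_adaptation", "near_perfect",
                              "unstimulated", "fcd_A1", "fcd_A2",
                              "mediator_kinase", "mediator_trapping"),
                     F_i = 1, seed = 1L, n_cells = 1L,
                     ctx = volume_context(), space = state_space(),
                     overrides = list()) {
  name <- match.arg(name)
  sc <- switch(name,
    perfect_adaptation = ,
    near_perfect = ,
    unstimulated = {
      dP <- if (name == "near_perfect") 0.01 else 0
      rates <- two_state_rates(dP = dP)
      sig <- if (name == "unstimulated")
        step_signal(c(0, 350), 0) else adaptation_signal(F_i)
      list(network = two_state_network(rates), rates = rates, signal = sig,
           grid = output_time_grid(7), init = c(P = 60L, Pm = 6L),
           space = space)
    },
    fcd_A1 = ,
    fcd_A2 = {
      rates <- two_state_rates(dP = 0)
      prof <- fold_profiles()
      sig <- if (name == "fcd_A1") prof$A1 else prof$A2
      eq <- equilibrium(rates, sig$level[1])
      init_conc <- c(P = eq$P_star, Pm = eq$Pm_star)
      list(network = two_state_network(rates), rates = rates, signal = sig,
           grid = output_time_grid(length(sig$level)),
           init = to_molecules(init_conc, ctx), init_conc = init_conc,
           space = space)
    },
    mediator_kinase = ,
    mediator_trapping = {
      rates <- if (name == "mediator_trapping")
        mediator_rates(ka2 = 0.1, ka3 = 0.1) else mediator_rates()
      # kinase-free equilibrium of the linear part for (P, Pm); the kinase
      # count is set by the signal, complexes start empty
      lin <- two_state_rates(ks = rates$ks, ka = 0, kf = rates$kf,
                             kr = rates$kr, dP = rates$dP, dPm = rates$dPm)
      eq <- equilibrium(lin, 0)
      init <- c(P = to_molecules(eq$P_star, ctx),
                Pm = to_molecules(eq$Pm_star, ctx),
                A_kin = 0L, B_phos = to_molecules(0.1, ctx),
                AP = 0L, BPm = 0L)
      list(network = mediator_network(rates), rates = rates,
           signal = adaptation_signal(F_i), grid = output_time_grid(7),
           init = init, space = NULL)
    })
  sc$name <- name
  sc$F_i <- F_i
  sc$seed <- as.integer(seed)
  sc$n_cells <- as.integer(n_cells)
  sc$ctx <- ctx
  if (is.null(sc$init_conc))
    sc$init_conc <- to_concentration(sc$init[c("P", "Pm")], ctx)
  for (nm in names(overrides)) sc[[nm]] <- overrides[[nm]]
  if (any(sc$init < 0) || sc$n_cells < 1L)
    stop("scenario requires non-negative initial counts and n_cells >= 1")
  class(sc) <- "scenario"
  sc
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s (F_i = %g, seed = %d, n_cells = %d)\n",
              x$name, x$F_i, x$seed, x$n_cells))
  cat("  init:", paste(names(x$init), x$init, sep = "=", collapse = " "), "\n")
  cat(sprintf("  signal: %d intervals on [%g, %g)\n", length(x$signal$level),
              x$signal$t_start[1], signal_t_end(x$signal)))
  invisible(x)
}
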