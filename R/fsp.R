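#' Finite state projection bounds for the linear two-state model
#'
#' The CME state space is truncated to the rectangle
#' `P in [0, MP]`, `Pm in [0, MPm]`. The study's bounds (110, 30) retain at
#' least 99.99% of the probability mass for the `F_i = 1` step protocol.
#'
#' @param MP,MPm Maximum copy numbers of P and Pm kept in the projection.
#' @return An object of class `state_space`.
#' @export
state_space <- function(MP = 110, MPm = 30) {
  stopifnot(MP >= 0, MPm >= 0)
  structure(list(MP = as.integer(MP), MPm = as.integer(MPm),
                 n_states = (as.integer(MP) + 1L) * (as.integer(MPm) + 1L)),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> P in [0,%d], Pm in [0,%d]: %d states\n",
              x$MP, x$MPm, x$n_states))
  invisible(x)
}

#' Enumeration of FSP states
#'
#' States `(i, j)` with `i` copies of P and `j` copies of Pm are numbered
#' row-wise: `state_index(i, j) = j (MP + 1) + i + 1` (1-based).
#' [state_at()] is the inverse.
#'
#' @param i,j Copy numbers of P and Pm (vectorized).
#' @param space A [state_space()].
#' @return 1-based state numbers.
#' @examples
#' state_index(0, 0)            # 1
#' state_index(110, 30)         # 3441
#' state_at(112)                # (0, 1)
#' @export
state_index <- function(i, j, space = state_space()) {
  if (any(i < 0 | i > space$MP | j < 0 | j > space$MPm))
    stop("state outside the projection rectangle")
  as.integer(j) * (space$MP + 1L) + as.integer(i) + 1L
}

#' @rdname state_index
#' @param index 1-based state number(s).
#' @export
state_at <- function(index, space = state_space()) {
  if (any(index < 1 | index > space$n_states)) stop("state index out of range")
  k <- index - 1L
  cbind(i = k %% (space$MP + 1L), j = k %/% (space$MP + 1L))
}

#' Sparse CME generator of the linear model at one signal level
#'
#' Assembles the infinitesimal generator of the chemical master equation
#' over the truncated state space, for the probability-flow convention
#' `dp/dt = G p` (columns sum to zero for interior states). The six terms
#' are synthesis `ks` (state `(n, m) -> (n+1, m)` at molecule-unit rate
#' `ks V N_A 1e-6`), degradation of P at `n dP`, conversion at
#' `n (kf + ka A)`, reverse conversion at `m kr` and degradation of Pm at
#' `m dPm`. Transitions leaving the rectangle are dropped while their
#' propensity stays on the diagonal, so boundary columns sum to a negative
#' number: the leaked mass measures the truncation error.
#'
#' @param rates A [two_state_rates()] object.
#' @param A Constant signal level (micromolar).
#' @param space A [state_space()].
#' @param ctx A [volume_context()].
#' @return A `dgCMatrix` of dimension `n_states x n_states`.
#' @export
build_generator <- function(rates, A = 0, space = state_space(),
                            ctx = volume_context()) {
  stopifnot(inherits(rates, "rate_set"), A >= 0)
  MP <- space$MP; MPm <- space$MPm
  st <- state_at(seq_len(space$n_states), space)
  n <- st[, "i"]; m <- st[, "j"]
  ks_mol <- rates$ks * molecules_per_um(ctx)
  kconv <- rates$kf + rates$ka * A

  from <- integer(0); to <- integer(0); val <- numeric(0)
  add <- function(ok, i2, j2, rate) {
    from <<- c(from, which(ok))
    to <<- c(to, state_index(i2[ok], j2[ok], space))
    val <<- c(val, rate[ok])
  }
  add(n < MP, n + 1L, m, rep(ks_mol, length(n)))          # synthesis
  add(n > 0, n - 1L, m, n * rates$dP)                     # P degradation
  add(n > 0 & m < MPm, n - 1L, m + 1L, n * kconv)         # P -> Pm
  add(m > 0 & n < MP, n + 1L, m - 1L, m * rates$kr)       # Pm -> P
  add(m > 0, n, m - 1L, m * rates$dPm)                    # Pm degradation

  outflow <- ks_mol + n * (rates$dP + kconv) + m * (rates$kr + rates$dPm)
  Matrix::sparseMatrix(
    i = c(to, seq_len(space$n_states)),
    j = c(from, seq_len(space$n_states)),
    x = c(val, -outflow),
    dims = c(space$n_states, space$n_states))
}

#' Initial probability vector over the FSP state space
#'
#' Either a point mass at `(P, Pm)` copies, or a product of independent
#' Poisson marginals with means `(P, Pm)` truncated to the rectangle (the
#' stationary family of the open linear network).
#'
#' @param space A [state_space()].
#' @param P,Pm Copy numbers (point mass) or means (Poisson).
#' @param type `"point"` or `"poisson"`.
#' @return A probability vector of length `space$n_states` with a `time`
#'   attribute of 0.
#' @export
fsp_initial <- function(space = state_space(), P = 60, Pm = 6,
                        type = c("point", "poisson")) {
  type <- match.arg(type)
  p <- numeric(space$n_states)
  if (type == "point") {
    p[state_index(as.integer(round(P)), as.integer(round(Pm)), space)] <- 1
  } else {
    pp <- stats::dpois(0:space$MP, P)
    pm <- stats::dpois(0:space$MPm, Pm)
    p <- as.vector(outer(pp, pm)) # column j varies slowest, matches indexing
  }
  structure(p, time = 0)
}

#' Propagate an FSP probability vector through a step signal
#'
#' Within each constant-signal interval the solution of `dp/dt = G p` is
#' `p(t + d) = expm(d G) p(t)`; the action of the matrix exponential on the
#' vector is computed by uniformization of the sparse generator (series of
#' substochastic powers with Poisson weights, truncation tolerance `tol`),
#' never forming a dense exponential. Generators are cached per distinct
#' signal level. Retained probability mass is non-increasing in time; if it
#' drops below `mass_threshold` at any grid point the propagation aborts
#' naming the worst time point (enlarge the state space in that case).
#'
#' @param p0 Initial probability vector (length `space$n_states`, sums to 1).
#' @param rates A [two_state_rates()] object.
#' @param signal A [step_signal()].
#' @param space A [state_space()].
#' @param grid Output times (strictly increasing, within the signal support).
#' @param ctx A [volume_context()].
#' @param mass_threshold Minimum acceptable retained mass (default 0.9999);
#'   set to 0 to disable the check.
#' @param tol Series truncation tolerance of the exponential action.
#' @return An `fsp_solution`: list with `times`, `probs` (states x times
#'   matrix), `mass` (retained mass per time), `space`, `grid`.
#' @export
fsp_propagate <- function(p0, rates, signal, space = state_space(),
                          grid = output_time_grid(7), ctx = volume_context(),
                          mass_threshold = 0.9999, tol = 1e-10) {
  stopifnot(length(p0) == space$n_states)
  if (abs(sum(p0) - 1) > 1e-8) stop("initial probabilities must sum to 1")
  if (any(diff(grid) <= 0)) stop("grid times must be strictly increasing")
  t0 <- attr(p0, "time")
  if (is.null(t0)) t0 <- signal$t_start[1]
  if (grid[1] < t0 || grid[length(grid)] > signal_t_end(signal))
    stop("grid time outside signal support")

  gens <- list() # per-level cache: generator CSC pieces + uniformization rate
  get_gen <- function(level) {
    key <- format(level, digits = 15)
    if (is.null(gens[[key]])) {
      G <- build_generator(rates, level, space, ctx)
      gens[[key]] <<- list(p = G@p, i = G@i, x = G@x,
                           lam = max(-Matrix::diag(G)))
    }
    gens[[key]]
  }

  # breakpoints: grid times plus signal switches strictly inside each step
  probs <- matrix(NA_real_, space$n_states, length(grid))
  p <- as.numeric(p0)
  tcur <- t0
  for (k in seq_along(grid)) {
    target <- grid[k]
    while (tcur < target) {
      switches <- signal$t_start[signal$t_start > tcur & signal$t_start < target]
      tnext <- if (length(switches)) min(switches) else target
      level <- signal_level(signal, tcur)
      g <- get_gen(level)
      p <- expmv_unif_cpp(space$n_states, g$p, g$i, g$x, g$lam, p,
                          tnext - tcur, tol)
      tcur <- tnext
    }
    probs[, k] <- p
  }
  mass <- colSums(probs)
  if (mass_threshold > 0 && any(mass < mass_threshold)) {
    worst <- which.min(mass)
    stop(sprintf(paste0("FSP truncation insufficient: retained mass %.6f < %g",
                        " at t = %g; enlarge the state space"),
                 mass[worst], mass_threshold, grid[worst]))
  }
  structure(list(times = grid, probs = probs, mass = mass, space = space,
                 signal = signal), class = "fsp_solution")
}

#' @export
print.fsp_solution <- function(x, ...) {
  cat(sprintf("<fsp_solution> %d states x %d times, min retained mass %.6f\n",
              nrow(x$probs), length(x$times), min(x$mass)))
  invisible(x)
}

#' Marginal copy-number distribution of one species
#'
#' Sums the joint FSP probability vector over the other species' index. The
#' result sums to the retained (not renormalized) mass.
#'
#' @param p Probability vector over the enumerated states.
#' @param species `"P"` or `"Pm"`.
#' @param space A [state_space()].
#' @return Numeric vector of length `MP + 1` (or `MPm + 1`), named by copy
#'   number starting at 0.
#' @export
fsp_marginal <- function(p, species = c("Pm", "P"), space = state_space()) {
  species <- match.arg(species)
  stopifnot(length(p) == space$n_states)
  m <- matrix(p, nrow = space$MP + 1L) # rows: P count, cols: Pm count
  out <- if (species == "P") rowSums(m) else colSums(m)
  stats::setNames(out, 0:(if (species == "P") space$MP else space$MPm))
}

#' Probability of a copy-number range
#'
#' `P(lo <= species <= hi)` from the FSP vector, e.g. the study's tracked
#' sets 0-4, 5-6 and 7-30 molecules of Pm.
#'
#' @inheritParams fsp_marginal
#' @param lo,hi Inclusive copy-number bounds.
#' @return A single probability.
#' @export
set_probability <- function(p, species = c("Pm", "P"), lo, hi,
                            space = state_space()) {
  species <- match.arg(species)
  bound <- if (species == "P") space$MP else space$MPm
  if (lo < 0 || hi > bound || lo > hi) stop("invalid copy-number bounds")
  marg <- fsp_marginal(p, species, space)
  sum(marg[(lo:hi) + 1L])
}

#' Mean copy numbers under an FSP probability vector
#'
#' First moments of P and Pm, renormalized by the retained mass (raw
#' probabilities are never renormalized; only the moment is).
#'
#' @param p Probability vector.
#' @param space A [state_space()].
#' @return Named numeric vector `c(P = , Pm = )`.
#' @export
first_moment <- function(p, space = state_space()) {
  mass <- sum(p)
  if (mass <= 0) stop("zero retained mass")
  st <- state_at(seq_along(p), space)
  c(P = sum(st[, "i"] * p) / mass, Pm = sum(st[, "j"] * p) / mass)
}

#' Total-variation distance of a marginal from a Poisson law
#'
#' `0.5 * sum_k |marginal_k - dpois(k, lam)|` over the truncated support,
#' plus half the Poisson tail mass beyond the support (counted as
#' discrepancy). The open linear network maps Poisson initial laws to
#' Poisson laws at all times, so this distance measures both truncation and
#' non-Poissonity.
#'
#' @param marginal Copy-number distribution from [fsp_marginal()] (support
#'   `0:(length(marginal) - 1)`).
#' @param lam Poisson mean, typically the first moment.
#' @return Total-variation distance in `[0, 1]`.
#' @export
poisson_distance <- function(marginal, lam) {
  stopifnot(lam >= 0)
  k <- seq_along(marginal) - 1L
  pk <- stats::dpois(k, lam)
  tail <- stats::ppois(max(k), lam, lower.tail = FALSE)
  0.5 * (sum(abs(marginal - pk)) + tail)
}
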