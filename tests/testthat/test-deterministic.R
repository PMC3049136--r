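test_that("closed-form equilibria evaluate the steady-state formulas", {
  perfect <- two_state_rates(dP = 0)
  # dP = 0: Pm* = ks/dPm independent of the signal
  for (A in c(0, 1, 10, 100)) {
    expect_equal(equilibrium(perfect, A)$Pm_star, 0.01)
  }
  expect_equal(equilibrium(perfect, 0)$P_star, 0.11)
  expect_equal(equilibrium(two_state_rates(), 0)$Pm_star, 0.01 / 1.11)
  # dPm = 0: P* = ks/dP independent of the signal
  nodpm <- two_state_rates(dPm = 0)
  pstars <- vapply(c(0, 0.5, 2, 64), function(A)
    equilibrium(nodpm, A)$P_star, numeric(1))
  expect_equal(pstars, rep(0.01 / 0.01, 4))
  expect_error(equilibrium(two_state_rates(ks = 0, ka = 0, kf = 0, kr = 0,
                                           dP = 0, dPm = 0), 0), "degenerate")
})

test_that("the piecewise solver is exact at fixed points and equilibria", {
  rates <- two_state_rates(dP = 0)
  eq <- equilibrium(rates, 0)
  sig <- step_signal(c(0, 100), 0)
  tr <- solve_piecewise(rates, sig, c(P = eq$P_star, Pm = eq$Pm_star),
                        times = seq(1, 100, by = 7))
  expect_equal(tr$P, rep(eq$P_star, nrow(tr)), tolerance = 1e-12)
  expect_equal(tr$Pm, rep(eq$Pm_star, nrow(tr)), tolerance = 1e-12)
  # long constant signal relaxes to the A = 1 equilibrium
  sig1 <- step_signal(c(0, 500), 1)
  tr1 <- solve_piecewise(rates, sig1, c(P = 0.1, Pm = 0.01), times = 500)
  eq1 <- equilibrium(rates, 1)
  expect_equal(tr1$P, eq1$P_star, tolerance = 1e-9)
  expect_equal(tr1$Pm, eq1$Pm_star, tolerance = 1e-9)
  expect_error(solve_piecewise(rates, sig, c(P = 0.1, Pm = 0.01),
                               times = c(5, 101)), "outside")
})

test_that("the closed-form solution matches independent integrators", {
  rates <- two_state_rates(dP = 0)
  sc <- scenario("perfect_adaptation", F_i = 1)
  tr <- solve_piecewise(rates, sc$signal, sc$init_conc, times = c(55, 95))
  # brute-force fine-step explicit Euler oracle
  expect_equal(as.numeric(tr[tr$time == 55, c("P", "Pm")]),
               euler_ode(rates, sc$signal, sc$init_conc, 55, 1e-4),
               tolerance = 1e-3)
  skip_if_not_installed("deSolve")
  f <- function(t, y, p) {
    A <- signal_level(sc$signal, t)
    k1 <- rates$kf + rates$ka * A
    list(c(rates$ks + rates$kr * y[2] - (rates$dP + k1) * y[1],
           k1 * y[1] - (rates$kr + rates$dPm) * y[2]))
  }
  # integrate per constant-signal piece so lsoda never smooths a switch
  y <- as.numeric(sc$init_conc); piece_t <- c(0, 50, 55, 95, 100)
  for (i in 2:length(piece_t)) {
    out <- deSolve::lsoda(y, piece_t[c(i - 1, i)], f, NULL, rtol = 1e-10,
                          atol = 1e-12)
    y <- as.numeric(out[2, 2:3])
    row <- tr[abs(tr$time - piece_t[i]) < 1e-12, ]
    if (nrow(row) == 1)
      expect_equal(as.numeric(row[c("P", "Pm")]), y, tolerance = 1e-8)
  }
})

test_that("perfect adaptation: Pm surges after stimulation and re-adapts", {
  sc <- scenario("perfect_adaptation", F_i = 1)
  tr <- solve_piecewise(sc$rates, sc$signal, sc$init_conc, sc$grid)
  pk <- interval_peaks(tr, sc$signal, "Pm")
  expect_gt(pk$peak[2], pk$pre[2] * 1.5)       # sizeable response
  expect_equal(pk$end[2], 0.01, tolerance = 1e-3) # returns to ks/dPm
  expect_true(all(pk$peak_time[2] > 50 & pk$peak_time[2] < 52))
})

test_that("interval peaks degrade gracefully on constant trajectories", {
  rates <- two_state_rates(dP = 0)
  eq <- equilibrium(rates, 0)
  sig <- step_signal(c(0, 50, 100), c(0, 0))
  tr <- solve_piecewise(rates, sig, c(P = eq$P_star, Pm = eq$Pm_star),
                        times = seq(0, 100, by = 5))
  pk <- interval_peaks(tr, sig, "Pm")
  expect_equal(pk$peak, pk$pre, tolerance = 1e-9)
  expect_equal(pk$peak, pk$end, tolerance = 1e-9)
  expect_error(interval_peaks(tr, sig, "Qx"), "not in trajectory")
})

test_that("near-perfect equilibria converge to the perfect case along folds", {
  conv <- equilibrium_convergence(levels = 2^(0:10))
  expect_equal(conv$Pm_perfect, rep(0.01, 11))
  expect_lt(conv$gap[11], conv$gap[1])
  expect_true(all(diff(conv$gap) < 0))
  # closed-form spot check at A = 1: |0.01*2/1.11... - 0.01|
  expect_equal(conv$gap[1], abs(0.01 * 2 / (0.1 + 2.01) - 0.01))
  same <- equilibrium_convergence(two_state_rates(dP = 0),
                                  two_state_rates(dP = 0), 2^(0:4))
  expect_equal(same$gap, rep(0, 5))
})
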