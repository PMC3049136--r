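test_that("degenerate SSA runs hold still and start from the given state", {
  rates0 <- two_state_rates(ks = 0, ka = 0, kf = 0, kr = 0, dP = 0, dPm = 0)
  sc <- scenario("perfect_adaptation", F_i = 1, seed = 3, overrides = list(
    network = two_state_network(rates0), rates = rates0))
  tr <- ssa_run(sc, "grid", times = c(0, 100, 349))
  expect_true(all(tr$counts[, "P"] == 60L))
  expect_true(all(tr$counts[, "Pm"] == 6L))
  sc1 <- scenario("perfect_adaptation", F_i = 1, seed = 4)
  ev <- ssa_run(sc1, "events", max_events = 5e5)
  expect_identical(unname(ev$counts[1, ]), c(60L, 6L))
  expect_true(all(diff(ev$times) >= 0))
  expect_true(all(ev$counts >= 0L))
})

test_that("trajectory_at holds the last state between events", {
  rates0 <- two_state_rates(ks = 0, ka = 0, kf = 0, kr = 0, dP = 0, dPm = 1)
  sc <- scenario("unstimulated", seed = 8, overrides = list(
    network = two_state_network(rates0), rates = rates0,
    init = c(P = 0L, Pm = 3L)))
  ev <- ssa_run(sc, "events")
  # pure death of 3 molecules: 4 records (initial + 3 events)
  expect_identical(ev$counts[, "Pm"], c(3L, 2L, 1L, 0L))
  mid <- (ev$times[2] + ev$times[3]) / 2
  expect_identical(unname(trajectory_at(ev, mid)[1, "Pm"]), 2L)
  expect_error(trajectory_at(ev, -1), "before")
})

test_that("pure-birth inter-event times are exponential (KS at alpha 0.01)", {
  rates0 <- two_state_rates(ks = 0.01, ka = 0, kf = 0, kr = 0, dP = 0,
                            dPm = 0)
  ks_mol <- 0.01 * OM
  sc <- scenario("unstimulated", seed = 17, overrides = list(
    network = two_state_network(rates0), rates = rates0,
    init = c(P = 0L, Pm = 0L),
    signal = step_signal(c(0, 1e4 / ks_mol), 0)))
  ev <- ssa_run(sc, "events", max_events = 2e4)
  gaps <- diff(ev$times)
  gaps <- gaps[gaps > 0]
  expect_gt(length(gaps), 9.5e3)
  expect_gt(stats::ks.test(gaps, "pexp", ks_mol)$p.value, 0.01)
})

test_that("SSA state frequencies match the FSP law after a signal switch", {
  # the t = 60 distribution reached through the switch at t = 50 equals (in
  # distribution) a run restarted at the switch with the new generator, and
  # both match the FSP marginal within binomial error
  n <- 2000
  sc <- scenario("perfect_adaptation", F_i = 1, seed = 23)
  sol <- fsp_propagate(fsp_initial(), sc$rates, sc$signal,
                       grid = c(50, 60), mass_threshold = 0)
  marg <- fsp_marginal(sol$probs[, 2], "Pm")
  through <- vapply(seq_len(n), function(cell) {
    set.seed(sc$seed + cell)
    adaptmotif:::ssa_sample_cpp(
      c(60L, 6L), sc$network$stoich, sc$network$reactants,
      as.numeric(molecule_rates(sc$network)), c(rep(FALSE, 2), TRUE,
                                                rep(FALSE, 3)), -1L,
      sc$signal$t_start, sc$signal$level, integer(7), 0, 60)[1, 2]
  }, numeric(1))
  # restarted construction: draw the t = 50 state from the FSP law, then run
  # only the constant-A segment [50, 60]
  marg50 <- sol$probs[, 1] / sum(sol$probs[, 1])
  sig1 <- step_signal(c(50, 60), 1)
  sc1 <- scenario("perfect_adaptation", F_i = 1, seed = 331)
  set.seed(5150)
  starts <- state_at(sample.int(length(marg50), n, TRUE, prob = marg50))
  restarted <- vapply(seq_len(n), function(cell) {
    set.seed(sc1$seed + cell)
    adaptmotif:::ssa_sample_cpp(
      c(starts[cell, "i"], starts[cell, "j"]), sc$network$stoich,
      sc$network$reactants, as.numeric(molecule_rates(sc$network)),
      c(rep(FALSE, 2), TRUE, rep(FALSE, 3)), -1L,
      sig1$t_start, sig1$level, integer(1), 50, 60)[1, 2]
  }, numeric(1))
  for (k in c(3:10)) {
    p <- sum(marg[as.character(k)])
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(through == k) - p), 4 * se + 1e-9)
    expect_lt(abs(mean(restarted == k) - p), 4 * se + 1e-9)
  }
})

test_that("ensemble summaries reduce to single runs and honor chunking", {
  sc <- scenario("perfect_adaptation", F_i = 1, seed = 31)
  times <- c(25, 50.5, 60, 100)
  e1 <- ensemble_mean(sc, n_cells = 1, times = times)
  single <- ssa_run(sc, "grid", times = times, seed = sc$seed + 1)
  expect_equal(e1$mean, single$counts + 0, ignore_attr = TRUE)
  # mean/variance equal the per-cell aggregation regardless of chunking
  e <- ensemble_mean(sc, n_cells = 8, times = times)
  cells <- vapply(1:8, function(cell)
    ssa_run(sc, "grid", times = times, seed = sc$seed + cell)$counts[, "Pm"],
    numeric(length(times)))
  expect_equal(e$mean[, "Pm"], rowMeans(cells), ignore_attr = TRUE)
  expect_equal(e$var[, "Pm"], apply(cells, 1, var), ignore_attr = TRUE)
})

test_that("snapshot and time-series samples reach the stationary law", {
  sc <- scenario("unstimulated", seed = 41, overrides = list(
    signal = step_signal(c(0, 6100), 0)))
  sol <- fsp_propagate(fsp_initial(), sc$rates, sc$signal,
                       grid = c(60, 100), mass_threshold = 0)
  fm <- first_moment(sol$probs[, 2])
  snap <- snapshot_sample(sc, 800, t_star = 100)
  expect_identical(dim(snap), c(800L, 2L))
  se <- sd(snap[, "Pm"]) / sqrt(800)
  expect_lt(abs(mean(snap[, "Pm"]) - fm["Pm"]), 3 * se)
  ts <- timeseries_sample(sc, t_star = 100, dt = 6, n_points = 1000)
  # thinned single-run mean approaches the same stationary mean
  expect_lt(abs(mean(ts[, "Pm"]) - fm["Pm"]), 0.5)
  expect_identical(nrow(timeseries_sample(sc, 100, 1, 1)), 1L)
  expect_error(timeseries_sample(sc, 6000, 10, 100), "outside")
})

test_that("the Langevin scheme degenerates and averages correctly", {
  rates0 <- two_state_rates(ks = 0, ka = 0, kf = 0, kr = 0, dP = 0, dPm = 0)
  sc0 <- scenario("perfect_adaptation", seed = 51, overrides = list(
    network = two_state_network(rates0), rates = rates0))
  path <- cle_run(sc0, dt = 0.01, times = c(10, 300))
  expect_equal(unname(path$counts[, "P"]), c(60, 60))
  expect_warning(cle_run(scenario("perfect_adaptation", seed = 1), dt = 0.05,
                         times = c(1, 2)), "dt")
  # ensemble mean vs ODE at a pre-switch and an early post-switch time
  sc <- scenario("perfect_adaptation", F_i = 1, seed = 52)
  times <- c(25, 50.78125, 53.125)
  n <- 400
  acc <- matrix(0, length(times), 2)
  for (i in seq_len(n))
    acc <- acc + cle_run(sc, dt = 1e-3, times = times,
                         seed = sc$seed + i)$counts
  m <- acc / n
  ode <- solve_piecewise(sc$rates, sc$signal, sc$init_conc, times)
  expect_lt(max(abs(m[, "Pm"] - ode$Pm * OM)), 3 * sqrt(11 / n))
  # stationary fluctuations are Poisson-like: variance ~ mean
  long <- cle_run(scenario("unstimulated", seed = 53), dt = 1e-3,
                  times = seq(50, 350, by = 1))
  expect_lt(abs(var(long$counts[, "Pm"]) / mean(long$counts[, "Pm"]) - 1),
            0.45)
})

test_that("a high ka1/ka2 ratio traps protein in kinase complexes", {
  sct <- scenario("mediator_trapping", F_i = 1, seed = 201)
  trt <- ssa_run(sct, "grid", times = seq(200, 350, by = 5))
  sck <- scenario("mediator_kinase", F_i = 1, seed = 201)
  trk <- ssa_run(sck, "grid", times = seq(200, 350, by = 5))
  # trapping variant accumulates bound AP far beyond free P and Pm...
  expect_gt(mean(trt$counts[, "AP"]), 10 * mean(trt$counts[, "P"]))
  expect_gt(mean(trt$counts[, "AP"]), 10 * mean(trt$counts[, "Pm"]))
  # ...while the reference parameterization keeps complexes transient
  expect_lt(mean(trk$counts[, "AP"]), mean(trt$counts[, "AP"]) / 5)
  # kinase totals: free + bound never drops below the signal level set
  expect_true(all(trt$counts[, "A_kin"] + trt$counts[, "AP"] >=
                    to_molecules(2, volume_context())))
})
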