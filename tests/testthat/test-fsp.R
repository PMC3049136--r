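test_that("state enumeration is the row-wise bijection on the rectangle", {
  sp <- state_space(110, 30)
  expect_identical(state_index(0, 0, sp), 1L)
  expect_identical(state_index(110, 30, sp), 3441L)
  expect_identical(sp$n_states, 3441L)
  expect_equal(unname(state_at(112, sp)[1, ]), c(0, 1))
  # brute-force inversion over a small rectangle
  sp2 <- state_space(5, 3)
  for (i in 0:5) for (j in 0:3) {
    k <- state_index(i, j, sp2)
    expect_equal(unname(state_at(k, sp2)[1, ]), c(i, j))
  }
  expect_error(state_index(111, 0, sp), "outside")
  expect_error(state_at(3442, sp), "out of range")
})

test_that("the generator wires the six master-equation terms", {
  sp <- state_space(8, 5)
  rates <- two_state_rates(dP = 0.02)
  G <- build_generator(rates, 1.5, sp)
  st <- state_at(seq_len(sp$n_states), sp)
  interior <- st[, "i"] < 8 & st[, "j"] < 5
  cs <- Matrix::colSums(G)
  expect_lt(max(abs(cs[interior])), 1e-10)   # probability conserved
  expect_true(all(cs <= 1e-10))              # boundary columns only leak
  # the kf + ka A channel: inflow into (n, m) from (n+1, m-1) is (n+1) kconv
  kconv <- rates$kf + rates$ka * 1.5
  expect_equal(G[state_index(3, 2, sp), state_index(4, 1, sp)], 4 * kconv)
  # synthesis inflow from the left neighbor is ks V N_A
  expect_equal(G[state_index(4, 1, sp), state_index(3, 1, sp)], 0.01 * OM)
  # reverse conversion into (n, m) from (n-1, m+1) is (m+1) kr
  expect_equal(G[state_index(4, 1, sp), state_index(3, 2, sp)], 2 * 10)
  # A = 0 wipes out the signal channel regardless of ka
  expect_equal(as.matrix(build_generator(two_state_rates(ka = 5), 0, sp)),
               as.matrix(build_generator(two_state_rates(ka = 99), 0, sp)))
})

test_that("expm propagation matches a dense Euler oracle on a tiny space", {
  sp <- state_space(6, 4)
  rates <- two_state_rates(ks = 0.001, dP = 0)
  sig <- step_signal(c(0, 0.6, 1), c(1, 3)) # includes a mid-flight switch
  p0 <- fsp_initial(sp, 1, 1)
  sol <- fsp_propagate(p0, rates, sig, sp, grid = c(0.6, 1),
                       mass_threshold = 0)
  Gd1 <- dense_cme_matrix(rates, 1, 6, 4, 0.001 * OM)
  Gd2 <- dense_cme_matrix(rates, 3, 6, 4, 0.001 * OM)
  pe <- euler_cme(Gd1, as.numeric(p0), 0.6, 1e-5)
  pe <- euler_cme(Gd2, pe, 0.4, 1e-5)
  expect_lt(max(abs(sol$probs[, 2] - pe)), 1e-6)
  # and against a dense matrix exponential as a second, sharper oracle
  pm <- as.numeric(Matrix::expm(Matrix::Matrix(Gd2) * 0.4) %*%
                     (Matrix::expm(Matrix::Matrix(Gd1) * 0.6) %*%
                        as.numeric(p0)))
  expect_lt(max(abs(sol$probs[, 2] - pm)), 1e-10)
})

test_that("propagation over zero time is the identity", {
  sp <- state_space(6, 4)
  p0 <- fsp_initial(sp, 2, 1)
  sig <- step_signal(c(0, 10), 1)
  sol <- fsp_propagate(p0, two_state_rates(ks = 0.001), sig, sp,
                       grid = c(1e-12, 5), mass_threshold = 0)
  expect_equal(sol$probs[, 1], as.numeric(p0), tolerance = 1e-9)
})

test_that("marginals, set probabilities and moments are consistent", {
  sp <- state_space(10, 6)
  p <- fsp_initial(sp, 7, 3) # point mass
  expect_equal(unname(fsp_marginal(p, "Pm", sp)), c(0, 0, 0, 1, 0, 0, 0))
  expect_equal(unname(fsp_marginal(p, "P", sp)[8]), 1)
  expect_equal(set_probability(p, "Pm", 0, 6, sp), 1)
  expect_equal(set_probability(p, "Pm", 3, 3, sp), 1)
  expect_error(set_probability(p, "Pm", 4, 2, sp), "bounds")
  expect_error(set_probability(p, "Pm", 0, 7, sp), "bounds")
  expect_equal(unname(first_moment(p, sp)), c(7, 3))
  # uniform vector: uniform marginals
  pu <- structure(rep(1 / sp$n_states, sp$n_states), time = 0)
  expect_equal(unname(fsp_marginal(pu, "P", sp)), rep(1 / 11, 11))
  # Poisson product initializer has the requested means and factorizes
  pp <- fsp_initial(sp, 3, 2, type = "poisson")
  fm <- first_moment(pp, sp)
  expect_equal(unname(fm), c(3, 2), tolerance = 0.01)
  joint <- matrix(pp, nrow = 11)
  expect_equal(joint, outer(fsp_marginal(pp, "P", sp),
                            fsp_marginal(pp, "Pm", sp)) / sum(pp),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("first moments agree with a Monte-Carlo draw from the vector", {
  sp <- state_space(12, 8)
  pp <- fsp_initial(sp, 5, 3, type = "poisson")
  fm <- first_moment(pp, sp)
  set.seed(99)
  draws <- sample.int(sp$n_states, 1e5, replace = TRUE, prob = pp)
  st <- state_at(draws, sp)
  se_p <- sd(st[, "i"]) / sqrt(1e5)
  se_m <- sd(st[, "j"]) / sqrt(1e5)
  expect_lt(abs(mean(st[, "i"]) - fm["P"]), 3 * se_p)
  expect_lt(abs(mean(st[, "j"]) - fm["Pm"]), 3 * se_m)
})

test_that("poisson_distance measures tail mass and total variation", {
  lam <- 4
  trunc <- dpois(0:15, lam)
  tail <- ppois(15, lam, lower.tail = FALSE)
  expect_equal(poisson_distance(trunc, lam), tail / 2)
  expect_equal(poisson_distance(c(1), 0), 0)
  half <- c(0.5, 0.5)
  expect_gt(poisson_distance(half, 20), 0.9)
})

test_that("retained mass is monotone in time and in the space bounds", {
  rates <- two_state_rates(dP = 0)
  sig <- adaptation_signal(1)
  grid <- output_time_grid(2)
  sol_small <- fsp_propagate(fsp_initial(state_space(80, 20), 60, 6), rates,
                             sig, state_space(80, 20), grid,
                             mass_threshold = 0)
  sol_big <- fsp_propagate(fsp_initial(state_space(110, 30), 60, 6), rates,
                           sig, state_space(110, 30), grid,
                           mass_threshold = 0)
  expect_true(all(diff(sol_small$mass) <= 1e-12))
  expect_true(all(diff(sol_big$mass) <= 1e-12))
  expect_true(all(sol_big$mass >= sol_small$mass - 1e-9))
  # truncation-insufficient runs abort naming the worst time point
  expect_error(
    fsp_propagate(fsp_initial(state_space(70, 12), 60, 6), rates, sig,
                  state_space(70, 12), grid),
    "retained mass")
})
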