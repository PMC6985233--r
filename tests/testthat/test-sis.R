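test_that("simulate_sis is seed-reproducible and handles edge regimes", {
  net <- cycle_network(4, n_nodes = 6)
  s1 <- simulate_sis(net, duration = 100, seed = 8)
  s2 <- simulate_sis(net, duration = 100, seed = 8)
  expect_identical(s1$p_hat, s2$p_hat)
  expect_identical(s1$n_reinits, s2$n_reinits)
  # r = 0 on a strongly connected network: absorbing all-infected state
  s3 <- simulate_sis(cycle_network(5), beta = 1, r = 0, duration = 200,
                     seed = 3)
  expect_true(all(s3$p_hat > 0.9))
  # edgeless network: every infection comes from re-seeding and decays
  s4 <- simulate_sis(directed_network(matrix(0, 6, 6)), beta = 1, r = 2,
                     duration = 400, reinit = "bernoulli", seed = 4)
  expect_true(all(s4$p_hat < 0.5))
  expect_gt(s4$n_reinits, 10)
})

test_that("stochastic prevalence matches the mean-field fixed point when valid", {
  # dense strongly connected graph: individual-based mean field is accurate
  n <- 40
  dense <- directed_network(1 - diag(n))
  beta <- 0.05; r <- 0.5
  mf <- meanfield_sis(dense, beta, r, p0 = rep(0.5, n), t_grid = c(0, 200))
  sim <- simulate_sis(dense, beta = beta, r = r, duration = 2000,
                      reinit = "bernoulli", seed = 2)
  expect_equal(mean(sim$p_hat), mf[2, 1], tolerance = 0.05)
})

test_that("meanfield_sis integrates the contact ODE", {
  # edgeless: closed-form exponential decay
  empty <- directed_network(matrix(0, 3, 3))
  p <- meanfield_sis(empty, beta = 1, r = 0.7, p0 = c(0.9, 0.5, 0.1),
                     t_grid = c(0, 2))
  expect_equal(p[2, ], c(0.9, 0.5, 0.1) * exp(-1.4), tolerance = 1e-8)
  # mutual 2-cycle, symmetric start: fixed point p* = 1 - r/beta
  p2 <- meanfield_sis(cycle_network(2), beta = 1, r = 0.5, p0 = c(0.3, 0.3),
                      t_grid = c(0, 200))
  expect_equal(p2[2, ], c(0.5, 0.5), tolerance = 1e-6)
  # solutions stay in [0, 1]
  set.seed(6)
  net <- sample_er(15, 2)
  traj <- meanfield_sis(net, 1, 0.5, p0 = runif(15), t_grid = seq(0, 10, 1))
  expect_true(all(traj >= -1e-10 & traj <= 1 + 1e-10))
  expect_error(meanfield_sis(net, 1, 0.5, p0 = rep(2, 15), t_grid = c(0, 1)),
               "0, 1")
})

test_that("small-prevalence mean field linearizes to the catalytic dynamics", {
  set.seed(12)
  net <- sample_conditioned(30, 1, "single_cycle", max_attempts = 2000)
  beta <- 2; r <- 1
  eps <- 1e-4
  p0 <- rep(eps, 30)
  t_end <- 2
  traj <- meanfield_sis(net, beta, r, p0, t_grid = c(0, t_end))
  # catalytic linear dynamics with phi = r/beta on the rescaled time t' = beta*t;
  # the relative nonlinear correction is of the order of the prevalence itself
  X <- integrate_states(net, t_grid = c(0, beta * t_end), phi = r / beta,
                        x0 = p0)
  expect_lt(max(abs(traj[2, ] - X[2, ])) / max(X[2, ]), 0.02)
})

test_that("rescale_infection_times shifts the first maximum to one", {
  r0 <- rescale_infection_times(rep(0.3, 20))
  expect_equal(r0$p_min, 0.3)
  expect_equal(r0$rescaled, rep(1, 20))
  set.seed(1)
  v <- c(rnorm(200, 0.1, 0.004), rnorm(100, 0.2, 0.004))
  r2 <- rescale_infection_times(v)
  expect_equal(r2$p_min, 0.1, tolerance = 0.02)
  pk <- count_integer_peaks(r2$rescaled, min_occupancy = 0.05)
  expect_setequal(pk$peak_levels, c(1, 2))
  expect_error(rescale_infection_times(rep(0, 5)), "degenerate")
  # per-network rescaling aligns ensembles with different absolute scales
  r3 <- rescale_infection_times(list(rep(0.1, 10), rep(0.4, 10)))
  expect_equal(r3$rescaled, rep(1, 20))
  expect_equal(r3$p_min, c(0.1, 0.4))
})

test_that("count_integer_peaks finds integer clustering only where present", {
  set.seed(2)
  clustered <- c(rnorm(300, 0, 0.05), rnorm(300, 1, 0.05),
                 rnorm(250, 2, 0.05), rnorm(200, 3, 0.05))
  clustered <- pmax(clustered, 0)
  pk <- count_integer_peaks(clustered)
  expect_equal(pk$n_peaks, 4)
  expect_setequal(pk$peak_levels, 0:3)
  # uniform values: every window holds ~25% of a 1-wide slice; use a narrow
  # window so absence of clustering is visible
  flat <- runif(2000, 0, 4)
  pk2 <- count_integer_peaks(flat, half_width = 0.1, min_occupancy = 0.08)
  expect_equal(pk2$n_peaks, 0)
  expect_equal(count_integer_peaks(numeric(0))$n_peaks, 0)
})
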