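test_that("katz_centrality solves the attenuated linear system", {
  empty <- directed_network(matrix(0, 4, 4))
  expect_equal(katz_centrality(empty, alpha = 0.7), rep(1, 4))
  # single link 1 -> 2, alpha = 0.5, beta = 1: scores (1, 1.5)
  link <- directed_network(matrix(c(0, 1, 0, 0), 2, 2))
  expect_equal(katz_centrality(link, alpha = 0.5), c(1, 1.5))
  # defining relation holds on random networks
  set.seed(3)
  net <- sample_er(20, 1)
  l1 <- dominant_eigenvalue(net)
  alpha <- if (l1 > 0) 0.9 / l1 else 0.9
  x <- katz_centrality(net, alpha, beta_k = 2)
  expect_equal(x, alpha * as.numeric(adjacency(net) %*% x) + 2,
               tolerance = 1e-10)
  expect_error(katz_centrality(cycle_network(3), alpha = 1), "alpha")
})

test_that("katz direction approaches the quantized eigenvector as alpha -> 1", {
  set.seed(13)
  net <- sample_conditioned(50, 1, "single_cycle", max_attempts = 5000)
  x_eig <- attractor(net)$x
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  alphas <- c(0.5, 0.9, 0.99, 1 - 1e-6)
  sims <- vapply(alphas, function(a)
    cosine(katz_centrality(net, a), x_eig), numeric(1))
  expect_true(all(diff(sims) > -1e-12))  # monotone approach
  expect_gt(sims[length(sims)], 0.999)
})

test_that("randomize_weights preserves topology and the epsilon interval", {
  set.seed(4)
  net <- sample_er(15, 1.5)
  w0 <- randomize_weights(net, 0)
  expect_equal(unclass(adjacency(w0)), unclass(adjacency(net)) * 1.0)
  w <- randomize_weights(net, 0.3)
  A <- adjacency(net); W <- adjacency(w)
  expect_identical(W > 0, A > 0)
  expect_true(all(W[A > 0] >= 0.7 & W[A > 0] <= 1))
  # epsilon = 0 leaves the attractor identical to the binary case
  net1 <- cycle_network(4)
  expect_equal(attractor(randomize_weights(net1, 0))$x, attractor(net1)$x)
})

test_that("leslie_matrix builds the stage-projection structure", {
  L <- adjacency(leslie_matrix(c(0, 0, 2), c(0.5, 0.25)))
  expect_equal(L[1, ], c(0, 0, 2))
  expect_equal(L[2, 1], 0.5)
  expect_equal(L[3, 2], 0.25)
  expect_equal(sum(L != 0), 3)
  # N = 2: smallest reproduction cycle
  L2 <- adjacency(leslie_matrix(c(0, 3), 0.8))
  expect_equal(L2, matrix(c(0, 0.8, 3, 0), 2, 2))
  # discrete iteration x(t+1) = L x(t) against a matrix-power oracle
  x0 <- c(1, 1, 1)
  x3 <- x0
  for (k in 1:3) x3 <- as.numeric(L %*% x3)
  expect_equal(as.numeric((L %*% L %*% L) %*% x0), x3)
})

test_that("leslie_spectral closed form matches dense eigensolutions", {
  ls <- leslie_spectral(f = 2, p = 0.5, N = 3)
  expect_equal(ls$lambda1, 0.5 * 4^(1/3), tolerance = 1e-12)
  expect_equal(ls$log_spacing, log(4) / 3, tolerance = 1e-12)
  # f = p: uniform population, spacing 0
  lsu <- leslie_spectral(f = 0.5, p = 0.5, N = 4)
  expect_equal(lsu$lambda1, 0.5)
  expect_equal(lsu$x, rep(1, 4))
  expect_equal(lsu$log_spacing, 0)
  # random grid: lambda1^N = f * p^(N-1) and eigensolver agreement to 1e-10
  set.seed(5)
  for (k in 1:20) {
    f <- runif(1, 0.2, 5); p <- runif(1, 0.05, 1); N <- sample(2:8, 1)
    ls <- leslie_spectral(f, p, N)
    expect_equal(ls$lambda1^N, f * p^(N - 1), tolerance = 1e-10)
    eig <- eigen(adjacency(ls$matrix))
    i <- which.max(Mod(eig$values))
    expect_equal(Mod(eig$values[i]), ls$lambda1, tolerance = 1e-10)
    v <- Mod(eig$vectors[, i]); v <- v / v[N]
    expect_equal(v, ls$x, tolerance = 1e-8)
    r <- detect_log_quantization(ls$x, tol = 1e-8)
    expect_true(r$is_quantized)
    expect_equal(abs(r$delta), abs(ls$log_spacing), tolerance = 1e-8)
  }
})
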