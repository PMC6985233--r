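test_that("network constructors enforce the influence-matrix invariants", {
  expect_error(directed_network(matrix(1, 2, 2)), "diagonal")
  expect_error(directed_network(matrix(c(0, 2, 0, 0), 2, 2)), "0 or 1")
  expect_error(weighted_network(matrix(c(0, -1, 0, 0), 2, 2)), "nonnegative")
  net <- cycle_network(3, n_nodes = 5)
  expect_equal(n_nodes(net), 5)
  expect_equal(sum(adjacency(net)), 3)
})

test_that("sample_er matches its link-probability contract", {
  set.seed(1)
  expect_equal(sum(adjacency(sample_er(10, 0))), 0)
  # c/(N-1) = 1: both possible links deterministically present
  expect_equal(sum(adjacency(sample_er(2, 1))), 2)
  # binomial mean: n(n-1) * c/(n-1) = n*c links on average
  n <- 200
  counts <- replicate(300, sum(adjacency(sample_er(n, 1))))
  expect_lt(abs(mean(counts) - n) / n, 0.05)
  expect_error(sample_er(10, 12), "mean degree")
})

test_that("count_cycles enumerates canonically and agrees with brute force", {
  expect_equal(count_cycles(cycle_network(5))$cycle_count, 1)
  expect_equal(count_cycles(fixture_chain(6))$cycle_count, 0)
  # complete digraph on 3 nodes: three 2-cycles + two 3-cycles
  K3 <- directed_network(1 - diag(3))
  census <- count_cycles(K3)
  expect_equal(census$cycle_count, 5)
  expect_false(census$capped)
  # every cycle starts at its smallest member
  expect_true(all(vapply(census$cycles, function(cy) cy[1] == min(cy), logical(1))))
  # brute-force oracle on random tiny graphs
  set.seed(42)
  for (k in 1:25) {
    net <- sample_er(6, runif(1, 0.5, 2.5))
    expect_equal(canon_cycles(count_cycles(net)$cycles),
                 canon_cycles(brute_force_cycles(net)))
  }
})

test_that("count_cycles caps early and flags it", {
  K4 <- directed_network(1 - diag(4))
  capped <- count_cycles(K4, max_count = 2)
  expect_true(capped$capped)
  expect_equal(capped$cycle_count, 2)
  full <- count_cycles(K4)
  expect_gt(full$cycle_count, 2)
  expect_false(full$capped)
})

test_that("count_cycles is invariant under node relabeling", {
  set.seed(7)
  for (k in 1:10) {
    net <- sample_er(8, 1.5)
    perm <- sample(8)
    A <- adjacency(net)
    relabeled <- directed_network(A[perm, perm])
    expect_equal(count_cycles(net)$cycle_count,
                 count_cycles(relabeled)$cycle_count)
  }
})

test_that("cycle_flags agrees with the capped census predicates", {
  set.seed(11)
  for (k in 1:60) {
    net <- sample_er(sample(5:30, 1), runif(1, 0.3, 1.8))
    census <- count_cycles(net, max_count = 2)
    flags <- cycle_flags(net)
    expect_identical(flags$has_cycle, census$cycle_count >= 1)
    expect_identical(flags$single_cycle,
                     census$cycle_count == 1 && !census$capped)
    if (flags$single_cycle)
      expect_setequal(flags$cycle_nodes, census$cycles[[1]])
  }
})

test_that("path_multiplicity counts directed paths from the cycle", {
  expect_equal(path_multiplicity(fixture_cycle_fan()), c(1, 1, 1, 2))
  expect_equal(path_multiplicity(cycle_network(4)), rep(1, 4))
  # 2-cycle plus an isolated node: unreachable node gets 0
  expect_equal(path_multiplicity(cycle_network(2, n_nodes = 3)), c(1, 1, 0))
  expect_error(path_multiplicity(fixture_chain(3)), "exactly one")
  expect_error(path_multiplicity(directed_network(1 - diag(3))), "exactly one")
})

test_that("path multiplicity satisfies the off-cycle fixed-point relation", {
  set.seed(19)
  done <- 0
  while (done < 30) {
    net <- try(sample_conditioned(40, 1, "single_cycle", max_attempts = 500),
               silent = TRUE)
    if (inherits(net, "try-error")) next
    done <- done + 1
    counts <- path_multiplicity(net)
    A <- adjacency(net)
    on_cycle <- seq_len(40) %in% cycle_flags(net)$cycle_nodes
    for (i in which(!on_cycle))
      expect_identical(counts[i], as.integer(sum(A[i, ] * counts)))
  }
})

test_that("sample_conditioned outputs pass census re-verification", {
  set.seed(23)
  for (k in 1:5) {
    net <- sample_conditioned(30, 1, "single_cycle")
    expect_equal(count_cycles(net, max_count = 2)$cycle_count, 1)
  }
  for (k in 1:5) {
    net <- sample_conditioned(30, 1.2, "multi_cycle")
    census <- count_cycles(net, max_count = 2)
    expect_gte(census$cycle_count, 2)
  }
  net <- sample_conditioned(200, 1, "single_cycle", min_max_multiplicity = 3)
  expect_gte(max(path_multiplicity(net)), 3)
  expect_error(sample_conditioned(6, 0, "single_cycle", max_attempts = 3),
               "attempts")
})
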