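test_that("jk_init draws the stated Erdős–Rényi ensemble", {
  set.seed(1)
  expect_equal(sum(adjacency(jk_init(20, 0))), 0)
  counts <- replicate(400, sum(adjacency(jk_init(100, 0.25))))
  expect_lt(abs(mean(counts) - 25) / 25, 0.1)   # binomial mean N*m
  set.seed(9); a <- jk_init(30, 0.5)
  set.seed(9); b <- jk_init(30, 0.5)
  expect_identical(adjacency(a), adjacency(b))
})

test_that("jk_step conserves N and never removes populated cycle nodes", {
  set.seed(2)
  # isolated 3-cycle plus 2 isolated nodes: weakest is an isolated node
  net <- cycle_network(3, n_nodes = 5)
  for (k in 1:10) {
    st <- jk_step(net, m = 0.25)
    expect_equal(n_nodes(st$net), 5)
    expect_true(st$weakest %in% 4:5)
    net <- cycle_network(3, n_nodes = 5)
  }
  # m = 0: the newcomer is always isolated, hence weakest-eligible next step
  st <- jk_step(cycle_network(3, n_nodes = 4), m = 0)
  expect_equal(sum(adjacency(st$net)[st$weakest, ]), 0)
  expect_equal(sum(adjacency(st$net)[, st$weakest]), 0)
})

test_that("single-cycle steps are always quantized within runs", {
  run <- jk_run(25, m = 0.25, n_steps = 120, seed = 31)
  rec <- run$records
  expect_true(all(rec$S >= 0 & rec$S <= 25))
  expect_true(all(rec$quantized[rec$single_cycle]))
  expect_true(all(rec$has_cycle[rec$single_cycle]))
  # lambda1 = 1 exactly on census-verified single-cycle steps
  expect_true(all(abs(rec$lambda1[rec$single_cycle] - 1) < 1e-9))
})

test_that("jk_harvest reproduces the jk_run trajectory under one seed", {
  r1 <- jk_run(25, m = 0.3, n_steps = 250, seed = 12, record_lambda1 = FALSE)
  r2 <- jk_harvest(25, m = 0.3, n_steps = 250, seed = 12)
  expect_identical(r1$records$S, r2$records$S)
  expect_identical(r1$records$has_cycle, r2$records$has_cycle)
  expect_identical(r1$records$single_cycle, r2$records$single_cycle)
})

test_that("collapse_records locates collapses from the census flags", {
  # synthetic flag sequence [multi, single, single, none]: one record, T = 2
  rec <- data.frame(has_cycle = c(TRUE, TRUE, TRUE, FALSE),
                    single_cycle = c(FALSE, TRUE, TRUE, FALSE))
  cr <- collapse_records(rec, m = 0.25)
  expect_equal(nrow(cr$records), 1)
  expect_equal(cr$records$t_cycl, 2)
  expect_equal(cr$records$t_collapse, 4)
  expect_equal(cr$records$T, 2)
  # no collapse: empty record set
  rec0 <- data.frame(has_cycle = c(FALSE, TRUE, TRUE),
                     single_cycle = c(FALSE, FALSE, TRUE))
  expect_equal(nrow(collapse_records(rec0)$records), 0)
  # a collapse without a preceding single-cycle step is inconsistent
  bad <- data.frame(has_cycle = c(TRUE, FALSE),
                    single_cycle = c(FALSE, FALSE))
  expect_error(collapse_records(bad), "single-cycle")
})

test_that("every simulated collapse is preceded by a single-cycle step", {
  h <- jk_harvest(25, m = 0.3, n_steps = 30000, seed = 41)
  rec <- h$records
  drops <- which(!rec$has_cycle & c(FALSE, head(rec$has_cycle, -1)))
  expect_gt(length(drops), 0)
  expect_true(all(rec$single_cycle[drops - 1]))
  # collapse_records runs without consistency errors on real data
  cr <- collapse_records(h)
  expect_equal(cr$stats$n_collapses, length(drops))
  expect_true(all(cr$records$T >= 1))
})

test_that("the non-structural signal matches the census on single-cycle steps", {
  agree <- tot <- fa <- 0
  for (seed in c(11, 22)) {
    run <- jk_run(25, m = 0.25, n_steps = 800, seed = seed,
                  record_lambda1 = FALSE)
    r <- run$records
    # theorem direction is exact: one cycle implies quantization, always
    expect_true(all(r$quantized[r$single_cycle]))
    cyc <- r$has_cycle
    agree <- agree + sum(r$quantized[cyc] == r$single_cycle[cyc])
    fa <- fa + sum(r$quantized[cyc] & !r$single_cycle[cyc])
    tot <- tot + sum(cyc)
  }
  # reverse direction is only approximate: a dominated second cycle leaves
  # the attractor exactly quantized, so discrepancies are reported, not
  # forbidden (they are false alarms only in the structural sense)
  cat(sprintf("\nsignal/census agreement on cycle-bearing steps: %.3f (%d false alarms / %d steps)\n",
              agree / tot, fa, tot))
  expect_gt(agree / tot, 0.5)
})

test_that("predicted_time_to_collapse encodes the geometric law", {
  th <- predicted_time_to_collapse(0.25)
  expect_equal(th$p, 0.25 / exp(1))
  expect_equal(th$expected_T, exp(1) / 0.25)
  expect_equal(th$expected_T, 10.873127, tolerance = 1e-6)
  expect_equal(th$pmf(1), th$p)
  expect_equal(sum(th$pmf(1:2000)), 1, tolerance = 1e-12)
  expect_equal(sum((1:5000) * th$pmf(1:5000)), th$expected_T, tolerance = 1e-6)
  expect_error(predicted_time_to_collapse(0), "positive")
})
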