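test_that("order-preserving matching finds the minimal L1 injection", {
  a <- order_preserving_match(c(4.0, 9.0), c(3.5, 7.0, 9.2))
  expect_equal(a$pairs$ladder_index, c(1L, 3L))
  expect_equal(a$total_cost, 0.7)
  expect_equal(a$gaps, 2L)
  # cost agrees with exhaustive enumeration on the same instance
  expect_equal(a$total_cost, brute_force_op_cost(c(4, 9), c(3.5, 7, 9.2)))

  b <- order_preserving_match(c(2.0, 5.0, 8.0), c(2.0, 5.0, 8.0))
  expect_equal(b$pairs$ladder_index, 1:3)
  expect_equal(b$total_cost, 0)
})

test_that("order-preserving cost ties break to the smallest ladder index", {
  a <- order_preserving_match(5.0, c(3.0, 7.0))
  expect_equal(a$pairs$ladder_index, 1L)
  expect_equal(a$total_cost, 2.0)
})

test_that("matching an experimental sequence longer than the ladder is infeasible", {
  expect_error(order_preserving_match(c(2, 5, 8), c(3, 7)),
               class = "pkaladder_infeasible_error")
  expect_error(window_match(c(2, 5, 8), c(3, 7)),
               class = "pkaladder_infeasible_error")
  expect_error(closest_match(4.2, numeric(0)),
               class = "pkaladder_infeasible_error")
  expect_error(pairwise_match(c(2, 5), 3),
               class = "pkaladder_infeasible_error")
})

test_that("window matching scans consecutive segments and prefers the earliest tie", {
  a <- window_match(c(4.0, 9.0), c(3.5, 7.0, 9.2))
  expect_equal(a$pairs$ladder_index, c(1L, 2L))
  expect_equal(a$total_cost, 2.5)

  b <- window_match(c(4.0, 9.0), c(3.9, 9.1))  # N == M: the unique window
  expect_equal(b$pairs$ladder_index, c(1L, 2L))

  c <- window_match(7.0, c(3.0, 7.0, 11.0))
  expect_equal(c$pairs$ladder_index, 2L)
  expect_equal(c$total_cost, 0)

  # symmetric tie between windows starting at 1 and 2
  d <- window_match(5.0, c(4.0, 6.0))
  expect_equal(d$pairs$ladder_index, 1L)
})

test_that("closest matching pairs to the nearest rung, lower index on ties", {
  expect_equal(closest_match(4.2, c(3.0, 4.5, 9.0))$pairs$ladder_index, 2L)
  expect_equal(closest_match(4.2, c(3.0, 4.5, 9.0))$total_cost, 0.3)
  expect_equal(closest_match(7.0, c(3.0, 7.0))$total_cost, 0)
  expect_equal(closest_match(5.0, c(3.0, 7.0))$pairs$ladder_index, 1L)
})

test_that("pairwise linear assignment matches brute force and prefers non-crossing ties", {
  a <- pairwise_match(c(2.3, 9.6), c(2.0, 7.0, 9.5))
  expect_equal(a$pairs$ladder_index, c(1L, 3L))
  expect_equal(a$total_cost, 0.4, tolerance = 1e-12)

  b <- pairwise_match(c(3.0, 5.0), c(3.0, 5.0))
  expect_equal(b$total_cost, 0)

  c <- pairwise_match(c(4.0, 4.0), c(3.0, 5.0))
  expect_equal(c$total_cost, 2.0)
  expect_equal(c$pairs$ladder_index, c(1L, 2L))
})

test_that("dynamic program equals exhaustive enumeration on 1000 seeded instances", {
  set.seed(7001)
  checks <- vapply(1:1000, function(rep) {
    inst <- random_instance()
    a <- order_preserving_match(inst$exp, inst$ladder)
    c(dp = a$total_cost,
      oracle = brute_force_op_cost(inst$exp, inst$ladder),
      recomputed = sum(abs(a$pairs$exp_value - a$pairs$ladder_value)),
      pairs_ok = nrow(a$pairs) == length(inst$exp) &&
        all(diff(a$pairs$ladder_index) > 0))
  }, numeric(4))
  expect_equal(checks["dp", ], checks["oracle", ], tolerance = 1e-9)
  expect_equal(checks["dp", ], checks["recomputed", ], tolerance = 1e-12)
  expect_true(all(checks["pairs_ok", ] == 1))
})

test_that("order-preserving cost never exceeds window cost, and both reduce for N = 1", {
  set.seed(7002)
  costs <- vapply(1:500, function(rep) {
    inst <- random_instance()
    c(op = order_preserving_match(inst$exp, inst$ladder)$total_cost,
      wi = window_match(inst$exp, inst$ladder)$total_cost,
      wi_oracle = brute_force_window_cost(inst$exp, inst$ladder))
  }, numeric(3))
  expect_true(all(costs["op", ] <= costs["wi", ] + 1e-12))
  expect_equal(costs["wi", ], costs["wi_oracle", ], tolerance = 1e-12)

  spread <- vapply(1:200, function(rep) {
    e <- runif(1, 0, 14)
    ladder <- sort(runif(sample(1:6, 1), 0, 14))
    costs <- c(order_preserving_match(e, ladder)$total_cost,
               window_match(e, ladder)$total_cost,
               closest_match(e, ladder)$total_cost)
    max(costs) - min(costs)
  }, numeric(1))
  expect_equal(max(spread), 0, tolerance = 1e-12)
})

test_that("pairwise assignment equals order-preserving matching on 2-value instances", {
  set.seed(7003)
  diffs <- vapply(1:1000, function(rep) {
    exp <- sort(round(runif(2, 0, 14), 3))
    ladder <- sort(round(runif(sample(2:6, 1), 0, 14), 3))
    abs(pairwise_match(exp, ladder)$total_cost -
          order_preserving_match(exp, ladder)$total_cost)
  }, numeric(1))
  expect_lt(max(diffs), 1e-9)
})

test_that("zero cost occurs exactly for numeric subsequences of the ladder", {
  set.seed(7004)
  for (rep in 1:100) {
    ladder <- sort(round(runif(6, 0, 14), 2))
    sub <- sort(sample(ladder, 3))
    expect_equal(order_preserving_match(sub, ladder)$total_cost, 0)
    perturbed <- sub + c(0.01, 0, 0)
    if (!all(perturbed %in% ladder)) {
      expect_gt(order_preserving_match(perturbed, ladder)$total_cost, 0)
    }
  }
})

test_that("appending a ladder value never increases the optimal cost", {
  set.seed(7005)
  deltas <- vapply(1:300, function(rep) {
    inst <- random_instance()
    before <- order_preserving_match(inst$exp, inst$ladder)$total_cost
    extended <- sort(c(inst$ladder, runif(1, 0, 14)))
    order_preserving_match(inst$exp, extended)$total_cost - before
  }, numeric(1))
  expect_lte(max(deltas), 1e-12)
})

test_that("typed-group consistency check flags within- and between-group violations", {
  ok <- typed_group_check(list(pKa1 = c(3.0, 3.2), pKa2 = 8.0))
  expect_true(ok$pass)
  expect_equal(nrow(ok$violations), 0)

  within <- typed_group_check(list(pKa1 = c(3.0, 4.5)))
  expect_false(within$pass)
  expect_equal(within$violations$kind, "within")
  expect_equal(within$violations$diff, 1.5)

  between <- typed_group_check(list(pKa1 = 3.0, pKa2 = 3.3))
  expect_false(between$pass)
  expect_equal(between$violations$kind, "between")
  expect_equal(between$violations$diff, 0.3, tolerance = 1e-12)

  # degenerate single-group single-value input passes
  expect_true(typed_group_check(list(pKa1 = 5.0))$pass)
})
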