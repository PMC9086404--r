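test_that("pair counts tally adjacent symbols exactly", {
  cc <- pair_counts(c(1, 1, -1, 1))
  expect_equal(cc["1", "1"], 1L)
  expect_equal(cc["1", "-1"], 1L)
  expect_equal(cc["-1", "1"], 1L)
  expect_equal(sum(cc), 3L)
  cc <- pair_counts(c(0, 0, 0))
  expect_equal(cc["0", "0"], 2L)
  expect_equal(sum(cc), 2L)
  cc <- pair_counts(c(1, -1, 1, -1))
  expect_equal(cc["1", "-1"], 2L)
  expect_equal(cc["-1", "1"], 1L)
  expect_error(pair_counts(1L), "at least 2")
})

test_that("two-state estimator matches hand computation and edge cases", {
  expect_equal(estimate_two_state(pair_counts(c(1, 1, -1, 1)))$a, 0.25)
  # chain that never switches: a-hat = 1 (degenerate downstream)
  expect_equal(estimate_two_state(pair_counts(c(1, 1, 1)))$a, 1)
  # no transitions out of the trending states at all
  expect_error(estimate_two_state(pair_counts(c(0, 0, 0))), "degenerate")
})

test_that("three-state estimator matches the printed row ratios", {
  counts <- matrix(c(2, 1, 1,
                     1, 2, 1,
                     1, 1, 2), 3, 3, byrow = TRUE,
                   dimnames = list(c("-1", "0", "1"), c("-1", "0", "1")))
  est <- estimate_three_state(counts)
  expect_equal(est$b, 0.5)
  expect_equal(est$c, 0.25)
  expect_equal(est$d, 0.25)
  expect_error(estimate_three_state(pair_counts(c(1, 1, -1))),
               "state 0")
})

test_that("estimators recover generating parameters on long chains", {
  set.seed(3)
  a_err <- d_err <- numeric(3)
  ms <- c(1e3, 1e4, 1e5)
  for (i in seq_along(ms)) {
    ae <- de <- numeric(10)
    for (r in 1:10) {
      d2 <- simulate_trend_chain(ms[i], two_state_params(0.7))
      ae[r] <- abs(estimate_two_state(pair_counts(d2))$a - 0.7)
      d3 <- simulate_trend_chain(ms[i], three_state_params(0.5, 0.1, 0.2))
      est <- estimate_three_state(pair_counts(d3))
      de[r] <- max(abs(est$b - 0.5), abs(est$c - 0.1), abs(est$d - 0.2))
    }
    a_err[i] <- mean(ae)
    d_err[i] <- mean(de)
  }
  expect_true(all(diff(a_err) < 0))
  expect_true(all(diff(d_err) < 0))
  expect_lt(a_err[3], 0.01)
  expect_lt(d_err[3], 0.01)
})

test_that("closed-form variances match their worked values", {
  expect_equal(sigma2_two(two_state_params(0.5), two_state_params(0.5)), 1)
  expect_equal(sigma2_two(two_state_params(0.75), two_state_params(0.75)),
               5 / 3)
  # the i.i.d. two-state value used by TLTA at t = 0
  expect_equal(sigma2_two(two_state_params(1 / 3), two_state_params(1 / 3)),
               1.25)
  p3 <- three_state_params(0.5, 0.1, 0.2)
  expect_equal(sigma2_three(p3, p3), 0.25 * 1.16 / 0.84)
  pr <- three_state_params(0.25, 0.25, 0.25)  # rho = 0
  expect_equal(sigma2_three(pr, pr), 0.25)
  expect_equal(sigma2_mixed(two_state_params(0.8), p3), 0.5 * 1.24 / 0.76)
  # symmetric in argument order; r = 0 collapses to the marginal factor
  expect_equal(sigma2_mixed(p3, two_state_params(0.8)),
               sigma2_mixed(two_state_params(0.8), p3))
  expect_equal(sigma2_mixed(two_state_params(0.5), p3), 2 * p3$phi1)
  expect_error(sigma2_two(two_state_params(1), two_state_params(1)),
               "degenerate")
})

test_that("closed forms equal the truncated autocovariance series", {
  set.seed(5)
  for (i in 1:40) {
    a1 <- runif(1, 0.05, 0.95)
    a2 <- runif(1, 0.05, 0.95)
    p2a <- two_state_params(a1)
    p2b <- two_state_params(a2)
    b <- runif(1, 0, 0.9)
    c <- runif(1, 0, 0.9 - b)
    d <- runif(1, 0.05, 0.45)
    p3a <- three_state_params(b, c, d)
    b2 <- runif(1, 0, 0.9)
    c2 <- runif(1, 0, 0.9 - b2)
    p3b <- three_state_params(b2, c2, runif(1, 0.05, 0.45))
    expect_lt(abs(sigma2_two(p2a, p2b) - sigma2_series(p2a, p2b)), 1e-10)
    expect_lt(abs(sigma2_three(p3a, p3b) - sigma2_series(p3a, p3b)),
              1e-10)
    expect_lt(abs(sigma2_mixed(p2a, p3a) - sigma2_series(p2a, p3a)),
              1e-10)
  }
})

test_that("matrix-power autocovariance equals the closed forms", {
  expect_equal(autocov_exact(two_state_params(0.5), 3), 0)
  expect_equal(autocov_exact(two_state_params(0.75), 2), 0.25)
  expect_equal(autocov_exact(three_state_params(0.5, 0.1, 0.2), 1), 0.2)
  set.seed(8)
  for (i in 1:20) {
    a <- runif(1)
    p2 <- two_state_params(a)
    b <- runif(1, 0, 0.95)
    c <- runif(1, 0, 0.95 - b)
    d <- runif(1, 0.025, 0.475)
    p3 <- three_state_params(b, c, d)
    for (k in sample(1:20, 4)) {
      expect_lt(abs(autocov_exact(p2, k) - (2 * a - 1)^k), 1e-12)
      expect_lt(abs(autocov_exact(p3, k) - 2 * p3$phi1 * (b - c)^k),
                1e-12)
    }
  }
})

test_that("stationary law satisfies the balance equation", {
  set.seed(2)
  for (i in 1:20) {
    b <- runif(1, 0, 0.9)
    c <- runif(1, 0, 0.9 - b)
    p3 <- three_state_params(b, c, runif(1, 0.05, 0.45))
    phi <- c(p3$phi1, 1 - 2 * p3$phi1, p3$phi1)
    expect_equal(drop(phi %*% transition_matrix(p3)), phi,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("i.i.d. trend parameters are distribution-free at t = 0", {
  expect_equal(iid_params(0)$a, 1 / 3)
})

test_that("i.i.d. trend parameters are Monte-Carlo stable at t = 0.5", {
  p1 <- iid_params(0.5, N = 1e6, seed = 101)
  p2 <- iid_params(0.5, N = 1e6, seed = 202)
  expect_lt(abs(p1$b - p2$b), 0.005)
  expect_lt(abs(p1$c - p2$c), 0.005)
  expect_lt(abs(p1$d - p2$d), 0.005)
  # cached: repeated call returns the identical object
  expect_identical(iid_params(0.5, N = 1e6, seed = 101), p1)
})
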