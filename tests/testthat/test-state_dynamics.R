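test_that("label_states orders by grand emission mean with documented conventions", {
  # state grand means (3.35, 1.51, 5.0): middle state is lowest valence
  means <- rbind(rep(3.35, 7), rep(1.51, 7), rep(5.0, 7))
  lab <- label_states(means)
  expect_equal(lab$labels, c("neutral_moderate", "negative", "positive"))

  # ties fall back to state index order
  lab2 <- label_states(matrix(2, 3, 4))
  expect_equal(lab2$labels, c("negative", "neutral_moderate", "positive"))

  # K = 2 uses rank labels (valence names are reserved for K = 3)
  lab3 <- label_states(rbind(rep(4, 3), rep(2, 3)))
  expect_equal(lab3$labels, c("state_2", "state_1"))

  lab4 <- label_states(matrix(3, 1, 7))
  expect_equal(lab4$labels, "single_state")
})

test_that("stationary_distribution solves the fixed point and rejects reducible chains", {
  # period-2 chain still has the unique stationary vector (0.5, 0.5)
  A <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
  expect_equal(stationary_distribution(A), c(0.5, 0.5), tolerance = 1e-12)

  # rank-one chain: stationary equals the common row
  p <- c(0.2, 0.5, 0.3)
  expect_equal(stationary_distribution(rbind(p, p, p)), p, tolerance = 1e-12,
               ignore_attr = TRUE)

  # published transition matrix
  A3 <- happyhere_transition_matrix()
  pi3 <- stationary_distribution(A3)
  expect_equal(unname(pi3), c(0.3629, 0.1585, 0.4786), tolerance = 1e-3)
  expect_lt(max(abs(as.vector(pi3 %*% A3) - pi3)), 1e-10)
  expect_equal(pi3, power_iteration_stationary(A3), tolerance = 1e-10,
               ignore_attr = TRUE)

  # random irreducible chains: fixed point + power-iteration agreement
  set.seed(99)
  for (i in 1:20) {
    K <- sample(2:5, 1)
    A <- rand_stochastic(K)
    v <- stationary_distribution(A)
    expect_lt(max(abs(as.vector(v %*% A) - v)), 1e-10)
    expect_equal(v, power_iteration_stationary(A), tolerance = 1e-8)
  }

  # two closed blocks -> explicit error naming them
  Ared <- rbind(c(0.5, 0.5, 0, 0), c(0.4, 0.6, 0, 0),
                c(0, 0, 0.9, 0.1), c(0, 0, 0.2, 0.8))
  expect_error(stationary_distribution(Ared), "\\{1,2\\}.*\\{3,4\\}")
})

test_that("stationary distribution matches simulated occupancy within 3 SE", {
  A <- happyhere_transition_matrix()
  pi_star <- stationary_distribution(A)
  T_len <- 1e5
  path <- simulate_state_path(A, pi_star, T_len, seed = 7)
  occ <- tabulate(path, 3) / T_len
  se <- sqrt(pi_star * (1 - pi_star) / T_len) * sqrt(2 / (1 - max(diag(A))))
  expect_true(all(abs(occ - pi_star) < 3 * se))
})

test_that("dwell times follow the geometric closed form and simulated run lengths", {
  A <- happyhere_transition_matrix()
  d <- expected_dwell_times(A)$geometric
  expect_equal(unname(d[1]), 8, tolerance = 1e-12)          # 1/(1 - 0.875)
  expect_equal(unname(d[2]), 1.821, tolerance = 1e-3)        # ~1.8 steps
  expect_equal(unname(d[3]), 1 / 0.195, tolerance = 1e-12)

  # absorbing state flagged infinite
  expect_equal(expected_dwell_times(diag(2))$geometric, c(Inf, Inf))

  # monotone in the self-transition probability
  a <- seq(0.1, 0.9, by = 0.1)
  dd <- 1 / (1 - a)
  expect_true(all(diff(dd) > 0))

  # empirical mean run length on a long simulated path within 3 SE
  path <- simulate_state_path(A, c(1, 0, 0), 1e5, seed = 21)
  emp <- expected_dwell_times(A, path = path)$empirical
  r <- rle(path)
  for (k in 1:3) {
    runs <- r$lengths[r$values == k]
    se <- sd(runs) / sqrt(length(runs))
    expect_lt(abs(emp[k] - d[k]), 3 * se)
  }
})

test_that("transition entropy attains its bounds and published-row value", {
  expect_equal(unname(transition_entropy(rbind(c(1, 0, 0), rep(1 / 3, 3),
                                               c(0.5, 0.25, 0.25)))[1]), 0)
  expect_equal(unname(transition_entropy(matrix(1 / 3, 3, 3))[1]), log(3),
               tolerance = 1e-12)
  A <- happyhere_transition_matrix()
  expect_equal(unname(transition_entropy(A)[2]), 0.9381, tolerance = 1e-4)

  # base conversions
  row <- matrix(c(0.5, 0.5), 1)
  expect_equal(unname(transition_entropy(rbind(c(0.5, 0.5), c(1, 0)), "2")[1]), 1)
  expect_equal(unname(transition_entropy(matrix(1 / 4, 4, 4), "normalized")[1]), 1)

  # bounds and invariance under within-row permutation
  set.seed(31)
  for (i in 1:25) {
    K <- sample(2:5, 1)
    A <- rand_stochastic(K)
    H <- transition_entropy(A)
    expect_true(all(H >= 0 & H <= log(K) + 1e-12))
    perm <- sample(K)
    expect_equal(sort(transition_entropy(A[, perm, drop = FALSE] /
                                           rowSums(A))), sort(H))
  }
})

test_that("bootstrap transition statistics are reproducible, ordered, and honest about absent states", {
  # constant path: the self-transition CI is degenerate at 1
  bs <- suppressWarnings(bootstrap_transition_stats(rep(1L, 50), B = 50,
                                                    seed = 3, K = 2))
  expect_equal(bs$transition_lower[1, 1], 1)
  expect_equal(bs$transition_upper[1, 1], 1)
  expect_warning(bootstrap_transition_stats(rep(1L, 50), B = 5, seed = 3, K = 2),
                 "absent")
  expect_true(all(is.na(bs$entropy[2])))

  path <- simulate_state_path(happyhere_transition_matrix(), c(1, 0, 0),
                              2000, seed = 17)
  b1 <- bootstrap_transition_stats(path, B = 200, seed = 11)
  b2 <- bootstrap_transition_stats(path, B = 200, seed = 11)
  expect_identical(b1, b2)

  # lower <= point <= upper for the self-transitions (resampling slack 0)
  for (k in 1:3) {
    expect_lte(b1$transition_lower[k, k], b1$transition[k, k])
    expect_gte(b1$transition_upper[k, k], b1$transition[k, k])
  }
  expect_true(all(b1$entropy_lower <= b1$entropy_upper))
  expect_true(all(b1$dwell_lower <= b1$dwell_upper))

  # interval width shrinks as T grows
  path5k <- simulate_state_path(happyhere_transition_matrix(), c(1, 0, 0),
                                5000, seed = 17)
  path500 <- path5k[1:500]
  bshort <- bootstrap_transition_stats(path500, B = 300, seed = 5)
  blong <- bootstrap_transition_stats(path5k, B = 300, seed = 5)
  w_short <- diag(bshort$transition_upper) - diag(bshort$transition_lower)
  w_long <- diag(blong$transition_upper) - diag(blong$transition_lower)
  expect_true(all(w_long < w_short))
})
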