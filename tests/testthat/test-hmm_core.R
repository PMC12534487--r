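test_that("gaussian_log_density matches closed forms and the dense-algebra oracle", {
  expect_equal(gaussian_log_density(0, 0, matrix(1)), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  mu <- rnorm(7)
  expect_equal(gaussian_log_density(mu, mu, diag(7)), -3.5 * log(2 * pi),
               tolerance = 1e-12)

  set.seed(101)
  for (i in 1:20) {
    S <- rand_spd(7)
    x <- rnorm(7); mu <- rnorm(7)
    expect_equal(gaussian_log_density(x, mu, S), dense_log_density(x, mu, S),
                 tolerance = 1e-10)
  }
  expect_error(gaussian_log_density(rnorm(2), rnorm(2),
                                    matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("forward_backward handles degenerate cases exactly", {
  # T = 1, two states with identical emissions: posterior stays at the prior
  p <- hmm_params(c(0.5, 0.5), matrix(0.5, 2, 2),
                  matrix(0, 2, 1), list(matrix(1), matrix(1)))
  r <- forward_backward(matrix(0, 1, 1), p)
  expect_equal(r$gamma[1, ], c(0.5, 0.5))
  expect_equal(r$log_likelihood, gaussian_log_density(0, 0, matrix(1)),
               tolerance = 1e-12)

  # K = 1: log-likelihood is the iid Gaussian sum, gamma all ones
  set.seed(7)
  X <- matrix(rnorm(30), 10, 3)
  p1 <- hmm_params(1, matrix(1), matrix(0, 1, 3), list(diag(3)))
  r1 <- forward_backward(X, p1)
  expect_equal(r1$log_likelihood,
               sum(gaussian_log_density(X, rep(0, 3), diag(3))),
               tolerance = 1e-10)
  expect_true(all(r1$gamma == 1))
})

test_that("forward_backward and Viterbi agree with exhaustive path enumeration", {
  set.seed(202)
  for (i in 1:60) {
    K <- sample(2:3, 1)
    T_len <- sample(2:6, 1)
    d <- sample(1:2, 1)
    p <- rand_hmm(K, d)
    X <- matrix(rnorm(T_len * d, sd = 2), T_len, d)
    oracle <- enumerate_paths(X, p)
    fb <- forward_backward(X, p)
    expect_equal(fb$log_likelihood, oracle$log_likelihood, tolerance = 1e-9)
    vit <- viterbi_decode(X, p)
    expect_equal(vit$log_prob, oracle$max_path_logprob, tolerance = 1e-9)
    # posteriors normalise
    expect_true(max(abs(rowSums(fb$gamma) - 1)) < 1e-8)
    if (T_len > 1)
      expect_true(max(abs(apply(fb$xi, 1, sum) - 1)) < 1e-8)
  }
})

test_that("Viterbi degenerate paths and tie-breaking", {
  p1 <- hmm_params(1, matrix(1), matrix(0, 1, 2), list(diag(2)))
  expect_equal(viterbi_decode(matrix(rnorm(10), 5, 2), p1)$path, rep(1L, 5))

  # absorbing start dominates regardless of emissions
  p2 <- hmm_params(c(1, 0), diag(2), matrix(c(0, 5), 2, 1),
                   list(matrix(1), matrix(1)))
  expect_equal(viterbi_decode(matrix(c(5, 5, 5), 3, 1), p2)$path, rep(1L, 3))

  # exact tie between states -> lower index wins
  p3 <- hmm_params(c(0.5, 0.5), matrix(0.5, 2, 2), matrix(0, 2, 1),
                   list(matrix(1), matrix(1)))
  expect_equal(viterbi_decode(matrix(0, 4, 1), p3)$path, rep(1L, 4))
})

test_that("likelihood is invariant under state permutation", {
  set.seed(303)
  p <- rand_hmm(3, 2)
  X <- matrix(rnorm(40), 20, 2)
  base <- forward_backward(X, p)$log_likelihood
  perm <- c(3, 1, 2)
  pp <- hmm_params(p$initial[perm], p$transition[perm, perm],
                   p$means[perm, , drop = FALSE],
                   p$covariances[, , perm, drop = FALSE])
  expect_equal(forward_backward(X, pp)$log_likelihood, base, tolerance = 1e-10)
})

test_that("single-state EM equals the closed-form Gaussian MLE", {
  set.seed(404)
  X <- matrix(rnorm(200, mean = 3), 50, 4)
  cfg <- fit_config(n_restarts = 1, max_iter = 50, cov_ridge = 1e-6, seed = 1)
  fit <- baum_welch_fit(X, 1, cfg)
  expect_equal(as.numeric(fit$params$means), colMeans(X), tolerance = 1e-10)
  S_mle <- cov(X) * (nrow(X) - 1) / nrow(X) + diag(1e-6, 4)
  expect_equal(fit$params$covariances[, , 1], S_mle, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("EM log-likelihood traces are nondecreasing and reach a fixed point", {
  set.seed(505)
  cfg3 <- three_cluster_config(n = 400, seed = 6)
  g <- generate_dataset(cfg3)
  X <- as.matrix(g$table[, swemwbs_items])
  for (seed in 1:3) {
    fit <- baum_welch_fit(X, 3, fit_config(n_restarts = 2, max_iter = 200,
                                           seed = seed))
    expect_true(all(diff(fit$loglik_trace) >= -1e-8 * abs(fit$loglik_trace[-1])))
    expect_true(fit$converged)
    # one further EM step moves the log-likelihood by less than tol
    post <- forward_backward(X, fit$params)
    stepped <- affecthmm:::m_step(X, post$gamma, post$xi,
                                  fit_config(seed = seed))
    ll_next <- forward_backward(X, stepped)$log_likelihood
    expect_lt(abs(ll_next - fit$log_likelihood), 1e-6 * abs(fit$log_likelihood))
  }
  expect_error(baum_welch_fit(X[1:3, ], 3, fit_config()), "T > K")
})

test_that("BIC parameter counts and arithmetic are exact", {
  # K=3, d=7 full: p = 2 + 6 + 21 + 84 = 113
  expect_equal(compute_bic(-1000, 3, 7, 6559, "full"),
               2000 + 113 * log(6559), tolerance = 1e-12)
  # K=1, d=1 full: p = 2
  expect_equal(compute_bic(0, 1, 1, 10, "full"), 2 * log(10), tolerance = 1e-12)
  # diagonal swaps K d(d+1)/2 for K d
  expect_equal(compute_bic(0, 2, 3, 100, "diagonal"),
               (1 + 2 + 6 + 6) * log(100), tolerance = 1e-12)
})

test_that("select_n_states returns the singleton fit and a complete table", {
  set.seed(606)
  g <- generate_dataset(three_cluster_config(n = 300, seed = 2))
  X <- as.matrix(g$table[, swemwbs_items])
  cfg <- fit_config(n_restarts = 2, max_iter = 100, seed = 4)
  sel <- select_n_states(X, 2, cfg)
  expect_equal(sel$best_K, 2)
  expect_equal(nrow(sel$bic_table), 1)
  expect_false(any(sel$bic_table$failed))
})

test_that("fitted log-likelihood matches an independent HMM implementation", {
  g <- generate_dataset(three_cluster_config(n = 400, seed = 12))
  X <- as.matrix(g$table[, swemwbs_items])
  fit <- baum_welch_fit(X, 3, fit_config(n_restarts = 3, max_iter = 300,
                                         tol = 1e-8, cov_ridge = 1e-6, seed = 1))

  csv <- tempfile(fileext = ".csv")
  write.table(X, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "from hmmlearn.hmm import GaussianHMM",
    "X = np.loadtxt(sys.argv[1], delimiter=',')",
    "best = -np.inf",
    "for rs in range(5):  # restarts: compare best optimum to best optimum",
    "    m = GaussianHMM(n_components=3, covariance_type='full', n_iter=500,",
    "                    tol=1e-8, min_covar=1e-6, random_state=rs)",
    "    m.fit(X)",
    "    best = max(best, m.score(X))",
    "print(repr(best))"), py)
  out <- suppressWarnings(system2("python", c(py, csv), stdout = TRUE,
                                  stderr = FALSE))
  ll_ref <- as.numeric(out[length(out)])
  expect_true(is.finite(ll_ref))
  expect_lt(abs(fit$log_likelihood - ll_ref) / abs(ll_ref), 1e-4)
})
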