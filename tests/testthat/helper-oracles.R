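# Shared fixtures and independent oracles for the suite. The oracles are
# deliberately naive (dense algebra, exhaustive path enumeration) and never
# share code with the implementation paths they check.

rand_spd <- function(d) {
  M <- matrix(rnorm(d * d), d)
  crossprod(M) + diag(0.5, d)
}

rand_stochastic <- function(K) {
  A <- matrix(rexp(K * K), K)
  A / rowSums(A)
}

rand_hmm <- function(K, d) {
  p <- rexp(K)
  covs <- array(0, c(d, d, K))
  for (k in seq_len(K)) covs[, , k] <- rand_spd(d)
  hmm_params(p / sum(p), rand_stochastic(K),
             matrix(rnorm(K * d, sd = 2), K, d), covs)
}

# Dense-algebra Gaussian log density (explicit inverse + determinant).
dense_log_density <- function(x, mu, sigma) {
  d <- length(x)
  xc <- x - mu
  -0.5 * (d * log(2 * pi) + determinant(sigma, logarithm = TRUE)$modulus[1] +
            drop(t(xc) %*% solve(sigma) %*% xc))
}

# log-emission matrix via the dense oracle (row t, state k)
dense_logB <- function(X, params) {
  T_len <- nrow(X)
  d <- params$d
  out <- matrix(0, T_len, params$K)
  for (t in seq_len(T_len))
    for (k in seq_len(params$K))
      out[t, k] <- dense_log_density(X[t, ], params$means[k, ],
                                     matrix(params$covariances[, , k], d, d))
  out
}

# Exhaustive enumeration over all K^T state paths: exact log-likelihood and
# the maximum joint path log-probability.
enumerate_paths <- function(X, params) {
  K <- params$K
  T_len <- nrow(X)
  logB <- dense_logB(X, params)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
  lp <- apply(paths, 1, function(s) {
    v <- log(params$initial[s[1]]) + logB[1, s[1]]
    for (t in seq_len(T_len - 1))
      v <- v + log(params$transition[s[t], s[t + 1]]) + logB[t + 1, s[t + 1]]
    v
  })
  m <- max(lp)
  list(log_likelihood = m + log(sum(exp(lp - m))),
       max_path_logprob = m,
       argmax_path = as.integer(paths[which.max(lp), ]))
}

# Stationary distribution by plain power iteration to convergence,
# independent of the eigen-decomposition route (aperiodic chains only).
power_iteration_stationary <- function(A, tol = 1e-14, max_iter = 1e6) {
  K <- nrow(A)
  v <- rep(1 / K, K)
  for (i in seq_len(max_iter)) {
    v_new <- as.vector(v %*% A)
    v_new <- v_new / sum(v_new)
    if (max(abs(v_new - v)) < tol) return(v_new)
    v <- v_new
  }
  v
}

# Small in-memory submission table for data_io tests.
toy_table <- function(values, times = NULL) {
  n <- nrow(values)
  if (is.null(times))
    times <- as.POSIXct("2024-06-01 10:00", tz = "UTC") + seq_len(n) * 60
  tab <- data.frame(timestamp = times)
  for (j in seq_len(ncol(values))) tab[[affecthmm::swemwbs_items[j]]] <- values[, j]
  class(tab) <- c("submission_table", "data.frame")
  tab
}

# A well-separated 3-state valence dataset for selection/recovery tests.
three_cluster_config <- function(n, seed, sd = 0.3, discretize = FALSE) {
  means <- matrix(rep(c(1.5, 3.3, 5.0), each = 7), nrow = 3, byrow = FALSE)
  means <- matrix(c(rep(1.5, 7), rep(3.3, 7), rep(5.0, 7)), nrow = 3, byrow = TRUE)
  covs <- array(0, c(7, 7, 3))
  for (k in 1:3) covs[, , k] <- diag(sd^2, 7)
  synthetic_config(K = 3, A_true = happyhere_transition_matrix(),
                   initial_true = c(1, 1, 1) / 3, means_true = means,
                   covs_true = covs, n = n, anomaly_rate = 0,
                   discretize = discretize, seed = seed)
}
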