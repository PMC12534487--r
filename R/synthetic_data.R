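#' Configuration for the synthetic submission generator
#'
#' Describes a K-state first-order Markov chain over chronologically ordered
#' submissions with state-conditional Gaussian emissions on the seven
#' SWEMWBS items, optional discretization to the 1-5 Likert grid, injection
#' of invalid codes (0 / -1), and timestamps confined to daily opening
#' hours across a multi-week span.
#'
#' @param K Number of latent states.
#' @param A_true K x K row-stochastic transition matrix.
#' @param initial_true Length-K initial distribution.
#' @param means_true K x d matrix of emission means, entries in \[1, 5\].
#' @param covs_true d x d x K array (or list of K matrices) of symmetric
#'   positive-definite emission covariances.
#' @param n Number of records to generate.
#' @param anomaly_rate Probability in \[0, 1) that a record carries one
#'   invalid code (0 or -1) on one randomly chosen item.
#' @param discretize If `TRUE`, emissions are rounded to the nearest integer
#'   and clipped to \[1, 5\].
#' @param opening_hours Length-2 numeric, daily clock window in hours
#'   (default 10:00-17:00).
#' @param n_days Number of calendar days spanned.
#' @param start_date First day of the span (Date or string).
#' @param seed Master seed; split deterministically between the state path,
#'   emissions, anomalies and timestamps so that, e.g., changing the anomaly
#'   rate does not perturb the path.
#' @return A validated `synthetic_config` object.
#' @export
synthetic_config <- function(K, A_true, initial_true, means_true, covs_true,
                             n, anomaly_rate = 0, discretize = TRUE,
                             opening_hours = c(10, 17), n_days = 60,
                             start_date = "2024-06-01", seed = 1) {
  if (is.list(covs_true)) {
    d <- nrow(covs_true[[1]])
    covs <- array(0, dim = c(d, d, K))
    for (k in seq_len(K)) covs[, , k] <- covs_true[[k]]
    covs_true <- covs
  }
  cfg <- structure(list(K = as.integer(K), A_true = A_true,
                        initial_true = initial_true, means_true = means_true,
                        covs_true = covs_true, n = as.integer(n),
                        anomaly_rate = anomaly_rate, discretize = discretize,
                        opening_hours = opening_hours,
                        n_days = as.integer(n_days),
                        start_date = as.Date(start_date),
                        seed = as.integer(seed)),
                   class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  assert_stochastic(cfg$A_true, "A_true")
  assert_prob_vector(cfg$initial_true, "initial_true")
  if (nrow(cfg$A_true) != cfg$K || length(cfg$initial_true) != cfg$K)
    stop("A_true / initial_true dimensions disagree with K", call. = FALSE)
  if (!is.matrix(cfg$means_true) || nrow(cfg$means_true) != cfg$K)
    stop("means_true must be a K x d matrix", call. = FALSE)
  if (any(cfg$means_true < 1 | cfg$means_true > 5))
    stop("means_true entries must lie in [1, 5]", call. = FALSE)
  d <- ncol(cfg$means_true)
  if (!all(dim(cfg$covs_true) == c(d, d, cfg$K)))
    stop("covs_true must be a d x d x K array", call. = FALSE)
  for (k in seq_len(cfg$K)) {
    S <- cfg$covs_true[, , k]
    if (max(abs(S - t(S))) > 1e-9 || any(eigen(S, symmetric = TRUE,
                                               only.values = TRUE)$values <= 0))
      stop("covs_true[,,", k, "] is not symmetric positive definite", call. = FALSE)
  }
  if (cfg$n < 1) stop("n must be >= 1", call. = FALSE)
  if (cfg$anomaly_rate < 0 || cfg$anomaly_rate >= 1)
    stop("anomaly_rate must lie in [0, 1)", call. = FALSE)
  if (length(cfg$opening_hours) != 2 || diff(cfg$opening_hours) <= 0)
    stop("opening_hours must be an increasing pair of clock hours", call. = FALSE)
  cfg
}

#' The "happyhere-like" default generator configuration
#'
#' Emulates the statistical structure reported for the HappyHere gallery
#' dataset: a 3-state chain with the published transition matrix, the
#' published per-state emission means (a low/negative profile near 1.5, a
#' moderately positive profile near 3.0-3.6, and a ceiling state at 5.0 on
#' all items), diagonal emission noise, invalid codes at a 0.1% rate, and
#' timestamps in gallery hours 10:00-17:00 over 60 days. The initial
#' distribution is the chain's stationary vector.
#'
#' The ceiling state's standard deviation defaults to 0.1 so that, after
#' round-and-clip discretization, it produces near-constant 5s.
#'
#' @param n Number of records (default 6559, the deposited sample size).
#' @param seed Master seed.
#' @param anomaly_rate Invalid-code rate (default 0.001).
#' @param discretize Round-and-clip to the Likert grid (default `TRUE`).
#' @param sds Per-state emission standard deviations (length K), applied on
#'   the diagonal of each covariance.
#' @return A `synthetic_config`.
#' @export
happyhere_config <- function(n = 6559, seed = 1, anomaly_rate = 0.001,
                             discretize = TRUE, sds = c(0.5, 0.5, 0.1)) {
  A <- happyhere_transition_matrix()
  mu <- happyhere_state_means()
  d <- ncol(mu)
  covs <- array(0, dim = c(d, d, 3))
  for (k in 1:3) covs[, , k] <- diag(sds[k]^2, d)
  synthetic_config(K = 3, A_true = A,
                   initial_true = stationary_distribution(A),
                   means_true = mu, covs_true = covs, n = n,
                   anomaly_rate = anomaly_rate, discretize = discretize,
                   opening_hours = c(10, 17), n_days = 60, seed = seed)
}

#' Published 3-state transition matrix of the HappyHere model
#'
#' Rows/columns are ordered moderate, negative, positive (the source's
#' state IDs 0, 1, 2).
#'
#' @return A 3 x 3 row-stochastic matrix.
#' @export
happyhere_transition_matrix <- function() {
  matrix(c(0.875, 0.067, 0.058,
           0.093, 0.451, 0.456,
           0.064, 0.131, 0.805),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("moderate", "negative", "positive"),
                         c("moderate", "negative", "positive")))
}

#' Published per-state emission means of the HappyHere model
#'
#' @return A 3 x 7 matrix (states moderate/negative/positive by the seven
#'   SWEMWBS items).
#' @export
happyhere_state_means <- function() {
  matrix(c(3.55, 3.24, 3.02, 3.19, 3.21, 3.60, 3.60,
           1.63, 1.48, 1.48, 1.48, 1.48, 1.48, 1.48,
           5.00, 5.00, 5.00, 5.00, 5.00, 5.00, 5.00),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("moderate", "negative", "positive"),
                         swemwbs_items))
}

#' Simulate a latent Markov state path
#'
#' @param A K x K row-stochastic transition matrix.
#' @param initial Length-K initial distribution.
#' @param T_len Path length (>= 1).
#' @param seed Optional seed; if supplied, the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @return Integer vector of length `T_len` with states in 1..K.
#' @export
simulate_state_path <- function(A, initial, T_len, seed = NULL) {
  assert_stochastic(A, "transition matrix")
  assert_prob_vector(initial, "initial distribution")
  if (T_len < 1) stop("T_len must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  K <- nrow(A)
  path <- integer(T_len)
  u <- runif(T_len)
  cum_init <- cumsum(initial)
  cum_A <- t(apply(A, 1, cumsum))
  path[1] <- findInterval(u[1], cum_init, left.open = TRUE) + 1L
  for (t in seq_len(T_len - 1L)) {
    path[t + 1L] <- findInterval(u[t + 1L], cum_A[path[t], ], left.open = TRUE) + 1L
  }
  pmin(path, K)
}

#' Generate a synthetic submission table with ground truth
#'
#' Draws a latent state path, state-conditional Gaussian emissions
#' (optionally discretized to the Likert grid by round-and-clip), overwrites
#' one item of randomly chosen records with an invalid code (0 or -1) at the
#' configured rate, and attaches increasing timestamps confined to the daily
#' opening window. The truth record (state path, anomaly positions) supports
#' parameter-recovery and bookkeeping tests downstream.
#'
#' @param config A [synthetic_config()].
#' @return A list with `table` (a `submission_table`) and `truth` (a list
#'   with `states`, `anomaly_rows`, `anomaly_items`).
#' @export
generate_dataset <- function(config) {
  cfg <- validate_synthetic_config(config)
  n <- cfg$n
  d <- ncol(cfg$means_true)
  ss <- sub_seeds(cfg$seed, 4)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))

  # latent path
  states <- simulate_state_path(cfg$A_true, cfg$initial_true, n, seed = ss[1])

  # emissions
  set.seed(ss[2])
  X <- matrix(0, n, d)
  Z <- matrix(rnorm(n * d), n, d)
  for (k in seq_len(cfg$K)) {
    idx <- which(states == k)
    if (length(idx) == 0) next
    L <- chol(cfg$covs_true[, , k])
    X[idx, ] <- Z[idx, , drop = FALSE] %*% L +
      matrix(cfg$means_true[k, ], length(idx), d, byrow = TRUE)
  }
  if (cfg$discretize) X <- pmin(pmax(round(X), 1), 5)

  # anomaly injection: one invalid code per selected record
  set.seed(ss[3])
  hit <- which(rbinom(n, 1, cfg$anomaly_rate) == 1)
  items <- integer(0)
  if (length(hit) > 0) {
    items <- sample.int(d, length(hit), replace = TRUE)
    codes <- sample(c(0, -1), length(hit), replace = TRUE)
    X[cbind(hit, items)] <- codes
  }

  # timestamps in opening hours, sorted; minute resolution
  set.seed(ss[4])
  day <- sample.int(cfg$n_days, n, replace = TRUE) - 1L
  minute <- floor(runif(n, cfg$opening_hours[1] * 60, cfg$opening_hours[2] * 60))
  ts <- as.POSIXct(cfg$start_date, tz = "UTC") + day * 86400 + minute * 60
  ts <- sort(ts)

  tab <- data.frame(timestamp = ts)
  for (j in seq_len(d)) tab[[swemwbs_items[j]]] <- X[, j]
  class(tab) <- c("submission_table", "data.frame")

  list(table = tab,
       truth = list(states = states, anomaly_rows = hit, anomaly_items = items))
}
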