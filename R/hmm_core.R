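#' Construct and validate Gaussian-HMM parameters
#'
#' @param initial Length-K initial state distribution.
#' @param transition K x K row-stochastic transition matrix.
#' @param means K x d matrix of emission means.
#' @param covariances d x d x K array (or list of K matrices) of symmetric
#'   positive-definite emission covariances.
#' @param covariance_type `"full"` or `"diagonal"` (bookkeeping for BIC).
#' @return An `hmm_params` object.
#' @export
hmm_params <- function(initial, transition, means, covariances,
                       covariance_type = c("full", "diagonal")) {
  covariance_type <- match.arg(covariance_type)
  if (is.list(covariances)) {
    d <- nrow(covariances[[1]])
    a <- array(0, dim = c(d, d, length(covariances)))
    for (k in seq_along(covariances)) a[, , k] <- covariances[[k]]
    covariances <- a
  }
  if (is.vector(means)) means <- matrix(means, nrow = length(initial))
  p <- structure(list(K = length(initial), d = ncol(means),
                      initial = initial, transition = transition,
                      means = means, covariances = covariances,
                      covariance_type = covariance_type),
                 class = "hmm_params")
  validate_hmm_params(p)
}

validate_hmm_params <- function(p) {
  assert_prob_vector(p$initial, "initial distribution")
  assert_stochastic(p$transition, "transition matrix")
  if (nrow(p$transition) != p$K)
    stop("transition matrix size disagrees with K", call. = FALSE)
  if (nrow(p$means) != p$K)
    stop("means must have one row per state", call. = FALSE)
  if (!all(dim(p$covariances) == c(p$d, p$d, p$K)))
    stop("covariances must be a d x d x K array", call. = FALSE)
  for (k in seq_len(p$K)) {
    S <- p$covariances[, , k]
    if (max(abs(S - t(S))) > 1e-8)
      stop("covariance for state ", k, " is not symmetric", call. = FALSE)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0))
      stop("covariance for state ", k, " is not positive definite", call. = FALSE)
  }
  p
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("Gaussian HMM parameters: K = %d states, d = %d features (%s covariance)\n",
              x$K, x$d, x$covariance_type))
  cat("initial:", format(round(x$initial, 3)), "\n")
  cat("transition:\n"); print(round(x$transition, 3))
  cat("emission means:\n"); print(round(x$means, 3))
  invisible(x)
}

#' Multivariate Gaussian log-density
#'
#' Computes log N(x; mu, sigma) through a Cholesky (triangular)
#' factorization; no explicit matrix inverse is formed.
#'
#' @param x Numeric d-vector (or T x d matrix: one density per row).
#' @param mean Numeric d-vector.
#' @param sigma d x d symmetric positive-definite matrix.
#' @return Log density in nats (vector of length T for matrix input).
#' @export
gaussian_log_density <- function(x, mean, sigma) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  d <- ncol(x)
  L <- tryCatch(chol(sigma),
                error = function(e) stop("covariance is not positive definite",
                                         call. = FALSE))
  xc <- sweep(x, 2, mean)
  # solve t(L) %*% z = t(xc): quadratic form via triangular solve
  z <- backsolve(L, t(xc), transpose = TRUE)
  quad <- colSums(z^2)
  logdet <- 2 * sum(log(diag(L)))
  as.numeric(-0.5 * (d * log(2 * pi) + logdet + quad))
}

# T x K matrix of per-state log emission densities.
log_density_matrix <- function(X, params) {
  T_len <- nrow(X)
  out <- matrix(0, T_len, params$K)
  for (k in seq_len(params$K)) {
    out[, k] <- tryCatch(
      gaussian_log_density(X, params$means[k, ], params$covariances[, , k]),
      error = function(e) stop("state ", k, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  out
}

obs_matrix <- function(seq) {
  if (inherits(seq, "observation_sequence")) seq$values else as.matrix(seq)
}

#' Forward-backward posteriors
#'
#' Exact smoothed marginals under the model, computed with a scaled
#' forward-backward recursion that is stable for sequences of 10^4+
#' observations and extreme log-densities.
#'
#' @param seq An [observation_sequence()] or numeric T x d matrix.
#' @param params An [hmm_params()] object.
#' @return A list with `log_likelihood` (nats), `gamma` (T x K posterior
#'   state marginals, rows sum to 1) and `xi` ((T-1) x K x K pairwise
#'   posteriors, each time slice sums to 1).
#' @export
forward_backward <- function(seq, params) {
  X <- obs_matrix(seq)
  params <- validate_hmm_params(params)
  if (ncol(X) != params$d)
    stop("observation dimension (", ncol(X), ") disagrees with model d (",
         params$d, ")", call. = FALSE)
  logB <- log_density_matrix(X, params)
  res <- .fb_core(logB, params$transition, params$initial)
  dim(res$xi) <- c(max(nrow(X) - 1L, 0L), params$K, params$K)
  res
}

#' Viterbi decoding
#'
#' Most probable joint state path under the model, by the log-space Viterbi
#' recursion; ties are broken toward the lower state index.
#'
#' @inheritParams forward_backward
#' @return A list with `path` (integer vector, states 1..K) and `log_prob`
#'   (joint log probability of the path and data).
#' @export
viterbi_decode <- function(seq, params) {
  X <- obs_matrix(seq)
  params <- validate_hmm_params(params)
  if (ncol(X) != params$d)
    stop("observation dimension disagrees with model", call. = FALSE)
  logB <- log_density_matrix(X, params)
  .viterbi_core(logB, log(params$transition), log(params$initial))
}

#' Estimation controls for Baum-Welch
#'
#' @param n_restarts Independent EM initializations; the highest final
#'   log-likelihood wins.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param cov_ridge Ridge added to each covariance diagonal every M-step.
#' @param covariance_type `"full"` or `"diagonal"`.
#' @param init_method `"quantile"` partitions observations into K quantile
#'   groups of the per-record grand mean (a valence-ordered start), with
#'   per-restart seeded perturbation; `"random_responsibility"` draws random
#'   soft assignments.
#' @param seed Base seed; restart r uses `seed + r`.
#' @return A `fit_config` list.
#' @export
fit_config <- function(n_restarts = 10, max_iter = 500, tol = 1e-6,
                       cov_ridge = 1e-6,
                       covariance_type = c("full", "diagonal"),
                       init_method = c("quantile", "random_responsibility"),
                       seed = 1) {
  stopifnot(n_restarts >= 1, max_iter >= 1, tol > 0, cov_ridge >= 0)
  structure(list(n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 cov_ridge = cov_ridge,
                 covariance_type = match.arg(covariance_type),
                 init_method = match.arg(init_method),
                 seed = as.integer(seed)),
            class = "fit_config")
}

# M-step from posteriors; returns hmm_params or NULL when a state collapses
# below the effective-sample floor.
m_step <- function(X, gamma, xi, config) {
  K <- ncol(gamma); d <- ncol(X)
  Nk <- colSums(gamma)
  floor_k <- if (config$covariance_type == "full") d + 1 else 2
  if (any(Nk < floor_k)) return(NULL)

  means <- t(gamma) %*% X / Nk
  covs <- array(0, dim = c(d, d, K))
  for (k in seq_len(K)) {
    Xc <- sweep(X, 2, means[k, ])
    S <- crossprod(Xc * gamma[, k], Xc) / Nk[k]
    if (config$covariance_type == "diagonal") S <- diag(diag(S), d)
    covs[, , k] <- S + diag(config$cov_ridge, d)
  }
  xs <- apply(xi, c(2, 3), sum)
  A <- xs / rowSums(xs)
  init <- gamma[1, ]
  # guard against tiny negative rounding before validation
  init <- pmax(init, 0); init <- init / sum(init)
  A <- pmax(A, 0); A <- A / rowSums(A)
  hmm_params(init, A, means, covs, covariance_type = config$covariance_type)
}

initialize_params <- function(X, K, config, restart) {
  T_len <- nrow(X); d <- ncol(X)
  set.seed(config$seed + restart)
  if (config$init_method == "quantile" && K > 1) {
    g <- rowMeans(X)
    z <- ceiling(rank(g, ties.method = "first") * K / T_len)
    gamma <- matrix(0, T_len, K)
    gamma[cbind(seq_len(T_len), z)] <- 1
    gamma <- gamma + matrix(abs(rnorm(T_len * K, sd = 0.25)), T_len, K)
    gamma <- gamma / rowSums(gamma)
    # transition start from the hard quantile labels, +1 smoothing
    counts <- matrix(1, K, K)
    for (t in seq_len(T_len - 1)) counts[z[t], z[t + 1]] <- counts[z[t], z[t + 1]] + 1
  } else {
    gamma <- matrix(rexp(T_len * K), T_len, K)
    gamma <- gamma / rowSums(gamma)
    counts <- matrix(rexp(K * K) + 1, K, K)
  }
  Nk <- colSums(gamma)
  means <- t(gamma) %*% X / Nk
  covs <- array(0, dim = c(d, d, K))
  for (k in seq_len(K)) {
    Xc <- sweep(X, 2, means[k, ])
    S <- crossprod(Xc * gamma[, k], Xc) / Nk[k]
    if (config$covariance_type == "diagonal") S <- diag(diag(S), d)
    covs[, , k] <- S + diag(max(config$cov_ridge, 1e-6), d)
  }
  A <- counts / rowSums(counts)
  init <- rep(1 / K, K)
  hmm_params(init, A, means, covs, covariance_type = config$covariance_type)
}

#' Fit a Gaussian HMM by Baum-Welch EM
#'
#' Runs `n_restarts` independent seeded initializations of
#' expectation-maximization and keeps the restart with the highest final
#' log-likelihood. Within each run the log-likelihood trace is
#' nondecreasing (the EM guarantee); convergence is declared when the
#' relative change falls below `tol`. Every M-step adds `cov_ridge` to each
#' covariance diagonal.
#'
#' @param seq An [observation_sequence()] or numeric T x d matrix.
#' @param K Number of latent states (T > K required).
#' @param config A [fit_config()].
#' @return An `hmm_fit` object: `params`, `log_likelihood`, `loglik_trace`,
#'   `n_iter`, `converged`, `bic`, `gamma`, `xi`, `decoded_path`,
#'   `restarts_tried`, `seed`.
#' @export
baum_welch_fit <- function(seq, K, config = fit_config()) {
  X <- obs_matrix(seq)
  T_len <- nrow(X)
  if (T_len <= K) stop("need more observations than states (T > K)", call. = FALSE)

  old <- get_rng_state()
  on.exit(restore_rng_state(old))

  best <- NULL
  n_degenerate <- 0
  for (r in seq_len(config$n_restarts)) {
    params <- initialize_params(X, K, config, r)
    trace <- numeric(0)
    converged <- FALSE
    degenerate <- FALSE
    post <- NULL
    ll_prev <- NA_real_
    iter <- 0
    repeat {
      iter <- iter + 1
      post <- forward_backward(X, params)
      ll <- post$log_likelihood
      trace <- c(trace, ll)
      if (!is.na(ll_prev) && abs(ll - ll_prev) < config$tol * abs(ll_prev)) {
        converged <- TRUE
        break
      }
      if (iter >= config$max_iter) break
      new_params <- m_step(X, post$gamma, post$xi, config)
      if (is.null(new_params)) { degenerate <- TRUE; break }
      params <- new_params
      ll_prev <- ll
    }
    if (degenerate) { n_degenerate <- n_degenerate + 1; next }
    if (is.null(best) || trace[length(trace)] > best$log_likelihood) {
      best <- list(params = params, log_likelihood = trace[length(trace)],
                   loglik_trace = trace, n_iter = iter, converged = converged,
                   gamma = post$gamma, xi = post$xi)
    }
  }
  if (is.null(best))
    stop("all ", config$n_restarts, " restarts degenerated (a state captured ",
         "too few effective observations); try covariance_type = 'diagonal' ",
         "or a larger cov_ridge", call. = FALSE)

  best$bic <- compute_bic(best$log_likelihood, K, ncol(X), T_len,
                          config$covariance_type)
  best$decoded_path <- viterbi_decode(X, best$params)$path
  best$restarts_tried <- config$n_restarts
  best$n_degenerate <- n_degenerate
  best$seed <- config$seed
  class(best) <- "hmm_fit"
  best
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("Gaussian HMM fit: K = %d, logLik = %.3f, BIC = %.3f\n",
              x$params$K, x$log_likelihood, x$bic))
  cat(sprintf("  %d iterations, converged = %s, %d restart(s)\n",
              x$n_iter, x$converged, x$restarts_tried))
  invisible(x)
}

#' Bayesian Information Criterion for a Gaussian HMM
#'
#' BIC = -2 logL + p ln T, with free-parameter count
#' p = (K-1) + K(K-1) + K d + K d(d+1)/2 for full covariances
#' (K d covariance terms when diagonal). Lower is better.
#'
#' @param log_likelihood Maximized log-likelihood (nats).
#' @param K Number of states.
#' @param d Feature dimension.
#' @param T_len Number of observations.
#' @param covariance_type `"full"` or `"diagonal"`.
#' @return The BIC value.
#' @export
compute_bic <- function(log_likelihood, K, d, T_len,
                        covariance_type = c("full", "diagonal")) {
  covariance_type <- match.arg(covariance_type)
  p_cov <- if (covariance_type == "full") K * d * (d + 1) / 2 else K * d
  p <- (K - 1) + K * (K - 1) + K * d + p_cov
  -2 * log_likelihood + p * log(T_len)
}

#' Select the number of hidden states by BIC
#'
#' Fits every K in `K_range` with identical estimation budgets and returns
#' the fit minimizing BIC together with the full BIC-vs-K table. A K whose
#' fit fails is recorded as failed and skipped.
#'
#' @param seq An [observation_sequence()] or numeric matrix.
#' @param K_range Integer vector of candidate state counts.
#' @param config A [fit_config()] (shared across candidates).
#' @return A list with `best_fit` (an `hmm_fit`), `best_K`, and `bic_table`
#'   (data.frame: K, log_likelihood, n_params, bic, converged, failed).
#' @export
select_n_states <- function(seq, K_range, config = fit_config()) {
  stopifnot(length(K_range) >= 1)
  X <- obs_matrix(seq)
  if (max(K_range) >= nrow(X)) stop("max(K_range) must be < T", call. = FALSE)

  fits <- vector("list", length(K_range))
  tab <- data.frame(K = as.integer(K_range), log_likelihood = NA_real_,
                    n_params = NA_real_, bic = NA_real_,
                    converged = NA, failed = FALSE)
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    fit <- tryCatch(baum_welch_fit(X, K, config), error = function(e) e)
    if (inherits(fit, "error")) {
      tab$failed[i] <- TRUE
      next
    }
    fits[[i]] <- fit
    d <- ncol(X)
    p_cov <- if (config$covariance_type == "full") K * d * (d + 1) / 2 else K * d
    tab$n_params[i] <- (K - 1) + K * (K - 1) + K * d + p_cov
    tab$log_likelihood[i] <- fit$log_likelihood
    tab$bic[i] <- fit$bic
    tab$converged[i] <- fit$converged
  }
  if (all(tab$failed)) stop("every candidate K failed to fit", call. = FALSE)
  best_i <- which.min(ifelse(tab$failed, Inf, tab$bic))
  list(best_fit = fits[[best_i]], best_K = tab$K[best_i], bic_table = tab)
}
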