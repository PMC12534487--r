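#' Label states by valence
#'
#' Orders states by the grand mean of their emission means (ascending) and
#' assigns valence names. With K = 3 the names are
#' negative / neutral_moderate / positive; for other K, rank labels
#' state_1..state_K in ascending valence (to avoid over-interpreting
#' valence); K = 1 gets the single trivial label. Ties in the grand mean
#' are broken by state index.
#'
#' @param params An [hmm_params()] object (or anything with a `means` matrix).
#' @return A `state_labeling`: list with `order` (state indices by ascending
#'   grand mean) and `labels` (character vector indexed by state).
#' @export
label_states <- function(params) {
  means <- if (is.matrix(params)) params else params$means
  K <- nrow(means)
  grand <- rowMeans(means)
  ord <- order(grand, seq_len(K))  # ties broken by state index
  labels <- character(K)
  if (K == 1) {
    labels[1] <- "single_state"
  } else if (K == 3) {
    labels[ord] <- c("negative", "neutral_moderate", "positive")
  } else {
    labels[ord] <- paste0("state_", seq_len(K))
  }
  structure(list(order = ord, labels = labels, grand_means = grand),
            class = "state_labeling")
}

#' @export
print.state_labeling <- function(x, ...) {
  for (k in seq_along(x$labels))
    cat(sprintf("state %d -> %s (grand mean %.3f)\n", k, x$labels[k],
                x$grand_means[k]))
  invisible(x)
}

# Closed communicating classes of the chain's support graph; used to detect
# chains without a unique stationary distribution.
closed_classes <- function(A) {
  K <- nrow(A)
  reach <- (A > 0) | diag(TRUE, K)
  for (m in seq_len(ceiling(log2(K)) + 1))
    reach <- (reach %*% reach) > 0
  classes <- list()
  seen <- rep(FALSE, K)
  for (i in seq_len(K)) {
    if (seen[i]) next
    cls <- which(reach[i, ] & reach[, i])
    seen[cls] <- TRUE
    # closed iff no member reaches outside the class
    if (all(!reach[cls, -cls, drop = FALSE]) || length(cls) == K)
      classes[[length(classes) + 1]] <- cls
  }
  classes
}

#' Stationary distribution of a Markov chain
#'
#' Solves pi A = pi as the normalized left eigenvector for eigenvalue 1.
#' The chain must have a unique stationary distribution (a single closed
#' communicating class); otherwise an error names the offending blocks
#' rather than returning a silent pseudo-answer. Periodic but irreducible
#' chains are fine (their stationary vector is still unique).
#'
#' @param A K x K row-stochastic matrix.
#' @return Length-K probability vector `pi_star` with `pi_star %*% A == pi_star`.
#' @export
stationary_distribution <- function(A) {
  assert_stochastic(A, "transition matrix")
  cls <- closed_classes(A)
  if (length(cls) > 1) {
    blocks <- vapply(cls, function(cl) paste0("{", paste(cl, collapse = ","), "}"),
                     character(1))
    stop("chain is reducible with multiple closed classes ",
         paste(blocks, collapse = " and "),
         "; the stationary distribution is not unique", call. = FALSE)
  }
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10))
    stop("failed to extract a nonnegative stationary vector", call. = FALSE)
  v <- pmax(v, 0)
  v <- v / sum(v)
  names(v) <- rownames(A)
  resid <- max(abs(as.vector(v %*% A) - v))
  if (resid > 1e-8)
    stop("stationary fixed-point residual too large: ", format(resid),
         call. = FALSE)
  v
}

#' Expected dwell times
#'
#' Geometric mean run length 1/(1 - a_kk) per state: the expected number of
#' consecutive steps spent in a state before leaving. An absorbing state
#' (a_kk = 1) is reported as `Inf`. When a decoded path is supplied, the
#' empirical mean run length per state is returned alongside; the two
#' estimators can differ and both are reported by the pipeline.
#'
#' @param A K x K row-stochastic matrix.
#' @param path Optional decoded integer state path.
#' @return A list with `geometric` (length K) and, when `path` is given,
#'   `empirical` (length K; NA for states absent from the path).
#' @export
expected_dwell_times <- function(A, path = NULL) {
  assert_stochastic(A, "transition matrix")
  K <- nrow(A)
  geo <- ifelse(diag(A) >= 1, Inf, 1 / (1 - diag(A)))
  out <- list(geometric = geo)
  if (!is.null(path)) {
    r <- rle(path)
    emp <- rep(NA_real_, K)
    for (k in seq_len(K)) {
      runs <- r$lengths[r$values == k]
      if (length(runs) > 0) emp[k] <- mean(runs)
    }
    out$empirical <- emp
  }
  out
}

#' Shannon transition entropy per state
#'
#' H_k = -sum_j a_kj log a_kj with 0 log 0 := 0. Base e (nats) by default;
#' `"2"` gives bits; `"normalized"` divides the natural-log entropy by
#' log K, mapping to \[0, 1\].
#'
#' @param A K x K row-stochastic matrix.
#' @param base `"e"`, `"2"` or `"normalized"`.
#' @return Length-K vector of row entropies.
#' @export
transition_entropy <- function(A, base = c("e", "2", "normalized")) {
  base <- match.arg(base)
  assert_stochastic(A, "transition matrix")
  H <- apply(A, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  switch(base,
         e = H,
         "2" = H / log(2),
         normalized = if (nrow(A) == 1) H * 0 else H / log(nrow(A)))
}

#' Empirical transition matrix of a decoded path
#'
#' Row-normalized transition counts, with optional Laplace smoothing
#' `alpha` added to every cell. With `alpha = 0`, a state never visited in
#' `path[-T]` yields an NA row.
#'
#' @param path Integer state path (states in 1..K).
#' @param K Number of states (default `max(path)`).
#' @param alpha Laplace smoothing count (default 0).
#' @return K x K matrix.
#' @export
empirical_transition_matrix <- function(path, K = max(path), alpha = 0) {
  stopifnot(length(path) >= 2)
  code <- (path[-length(path)] - 1L) * K + path[-1L]
  counts <- matrix(tabulate(code, nbins = K * K), K, K, byrow = TRUE) + alpha
  rs <- rowSums(counts)
  A <- counts / rs
  A[rs == 0, ] <- NA_real_
  A
}

#' Bootstrap confidence intervals for transition statistics
#'
#' Resamples the T-1 consecutive decoded transition pairs with replacement
#' (the default, fast scheme), recomputes the empirical transition matrix
#' and the derived dwell times and row entropies per replicate, and returns
#' 2.5%/97.5% percentile bounds. Reproducible given `seed`. States absent
#' from the path get NA statistics with a warning, never fabricated values.
#'
#' @param path Decoded integer state path (length >= 2).
#' @param B Bootstrap iterations (default 1000).
#' @param seed Seed for the resampling stream.
#' @param K Number of states (default `max(path)`).
#' @param alpha Laplace smoothing for per-replicate transition matrices
#'   (default 0).
#' @param entropy_base Passed to [transition_entropy()].
#' @return A `transition_bootstrap` object: point estimates (`transition`,
#'   `dwell`, `entropy`), percentile bounds (`*_lower`, `*_upper`), `B`,
#'   `seed`, and `undefined_states`.
#' @export
bootstrap_transition_stats <- function(path, B = 1000, seed = 1,
                                       K = max(path), alpha = 0,
                                       entropy_base = "e") {
  stopifnot(length(path) >= 2, B >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  n_pairs <- length(path) - 1L
  code <- (path[-length(path)] - 1L) * K + path[-1L]
  absent <- setdiff(seq_len(K), unique(path))
  if (length(absent) > 0)
    warning("state(s) ", paste(absent, collapse = ", "),
            " absent from the decoded path; their statistics are undefined",
            call. = FALSE)

  point_A <- empirical_transition_matrix(path, K = K, alpha = alpha)
  point_d <- ifelse(is.na(diag(point_A)) | diag(point_A) >= 1,
                    ifelse(diag(point_A) >= 1, Inf, NA_real_),
                    1 / (1 - diag(point_A)))
  row_entropy <- function(A) {
    apply(A, 1, function(p) {
      if (anyNA(p)) return(NA_real_)
      p <- p[p > 0]
      H <- -sum(p * log(p))
      switch(entropy_base, e = H, "2" = H / log(2),
             normalized = if (K == 1) 0 else H / log(K))
    })
  }
  point_H <- row_entropy(point_A)

  A_reps <- array(NA_real_, dim = c(B, K, K))
  d_reps <- matrix(NA_real_, B, K)
  H_reps <- matrix(NA_real_, B, K)
  for (b in seq_len(B)) {
    cb <- code[sample.int(n_pairs, n_pairs, replace = TRUE)]
    counts <- matrix(tabulate(cb, nbins = K * K), K, K, byrow = TRUE) + alpha
    rs <- rowSums(counts)
    Ab <- counts / rs
    Ab[rs == 0, ] <- NA_real_
    A_reps[b, , ] <- Ab
    db <- diag(Ab)
    d_reps[b, ] <- ifelse(is.na(db), NA_real_, ifelse(db >= 1, Inf, 1 / (1 - db)))
    H_reps[b, ] <- row_entropy(Ab)
  }

  qlo <- function(x) if (all(is.na(x))) NA_real_ else quantile(x, 0.025, na.rm = TRUE, names = FALSE)
  qhi <- function(x) if (all(is.na(x))) NA_real_ else quantile(x, 0.975, na.rm = TRUE, names = FALSE)

  structure(list(
    transition = point_A,
    transition_lower = apply(A_reps, c(2, 3), qlo),
    transition_upper = apply(A_reps, c(2, 3), qhi),
    dwell = point_d,
    dwell_lower = apply(d_reps, 2, qlo),
    dwell_upper = apply(d_reps, 2, qhi),
    entropy = point_H,
    entropy_lower = apply(H_reps, 2, qlo),
    entropy_upper = apply(H_reps, 2, qhi),
    B = as.integer(B), seed = as.integer(seed), alpha = alpha,
    entropy_base = entropy_base,
    undefined_states = absent
  ), class = "transition_bootstrap")
}

#' @export
print.transition_bootstrap <- function(x, ...) {
  K <- nrow(x$transition)
  cat(sprintf("transition bootstrap: B = %d, seed = %d\n", x$B, x$seed))
  for (k in seq_len(K))
    cat(sprintf("  self-transition %d: %.3f [%.3f, %.3f]\n", k,
                x$transition[k, k], x$transition_lower[k, k],
                x$transition_upper[k, k]))
  invisible(x)
}

#' Summarise transition dynamics of a fitted model
#'
#' Bundles the stationary distribution, geometric and empirical dwell
#' times, row entropies, and (optionally) bootstrap percentile intervals
#' computed from the decoded path.
#'
#' @param params An [hmm_params()] object.
#' @param path Optional decoded state path (enables empirical dwell times
#'   and the bootstrap).
#' @param B Bootstrap iterations; 0 disables the bootstrap.
#' @param seed Bootstrap seed.
#' @param entropy_base Passed to [transition_entropy()].
#' @return A `dynamics_summary` list.
#' @export
dynamics_summary <- function(params, path = NULL, B = 1000, seed = 1,
                             entropy_base = "e") {
  A <- params$transition
  out <- list(
    stationary = tryCatch(stationary_distribution(A), error = function(e) {
      warning(conditionMessage(e), call. = FALSE); NULL
    }),
    dwell = expected_dwell_times(A, path = path),
    entropy = transition_entropy(A, base = entropy_base),
    entropy_base = entropy_base
  )
  if (!is.null(path) && B > 0)
    out$bootstrap <- bootstrap_transition_stats(path, B = B, seed = seed,
                                                K = params$K,
                                                entropy_base = entropy_base)
  structure(out, class = "dynamics_summary")
}
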