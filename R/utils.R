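#' @useDynLib affecthmm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cov pchisq prcomp quantile rbinom rexp rnorm runif sd
#' @importFrom utils read.csv write.csv
NULL

#' The seven SWEMWBS item names
#'
#' Canonical item order used throughout: optimism, usefulness, relaxation,
#' dealing with problems, thinking clearly, feeling close to other people,
#' and making up one's own mind. Each is rated 1-5.
#'
#' @export
swemwbs_items <- c("optimistic", "useful", "relaxed", "problems",
                   "clearly", "close_people", "own_mind")

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob_vector <- function(p, what = "probability vector", tol = 1e-9) {
  if (!is.numeric(p) || anyNA(p) || any(p < -tol))
    stop(what, " must be nonnegative", call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop(what, " must sum to 1 (got ", format(sum(p)), ")", call. = FALSE)
  invisible(p)
}

assert_stochastic <- function(A, what = "transition matrix", tol = 1e-9) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop(what, " must be a square matrix", call. = FALSE)
  if (anyNA(A) || any(A < -tol))
    stop(what, " must be nonnegative", call. = FALSE)
  if (any(abs(rowSums(A) - 1) > tol))
    stop(what, " rows must sum to 1", call. = FALSE)
  invisible(A)
}

# Deterministically split one master seed into n independent sub-seeds, so
# downstream draws (state path, emissions, anomalies, timestamps) do not
# perturb one another when one component's settings change.
sub_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# All K! permutations of 1:K (K is small here; used for state alignment).
all_permutations <- function(K) {
  if (K == 1) return(list(1L))
  out <- list()
  for (i in seq_len(K)) {
    for (p in all_permutations(K - 1L)) {
      rest <- seq_len(K)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Align estimated states to reference states
#'
#' Finds the permutation of estimated state indices that minimises the total
#' absolute difference between estimated and reference emission-mean rows.
#' Used to resolve label switching before comparing a fitted model with the
#' generating truth.
#'
#' @param est_means K x d matrix of estimated emission means.
#' @param ref_means K x d matrix of reference emission means.
#' @return Integer permutation `perm` such that estimated state `perm[k]`
#'   corresponds to reference state `k`.
#' @export
match_states <- function(est_means, ref_means) {
  stopifnot(is.matrix(est_means), is.matrix(ref_means),
            all(dim(est_means) == dim(ref_means)))
  K <- nrow(ref_means)
  best <- NULL
  best_cost <- Inf
  for (p in all_permutations(K)) {
    cost <- sum(abs(est_means[p, , drop = FALSE] - ref_means))
    if (cost < best_cost) {
      best_cost <- cost
      best <- p
    }
  }
  as.integer(best)
}
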