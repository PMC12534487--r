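#' Cross-tabulate valence labels by time bin
#'
#' Builds the morning/afternoon x valence contingency table over decoded,
#' labeled records. Rows are fixed as (morning, afternoon); records in the
#' `excluded` bin are dropped. Column order follows ascending valence:
#' negative, neutral_moderate, positive for the 3-state labeling, otherwise
#' the labeling's own ascending order.
#'
#' @param labels Character/factor vector of per-record valence labels.
#' @param bins Factor from [assign_time_bins()], aligned with `labels`.
#' @param label_levels Optional explicit column order.
#' @return Integer matrix of counts (2 x L).
#' @export
contingency_table <- function(labels, bins,
                              label_levels = NULL) {
  stopifnot(length(labels) == length(bins))
  keep <- bins %in% c("morning", "afternoon")
  if (!any(keep)) stop("no records fall in the morning/afternoon bins", call. = FALSE)
  labels <- as.character(labels)[keep]
  bins <- factor(as.character(bins)[keep], levels = c("morning", "afternoon"))
  if (is.null(label_levels)) {
    canonical <- c("negative", "neutral_moderate", "positive")
    label_levels <- if (all(labels %in% canonical)) canonical else sort(unique(labels))
  }
  labels <- factor(labels, levels = label_levels)
  counts <- table(bins, labels)
  m <- matrix(as.integer(counts), nrow = 2,
              dimnames = list(rownames(counts), colnames(counts)))
  m
}

#' Pearson chi-square test of independence
#'
#' chi^2 = sum (O - E)^2 / E with expected counts from the row/column
#' marginals; df = (r-1)(c-1); p from the upper tail of the chi-square
#' distribution. No continuity correction. An expected cell below 5 raises
#' a warning (not an error).
#'
#' @param counts r x c matrix of nonnegative counts with positive marginals.
#' @return A list with `chi_square`, `df`, `p_value`, `expected`, `N`.
#' @export
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("all row and column marginals must be positive", call. = FALSE)
  N <- sum(counts)
  E <- outer(rs, cs) / N
  if (any(E < 5))
    warning("some expected cell counts are below 5; the chi-square ",
            "approximation may be inaccurate", call. = FALSE)
  chi2 <- sum((counts - E)^2 / E)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(chi_square = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       expected = E, N = N)
}

#' Cramer's V effect size
#'
#' V = sqrt(chi^2 / (N (min(r, c) - 1))), in \[0, 1\]. The verdict follows
#' the conventional 0.1 / 0.3 / 0.5 thresholds (below 0.1 is reported as
#' negligible).
#'
#' @param chi_square Chi-square statistic.
#' @param N Total count.
#' @param r,c Table dimensions.
#' @return A list with `v` and `verdict`.
#' @export
cramers_v <- function(chi_square, N, r, c) {
  stopifnot(N > 0, min(r, c) >= 2)
  v <- sqrt(chi_square / (N * (min(r, c) - 1)))
  verdict <- if (v < 0.1) "negligible" else if (v < 0.3) "slight" else
    if (v < 0.5) "moderate" else "large"
  list(v = v, verdict = verdict)
}

#' Full temporal contingency analysis
#'
#' @inheritParams contingency_table
#' @return A `contingency_result`: counts, chi_square, df, p_value,
#'   cramers_v, verdict, N, expected counts, and any small-cell warning.
#' @export
temporal_contingency <- function(labels, bins, label_levels = NULL) {
  counts <- contingency_table(labels, bins, label_levels)
  small_cell <- FALSE
  test <- withCallingHandlers(
    pearson_chi_square(counts),
    warning = function(w) {
      small_cell <<- TRUE
      invokeRestart("muffleWarning")
    })
  v <- cramers_v(test$chi_square, test$N, nrow(counts), ncol(counts))
  structure(list(counts = counts, chi_square = test$chi_square, df = test$df,
                 p_value = test$p_value, cramers_v = v$v, verdict = v$verdict,
                 N = test$N, expected = test$expected,
                 small_expected_cells = small_cell),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$counts)
  cat(sprintf("chi-square(%d, N = %d) = %.3f, p = %.4f; Cramer's V = %.3f (%s)\n",
              x$df, x$N, x$chi_square, x$p_value, x$cramers_v, x$verdict))
  invisible(x)
}

#' Per-item descriptive statistics
#'
#' Mean, sample (n-1) standard deviation, minimum, quartiles (linear
#' interpolation between order statistics) and maximum for each item; when
#' decoded states are supplied, per-state per-item means as well.
#'
#' @param seq An [observation_sequence()] or numeric matrix.
#' @param states Optional integer decoded state per record.
#' @return A `descriptive_table`: data.frame `overall` (one row per item)
#'   and, when `states` is given, matrix `by_state` (state x item means).
#' @export
descriptive_stats <- function(seq, states = NULL) {
  X <- obs_matrix(seq)
  if (nrow(X) == 0) stop("empty observation sequence", call. = FALSE)
  items <- colnames(X) %||% paste0("item_", seq_len(ncol(X)))
  overall <- data.frame(
    item = items,
    mean = unname(colMeans(X)),
    std = unname(apply(X, 2, stats::sd)),
    min = unname(apply(X, 2, min)),
    q25 = unname(apply(X, 2, quantile, probs = 0.25, type = 7, names = FALSE)),
    q50 = unname(apply(X, 2, quantile, probs = 0.50, type = 7, names = FALSE)),
    q75 = unname(apply(X, 2, quantile, probs = 0.75, type = 7, names = FALSE)),
    max = unname(apply(X, 2, max)),
    row.names = NULL
  )
  out <- list(overall = overall)
  if (!is.null(states)) {
    stopifnot(length(states) == nrow(X))
    ks <- sort(unique(states))
    by_state <- t(vapply(ks, function(k) colMeans(X[states == k, , drop = FALSE]),
                         numeric(ncol(X))))
    dimnames(by_state) <- list(paste0("state_", ks), items)
    out$by_state <- by_state
  }
  structure(out, class = "descriptive_table")
}

#' Reconstruct the published morning/afternoon contingency table
#'
#' Rebuilds the 2 x 3 table from the published bin sizes (morning 1,042;
#' afternoon 5,517) and the published positive/neutral shares (morning
#' 78.8% positive, 13.8% neutral; afternoon 74.6% positive, 16.7% neutral),
#' using nearest-integer rounding per cell with the remainder assigned to
#' the negative column (only two of the three shares per bin were
#' published).
#'
#' @return 2 x 3 integer matrix (rows morning/afternoon; columns
#'   negative/neutral_moderate/positive).
#' @export
happyhere_contingency_table <- function() {
  n_bin <- c(morning = 1042, afternoon = 5517)
  pos <- round(n_bin * c(0.788, 0.746))
  neu <- round(n_bin * c(0.138, 0.167))
  neg <- n_bin - pos - neu
  m <- cbind(negative = neg, neutral_moderate = neu, positive = pos)
  rownames(m) <- names(n_bin)
  storage.mode(m) <- "integer"
  m
}
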