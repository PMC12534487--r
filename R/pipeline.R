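#' PCA projection for state separability
#'
#' Principal components of the observation matrix. Columns are centered but
#' not rescaled (all items share the 1-5 scale); components are eigenvectors
#' of the sample covariance in descending eigenvalue order. Sign convention:
#' the largest-magnitude loading of each component is positive, making the
#' projection deterministic.
#'
#' @param seq An [observation_sequence()] or numeric T x d matrix.
#' @param n_components Number of components (<= d).
#' @param scale. If `TRUE`, use correlation-matrix PCA instead.
#' @return A list with `scores` (T x n_components), `loadings`
#'   (d x n_components), `explained_variance` (fractions, length
#'   n_components).
#' @export
pca_project <- function(seq, n_components = 2, scale. = FALSE) {
  X <- obs_matrix(seq)
  if (n_components > ncol(X))
    stop("n_components (", n_components, ") exceeds feature count (",
         ncol(X), ")", call. = FALSE)
  if (nrow(X) < 2) stop("PCA needs at least two observations", call. = FALSE)
  pr <- stats::prcomp(X, center = TRUE, scale. = scale.)
  ev <- pr$sdev^2
  frac <- ev / sum(ev)
  rot <- pr$rotation[, seq_len(n_components), drop = FALSE]
  sco <- pr$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  list(scores = sco, loadings = rot,
       explained_variance = frac[seq_len(n_components)])
}

#' Pipeline configuration
#'
#' Exactly one of `input` (a CSV path or `submission_table`) and
#' `synthetic` (a [synthetic_config()]) must be supplied.
#'
#' @param input CSV path or `submission_table`, or `NULL`.
#' @param synthetic A [synthetic_config()], or `NULL`.
#' @param features Item subset to model (default all seven).
#' @param K Fixed state count; or
#' @param K_range Candidate counts for BIC selection (exactly one of
#'   `K`/`K_range`).
#' @param fit A [fit_config()].
#' @param bootstrap_B Bootstrap iterations (values below 1000 are flagged
#'   `reduced_B` in the report).
#' @param entropy_base Entropy base for dynamics summaries.
#' @param column_map Passed to [read_submissions()] for CSV input.
#' @param output_dir Optional directory for the JSON report, CSV tables and
#'   figures.
#' @param figures Write PNG figures when an output directory is set.
#' @param seed Pipeline seed (bootstrap stream; fit uses `fit$seed`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            features = swemwbs_items,
                            K = NULL, K_range = NULL,
                            fit = fit_config(), bootstrap_B = 1000,
                            entropy_base = "e", column_map = NULL,
                            output_dir = NULL, figures = FALSE, seed = 1) {
  if (is.null(input) == is.null(synthetic))
    stop("exactly one of 'input' and 'synthetic' must be set", call. = FALSE)
  if (is.null(K) == is.null(K_range))
    stop("exactly one of 'K' and 'K_range' must be set", call. = FALSE)
  structure(list(input = input, synthetic = synthetic, features = features,
                 K = K, K_range = K_range, fit = fit,
                 bootstrap_B = as.integer(bootstrap_B),
                 entropy_base = entropy_base, column_map = column_map,
                 output_dir = output_dir, figures = figures,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' clean -> fit (or BIC select) -> decode -> valence labels -> transition
#' dynamics (stationary distribution, dwell times, entropies, bootstrap
#' CIs) -> morning/afternoon contingency -> descriptives -> PCA. Writes a
#' JSON report, CSV tables and optional PNG figures when an output
#' directory is configured. Fully reproducible given the seeds in the
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list with sections `exclusion_report`,
#'   `model_selection`, `parameters`, `labeling`, `dynamics`, `temporal`,
#'   `descriptives`, `pca`, `warnings`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_out <- character(0)

  table <- if (!is.null(config$synthetic)) {
    generate_dataset(config$synthetic)$table
  } else if (is.character(config$input)) {
    read_submissions(config$input, column_map = config$column_map)
  } else {
    config$input
  }

  cleaned <- clean_submissions(table)
  seq <- cleaned$sequence
  feat_idx <- match(config$features, seq$item_names)
  if (anyNA(feat_idx))
    stop("unknown feature(s): ",
         paste(config$features[is.na(feat_idx)], collapse = ", "), call. = FALSE)
  X <- seq$values[, feat_idx, drop = FALSE]

  if (!is.null(config$K_range)) {
    sel <- select_n_states(X, config$K_range, config$fit)
    fit <- sel$best_fit
    bic_table <- sel$bic_table
  } else {
    fit <- baum_welch_fit(X, config$K, config$fit)
    bic_table <- data.frame(K = config$K, log_likelihood = fit$log_likelihood,
                            bic = fit$bic, converged = fit$converged,
                            failed = FALSE)
  }

  labeling <- label_states(fit$params)
  record_labels <- labeling$labels[fit$decoded_path]

  reduced_B <- config$bootstrap_B < 1000
  if (reduced_B)
    warnings_out <- c(warnings_out,
                      sprintf("bootstrap run with reduced B = %d (< 1000); intervals are coarse",
                              config$bootstrap_B))
  dyn <- withCallingHandlers(
    dynamics_summary(fit$params, path = fit$decoded_path,
                     B = config$bootstrap_B, seed = config$seed,
                     entropy_base = config$entropy_base),
    warning = function(w) {
      warnings_out <<- c(warnings_out, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  bins <- assign_time_bins(seq)
  temporal <- tryCatch(
    withCallingHandlers(
      temporal_contingency(record_labels, bins),
      warning = function(w) {
        warnings_out <<- c(warnings_out, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
    error = function(e) {
      warnings_out <<- c(warnings_out,
                         paste("temporal analysis skipped:", conditionMessage(e)))
      NULL
    })

  desc <- descriptive_stats(X, states = fit$decoded_path)
  pca <- pca_project(X, n_components = 2)

  report <- structure(list(
    exclusion_report = cleaned$report,
    model_selection = list(chosen_K = fit$params$K, bic_table = bic_table),
    parameters = list(initial = fit$params$initial,
                      transition = fit$params$transition,
                      means = fit$params$means,
                      covariance_type = fit$params$covariance_type,
                      log_likelihood = fit$log_likelihood, bic = fit$bic,
                      n_iter = fit$n_iter, converged = fit$converged),
    labeling = list(labels = labeling$labels, order = labeling$order,
                    grand_means = labeling$grand_means),
    dynamics = dyn,
    temporal = temporal %||% list(skipped = TRUE),
    descriptives = desc,
    pca = list(explained_variance = pca$explained_variance,
               loadings = pca$loadings),
    reduced_B = reduced_B,
    warnings = warnings_out,
    provenance = list(seed = config$seed, fit_seed = config$fit$seed,
                      bootstrap_B = config$bootstrap_B,
                      features = config$features,
                      package_version = as.character(utils::packageVersion("affecthmm")),
                      r_version = R.version.string,
                      timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "pipeline_report")

  report$.fit <- fit
  report$.sequence <- seq
  report$.pca_scores <- pca$scores
  report$.bins <- bins
  report$.record_labels <- record_labels

  if (!is.null(config$output_dir))
    write_pipeline_outputs(report, config$output_dir, figures = config$figures)
  report
}

#' Serialize a pipeline report to JSON
#'
#' Drops the in-memory-only sections (fit object, raw sequence, PCA scores)
#' and writes the report at full precision.
#'
#' @param report A `pipeline_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- unclass(report)
  out <- out[!startsWith(names(out), ".")]
  out$dynamics <- serialize_dynamics(report$dynamics)
  out$temporal <- serialize_temporal(report$temporal)
  out$descriptives <- list(overall = report$descriptives$overall,
                           by_state = report$descriptives$by_state)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, na = "null")
  invisible(path)
}

serialize_dynamics <- function(dyn) {
  if (is.null(dyn)) return(NULL)
  out <- list(stationary = dyn$stationary,
              dwell_geometric = dyn$dwell$geometric,
              dwell_empirical = dyn$dwell$empirical,
              entropy = dyn$entropy, entropy_base = dyn$entropy_base)
  if (!is.null(dyn$bootstrap)) {
    b <- dyn$bootstrap
    out$bootstrap <- list(B = b$B, seed = b$seed,
                          transition = b$transition,
                          transition_lower = b$transition_lower,
                          transition_upper = b$transition_upper,
                          dwell_lower = b$dwell_lower,
                          dwell_upper = b$dwell_upper,
                          entropy_lower = b$entropy_lower,
                          entropy_upper = b$entropy_upper)
  }
  out
}

serialize_temporal <- function(tmp) {
  if (is.null(tmp) || !inherits(tmp, "contingency_result")) return(tmp)
  list(counts = tmp$counts, chi_square = tmp$chi_square, df = tmp$df,
       p_value = tmp$p_value, cramers_v = tmp$cramers_v,
       verdict = tmp$verdict, N = tmp$N,
       small_expected_cells = tmp$small_expected_cells)
}

write_pipeline_outputs <- function(report, dir, figures = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_report_json(report, file.path(dir, "report.json"))

  A <- report$parameters$transition
  utils::write.csv(round(A, 6), file.path(dir, "transition_matrix.csv"))
  utils::write.csv(round(report$parameters$means, 6),
                   file.path(dir, "state_means.csv"))
  utils::write.csv(report$descriptives$overall,
                   file.path(dir, "descriptives.csv"), row.names = FALSE)
  decoded <- data.frame(timestamp = format(report$.sequence$timestamps,
                                           "%Y-%m-%d %H:%M", tz = "UTC"),
                        state = report$.fit$decoded_path,
                        label = report$.record_labels,
                        bin = as.character(report$.bins))
  utils::write.csv(decoded, file.path(dir, "decoded_states.csv"),
                   row.names = FALSE)

  if (figures) {
    fig_transition_heatmap(A, report$labeling$labels,
                           file.path(dir, "fig_transition_heatmap.png"))
    if (!is.null(report$dynamics$stationary))
      fig_stationary_bar(report$dynamics$stationary, report$labeling$labels,
                         file.path(dir, "fig_stationary.png"))
    fig_pca_scatter(report$.pca_scores, report$.record_labels,
                    file.path(dir, "fig_pca_states.png"))
    if (inherits(report$temporal, "contingency_result"))
      fig_temporal_shares(report$temporal$counts,
                          file.path(dir, "fig_temporal_shares.png"))
  }
  invisible(dir)
}

fig_transition_heatmap <- function(A, labels, path) {
  K <- nrow(A)
  grDevices::png(path, width = 700, height = 600)
  on.exit(grDevices::dev.off())
  graphics::image(seq_len(K), seq_len(K), t(A[K:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(50, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "to state", ylab = "from state",
                  main = "Transition probabilities", zlim = c(0, 1))
  graphics::axis(1, at = seq_len(K), labels = labels)
  graphics::axis(2, at = seq_len(K), labels = rev(labels))
  for (i in seq_len(K)) for (j in seq_len(K))
    graphics::text(j, K - i + 1, sprintf("%.3f", A[i, j]))
}

fig_stationary_bar <- function(pi_star, labels, path) {
  grDevices::png(path, width = 700, height = 500)
  on.exit(grDevices::dev.off())
  graphics::barplot(pi_star, names.arg = labels, ylim = c(0, 1),
                    ylab = "stationary probability",
                    main = "Long-run state occupancy")
}

fig_pca_scatter <- function(scores, labels, path) {
  grDevices::png(path, width = 700, height = 600)
  on.exit(grDevices::dev.off())
  f <- factor(labels)
  graphics::plot(scores[, 1], scores[, 2], col = as.integer(f), pch = 16,
                 cex = 0.5, xlab = "PC1", ylab = "PC2",
                 main = "PCA projection by decoded state")
  graphics::legend("topright", legend = levels(f), col = seq_along(levels(f)),
                   pch = 16)
}

fig_temporal_shares <- function(counts, path) {
  grDevices::png(path, width = 700, height = 500)
  on.exit(grDevices::dev.off())
  shares <- counts / rowSums(counts)
  graphics::barplot(t(shares), beside = TRUE, legend.text = colnames(counts),
                    ylab = "share of submissions",
                    main = "State shares by time bin", ylim = c(0, 1))
}
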