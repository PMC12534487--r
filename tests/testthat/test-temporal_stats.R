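test_that("contingency_table cross-tabulates in fixed order and drops excluded bins", {
  labels <- c("positive", "positive", "negative", "positive")
  bins <- factor(c("morning", "morning", "afternoon", "excluded"),
                 levels = c("morning", "afternoon", "excluded"))
  ct <- contingency_table(labels, bins)
  expect_equal(unname(ct), rbind(c(0, 0, 2), c(1, 0, 0)))
  expect_equal(rownames(ct), c("morning", "afternoon"))
  expect_equal(colnames(ct), c("negative", "neutral_moderate", "positive"))
  expect_error(contingency_table("positive", factor("excluded")), "no records")
})

test_that("pearson_chi_square matches hand arithmetic and the library oracle", {
  # perfectly proportional table: zero association
  r0 <- suppressWarnings(pearson_chi_square(rbind(c(10, 20), c(20, 40))))
  expect_equal(r0$chi_square, 0)
  expect_equal(r0$df, 1)
  expect_equal(r0$p_value, 1)

  # all expected cells are 15: chi2 = 4 * 25/15 = 20/3
  r1 <- pearson_chi_square(rbind(c(10, 20), c(20, 10)))
  expect_equal(r1$chi_square, 20 / 3, tolerance = 1e-12)
  expect_equal(r1$df, 1)

  # library cross-check on random tables
  set.seed(77)
  for (i in 1:100) {
    r <- sample(2:4, 1); c <- sample(2:4, 1)
    tab <- matrix(rpois(r * c, lambda = 30) + 1, r, c)
    mine <- suppressWarnings(pearson_chi_square(tab))
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(mine$chi_square, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
  }

  expect_error(pearson_chi_square(rbind(c(0, 0), c(1, 2))), "marginals")
  expect_warning(pearson_chi_square(rbind(c(1, 2), c(2, 1))), "below 5")

  # invariance under row/column permutation; linear scaling of counts
  set.seed(78)
  tab <- matrix(rpois(6, 40) + 1, 2, 3)
  base <- suppressWarnings(pearson_chi_square(tab)$chi_square)
  perm <- suppressWarnings(pearson_chi_square(tab[2:1, c(3, 1, 2)])$chi_square)
  expect_equal(perm, base, tolerance = 1e-12)
  scaled <- suppressWarnings(pearson_chi_square(tab * 7)$chi_square)
  expect_equal(scaled, base * 7, tolerance = 1e-10)
})

test_that("cramers_v attains its bounds and stays in [0, 1]", {
  expect_equal(cramers_v(0, 100, 2, 3)$v, 0)
  n <- 25
  perfect <- rbind(c(n, 0), c(0, n))
  chi2 <- suppressWarnings(pearson_chi_square(perfect)$chi_square)
  expect_equal(cramers_v(chi2, 2 * n, 2, 2)$v, 1, tolerance = 1e-12)

  set.seed(79)
  for (i in 1:50) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    res <- suppressWarnings(pearson_chi_square(tab))
    v <- cramers_v(res$chi_square, res$N, 2, 3)$v
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("the reconstructed published contingency table reproduces the printed test", {
  tab <- happyhere_contingency_table()
  expect_equal(unname(tab), rbind(c(77, 144, 821), c(480, 921, 4116)))
  res <- pearson_chi_square(tab)
  expect_equal(res$chi_square, 8.20, tolerance = 0.2 / 8.20)
  expect_equal(res$df, 2)
  v <- cramers_v(res$chi_square, res$N, 2, 3)
  expect_equal(v$v, 0.04, tolerance = 0.01 / 0.04)
  expect_equal(v$verdict, "negligible")
})

test_that("contingency counts from a labeled synthetic dataset match direct bookkeeping", {
  g <- generate_dataset(happyhere_config(n = 2000, seed = 8))
  cl <- clean_submissions(g$table)
  states <- g$truth$states[setdiff(seq_len(2000),
                                   g$truth$anomaly_rows)]
  # generator states are (moderate, negative, positive) = valence labels
  lab <- c("neutral_moderate", "negative", "positive")[states]
  bins <- assign_time_bins(cl$sequence)
  ct <- contingency_table(lab, bins)
  for (b in c("morning", "afternoon"))
    for (l in colnames(ct))
      expect_equal(ct[b, l], sum(lab == l & as.character(bins) == b))
  expect_equal(sum(ct), cl$report$n_retained)
})

test_that("descriptive statistics use sample sd and interpolated quartiles", {
  X <- cbind(rep(3, 5), c(1, 2, 3, 4, 5))
  colnames(X) <- c("a", "b")
  d <- descriptive_stats(X)
  expect_equal(d$overall$mean, c(3, 3))
  expect_equal(d$overall$std, c(0, sd(1:5)))
  expect_equal(d$overall[d$overall$item == "a", c("min", "q25", "q50", "q75", "max")],
               data.frame(min = 3, q25 = 3, q50 = 3, q75 = 3, max = 3),
               ignore_attr = TRUE)
  expect_equal(unlist(d$overall[2, c("q25", "q50", "q75")]), c(2, 3, 4),
               ignore_attr = TRUE)

  # two-pass vs streaming moments agree
  set.seed(80)
  Y <- matrix(rnorm(500), 100, 5)
  d2 <- descriptive_stats(Y)
  stream_mean <- apply(Y, 2, function(v) sum(v) / length(v))
  stream_var <- apply(Y, 2, function(v) {
    m <- 0; s <- 0
    for (i in seq_along(v)) {
      delta <- v[i] - m
      m <- m + delta / i
      s <- s + delta * (v[i] - m)
    }
    s / (length(v) - 1)
  })
  expect_equal(d2$overall$mean, stream_mean, tolerance = 1e-12)
  expect_equal(d2$overall$std, sqrt(stream_var), tolerance = 1e-12)

  # per-state means match stratified computation
  states <- rep(1:2, 50)
  d3 <- descriptive_stats(Y, states = states)
  expect_equal(d3$by_state["state_1", ], colMeans(Y[states == 1, ]),
               ignore_attr = TRUE)
})
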