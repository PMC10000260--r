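test_that("within-patient ranking sorts descending with id tie-break", {
  df <- tibble::tibble(patient_id = "P1", embryo_id = c("e1", "e2", "e3"),
                       beta1 = c(5.1, 3.0, 4.2))
  r <- rank_within_patient(df)
  expect_equal(r$rank[match(c("e1", "e2", "e3"), r$embryo_id)], c(1, 3, 2))

  tie <- tibble::tibble(patient_id = "P1", embryo_id = c("e2", "e1"),
                        beta1 = c(4.0, 4.0))
  rt <- rank_within_patient(tie)
  expect_equal(rt$embryo_id[rt$rank == 1], "e1")
  expect_equal(rt$embryo_id[rt$rank == 2], "e2")
})

test_that("ranks pool beyond K and invalid input errors", {
  df <- tibble::tibble(patient_id = "P1",
                       embryo_id = sprintf("e%02d", 1:12),
                       beta1 = 12:1)
  r <- rank_within_patient(df, pool_after = 10)
  expect_equal(sum(r$rank_label == ">10"), 2)
  expect_setequal(r$rank_label, c(as.character(1:10), ">10"))

  dup <- tibble::tibble(patient_id = "P1", embryo_id = c("e1", "e1"),
                        beta1 = c(1, 2))
  expect_error(rank_within_patient(dup), "duplicate")
  expect_error(rank_within_patient(dplyr::mutate(df, beta1 = -beta1)),
               "positive")
})

test_that("rate-table cells render numerator/denominator (percent)", {
  ranked <- tibble::tibble(
    rank = rep(1, 155), rank_label = "1",
    normal_group = c(rep(TRUE, 102), rep(FALSE, 53))
  )
  tab <- rank_rate_table(ranked)
  expect_equal(tab$cell, "102/155 (65.81)")
  # integral percentages drop trailing zeros like the published tables
  ranked2 <- tibble::tibble(rank = rep(2, 25), rank_label = "2",
                            normal_group = rep(c(TRUE, FALSE), c(13, 12)))
  expect_equal(rank_rate_table(ranked2)$cell, "13/25 (52)")
})

test_that("empty strata are omitted from rate tables", {
  ranked <- tibble::tibble(rank = c(1, 1, 2, 2), rank_label = c("1", "1", "2", "2"),
                           normal_group = c(TRUE, FALSE, TRUE, TRUE))
  tab <- rank_rate_table(ranked)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$rank_label, c("1", "2"))
})

test_that("Woolf odds ratios reproduce closed-form values and symmetry", {
  res <- odds_ratio_woolf(90, 65, 70, 85)
  expect_equal(res$estimate, (90 * 85) / (65 * 70))
  # closed-form Woolf interval computed independently
  se <- sqrt(1 / 90 + 1 / 65 + 1 / 70 + 1 / 85)
  expect_equal(res$ci_low, exp(log(res$estimate) - 1.95996 * se))
  expect_equal(res$ci_high, exp(log(res$estimate) + 1.95996 * se))
  expect_true(res$ci_low <= res$estimate & res$estimate <= res$ci_high)

  expect_equal(odds_ratio_woolf(37, 21, 37, 21)$estimate, 1)

  # reciprocal symmetry
  a <- odds_ratio_woolf(12, 7, 9, 15)
  b <- odds_ratio_woolf(7, 12, 15, 9)
  expect_equal(a$estimate * b$estimate, 1, tolerance = 1e-12)

  # the interval tightens as all cells scale up
  wide <- odds_ratio_woolf(10, 8, 7, 11)
  tight <- odds_ratio_woolf(100, 80, 70, 110)
  expect_lt(log(tight$ci_high / tight$ci_low),
            log(wide$ci_high / wide$ci_low))
})

test_that("zero cells trigger the Haldane correction or an error", {
  res <- odds_ratio_woolf(10, 0, 5, 7)
  expect_true(res$corrected)
  expect_true(is.finite(res$estimate))
  expect_error(odds_ratio_woolf(10, 0, 5, 7, haldane = FALSE), "zero cell")
})

test_that("Pearson chi-square matches the hand-expanded formula and stats::chisq.test", {
  m <- rbind(c(10, 20), c(30, 40))
  # hand expansion: E_ij = row_i * col_j / N
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  hand <- sum((m - e)^2 / e)
  res <- pearson_chi_square(m)
  expect_equal(res$statistic, hand)
  expect_equal(res$df, 1)
  ref <- stats::chisq.test(m, correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, unname(ref$p.value))
})

test_that("chi-square is zero for proportional rows, invariant to row order", {
  prop <- rbind(c(10, 20), c(20, 40), c(5, 10))
  expect_equal(pearson_chi_square(prop)$statistic, 0, tolerance = 1e-12)
  set.seed(61)
  m <- matrix(rpois(22, 40), ncol = 2)
  expect_equal(pearson_chi_square(m)$statistic,
               pearson_chi_square(m[sample(nrow(m)), ])$statistic)
  expect_error(pearson_chi_square(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("Spearman correlation equals mid-rank computation with ties", {
  x <- c(1, 2, 2, 3, 4, 5, 5, 5, 6, 7)
  set.seed(67)
  y <- x + rnorm(10, 0, 0.5)
  res <- spearman_rank_corr(x, y)
  # brute-force oracle: average ranks, then the Pearson formula
  rx <- rank(x); ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(res$rho, oracle)
  expect_equal(res$rho, unname(stats::cor(x, y, method = "spearman")))
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)

  expect_equal(spearman_rank_corr(1:10, 1:10)$rho, 1)
  expect_equal(spearman_rank_corr(1:10, -(1:10))$rho, -1)
  expect_false(spearman_rank_corr(rep(1, 5), 1:5)$defined)
})

test_that("Cochran Q matches the two-group hand computation", {
  groups <- tibble::tibble(mean = c(10, 14), sd = c(1, 1), n = c(4, 4))
  res <- cochran_heterogeneity(groups)
  # w = n/sd^2 = 4 each, pooled mean 12, Q = 4*4 + 4*4
  expect_equal(res$Q, 32)
  expect_equal(res$df, 1)
  expect_equal(res$I2_pct, (32 - 1) / 32 * 100)

  same <- tibble::tibble(mean = c(10, 10, 10), sd = 1, n = 4)
  res0 <- cochran_heterogeneity(same)
  expect_equal(res0$Q, 0)
  expect_equal(res0$I2_pct, 0)
})

test_that("heterogeneous simulated cohorts give I-squared above 90%", {
  set.seed(71)
  config <- sim_config(n_patients = 60, seed = 71)
  sim <- simulate_trajectories(config)
  groups <- sim$truth |>
    dplyr::filter(sex == "female") |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(mean = mean(beta1), sd = sd(beta1), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(n >= 2)
  res <- cochran_heterogeneity(groups)
  expect_gt(res$I2_pct, 90)
})

test_that("zero-variance groups are weight-capped and flagged", {
  groups <- tibble::tibble(mean = c(10, 12, 14), sd = c(0, 1, 1), n = 4)
  res <- cochran_heterogeneity(groups)
  expect_true(res$capped)
  expect_true(is.finite(res$Q))
})

test_that("top-vs-bottom odds ratios use per-patient extremes", {
  ranked <- tibble::tibble(
    patient_id = rep(c("P1", "P2", "P3"), each = 3),
    embryo_id = sprintf("e%d", 1:9),
    beta1 = c(3, 2, 1, 6, 5, 4, 9, 8, 7)
  ) |> rank_within_patient()
  ranked$normal_group <- ranked$rank == 1 # perfectly rank-determined outcome
  res <- rank_extreme_or(ranked, k = 1)
  expect_equal(res$a, 3); expect_equal(res$b, 0)
  expect_equal(res$c, 0); expect_equal(res$d, 3)
  expect_true(res$corrected) # zero cells -> Haldane
  expect_gt(res$estimate, 1)
})
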