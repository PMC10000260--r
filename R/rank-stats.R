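#' Rank embryos by beta1 within each patient
#'
#' Because the growth coefficient is strongly heterogeneous between
#' patients, comparisons are made on within-patient ranking orders: rank 1
#' is the embryo with the largest `beta1` in its patient. Ties are broken by
#' ascending `embryo_id` so reruns are deterministic. Ranks beyond
#' `pool_after` are pooled into a single `">K"` stratum for rate tables.
#'
#' @param embryos Data frame with `patient_id`, `embryo_id`, `beta1`
#'   (positive, finite); other columns are carried through.
#' @param pool_after Pooling threshold K (10 for blastocyst-formation
#'   tables, 8 for PGT outcome tables).
#' @return The input tibble plus `rank` (1..n within patient) and
#'   `rank_label` (`"1"`..`"K"`, `">K"`).
#' @export
rank_within_patient <- function(embryos, pool_after = 8) {
  check_columns(embryos, c("patient_id", "embryo_id", "beta1"), "embryos")
  stopifnot(pool_after >= 1)
  if (any(!is.finite(embryos$beta1)) || any(embryos$beta1 <= 0)) {
    stop("beta1 values must be finite and positive", call. = FALSE)
  }
  dup <- embryos |>
    dplyr::count(.data$patient_id, .data$embryo_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate embryo_id within patient: ",
         paste(dup$embryo_id, collapse = ", "), call. = FALSE)
  }
  embryos |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(dplyr::desc(.data$beta1), .data$embryo_id,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(rank_label = ifelse(.data$rank > pool_after,
                                      paste0(">", pool_after),
                                      as.character(.data$rank)))
}

#' Per-rank outcome rate table
#'
#' Tabulates a boolean outcome by pooled rank stratum, in the
#' `"numerator/denominator (percent)"` display form of clinical rate tables
#' (percent rounded to two decimals, trailing zeros dropped). Empty strata
#' are omitted.
#'
#' @param ranked Output of [rank_within_patient()].
#' @param outcome Name of a logical column on `ranked` (default
#'   `"normal_group"`).
#' @return A tibble `rank_label`, `numerator`, `denominator`, `rate_pct`,
#'   `cell` ordered by rank.
#' @export
rank_rate_table <- function(ranked, outcome = "normal_group") {
  check_columns(ranked, c("rank_label", "rank", outcome), "ranked")
  ranked |>
    dplyr::group_by(.data$rank_label) |>
    dplyr::summarise(
      numerator = sum(.data[[outcome]]),
      denominator = dplyr::n(),
      order = min(.data$rank),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$order) |>
    dplyr::mutate(
      rate_pct = round(100 * .data$numerator / .data$denominator, 2),
      cell = sprintf("%d/%d (%s)", .data$numerator, .data$denominator,
                     format(.data$rate_pct, trim = TRUE, drop0trailing = TRUE))
    ) |>
    dplyr::select(-"order")
}

#' Woolf odds ratio with 95% confidence interval
#'
#' Odds ratio of a 2x2 table `(a, b; c, d)` with the Woolf (log-OR normal
#' approximation) confidence interval
#' \eqn{\exp(\ln OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})}, z = 1.95996, and a
#' two-sided p-value from the same normal approximation. A zero cell
#' triggers the Haldane-Anscombe +0.5 correction on all four cells (flagged
#' in the output) unless `haldane = FALSE`, in which case it is an error.
#'
#' @param a,b,c,d Non-negative integer cell counts; rows are the two groups
#'   being compared, columns outcome yes/no, so `a/b` versus `c/d`.
#' @param conf_z Normal quantile for the interval (1.95996 for 95%).
#' @param haldane Allow the +0.5 zero-cell correction.
#' @return A one-row tibble: `estimate`, `ci_low`, `ci_high`, `p_value`,
#'   `corrected`.
#' @examples
#' odds_ratio_woolf(90, 65, 70, 85)
#' @export
odds_ratio_woolf <- function(a, b, c, d, conf_z = 1.95996, haldane = TRUE) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  corrected <- any(cells == 0)
  if (corrected) {
    if (!haldane) stop("zero cell with Haldane correction disabled", call. = FALSE)
    cells <- cells + 0.5
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble::tibble(
    estimate = or,
    ci_low = exp(log(or) - conf_z * se),
    ci_high = exp(log(or) + conf_z * se),
    p_value = 2 * stats::pnorm(-abs(log(or)) / se),
    corrected = corrected
  )
}

#' Pearson chi-square on an R x 2 count table
#'
#' Standard Pearson statistic \eqn{\sum (O - E)^2 / E} against independence,
#' with `df = R - 1` and no continuity correction, as used for the
#' rank-by-outcome formation tables.
#'
#' @param counts Numeric matrix or data frame with R rows and 2 columns of
#'   non-negative counts.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
pearson_chi_square <- function(counts) {
  m <- as.matrix(counts)
  if (ncol(m) != 2) stop("counts must have exactly 2 columns", call. = FALSE)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  row_tot <- rowSums(m)
  col_tot <- colSums(m)
  if (any(row_tot == 0) || any(col_tot == 0)) {
    stop("zero marginal total in chi-square table", call. = FALSE)
  }
  expected <- outer(row_tot, col_tot) / sum(m)
  stat <- sum((m - expected)^2 / expected)
  df <- nrow(m) - 1
  tibble::tibble(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties get averaged ranks), with a
#' two-sided p-value from the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}. A constant input vector has no
#' defined rank correlation and yields an `NA` estimate with
#' `defined = FALSE`.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return A one-row tibble: `rho`, `p_value`, `n`, `defined`.
#' @export
spearman_rank_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n,
                          defined = FALSE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  tibble::tibble(rho = rho, p_value = p, n = n, defined = TRUE)
}

#' Cochran Q heterogeneity across patients
#'
#' Fixed-effect Cochran Q over per-patient mean coefficients, weighting each
#' patient by the inverse squared standard error of its mean
#' (`w = n / sd^2`), with `df = k - 1` and
#' \eqn{I^2 = \max(0, (Q - df)/Q) \times 100}. A zero-variance patient would
#' carry infinite weight; its weight is capped at the largest finite weight
#' and the result is flagged.
#'
#' @param groups Data frame with one row per patient: `mean`, `sd`, `n`
#'   (n >= 2 per patient, at least 2 patients).
#' @return A one-row tibble: `Q`, `df`, `I2_pct`, `capped`.
#' @export
cochran_heterogeneity <- function(groups) {
  check_columns(groups, c("mean", "sd", "n"), "groups")
  if (nrow(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(groups$n < 2)) stop("each group needs n >= 2", call. = FALSE)
  w <- groups$n / groups$sd^2
  capped <- any(!is.finite(w))
  if (capped) {
    if (all(!is.finite(w))) stop("all groups have zero variance", call. = FALSE)
    w[!is.finite(w)] <- max(w[is.finite(w)])
  }
  pooled <- sum(w * groups$mean) / sum(w)
  q <- sum(w * (groups$mean - pooled)^2)
  df <- nrow(groups) - 1
  tibble::tibble(Q = q, df = df,
                 I2_pct = if (q > 0) max(0, (q - df) / q) * 100 else 0,
                 capped = capped)
}

#' Top-versus-bottom rank odds ratio
#'
#' Builds the 2x2 table comparing outcome rates of the `k` highest-ranked
#' embryos per patient against the `k` lowest-ranked and returns the Woolf
#' odds ratio. Embryos belonging to both extremes (patients with fewer than
#' `2k` embryos) are excluded from the comparison.
#'
#' @param ranked Output of [rank_within_patient()].
#' @param outcome Logical outcome column name.
#' @param k Number of extreme ranks on each side (1 = top 1 vs last 1).
#' @return A one-row tibble: the [odds_ratio_woolf()] columns plus the four
#'   cell counts and per-side rates.
#' @export
rank_extreme_or <- function(ranked, outcome = "normal_group", k = 1) {
  check_columns(ranked, c("patient_id", "rank", outcome), "ranked")
  extremes <- ranked |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      n_embryos = dplyr::n(),
      side = dplyr::case_when(
        .data$rank <= k & .data$rank > .data$n_embryos - k ~ "both",
        .data$rank <= k ~ "top",
        .data$rank > .data$n_embryos - k ~ "bottom",
        TRUE ~ "middle"
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$side %in% c("top", "bottom"))
  if (nrow(extremes) == 0) {
    stop("no patients with distinct top and bottom ranks", call. = FALSE)
  }
  a <- sum(extremes$side == "top" & extremes[[outcome]])
  b <- sum(extremes$side == "top" & !extremes[[outcome]])
  c <- sum(extremes$side == "bottom" & extremes[[outcome]])
  d <- sum(extremes$side == "bottom" & !extremes[[outcome]])
  res <- odds_ratio_woolf(a, b, c, d)
  dplyr::mutate(res, a = a, b = b, c = c, d = d,
                top_rate = a / (a + b), bottom_rate = c / (c + d))
}

#' Plot per-rank outcome rates
#'
#' @param rate_tables A named list of [rank_rate_table()] tibbles (e.g. one
#'   per coefficient variant) or a single such tibble.
#' @return A ggplot object.
#' @export
plot_rank_rates <- function(rate_tables) {
  if (is.data.frame(rate_tables)) rate_tables <- list(rates = rate_tables)
  df <- dplyr::bind_rows(rate_tables, .id = "variant") |>
    dplyr::mutate(rank_label = factor(.data$rank_label,
                                      levels = unique(.data$rank_label)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank_label, y = .data$rate_pct,
                                   group = .data$variant,
                                   colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "within-patient beta1 rank (1 = largest)",
                  y = "outcome rate (%)", colour = NULL)
}
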