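#' Fit the exponential pronuclear growth model
#'
#' Fits \eqn{f(t) = \beta_1 \beta_2^t} to one pronucleus area trajectory by
#' closed-form least squares on the log scale: `log(area)` is regressed on
#' hours post-ICSI, and the intercept and slope back-transform to
#' \eqn{\beta_1 = e^{a}} (the fictitious PN area at the time of ICSI, t = 0,
#' in square microns) and \eqn{\beta_2 = e^{b}} (the hourly growth factor).
#' The goodness of fit `r2` is reported on the original area scale,
#' \eqn{1 - SS_{res}/SS_{tot}} with back-transformed predictions, since that
#' is the scale on which the areas are measured.
#'
#' @param traj Trajectory data frame with columns `time_h` and `area_um2`
#'   (optionally `embryo_id`, `sex`, carried through), strictly positive
#'   areas, at least 4 points.
#' @param variant Label stored on the fit (see [coefficient_variants()]).
#' @return A `pn_growth_fit` object; use [generics::tidy()] /
#'   [generics::glance()] or `$beta1`, `$beta2`, `$r2` directly.
#' @examples
#' tr <- tibble::tibble(time_h = seq(6, 22, 0.25),
#'                      area_um2 = 600 * 1.04^seq(6, 22, 0.25))
#' fit_exponential(tr)
#' @export
fit_exponential <- function(traj, variant = "original") {
  check_columns(traj, c("time_h", "area_um2"), "traj")
  if (nrow(traj) < 4) {
    stop("growth fit needs at least 4 points, got ", nrow(traj), call. = FALSE)
  }
  if (any(traj$area_um2 <= 0) || any(!is.finite(traj$area_um2))) {
    stop("areas must be positive and finite", call. = FALSE)
  }
  t <- traj$time_h
  y <- log(traj$area_um2)
  tbar <- mean(t)
  sxx <- sum((t - tbar)^2)
  if (sxx == 0) stop("all time points identical: cannot fit growth", call. = FALSE)
  slope <- sum((t - tbar) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * tbar
  pred <- exp(intercept + slope * t)
  sstot <- sum((traj$area_um2 - mean(traj$area_um2))^2)
  ssres <- sum((traj$area_um2 - pred)^2)
  structure(
    list(
      embryo_id = if ("embryo_id" %in% names(traj)) traj$embryo_id[1] else NA_character_,
      sex = if ("sex" %in% names(traj)) traj$sex[1] else NA_character_,
      variant = variant,
      beta1 = exp(intercept),
      beta2 = exp(slope),
      r2 = if (sstot == 0) 1 else 1 - ssres / sstot,
      n_points = nrow(traj),
      data = tibble::tibble(time_h = t, area_um2 = traj$area_um2,
                            fitted = pred)
    ),
    class = "pn_growth_fit"
  )
}

#' @export
print.pn_growth_fit <- function(x, ...) {
  cat(sprintf(
    "<pn_growth_fit> %s/%s [%s]: beta1 = %.2f um^2, beta2 = %.4f /h, R^2 = %.4f (n = %d)\n",
    x$embryo_id, x$sex, x$variant, x$beta1, x$beta2, x$r2, x$n_points))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.pn_growth_fit <- function(x, ...) {
  tibble::tibble(term = c("beta1", "beta2"),
                 estimate = c(x$beta1, x$beta2))
}

#' @exportS3Method generics::glance
glance.pn_growth_fit <- function(x, ...) {
  tibble::tibble(embryo_id = x$embryo_id, sex = x$sex, variant = x$variant,
                 beta1 = x$beta1, beta2 = x$beta2, r2 = x$r2,
                 n_points = x$n_points)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pn_growth_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$area_um2), alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#2166ac") +
    ggplot2::labs(
      x = "hours post-ICSI", y = expression("PN area (" * mu * m^2 * ")"),
      title = sprintf("%s %s PN, %s fit", object$embryo_id, object$sex,
                      object$variant),
      subtitle = sprintf("beta1 = %.1f, beta2 = %.4f, R2 = %.4f",
                         object$beta1, object$beta2, object$r2)
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Fit the four coefficient variants of one trajectory
#'
#' The growth coefficient is extracted under four fitting windows that trade
#' data quantity against early-stage detection noise: `original` (all
#' points), `adjusted` (first and last three points dropped — those frames
#' have the highest recognition error and the highest leverage in the fit),
#' `h12` (points at >= 12 h post-insemination) and `h14` (>= 14 h). Whatever
#' the window, `beta1` is always the t = 0 (ICSI-time) intercept. A variant
#' whose window retains fewer than 4 points is flagged unavailable.
#'
#' @inheritParams fit_exponential
#' @param variants Character subset of
#'   `c("original", "adjusted", "h12", "h14")`.
#' @return A tibble with one row per variant: `embryo_id`, `sex`, `variant`,
#'   `beta1`, `beta2`, `r2`, `n_points`, `available`.
#' @export
coefficient_variants <- function(traj,
                                 variants = c("original", "adjusted",
                                              "h12", "h14")) {
  check_columns(traj, c("time_h", "area_um2"), "traj")
  variants <- match.arg(variants, several.ok = TRUE)
  traj <- dplyr::arrange(traj, .data$time_h)
  subset_for <- function(v) {
    switch(v,
      original = traj,
      adjusted = if (nrow(traj) > 6) traj[4:(nrow(traj) - 3), ] else traj[0, ],
      h12 = dplyr::filter(traj, .data$time_h >= 12),
      h14 = dplyr::filter(traj, .data$time_h >= 14)
    )
  }
  purrr::map_dfr(variants, function(v) {
    sub <- subset_for(v)
    base <- tibble::tibble(
      embryo_id = if ("embryo_id" %in% names(traj)) traj$embryo_id[1] else NA_character_,
      sex = if ("sex" %in% names(traj)) traj$sex[1] else NA_character_,
      variant = v
    )
    if (nrow(sub) < 4) {
      dplyr::mutate(base, beta1 = NA_real_, beta2 = NA_real_, r2 = NA_real_,
                    n_points = nrow(sub), available = FALSE)
    } else {
      f <- fit_exponential(sub, variant = v)
      dplyr::mutate(base, beta1 = f$beta1, beta2 = f$beta2, r2 = f$r2,
                    n_points = f$n_points, available = TRUE)
    }
  })
}

#' Fit growth variants across a cohort of trajectories
#'
#' Data-frame-first cohort wrapper over [coefficient_variants()]: one fit row
#' per embryo, sex and variant.
#'
#' @param trajectories Long tibble with `embryo_id`, `sex`, `time_h`,
#'   `area_um2` (as produced by [build_area_trajectories()] or
#'   [simulate_trajectories()]).
#' @inheritParams coefficient_variants
#' @return A tibble of fits (see [coefficient_variants()]).
#' @export
fit_growth <- function(trajectories,
                       variants = c("original", "adjusted", "h12", "h14")) {
  check_columns(trajectories, c("embryo_id", "sex", "time_h", "area_um2"),
                "trajectories")
  trajectories |>
    dplyr::group_by(.data$embryo_id, .data$sex) |>
    dplyr::group_split() |>
    purrr::map_dfr(coefficient_variants, variants = variants)
}

#' Cohort summary of fit quality
#'
#' Descriptive summary of the growth factor and goodness of fit per variant:
#' mean, SD and range of `beta2`, and the range of original-scale `r2`.
#'
#' @param fits Fits tibble from [fit_growth()] (unavailable variants are
#'   ignored).
#' @return A tibble with one row per variant.
#' @export
fit_quality_report <- function(fits) {
  check_columns(fits, c("variant", "beta2", "r2"), "fits")
  fits |>
    dplyr::filter(!is.na(.data$beta2)) |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(
      n_fits = dplyr::n(),
      beta2_mean = mean(.data$beta2),
      beta2_sd = if (dplyr::n() > 1) stats::sd(.data$beta2) else 0,
      beta2_min = min(.data$beta2),
      beta2_max = max(.data$beta2),
      r2_min = min(.data$r2),
      r2_max = max(.data$r2),
      .groups = "drop"
    )
}

#' Compare the exponential model against rejected families
#'
#' Fits linear, logarithmic, cosine and quadratic alternatives alongside the
#' exponential model on one trajectory and reports each family's
#' original-scale R-squared. This is a diagnostic utility for model-family
#' comparison, not a production fitting path. Note that for growth factors
#' close to 1 the exponential curve is locally near-linear, so the
#' alternatives can score deceptively well on short windows; the exponential
#' fit remains the best or tied-best.
#'
#' @inheritParams fit_exponential
#' @return A tibble `family`, `r2`.
#' @export
compare_model_families <- function(traj) {
  check_columns(traj, c("time_h", "area_um2"), "traj")
  t <- traj$time_h
  a <- traj$area_um2
  sstot <- sum((a - mean(a))^2)
  r2_of <- function(pred) if (sstot == 0) 1 else 1 - sum((a - pred)^2) / sstot
  fits <- list(
    exponential = exp(stats::fitted(stats::lm(log(a) ~ t))),
    linear = stats::fitted(stats::lm(a ~ t)),
    logarithmic = stats::fitted(stats::lm(a ~ log(t))),
    cosine = stats::fitted(stats::lm(a ~ cos(pi * t / diff(range(t))))),
    quadratic = stats::fitted(stats::lm(a ~ t + I(t^2)))
  )
  tibble::tibble(family = names(fits),
                 r2 = vapply(fits, r2_of, numeric(1)))
}
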