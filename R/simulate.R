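#' Simulator configuration
#'
#' Parameters of the synthetic zygote cohort generator. Defaults encode the
#' study conditions the pipeline is benchmarked under: a cohort of 155
#' patients with a handful of blastocyst-stage embryos each; pronuclear area
#' growth exponential with hourly growth factor drawn from a truncated
#' normal 1.04 +/- 0.017 on [1.01, 1.11]; the male pronucleus appearing
#' around 6.5-8 h post-ICSI, the female 0.5-1.5 h later, both fading at
#' 20-23 h; frames every 15 min; imaging calibrated at 0.3275 um/pixel;
#' strong between-patient heterogeneity of the area coefficient; and a
#' rank-dependent chromosomal-outcome model
#' `P(normal group) = logistic(alpha + gamma * z)` on the within-patient
#' beta1 z-score. The detector error model mirrors the two observed failure
#' modes: spurious 2PN calls concentrated before 12 h (vacuoles and
#' forming-PN overcalls) and merged detections when the juxtaposed PNs
#' partially overlap after 14 h.
#'
#' @param n_patients Number of patients.
#' @param embryo_lambda Embryos per patient are `2 + Poisson(embryo_lambda)`
#'   (every patient keeps at least two blastocysts so ranking extremes
#'   exist).
#' @param beta1_mean,beta1_between_sd,beta1_within_sd Female beta1
#'   distribution (um^2): patient effect ~ N(mean, between_sd), embryo
#'   deviation ~ N(0, within_sd). The default 75/40 split yields the high
#'   between-patient heterogeneity (I^2 > 90%) that motivates within-patient
#'   ranking, and a 0.75-0.8 female-male beta1 correlation via the shared
#'   patient effect.
#' @param male_size_factor Male-to-female beta1 ratio (male PNs are larger
#'   in the early zygote stage).
#' @param beta2_mean,beta2_sd,beta2_range Truncated-normal growth factor.
#' @param noise_sigma SD of multiplicative lognormal area noise per frame.
#' @param frame_interval_min Frame spacing in minutes.
#' @param male_appear_h,female_delay_h,fade_h Uniform windows (hours) for PN
#'   appearance and fade times.
#' @param scale_um_per_px Pixel calibration for detection tables and
#'   rendering.
#' @param outcome_alpha,outcome_gamma Logistic outcome model on the
#'   within-patient beta1 z-score; the defaults put the expected top-rank
#'   normal-group rate near 58% and the bottom-rank rate near 45% for
#'   typical patient sizes.
#' @param mosaic_share Share of normal-group embryos that are sole-mosaic
#'   rather than fully chromosome-normal.
#' @param overcall_rate_early,overcall_rate_mid Probability that a frame
#'   with fewer than two true PNs before 12 h (respectively 12-14 h) is
#'   spuriously called 2PN.
#' @param vacuole_rate Probability that a true 2PN frame gains a third
#'   vacuole-like detection (exercising the abandonment rule).
#' @param overlap_miss_rate Probability that a true 2PN frame after 14 h
#'   whose PNs overlap is merged into a single detection.
#' @param n_planes,image_px Rendering geometry for [render_zstack()].
#' @param seed Integer seed; everything the simulator emits is a
#'   deterministic function of (config, seed).
#' @return A `pn_sim_config` list.
#' @export
sim_config <- function(n_patients = 155,
                       embryo_lambda = 3.1,
                       beta1_mean = 250, beta1_between_sd = 75,
                       beta1_within_sd = 40,
                       male_size_factor = 1.25,
                       beta2_mean = 1.04, beta2_sd = 0.017,
                       beta2_range = c(1.01, 1.11),
                       noise_sigma = 0.02,
                       frame_interval_min = 15,
                       male_appear_h = c(6.5, 8),
                       female_delay_h = c(0.5, 1.5),
                       fade_h = c(20, 23),
                       scale_um_per_px = 0.3275,
                       outcome_alpha = 0.06, outcome_gamma = 0.23,
                       mosaic_share = 0.30,
                       overcall_rate_early = 0.25,
                       overcall_rate_mid = 0.02,
                       vacuole_rate = 0.01,
                       overlap_miss_rate = 0.1,
                       n_planes = 11, image_px = 256,
                       seed = 1L) {
  stopifnot(
    n_patients >= 1, embryo_lambda >= 0,
    beta1_between_sd >= 0, beta1_within_sd >= 0,
    beta2_sd >= 0, beta2_range[1] < beta2_range[2],
    noise_sigma >= 0, frame_interval_min > 0,
    male_appear_h[1] <= male_appear_h[2],
    female_delay_h[1] <= female_delay_h[2],
    fade_h[1] <= fade_h[2],
    overcall_rate_early >= 0, overcall_rate_early <= 1,
    overcall_rate_mid >= 0, overcall_rate_mid <= 1,
    vacuole_rate >= 0, vacuole_rate <= 1,
    overlap_miss_rate >= 0, overlap_miss_rate <= 1
  )
  if (fade_h[1] <= male_appear_h[2] + female_delay_h[2]) {
    stop("infeasible config: fade window must start after latest appearance",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "pn_sim_config")
}

#' @export
print.pn_sim_config <- function(x, ...) {
  cat("<pn_sim_config>", x$n_patients, "patients, beta2 ~ truncN(",
      x$beta2_mean, ",", x$beta2_sd, "), noise sigma", x$noise_sigma,
      ", seed", x$seed, "\n")
  invisible(x)
}

rtrunc_norm <- function(n, mean, sd, range) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < range[1] | out > range[2])
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < range[1] | out > range[2])
  }
  out
}

#' Draw a beta1 cohort without expanding trajectories
#'
#' The patient/embryo structure and female beta1 draws of
#' [simulate_trajectories()], without the per-frame area series — convenient
#' for large outcome-model simulations where only the coefficients matter.
#'
#' @inheritParams simulate_trajectories
#' @return A tibble `patient_id`, `embryo_id`, `beta1`.
#' @export
simulate_beta1_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "pn_sim_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  n_embryos <- 2 + stats::rpois(config$n_patients, config$embryo_lambda)
  tibble::tibble(
    patient_id = rep(sprintf("P%04d", seq_len(config$n_patients)), n_embryos),
    patient_effect = rep(stats::rnorm(config$n_patients, config$beta1_mean,
                                      config$beta1_between_sd), n_embryos)
  ) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(embryo_id = sprintf("%s-E%02d", .data$patient_id,
                                      dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::mutate(beta1 = pmax(.data$patient_effect +
                                 stats::rnorm(dplyr::n(), 0,
                                              config$beta1_within_sd), 30)) |>
    dplyr::select("patient_id", "embryo_id", "beta1")
}

#' Simulate pronuclear area trajectories for a cohort
#'
#' Draws the patient/embryo structure and per-pronucleus growth parameters,
#' then evaluates `area(t) = beta1 * beta2^t` on the frame grid from each
#' PN's appearance to fade, with multiplicative lognormal measurement noise.
#' The male PN appears earlier and is larger early (its beta1 is scaled by
#' `male_size_factor`); female and male beta1 share the patient effect, so
#' they are strongly correlated across embryos as observed in real cohorts.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list: `trajectories` (tibble `patient_id`, `embryo_id`, `sex`,
#'   `frame_index`, `time_h`, `area_um2`) and `truth` (tibble per embryo and
#'   sex: true `beta1`, `beta2`, `appear_h`, `fade_h`).
#' @export
simulate_trajectories <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "pn_sim_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  n_embryos <- 2 + stats::rpois(config$n_patients, config$embryo_lambda)
  patients <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(config$n_patients)),
    patient_effect = stats::rnorm(config$n_patients, config$beta1_mean,
                                  config$beta1_between_sd),
    n_embryos = n_embryos
  )
  embryos <- patients |>
    tidyr::uncount(.data$n_embryos, .remove = FALSE) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(embryo_id = sprintf("%s-E%02d", .data$patient_id,
                                      dplyr::row_number())) |>
    dplyr::ungroup()
  n <- nrow(embryos)
  # female and male beta1 share the patient effect but carry independent
  # embryo-level deviations; truncated away from zero so areas stay positive
  beta1_f <- pmax(embryos$patient_effect +
                    stats::rnorm(n, 0, config$beta1_within_sd), 30)
  beta1_m <- pmax(embryos$patient_effect +
                    stats::rnorm(n, 0, config$beta1_within_sd), 30) *
    config$male_size_factor
  male_appear <- stats::runif(n, config$male_appear_h[1], config$male_appear_h[2])
  truth <- tibble::tibble(
    patient_id = rep(embryos$patient_id, 2),
    embryo_id = rep(embryos$embryo_id, 2),
    sex = rep(c("female", "male"), each = n),
    beta1 = c(beta1_f, beta1_m),
    beta2 = rtrunc_norm(2 * n, config$beta2_mean, config$beta2_sd,
                        config$beta2_range),
    appear_h = c(male_appear + stats::runif(n, config$female_delay_h[1],
                                            config$female_delay_h[2]),
                 male_appear),
    fade_h = rep(stats::runif(n, config$fade_h[1], config$fade_h[2]), 2)
  )
  dt <- config$frame_interval_min / 60
  trajectories <- truth |>
    dplyr::rowwise() |>
    dplyr::reframe(
      patient_id = .data$patient_id, embryo_id = .data$embryo_id,
      sex = .data$sex,
      frame_index = seq(ceiling(.data$appear_h / dt),
                        floor(.data$fade_h / dt)),
      time_h = .data$frame_index * dt,
      area_um2 = .data$beta1 * .data$beta2^.data$time_h
    ) |>
    dplyr::mutate(area_um2 = .data$area_um2 *
                    exp(stats::rnorm(dplyr::n(), 0, config$noise_sigma)))
  list(trajectories = tibble::as_tibble(trajectories), truth = truth)
}

#' Simulate a detection and annotation table pair
#'
#' Converts true pronuclear states into the per-frame detection rows the
#' tracking stage consumes, injecting the detector's characteristic error
#' modes: early-stage spurious 2PN calls (before both PNs truly exist),
#' occasional vacuole-like third detections on true 2PN frames, and merged
#' single detections when the juxtaposed PNs overlap late. PN centres
#' migrate from the zygote periphery to adjacent positions near the centre.
#' The annotation table carries the true per-frame PN count.
#'
#' @param sim Output of [simulate_trajectories()].
#' @param config The same [sim_config()].
#' @param seed Optional seed for the error-injection draws (default
#'   `config$seed + 1`).
#' @return A list of tibbles: `detections` (`embryo_id`, `frame_index`,
#'   `time_h`, `x_px`, `y_px`, `area_px`, `area_um2`), `annotations` (same
#'   keys plus `pn_count`, `frame_id`), and `auto_counts` (`frame_id`,
#'   `pn_count` as the detector reports them).
#' @export
simulate_detections <- function(sim, config = sim_config(), seed = NULL) {
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  scale <- config$scale_um_per_px
  dt <- config$frame_interval_min / 60
  zygote_r_um <- 55
  shift_um <- 60  # keeps all coordinates positive in the field of view
  jitter_um <- 0.5

  emb <- sim$truth |>
    dplyr::group_by(.data$embryo_id) |>
    dplyr::summarise(
      t0 = min(.data$appear_h), t1 = max(.data$fade_h),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      t_meet = stats::runif(dplyr::n(), 12, 15),  # PNs juxtaposed from here on
      ang = stats::runif(dplyr::n(), 0, 2 * pi),
      sep_ang = stats::runif(dplyr::n(), pi / 3, 2 * pi / 3)
    )

  # PN centres migrate from the periphery until they meet near the centre,
  # after which they stay adjacent (separation ~ sum of current radii), so
  # partial overlap can occur in mid/late stage.
  tr <- sim$trajectories |>
    dplyr::left_join(emb, by = "embryo_id") |>
    dplyr::mutate(r_um = sqrt(.data$area_um2 / pi)) |>
    dplyr::group_by(.data$embryo_id, .data$frame_index) |>
    dplyr::mutate(r_sum_t = sum(.data$r_um)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      start_ang = ifelse(.data$sex == "female", .data$ang,
                         .data$ang + .data$sep_ang),
      frac = pmin(pmax((.data$time_h - .data$t0) /
                         (.data$t_meet - .data$t0), 0), 1),
      x_um = (1 - .data$frac) * 0.7 * zygote_r_um * cos(.data$start_ang) +
        .data$frac * ifelse(.data$sex == "female", -0.5, 0.5) * .data$r_sum_t +
        stats::rnorm(dplyr::n(), 0, jitter_um),
      y_um = (1 - .data$frac) * 0.7 * zygote_r_um * sin(.data$start_ang) +
        stats::rnorm(dplyr::n(), 0, jitter_um)
    )

  pair <- tr |>
    dplyr::group_by(.data$embryo_id, .data$frame_index, .data$time_h) |>
    dplyr::summarise(
      true_count = dplyr::n(),
      dist_um = if (dplyr::n() == 2) {
        sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)
      } else NA_real_,
      r_sum = sum(.data$r_um),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      miss = .data$true_count == 2 & .data$time_h >= 14 &
        !is.na(.data$dist_um) & .data$dist_um < 0.97 * .data$r_sum &
        stats::runif(dplyr::n()) < config$overlap_miss_rate,
      vacuole = .data$true_count == 2 & !.data$miss &
        stats::runif(dplyr::n()) < config$vacuole_rate
    )

  det_true <- tr |>
    dplyr::anti_join(dplyr::filter(pair, .data$miss),
                     by = c("embryo_id", "frame_index")) |>
    dplyr::transmute(
      embryo_id = .data$embryo_id, frame_index = .data$frame_index,
      time_h = .data$time_h,
      x_px = (.data$x_um + shift_um) / scale,
      y_px = (.data$y_um + shift_um) / scale,
      area_um2 = .data$area_um2, sex_true = .data$sex
    )
  det_miss <- tr |>
    dplyr::semi_join(dplyr::filter(pair, .data$miss),
                     by = c("embryo_id", "frame_index")) |>
    dplyr::group_by(.data$embryo_id, .data$frame_index, .data$time_h) |>
    dplyr::summarise(
      x_px = mean((.data$x_um + shift_um) / scale),
      y_px = mean((.data$y_um + shift_um) / scale),
      area_um2 = 0.85 * sum(.data$area_um2),  # merged blob reads smaller than the sum
      .groups = "drop"
    ) |>
    dplyr::mutate(sex_true = NA_character_)
  det_vac <- pair |>
    dplyr::filter(.data$vacuole) |>
    dplyr::transmute(
      embryo_id = .data$embryo_id, frame_index = .data$frame_index,
      time_h = .data$time_h,
      x_px = (shift_um + stats::runif(dplyr::n(), -25, 25)) / scale,
      y_px = (shift_um + stats::runif(dplyr::n(), -25, 25)) / scale,
      area_um2 = stats::runif(dplyr::n(), 60, 150),
      sex_true = NA_character_
    )

  # full frame grid from ICSI (t = 0) to fade, with true counts
  grid <- emb |>
    dplyr::mutate(frame_index = purrr::map2(
      0L, floor(.data$t1 / dt), seq)) |>
    tidyr::unnest("frame_index") |>
    dplyr::mutate(time_h = .data$frame_index * dt) |>
    dplyr::left_join(
      dplyr::select(pair, "embryo_id", "frame_index", "true_count", "miss",
                    "vacuole"),
      by = c("embryo_id", "frame_index")
    ) |>
    dplyr::mutate(
      true_count = dplyr::coalesce(.data$true_count, 0L),
      miss = dplyr::coalesce(.data$miss, FALSE),
      vacuole = dplyr::coalesce(.data$vacuole, FALSE)
    )

  # early-stage spurious 2PN calls on frames with fewer than two true PNs
  rate <- ifelse(grid$time_h < 12, config$overcall_rate_early,
                 ifelse(grid$time_h < 14, config$overcall_rate_mid, 0))
  grid$overcall <- grid$true_count < 2 & stats::runif(nrow(grid)) < rate
  det_spur <- grid |>
    dplyr::filter(.data$overcall) |>
    dplyr::mutate(n_add = 2L - .data$true_count) |>
    tidyr::uncount(.data$n_add) |>
    dplyr::transmute(
      embryo_id = .data$embryo_id, frame_index = .data$frame_index,
      time_h = .data$time_h,
      x_px = (shift_um + stats::runif(dplyr::n(), -30, 30)) / scale,
      y_px = (shift_um + stats::runif(dplyr::n(), -30, 30)) / scale,
      area_um2 = stats::runif(dplyr::n(), 80, 250),
      sex_true = NA_character_
    )

  detections <- dplyr::bind_rows(det_true, det_miss, det_vac, det_spur) |>
    dplyr::arrange(.data$embryo_id, .data$frame_index) |>
    dplyr::mutate(area_px = .data$area_um2 / scale^2) |>
    dplyr::select("embryo_id", "frame_index", "time_h", "x_px", "y_px",
                  "area_px", "area_um2", "sex_true")

  auto <- detections |>
    dplyr::count(.data$embryo_id, .data$frame_index, name = "auto_count")
  annotations <- grid |>
    dplyr::left_join(auto, by = c("embryo_id", "frame_index")) |>
    dplyr::mutate(
      auto_count = dplyr::coalesce(.data$auto_count, 0L),
      frame_id = paste(.data$embryo_id, .data$frame_index, sep = ":")
    )
  list(
    detections = detections,
    annotations = annotations |>
      dplyr::select("embryo_id", "frame_index", "frame_id", "time_h",
                    "pn_count" = "true_count"),
    auto_counts = annotations |>
      dplyr::transmute(frame_id = .data$frame_id,
                       pn_count = .data$auto_count,
                       time_h = .data$time_h)
  )
}

#' Flip sex labels on chosen frames of a sexed track
#'
#' Ground-truth swap injection for benchmarking the cosine-similarity
#' stability rule: the female/male labels of the given retained frames are
#' exchanged, emulating per-frame labelling errors.
#'
#' @param track A sexed `pn_track`.
#' @param frames Frame indices to flip.
#' @return The corrupted track.
#' @export
inject_label_swaps <- function(track, frames) {
  stopifnot(inherits(track, "pn_track"), isTRUE(track$sexed))
  flip <- track$detections$frame_index %in% frames
  track$detections$sex[flip] <-
    ifelse(track$detections$sex[flip] == "male", "female", "male")
  track
}

#' Simulate rank-dependent PGT outcomes
#'
#' Assigns each embryo a chromosomal outcome from the logistic model
#' `P(normal group) = plogis(alpha + gamma * z)` where `z` is the
#' within-patient z-score of the (true) female beta1, then synthesises a
#' PGT result string consistent with the drawn category so the karyotype
#' parser is exercised on generator output. Setting `gamma = 0` gives the
#' null model with no rank-outcome association.
#'
#' @param cohort Tibble with `patient_id`, `embryo_id`, `beta1` (one row per
#'   embryo, female coefficient).
#' @param config A [sim_config()] (fields `outcome_alpha`, `outcome_gamma`,
#'   `mosaic_share`).
#' @param seed Optional seed (default `config$seed + 2`).
#' @return The cohort plus `z`, `normal_group` (logical), `category`,
#'   `pgt_string`.
#' @export
simulate_outcomes <- function(cohort, config = sim_config(), seed = NULL) {
  check_columns(cohort, c("patient_id", "embryo_id", "beta1"), "cohort")
  set.seed(if (is.null(seed)) config$seed + 2L else seed)
  cohort <- cohort |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(z = if (dplyr::n() > 1 && stats::sd(.data$beta1) > 0) {
      (.data$beta1 - mean(.data$beta1)) / stats::sd(.data$beta1)
    } else 0) |>
    dplyr::ungroup()
  p_normal <- stats::plogis(config$outcome_alpha + config$outcome_gamma * cohort$z)
  normal <- stats::runif(nrow(cohort)) < p_normal
  abnormal_cats <- c("sole_aneuploidy", "sole_del_dup",
                     "aneuploidy_with_errors", "euploidy_with_errors",
                     "complex")
  abnormal_probs <- c(0.45, 0.18, 0.15, 0.12, 0.10)
  category <- ifelse(
    normal,
    ifelse(stats::runif(nrow(cohort)) < config$mosaic_share,
           "sole_mosaic", "chromosome_normal"),
    sample(abnormal_cats, nrow(cohort), replace = TRUE, prob = abnormal_probs)
  )
  cohort |>
    dplyr::mutate(
      normal_group = normal,
      category = category,
      pgt_string = unname(vapply(category, synth_pgt_string, character(1)))
    )
}

# Random PGT string realising a target category.
synth_pgt_string <- function(category) {
  chr2 <- function(exclude = NULL) {
    pool <- setdiff(as.character(1:22), exclude)
    sample(pool, 1)
  }
  band <- function() {
    arm <- sample(c("p", "q"), 1)
    sprintf("%s%d.%d%s%d.%d", arm, sample(1:3, 1), sample(1:3, 1),
            arm, sample(2:4, 1) + 1, sample(1:3, 1))
  }
  mb <- function() sprintf("%.1f Mb", stats::runif(1, 1, 60))
  pct <- function() sprintf("%d%%", sample(20:80, 1))
  gain <- function(c) sprintf("+%s(×3)", c)
  loss <- function(c) sprintf("(−%s)", c)
  dup <- function(c) sprintf("dup (%s) (%s) (%s)", c, band(), mb())
  mosw <- function(c) sprintf("+mosaic (%s) (%s)", c, pct())
  switch(category,
    chromosome_normal = "46 XN",
    sole_mosaic = {
      c1 <- chr2()
      if (stats::runif(1) < 0.5) paste0("46XN, ", mosw(c1))
      else sprintf("46 XN, dup (%s) (%s) (%s) (mos, %s)", c1, band(), mb(), pct())
    },
    sole_aneuploidy = {
      c1 <- chr2()
      prefix <- if (stats::runif(1) < 0.5) "47, XN, " else "45, XN, "
      if (startsWith(prefix, "47")) paste0(prefix, gain(c1))
      else paste0(prefix, loss(c1))
    },
    sole_del_dup = paste0("46, XN, ", dup(chr2())),
    aneuploidy_with_errors = {
      c1 <- chr2()
      paste0("47, XN, ", gain(c1), ", ",
             if (stats::runif(1) < 0.5) dup(chr2(c1)) else mosw(chr2(c1)))
    },
    euploidy_with_errors = {
      c1 <- chr2()
      paste0("46, XN, ", dup(c1), ", ", mosw(chr2(c1)))
    },
    complex = {
      c1 <- chr2(); c2 <- chr2(c1); c3 <- chr2(c(c1, c2))
      sprintf("45, XN, %s, %s, %sq (q1%d.1q2%d.1, %s, ×1, mos, %s)",
              loss(c1), dup(c2), c3, sample(1:3, 1), sample(1:3, 1), mb(), pct())
    },
    stop("unknown category: ", category, call. = FALSE)
  )
}

#' Render a single focused zygote frame
#'
#' Draws the zygote as a darker disk on a dim background with the two
#' pronuclei as bright disks whose pixel areas match the requested areas at
#' the rendering scale, plus optional Gaussian sensor noise.
#'
#' @param areas_um2 Named numeric vector `c(female = , male = )` (either may
#'   be omitted); a `vacuole` entry adds a third small disk.
#' @param centres_px Matrix with one `(x, y)` row per area entry, pixel
#'   coordinates; default places the PNs adjacent at the centre.
#' @param image_px Image side length in pixels.
#' @param scale_um_per_px Rendering scale; the default maps a 250 um well
#'   onto the frame width.
#' @param noise_sd Gaussian sensor noise SD (intensity units, image in
#'   [0, 1]).
#' @return An intensity matrix (rows = y, columns = x).
#' @export
render_frame <- function(areas_um2, centres_px = NULL, image_px = 256,
                         scale_um_per_px = 250 / image_px, noise_sd = 0.01) {
  zygote_r_px <- 55 / scale_um_per_px
  if (any(areas_um2 <= 0)) stop("PN areas must be positive", call. = FALSE)
  r_px <- sqrt(areas_um2 / pi) / scale_um_per_px
  if (any(r_px > zygote_r_px)) {
    stop("PN radius exceeds zygote radius at this scale", call. = FALSE)
  }
  mid <- image_px / 2
  if (is.null(centres_px)) {
    offs <- seq_along(r_px)
    centres_px <- cbind(mid + (offs - mean(offs)) * 2.4 * max(r_px), mid)
  }
  xs <- matrix(rep(seq_len(image_px), each = image_px), image_px) # cols = x
  ys <- matrix(rep(seq_len(image_px), image_px), image_px)        # rows = y
  img <- matrix(0.15, image_px, image_px)
  img[(xs - mid)^2 + (ys - mid)^2 <= zygote_r_px^2] <- 0.3
  for (i in seq_along(r_px)) {
    img[(xs - centres_px[i, 1])^2 + (ys - centres_px[i, 2])^2 <= r_px[i]^2] <- 0.9
  }
  if (noise_sd > 0) {
    img <- img + matrix(stats::rnorm(image_px^2, 0, noise_sd), image_px)
  }
  img
}

#' Render a Z-stack with a blur ladder
#'
#' Renders one time point as a stack of focal planes: the plane at
#' `true_plane` is the sharp [render_frame()] image and every other plane is
#' Gaussian-blurred in proportion to its focal distance, emulating defocus,
#' before sensor noise is added. Focal-plane selection on such a stack
#' should recover `true_plane`.
#'
#' @inheritParams render_frame
#' @param n_planes Number of focal planes (offsets -75..75 um when 11).
#' @param true_plane 1-based index of the in-focus plane.
#' @param blur_per_um Defocus blur SD in pixels per micron of focal offset.
#' @return A `pn_zstack` object.
#' @export
render_zstack <- function(areas_um2, n_planes = 11, true_plane = 6,
                          centres_px = NULL, image_px = 256,
                          scale_um_per_px = 250 / image_px, noise_sd = 0.01,
                          blur_per_um = 0.08) {
  stopifnot(true_plane >= 1, true_plane <= n_planes)
  offsets <- default_plane_offsets(n_planes)
  sharp <- render_frame(areas_um2, centres_px, image_px, scale_um_per_px,
                        noise_sd = 0)
  planes <- lapply(seq_len(n_planes), function(k) {
    sigma <- blur_per_um * abs(offsets[k] - offsets[true_plane])
    sigma <- min(sigma, (image_px / 2 - 1) / 3)  # keep the blur brush inside the image
    img <- if (sigma > 0) {
      as.matrix(EBImage::gblur(EBImage::Image(sharp), sigma = sigma))
    } else {
      sharp
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(image_px^2, 0, noise_sd), image_px)
    }
    img
  })
  zstack(planes, plane_offsets_um = offsets)
}
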