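# Shared in-code fixtures for the test suite.

# Binary disk image: background 0, disk(s) of intensity 1.
disk_image <- function(nx = 128, ny = nx, centers, radii, value = 1,
                       background = 0) {
  xs <- matrix(rep(seq_len(nx), each = ny), ny)
  ys <- matrix(rep(seq_len(ny), nx), ny)
  img <- matrix(background, ny, nx)
  for (i in seq_len(nrow(centers))) {
    img[(xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <= radii[i]^2] <- value
  }
  img
}

# Noiseless exponential trajectory.
exp_traj <- function(beta1 = 600, beta2 = 1.04, times = seq(6, 22, 0.25),
                     embryo_id = "E1", sex = "female", noise_sigma = 0) {
  area <- beta1 * beta2^times
  if (noise_sigma > 0) area <- area * exp(rnorm(length(times), 0, noise_sigma))
  tibble::tibble(embryo_id = embryo_id, sex = sex, time_h = times,
                 area_um2 = area)
}

# Detection table for one embryo with two PNs moving on straight paths.
two_pn_detections <- function(n_frames = 40, t0 = 7, dt = 0.25,
                              beta1 = c(female = 500, male = 625),
                              beta2 = c(female = 1.04, male = 1.045),
                              embryo_id = "E1") {
  times <- t0 + dt * (seq_len(n_frames) - 1)
  frames <- round(times / dt)
  purrr::map_dfr(c("female", "male"), function(s) {
    sgn <- if (s == "female") -1 else 1
    tibble::tibble(
      embryo_id = embryo_id,
      frame_index = frames,
      time_h = times,
      x_px = 400 + sgn * (90 - seq_len(n_frames)),  # drifting toward centre
      y_px = 400 + sgn * 5,
      area_um2 = beta1[[s]] * beta2[[s]]^times,
      sex_true = s
    )
  }) |>
    dplyr::arrange(frame_index)
}

# A sexed, linked track built from truth labels (for stability tests).
sexed_track <- function(det = two_pn_detections()) {
  track <- filter_two_pn_frames(det)
  track <- link_identities_for_test(track)
  track$detections$sex <- track$detections$sex_true
  track$sexed <- TRUE
  track
}

link_identities_for_test <- function(track) {
  # go through the exported sexing path but keep truth labels
  getFromNamespace("link_identities", "pnquant")(track)
}

fast_sim_config <- function(...) {
  sim_config(n_patients = 12, embryo_lambda = 2.5, ...)
}
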