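test_that("abandonment keeps exactly-2PN frames and logs the rest", {
  det <- two_pn_detections(n_frames = 5)
  # corrupt frame 1 to 1PN and frame 4 to 3PN
  f <- unique(det$frame_index)
  det <- det[!(det$frame_index == f[1] & det$sex_true == "male"), ]
  extra <- det[det$frame_index == f[4], ][1, ]
  extra$x_px <- extra$x_px + 40
  det <- rbind(det, extra)
  track <- filter_two_pn_frames(det)
  expect_setequal(unique(track$detections$frame_index), f[c(2, 3, 5)])
  expect_equal(nrow(track$discarded), 2)
  expect_setequal(track$discarded$reason, c("1PN", "3PN"))
})

test_that("an all-2PN sequence discards nothing and all-0PN is unanalyzable", {
  det <- two_pn_detections(n_frames = 6)
  track <- filter_two_pn_frames(det)
  expect_equal(nrow(track$discarded), 0)
  expect_true(track$analyzable)

  lone <- tibble::tibble(embryo_id = "E1", frame_index = 1:6,
                         time_h = 7 + 1:6 / 4, x_px = 1, y_px = 1,
                         area_um2 = 100)
  bad <- filter_two_pn_frames(lone)
  expect_false(bad$analyzable)
  expect_equal(nrow(bad$discarded), 6)
})

test_that("earlier appearance assigns the male label", {
  det <- two_pn_detections(n_frames = 10)
  track <- link_identities_for_test(filter_two_pn_frames(det))
  # identity that is truly male appeared 1.5 h before the other
  male_id <- track$detections$pn[track$detections$sex_true == "male"][1]
  other <- setdiff(c("A", "B"), male_id)
  at <- setNames(c(7.0, 8.5), c(male_id, other))
  sexed <- assign_sex(track, appearance_times = at)
  expect_true(all(sexed$detections$sex[sexed$detections$pn == male_id] == "male"))
  expect_true(sexed$sexed)
})

test_that("simultaneous appearance falls back to the early-size rule", {
  det <- two_pn_detections(n_frames = 10,
                           beta1 = c(female = 480, male = 520))
  track <- link_identities_for_test(filter_two_pn_frames(det))
  sexed <- assign_sex(track, appearance_times = c(A = 7, B = 7))
  by_pn <- sexed$detections |>
    dplyr::distinct(pn, sex, sex_true)
  expect_equal(by_pn$sex, by_pn$sex_true)
})

test_that("equal appearance and equal early areas are indistinguishable", {
  det <- two_pn_detections(n_frames = 8,
                           beta1 = c(female = 500, male = 500),
                           beta2 = c(female = 1.04, male = 1.04))
  track <- link_identities_for_test(filter_two_pn_frames(det))
  expect_error(assign_sex(track, appearance_times = c(A = 7, B = 7)),
               "indistinguishable")
})

test_that("a manual sex_override outranks the automatic rules", {
  det <- two_pn_detections(n_frames = 10,
                           beta1 = c(female = 480, male = 520))
  # override claims the smaller PN is male (embryologist correction)
  det$sex_override <- NA_character_
  fem_row <- which(det$sex_true == "female")[1]
  det$sex_override[fem_row] <- "male"
  track <- link_identities_for_test(filter_two_pn_frames(det))
  sexed <- assign_sex(track, appearance_times = c(A = 7, B = 7))
  got <- sexed$detections |> dplyr::distinct(sex, sex_true)
  expect_equal(got$sex[got$sex_true == "female"], "male")
})

test_that("sex assignment is invariant to detection row order", {
  det <- two_pn_detections(n_frames = 12)
  run <- function(d) {
    tr <- assign_sex(link_identities_for_test(filter_two_pn_frames(d)),
                     appearance_times = c(A = 7, B = 7))
    tr$detections |>
      dplyr::arrange(frame_index, sex) |>
      dplyr::pull(sex)
  }
  set.seed(99)
  shuffled <- det[sample(nrow(det)), ]
  expect_identical(run(det), run(shuffled))
})

test_that("consistent labels produce no swaps and cos > 0 throughout", {
  track <- sexed_track()
  out <- enforce_label_stability(track)
  expect_length(out$swap_events, 0)
  expect_equal(nrow(out$detections), nrow(track$detections))
})

test_that("a single flipped frame is swapped back (cos = -1 -> +1)", {
  track <- sexed_track()
  flip_at <- unique(track$detections$frame_index)[5]
  corrupted <- inject_label_swaps(track, flip_at)
  fixed <- enforce_label_stability(corrupted)
  expect_equal(fixed$swap_events, flip_at)
  expect_identical(
    fixed$detections |> dplyr::arrange(frame_index, sex) |> dplyr::pull(sex),
    track$detections |> dplyr::arrange(frame_index, sex) |> dplyr::pull(sex)
  )
})

test_that("injected swaps are recovered exactly in noiseless runs", {
  set.seed(17)
  for (i in 1:5) {
    track <- sexed_track(two_pn_detections(n_frames = 30))
    frames <- unique(track$detections$frame_index)
    inj <- sort(sample(frames[3:28], sample(1:4, 1)))
    # keep injected flips non-adjacent so each is an isolated event
    inj <- inj[c(TRUE, diff(inj) > 1)]
    fixed <- enforce_label_stability(inject_label_swaps(track, inj))
    expect_equal(fixed$swap_events, inj)
    expect_identical(
      fixed$detections |> dplyr::arrange(frame_index, sex) |> dplyr::pull(sex_true),
      fixed$detections |> dplyr::arrange(frame_index, sex) |> dplyr::pull(sex)
    )
  }
})

test_that("after stabilisation every consecutive pair satisfies cos > 0", {
  set.seed(23)
  track <- sexed_track(two_pn_detections(n_frames = 25))
  track <- inject_label_swaps(track, unique(track$detections$frame_index)[c(6, 12)])
  out <- enforce_label_stability(track)
  det <- out$detections |> dplyr::arrange(frame_index)
  by_frame <- split(det, det$frame_index)
  vecs <- vapply(by_frame, function(f) {
    c(f$x_px[f$sex == "male"] - f$x_px[f$sex == "female"],
      f$y_px[f$sex == "male"] - f$y_px[f$sex == "female"])
  }, numeric(2))
  cosines <- vapply(seq_len(ncol(vecs) - 1), function(i) {
    sum(vecs[, i] * vecs[, i + 1]) /
      sqrt(sum(vecs[, i]^2) * sum(vecs[, i + 1]^2))
  }, numeric(1))
  expect_true(all(cosines > 0))
})

test_that("perpendicular and coincident frames are discarded", {
  base <- tibble::tibble(
    embryo_id = "E1",
    frame_index = rep(1:4, each = 2),
    time_h = rep(1:4 / 4 + 7, each = 2),
    x_px = c(0, 10, 0, 10, 5, 5, 0, 10),
    y_px = c(0, 0, 0, 0, -5, 5, 0, 0),
    area_um2 = 500
  )
  track <- filter_two_pn_frames(base)
  track$detections$pn <- rep(c("A", "B"), 4)
  track$detections$sex <- rep(c("female", "male"), 4)
  track$sexed <- TRUE
  # frame 3's vector is perpendicular to frame 2's -> discarded either way
  out <- enforce_label_stability(track)
  expect_true(any(out$discarded$reason == "stability"))
  expect_false(3 %in% out$detections$frame_index)

  coinc <- track
  coinc$detections$x_px[5:6] <- 5
  coinc$detections$y_px[5:6] <- 0
  out2 <- enforce_label_stability(coinc)
  expect_true(any(out2$discarded$reason == "coincident"))
})

test_that("trajectories carry one point per retained frame and sex", {
  det <- two_pn_detections(n_frames = 43)
  f <- unique(det$frame_index)
  det <- det[!(det$frame_index %in% f[1:3] & det$sex_true == "male"), ]
  res <- track_embryo(det)
  traj <- res$trajectories
  expect_equal(nrow(traj), 2 * 40)
  expect_true(all(table(traj$sex) == 40))
  expect_true(all(diff(traj$time_h[traj$sex == "female"]) > 0))
  empty_track <- filter_two_pn_frames(two_pn_detections(n_frames = 5)[0, ])
  empty_track$sexed <- TRUE
  expect_error(build_area_trajectories(empty_track), "empty track")
})

test_that("single-PN frames before the first 2PN frame set appearance times", {
  det <- two_pn_detections(n_frames = 20, t0 = 8)
  # male PN alone for 4 frames before the 2PN stage
  male_first <- det[det$sex_true == "male", ][1, ]
  early <- purrr::map_dfr(1:4, function(k) {
    r <- male_first
    r$frame_index <- r$frame_index - 5 + k
    r$time_h <- r$time_h - (5 - k) * 0.25
    r
  })
  res <- track_embryo(rbind(early, det))
  got <- res$track$detections |> dplyr::distinct(sex, sex_true)
  expect_equal(got$sex, got$sex_true)
})
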