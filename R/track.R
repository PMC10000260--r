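#' Keep only clean 2PN frames (abandonment mechanism)
#'
#' Frames whose detection count differs from 2 (0, 1, 3 or more pronuclei,
#' e.g. a vacuole mislabelled as a PN, or two overlapping PNs merged into
#' one) are discarded from the sequence and logged with the offending count;
#' only exact-2PN frames take part in tracking and growth fitting.
#'
#' @param detections Detection tibble for one embryo (columns `embryo_id`,
#'   `frame_index`, `time_h`, `x_px`, `y_px` and `area_px` and/or `area_um2`).
#' @param min_frames Minimum retained frames for the embryo to be analyzable
#'   (default 4, the minimum the growth fit accepts).
#' @return A `pn_track` object: list with `embryo_id`, `detections` (retained
#'   rows), `discarded` (tibble `frame_index`, `time_h`, `reason`),
#'   `analyzable`, `sexed`, `swap_events`.
#' @export
filter_two_pn_frames <- function(detections, min_frames = 4) {
  check_columns(detections, c("embryo_id", "frame_index", "time_h",
                              "x_px", "y_px"), "detections")
  if (!"area_um2" %in% names(detections) && !"area_px" %in% names(detections)) {
    stop("detections need an area_px or area_um2 column", call. = FALSE)
  }
  if (length(unique(detections$embryo_id)) > 1) {
    stop("filter_two_pn_frames expects detections of a single embryo",
         call. = FALSE)
  }
  counts <- detections |>
    dplyr::count(.data$frame_index, .data$time_h, name = "pn_count")
  bad <- dplyr::filter(counts, .data$pn_count != 2)
  discarded <- tibble::tibble(
    frame_index = bad$frame_index,
    time_h = bad$time_h,
    reason = paste0(bad$pn_count, "PN")
  )
  kept <- detections |>
    dplyr::semi_join(dplyr::filter(counts, .data$pn_count == 2),
                     by = "frame_index") |>
    dplyr::arrange(.data$time_h, .data$frame_index)
  n_kept <- length(unique(kept$frame_index))
  structure(
    list(
      embryo_id = detections$embryo_id[1],
      detections = kept,
      discarded = discarded,
      analyzable = n_kept >= min_frames,
      sexed = FALSE,
      swap_events = integer(0)
    ),
    class = "pn_track"
  )
}

#' @export
print.pn_track <- function(x, ...) {
  cat("<pn_track> embryo", x$embryo_id, "-",
      length(unique(x$detections$frame_index)), "retained frames,",
      nrow(x$discarded), "discarded,",
      if (x$sexed) "sexed" else "unsexed",
      if (length(x$swap_events)) paste0("(", length(x$swap_events), " swaps)") else "",
      "\n")
  invisible(x)
}

# Link the two detections of each retained frame into continuous identities
# "A"/"B" by nearest-centroid matching to the previous frame. PN displacement
# per 10-15 min frame is far smaller than the inter-PN distance, so greedy
# per-frame matching is sufficient.
link_identities <- function(track) {
  det <- track$detections
  if (nrow(det) == 0) {
    track$detections <- dplyr::mutate(det, pn = character(0))
    return(track)
  }
  frames <- split(det, factor(det$frame_index, levels = unique(det$frame_index)))
  prev <- NULL
  linked <- lapply(frames, function(f) {
    f <- dplyr::arrange(f, .data$x_px, .data$y_px)
    if (is.null(prev)) {
      f$pn <- c("A", "B")
    } else {
      d_straight <- (f$x_px - prev$x_px)^2 + (f$y_px - prev$y_px)^2
      d_crossed <- (f$x_px - rev(prev$x_px))^2 + (f$y_px - rev(prev$y_px))^2
      f$pn <- if (sum(d_straight) <= sum(d_crossed)) prev$pn else rev(prev$pn)
    }
    prev <<- f
    f
  })
  track$detections <- dplyr::bind_rows(linked)
  track
}

#' Assign female/male labels to the two pronuclear identities
#'
#' Applies the two automatic sexing rules in their order of precedence:
#' the male pronucleus appears earlier, and, when appearance times cannot be
#' told apart (difference below one frame interval), the male pronucleus is
#' the larger one over the first `early_window` retained frames. The
#' polar-body proximity rule is manual-only; a `sex_override` column on the
#' detections (an embryologist's correction) trumps both automatic rules.
#'
#' @param track A `pn_track` (identities are linked internally if needed).
#' @param appearance_times Named numeric vector `c(A = , B = )` of first-seen
#'   times in hours for the two identities, e.g. from pre-2PN single
#'   detection frames or simulator truth. Defaults to each identity's first
#'   retained time (forcing the size rule when those coincide).
#' @param early_window Number of initial retained frames over which early
#'   mean areas are compared (default 5).
#' @return The track with a `sex` column (`female`/`male`) on every retained
#'   detection and `sexed = TRUE`.
#' @export
assign_sex <- function(track, appearance_times = NULL, early_window = 5) {
  stopifnot(inherits(track, "pn_track"))
  if (!track$analyzable) stop("embryo ", track$embryo_id, " is unanalyzable",
                              call. = FALSE)
  if (!"pn" %in% names(track$detections)) track <- link_identities(track)
  det <- track$detections
  if (!"area_um2" %in% names(det)) det$area_um2 <- area_to_microns(det$area_px)

  male_pn <- NULL
  if ("sex_override" %in% names(det) && any(!is.na(det$sex_override))) {
    ov <- det[!is.na(det$sex_override), ][1, ]
    male_pn <- if (ov$sex_override == "male") ov$pn else setdiff(c("A", "B"), ov$pn)
  }

  times <- sort(unique(det$time_h))
  interval <- if (length(times) > 1) stats::median(diff(times)) else 0.25

  if (is.null(male_pn)) {
    first_seen <- if (!is.null(appearance_times)) {
      appearance_times[c("A", "B")]
    } else {
      c(A = min(det$time_h[det$pn == "A"]), B = min(det$time_h[det$pn == "B"]))
    }
    if (abs(first_seen[["A"]] - first_seen[["B"]]) >= interval) {
      male_pn <- names(which.min(first_seen))
    } else {
      early_frames <- utils::head(unique(det$frame_index), early_window)
      early <- det |>
        dplyr::filter(.data$frame_index %in% early_frames) |>
        dplyr::group_by(.data$pn) |>
        dplyr::summarise(mean_area = mean(.data$area_um2), .groups = "drop")
      if (diff(range(early$mean_area)) == 0) {
        stop("indistinguishable male/female PNs for embryo ", track$embryo_id,
             ": equal appearance times and equal early areas", call. = FALSE)
      }
      male_pn <- early$pn[which.max(early$mean_area)]
    }
  }
  det$sex <- ifelse(det$pn == male_pn, "male", "female")
  track$detections <- det
  track$sexed <- TRUE
  track
}

#' Enforce label stability with the cosine-similarity rule
#'
#' Per-frame sexing can still flip labels on individual frames. For every
#' consecutive pair of retained frames the cosine between the female-to-male
#' centre vectors is computed; the rule demands strictly `cos(theta) > 0`.
#' A failing frame has its labels swapped (reversing its vector) and is
#' re-checked; a frame failing both labelings (exactly perpendicular
#' vectors) is discarded with reason `"stability"`, and coincident PN
#' centres (zero-length vector) discard the frame with reason
#' `"coincident"`. Corrections are recorded in `swap_events` and each
#' subsequent pair is re-evaluated against the corrected frame, so a
#' persistent identity exchange is rolled forward frame by frame.
#'
#' @param track A sexed `pn_track`.
#' @return The track with stabilised labels, updated `discarded` and
#'   `swap_events`.
#' @export
enforce_label_stability <- function(track) {
  stopifnot(inherits(track, "pn_track"))
  if (!isTRUE(track$sexed)) stop("track must be sexed first", call. = FALSE)
  det <- track$detections
  frame_ids <- unique(det$frame_index)
  if (length(frame_ids) < 2) return(track)

  fm_vector <- function(f) {
    c(f$x_px[f$sex == "male"] - f$x_px[f$sex == "female"],
      f$y_px[f$sex == "male"] - f$y_px[f$sex == "female"])
  }
  frames <- split(det, factor(det$frame_index, levels = frame_ids))
  kept <- list()
  dropped <- list()
  swaps <- integer(0)
  prev_v <- NULL
  for (f in frames) {
    v <- fm_vector(f)
    if (sqrt(sum(v^2)) == 0) {
      dropped[[length(dropped) + 1]] <- tibble::tibble(
        frame_index = f$frame_index[1], time_h = f$time_h[1],
        reason = "coincident")
      next
    }
    if (!is.null(prev_v)) {
      cos_th <- sum(prev_v * v) / (sqrt(sum(prev_v^2)) * sqrt(sum(v^2)))
      if (cos_th <= 0) {
        if (-cos_th > 0) { # swapping reverses the vector, so cos flips sign
          f$sex <- ifelse(f$sex == "male", "female", "male")
          v <- -v
          swaps <- c(swaps, f$frame_index[1])
        } else {
          dropped[[length(dropped) + 1]] <- tibble::tibble(
            frame_index = f$frame_index[1], time_h = f$time_h[1],
            reason = "stability")
          next
        }
      }
    }
    kept[[length(kept) + 1]] <- f
    prev_v <- v
  }
  track$detections <- dplyr::bind_rows(kept)
  track$discarded <- dplyr::bind_rows(track$discarded, dplyr::bind_rows(dropped))
  track$swap_events <- swaps
  track
}

#' Extract the two sex-labelled area trajectories
#'
#' @param track A sexed (and normally stabilised) `pn_track`.
#' @return A tibble `embryo_id`, `sex`, `time_h`, `area_um2`, strictly
#'   time-ordered within each sex; one point per retained frame and sex.
#' @export
build_area_trajectories <- function(track) {
  stopifnot(inherits(track, "pn_track"))
  if (!isTRUE(track$sexed)) stop("track must be sexed first", call. = FALSE)
  det <- track$detections
  if (nrow(det) == 0) stop("empty track: no retained frames", call. = FALSE)
  if (!"area_um2" %in% names(det)) det$area_um2 <- area_to_microns(det$area_px)
  det |>
    dplyr::arrange(.data$sex, .data$time_h) |>
    dplyr::select("embryo_id", "sex", "time_h", "area_um2") |>
    tibble::as_tibble()
}

#' Track one embryo from detections to trajectories
#'
#' Convenience chain: abandonment filter, identity linking, sexing, cosine
#' stability, trajectory extraction. Appearance times are inferred from
#' single-detection frames preceding the first 2PN frame when present (the
#' lone early pronucleus is matched to an identity by nearest centroid).
#'
#' @inheritParams filter_two_pn_frames
#' @inheritParams assign_sex
#' @param scale_um_per_px Pixel scale used when only `area_px` is present.
#' @return A list with `track` (the final `pn_track`) and `trajectories`
#'   (the [build_area_trajectories()] tibble).
#' @export
track_embryo <- function(detections, scale_um_per_px = 0.3275,
                         appearance_times = NULL, early_window = 5,
                         min_frames = 4) {
  if (!"area_um2" %in% names(detections) && "area_px" %in% names(detections)) {
    detections$area_um2 <- area_to_microns(detections$area_px, scale_um_per_px)
  }
  track <- filter_two_pn_frames(detections, min_frames = min_frames)
  if (!track$analyzable) {
    return(list(track = track, trajectories = NULL))
  }
  track <- link_identities(track)
  if (is.null(appearance_times)) {
    appearance_times <- infer_appearance_times(detections, track)
  }
  track <- assign_sex(track, appearance_times = appearance_times,
                      early_window = early_window)
  track <- enforce_label_stability(track)
  list(track = track, trajectories = build_area_trajectories(track))
}

# First-seen time per linked identity, using single-detection frames that
# precede the first retained 2PN frame: the lone pronucleus visible there is
# matched to identity A or B by proximity to the first 2PN frame's centres.
infer_appearance_times <- function(detections, linked_track) {
  det <- linked_track$detections
  first2 <- det[det$frame_index == det$frame_index[1], ]
  first_seen <- c(A = min(first2$time_h), B = min(first2$time_h))
  counts <- table(detections$frame_index)
  singles <- detections[detections$frame_index %in%
                          names(counts)[counts == 1] &
                          detections$time_h < min(first2$time_h), , drop = FALSE]
  if (nrow(singles) > 0) {
    s <- singles[which.min(singles$time_h), ]
    d2 <- (first2$x_px - s$x_px)^2 + (first2$y_px - s$y_px)^2
    id <- first2$pn[which.min(d2)]
    first_seen[[id]] <- s$time_h
  }
  first_seen
}
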