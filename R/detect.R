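#' Baseline pronucleus detector
#'
#' Classical segmentation stand-in for a learned instance-segmentation
#' detector: Gaussian smoothing, Otsu thresholding, connected-component
#' labelling, then area and circularity filters. It is deterministic and
#' adequate for the bright, roughly circular pronuclei of rendered or other
#' high-contrast zygote imagery; clinical users with a trained detector can
#' bypass it entirely and ingest detection tables (see [read_detections()]).
#'
#' Circularity is \eqn{4\pi A / P^2} from the component's pixel area and
#' boundary-pixel perimeter; a perfect disk scores close to 1.
#'
#' @param image Numeric intensity matrix (rows = y, columns = x).
#' @param params Detector settings from [detector_params()].
#' @return A tibble with one row per detection: `x_px`, `y_px` (centroid,
#'   1-based pixel coordinates: x along columns, y along rows), `area_px`,
#'   `circularity`. Zero rows when nothing passes the filters; a degenerate
#'   image with zero dynamic range yields zero rows with a warning.
#' @examples
#' img <- matrix(0, 64, 64)
#' img[as.matrix(expand.grid(y = 1:64, x = 1:64))[
#'   (rep(1:64, 64) - 32)^2 + (rep(1:64, each = 64) - 32)^2 <= 10^2, ]] <- 1
#' detect_pronuclei(img)
#' @export
detect_pronuclei <- function(image, params = detector_params()) {
  image <- as_gray_matrix(image)
  rng <- range(image)
  empty <- tibble::tibble(x_px = numeric(), y_px = numeric(),
                          area_px = numeric(), circularity = numeric())
  if (diff(rng) == 0) {
    warning("degenerate image with zero dynamic range: no detections",
            call. = FALSE)
    return(empty)
  }
  norm <- (image - rng[1]) / diff(rng)
  # EBImage works on [x, y] arrays; transpose so x follows columns of `image`
  img <- EBImage::Image(t(norm))
  if (params$sigma > 0) img <- EBImage::gblur(img, sigma = params$sigma)
  thr <- EBImage::otsu(img, range = c(0, 1))
  mask <- img > thr
  labels <- EBImage::bwlabel(mask)
  n <- max(labels)
  if (n == 0) return(empty)
  shape <- EBImage::computeFeatures.shape(labels)
  moments <- EBImage::computeFeatures.moment(labels, t(norm))
  # Otsu under-thresholds a blurred step edge, inflating areas; re-measure
  # each component at half-maximum (midpoint of plateau and surround), the
  # area-preserving level for a symmetric edge profile.
  lab <- as.matrix(EBImage::imageData(labels))
  smooth <- as.matrix(EBImage::imageData(img))
  ring_brush <- EBImage::makeBrush(15, shape = "disc")
  area_hm <- vapply(seq_len(n), function(i) {
    comp <- lab == i
    ring <- as.matrix(EBImage::imageData(
      EBImage::dilate(EBImage::Image(comp), ring_brush))) > 0 & !comp
    # lower quartile: robust to the blur skirt adjacent to the component
    bg_level <- if (any(ring)) stats::quantile(smooth[ring], 0.25, names = FALSE) else 0
    inside <- smooth[comp]
    halfmax <- (stats::quantile(inside, 0.95, names = FALSE) + bg_level) / 2
    if (thr >= halfmax) length(inside) else sum(inside >= halfmax)
  }, numeric(1))
  out <- tibble::tibble(
    x_px = as.numeric(moments[, "m.cx"]),
    y_px = as.numeric(moments[, "m.cy"]),
    area_px = area_hm,
    circularity = 4 * pi * as.numeric(shape[, "s.area"]) /
      pmax(as.numeric(shape[, "s.perimeter"]), 1)^2
  )
  out |>
    dplyr::filter(
      .data$area_px >= params$min_area_px,
      .data$area_px <= params$max_area_px,
      .data$circularity >= params$min_circularity
    )
}

#' Detector settings
#'
#' @param sigma Gaussian smoothing SD in pixels before thresholding.
#' @param min_area_px,max_area_px Area gate in pixels.
#' @param min_circularity Minimum \eqn{4\pi A/P^2}; raster perimeters make
#'   near-perfect disks score around 0.9-1.1, so 0.7 rejects elongated debris
#'   while keeping slightly blurred pronuclei.
#' @return A named list of settings.
#' @export
detector_params <- function(sigma = 2, min_area_px = 60, max_area_px = 20000,
                            min_circularity = 0.7) {
  stopifnot(sigma >= 0, min_area_px > 0, max_area_px >= min_area_px,
            min_circularity >= 0)
  list(sigma = sigma, min_area_px = min_area_px, max_area_px = max_area_px,
       min_circularity = min_circularity)
}

#' Convert pixel area to square microns
#'
#' @param area_px Positive pixel area(s).
#' @param scale_um_per_px Positive scale; the default 0.3275 um/pixel is the
#'   calibration of the EmbryoScope time-lapse imagery this method targets.
#' @return `area_px * scale_um_per_px^2`, in square microns.
#' @examples
#' area_to_microns(1)            # 0.10725625
#' area_to_microns(4662, 0.3275) # about 500 um^2
#' @export
area_to_microns <- function(area_px, scale_um_per_px = 0.3275) {
  if (any(!is.finite(area_px)) || any(area_px <= 0)) {
    stop("area_px must be positive and finite", call. = FALSE)
  }
  if (!is.finite(scale_um_per_px) || scale_um_per_px <= 0) {
    stop("scale_um_per_px must be positive", call. = FALSE)
  }
  area_px * scale_um_per_px^2
}

#' Score automatic 2PN recognition against annotation
#'
#' Compares automatic per-frame pronucleus counts with annotated truth on a
#' shared frame set and summarises the three outcomes of 2PN-stage
#' recognition: frames both call 2PN (`correct_2pn`), frames auto-called 2PN
#' that annotation says are not (`overestimated`, e.g. early-stage vacuole
#' overcalls), and annotated 2PN frames the detector did not call 2PN
#' (`missed`, e.g. partial PN overlap). Accuracy is
#' `correct / (correct + overestimated + missed)`.
#'
#' @param auto Data frame with columns `frame_id`, `pn_count` (automatic).
#' @param annotated Data frame with the same columns (truth); may carry a
#'   `time_h` column used by `window`.
#' @param window Optional lower time bound in hours: only frames with
#'   `time_h >= window` are scored (e.g. 12 or 14 to reproduce the late-stage
#'   accuracy windows). Requires `time_h` on `annotated`.
#' @return A one-row tibble: `correct_2pn`, `overestimated`, `missed`,
#'   `accuracy`.
#' @export
evaluate_recognition <- function(auto, annotated, window = NULL) {
  check_columns(auto, c("frame_id", "pn_count"), "auto")
  check_columns(annotated, c("frame_id", "pn_count"), "annotated")
  joined <- dplyr::inner_join(
    auto |> dplyr::select("frame_id", auto_count = "pn_count"),
    annotated |> dplyr::rename(true_count = "pn_count"),
    by = "frame_id"
  )
  if (!is.null(window)) {
    check_columns(annotated, "time_h", "annotated (when window is used)")
    joined <- dplyr::filter(joined, .data$time_h >= window)
  }
  if (nrow(joined) == 0) {
    stop("no frames shared between auto and annotated tables", call. = FALSE)
  }
  recognition_counts(
    correct_2pn = sum(joined$auto_count == 2 & joined$true_count == 2),
    overestimated = sum(joined$auto_count == 2 & joined$true_count != 2),
    missed = sum(joined$auto_count != 2 & joined$true_count == 2)
  )
}

#' Recognition accuracy from raw outcome counts
#'
#' The count-level form of [evaluate_recognition()], for when the per-frame
#' tables are not available but the three outcome totals are (as in a
#' published confusion summary).
#'
#' @param correct_2pn,overestimated,missed Non-negative integers.
#' @return A one-row tibble: the three counts and `accuracy`.
#' @export
recognition_counts <- function(correct_2pn, overestimated, missed) {
  stopifnot(correct_2pn >= 0, overestimated >= 0, missed >= 0)
  denom <- correct_2pn + overestimated + missed
  tibble::tibble(
    correct_2pn = correct_2pn,
    overestimated = overestimated,
    missed = missed,
    accuracy = if (denom == 0) NA_real_ else correct_2pn / denom
  )
}

#' Read a pronucleus detection table
#'
#' Detection tables let a trained external detector (for example an
#' instance-segmentation network) feed the pipeline directly, bypassing the
#' baseline image detector. Expected columns: `embryo_id`, `frame_index`,
#' `time_h`, `x_px`, `y_px`, `area_px`; an optional `sex_override` column
#' (values `female`/`male`) is honoured downstream as a manual embryologist
#' correction. Annotation tables share the schema plus `pn_count`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_detections <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("embryo_id", "frame_index", "time_h", "x_px", "y_px",
                      "area_px"), basename(path))
  df
}
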