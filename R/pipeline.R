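#' Quantify pronuclear growth for a cohort
#'
#' End-to-end quantification stage: per embryo, abandonment filtering,
#' identity linking, female/male assignment, cosine-similarity label
#' stability, trajectory extraction and variant growth fits — in that
#' order. Input is either a detection table (image-free mode, e.g. from an
#' external detector or [simulate_detections()]) or a simulator
#' configuration.
#'
#' @param detections Detection table (see [read_detections()] for the
#'   schema). `area_um2` is computed from `area_px` at `scale_um_per_px`
#'   when absent.
#' @param scale_um_per_px Pixel calibration.
#' @param variants Coefficient variants to fit.
#' @param min_frames Abandonment threshold below which an embryo is
#'   unanalyzable.
#' @return A list: `fits` (tibble of per-embryo/sex/variant fits),
#'   `discards` (frame discard log with reasons), `swaps` (per-embryo swap
#'   events), `unanalyzable` (embryo ids), `manifest` (run metadata).
#' @export
run_quantify <- function(detections, scale_um_per_px = 0.3275,
                         variants = c("original", "adjusted", "h12", "h14"),
                         min_frames = 4) {
  check_columns(detections, c("embryo_id", "frame_index", "time_h",
                              "x_px", "y_px"), "detections")
  per_embryo <- split(detections, detections$embryo_id)
  results <- purrr::imap(per_embryo, function(det, eid) {
    tryCatch(
      {
        tr <- track_embryo(det, scale_um_per_px = scale_um_per_px,
                           min_frames = min_frames)
        if (is.null(tr$trajectories)) {
          list(fits = NULL, discards = tr$track$discarded |>
                 dplyr::mutate(embryo_id = eid),
               swaps = NULL, unanalyzable = eid)
        } else {
          list(
            fits = fit_growth(tr$trajectories, variants = variants),
            discards = tr$track$discarded |> dplyr::mutate(embryo_id = eid),
            swaps = if (length(tr$track$swap_events)) {
              tibble::tibble(embryo_id = eid,
                             frame_index = tr$track$swap_events)
            } else NULL,
            unanalyzable = NULL
          )
        }
      },
      error = function(e) {
        msg <- conditionMessage(e)
        if (grepl("indistinguishable", msg)) {
          # mirror the clinical exclusion of embryos whose PNs cannot be sexed
          list(fits = NULL, discards = NULL, swaps = NULL, unanalyzable = eid)
        } else {
          stop("quantification failed for embryo ", eid, ": ", msg,
               call. = FALSE)
        }
      }
    )
  })
  list(
    fits = purrr::map_dfr(results, "fits"),
    discards = purrr::map_dfr(results, "discards"),
    swaps = purrr::map_dfr(results, "swaps"),
    unanalyzable = unlist(purrr::map(results, "unanalyzable"),
                          use.names = FALSE),
    manifest = run_manifest(list(scale_um_per_px = scale_um_per_px,
                                 variants = variants,
                                 min_frames = min_frames))
  )
}

#' Rank statistics report for fitted coefficients and PGT outcomes
#'
#' Joins the growth fits with classified PGT results and computes the
#' statistical battery per coefficient variant: within-patient beta1
#' ranking, per-rank normal-group rate table, top-versus-bottom Woolf odds
#' ratios (k = 1 and k = 2), Spearman correlation between rank and outcome
#' rate, plus a single Cochran heterogeneity test of beta1 across patients.
#'
#' @param fits Fits tibble from [run_quantify()] / [fit_growth()] (the
#'   female PN rows are used for ranking).
#' @param pgt PGT table with `embryo_id`, `pgt_string`, `patient_id` (see
#'   [classify_pgt()]); pre-classified tables with `normal_group` are
#'   accepted as-is.
#' @param sex Which PN's coefficient to rank on (default `"female"`).
#' @param pool_after Rank pooling threshold K for the rate tables.
#' @return A list: `rank_tables` (named by variant), `odds_ratios` (tibble
#'   over variant and k), `spearman` (tibble per variant), `heterogeneity`
#'   (one row), `ranked` (the per-variant ranked embryo tibble).
#' @export
run_stats <- function(fits, pgt, sex = "female", pool_after = 8) {
  check_columns(fits, c("embryo_id", "sex", "variant", "beta1"), "fits")
  if (!"normal_group" %in% names(pgt)) pgt <- classify_pgt(pgt)
  check_columns(pgt, c("embryo_id", "normal_group"), "pgt")

  fem <- fits |>
    dplyr::filter(.data$sex == !!sex, !is.na(.data$beta1))
  pgt_cols <- c("normal_group", "category",
                if (!"patient_id" %in% names(fem)) "patient_id")
  joined <- dplyr::inner_join(
    fem,
    dplyr::select(pgt, "embryo_id", dplyr::any_of(pgt_cols)),
    by = "embryo_id"
  )
  orphans <- setdiff(fem$embryo_id, pgt$embryo_id)
  if (length(orphans) > 0) {
    stop("embryos missing from the PGT table: ",
         paste(utils::head(orphans, 5), collapse = ", "),
         if (length(orphans) > 5) " ..." else "", call. = FALSE)
  }
  if (!"patient_id" %in% names(joined)) {
    stop("a patient_id column is required (on fits or pgt)", call. = FALSE)
  }

  variants <- unique(joined$variant)
  ranked <- purrr::map(
    rlang::set_names(variants),
    function(v) {
      joined |>
        dplyr::filter(.data$variant == v) |>
        rank_within_patient(pool_after = pool_after)
    })
  rank_tables <- purrr::map(ranked, rank_rate_table)
  single_patient <- all(purrr::map_int(
    ranked, ~ length(unique(.x$patient_id))) <= 1)
  odds_ratios <- if (single_patient) {
    tibble::tibble()
  } else {
    purrr::map_dfr(
      rlang::set_names(variants),
      function(v) {
        purrr::map_dfr(c(1, 2), function(k) {
          dplyr::mutate(rank_extreme_or(ranked[[v]], k = k), k = k)
        })
      },
      .id = "variant"
    )
  }
  spearman <- purrr::map_dfr(
    rlang::set_names(variants),
    function(v) {
      rt <- rank_tables[[v]]
      if (nrow(rt) < 3) {
        return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                              n = nrow(rt), defined = FALSE))
      }
      # negative rank order so positive rho = higher rate at better rank
      spearman_rank_corr(-seq_len(nrow(rt)), rt$rate_pct)
    },
    .id = "variant"
  )
  het <- joined |>
    dplyr::filter(.data$variant == variants[1]) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(mean = mean(.data$beta1), sd = stats::sd(.data$beta1),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n >= 2)
  heterogeneity <- if (nrow(het) >= 2) cochran_heterogeneity(het) else NULL

  list(rank_tables = rank_tables, odds_ratios = odds_ratios,
       spearman = spearman, heterogeneity = heterogeneity, ranked = ranked,
       manifest = run_manifest(list(sex = sex, pool_after = pool_after)))
}

run_manifest <- function(config) {
  list(
    package = "pnquant",
    version = as.character(utils::packageVersion("pnquant")),
    config = config,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}

#' Write a stats report bundle to disk
#'
#' Serialises a [run_stats()] result as CSV files plus one JSON summary in
#' `dir`.
#'
#' @param stats A [run_stats()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_stats_bundle <- function(stats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (v in names(stats$rank_tables)) {
    p <- file.path(dir, paste0("rank_table_", v, ".csv"))
    readr::write_csv(stats$rank_tables[[v]], p)
    paths <- c(paths, p)
  }
  if (nrow(stats$odds_ratios) > 0) {
    p <- file.path(dir, "odds_ratios.csv")
    readr::write_csv(stats$odds_ratios, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(
      spearman = stats$spearman,
      heterogeneity = stats$heterogeneity,
      manifest = stats$manifest
    ),
    p, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  paths <- c(paths, p)
  invisible(paths)
}
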