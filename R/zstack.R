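#' Variance-of-Laplacian sharpness score
#'
#' Scores the sharpness (focus) of a grayscale image as the population
#' variance of its discrete Laplacian response. The Laplacian is computed
#' with the standard 4-neighbour kernel `[[0,1,0],[1,-4,1],[0,1,0]]`; the
#' one-pixel image border, where the kernel does not fit, is excluded from
#' the variance rather than padded. Blurred images have weak high-frequency
#' content and hence low Laplacian variance, so the score is maximal at the
#' best-focused plane of a Z-stack.
#'
#' The score is zero for a constant image, invariant under adding a constant
#' to all pixels, and scales as \eqn{c^2} when intensities are scaled by
#' \eqn{c}.
#'
#' @param image Numeric matrix of pixel intensities (rows = y, columns = x),
#'   at least 3x3. A 3-D array with a third colour dimension is converted to
#'   luma grayscale (0.299 R + 0.587 G + 0.114 B) first.
#' @return A single non-negative number.
#' @examples
#' laplacian_sharpness(matrix(1, 5, 5)) # flat field -> 0
#' img <- matrix(0, 5, 5); img[3, 3] <- 1
#' laplacian_sharpness(img)
#' @export
laplacian_sharpness <- function(image) {
  image <- as_gray_matrix(image)
  if (nrow(image) < 3 || ncol(image) < 3) {
    stop("image must be at least 3x3 pixels for the Laplacian kernel, got ",
         nrow(image), "x", ncol(image), call. = FALSE)
  }
  bad <- which(!is.finite(image), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-finite pixel at row %d, column %d", bad[1, 1], bad[1, 2]),
         call. = FALSE)
  }
  nr <- nrow(image); nc <- ncol(image)
  core <- image[2:(nr - 1), 2:(nc - 1), drop = FALSE]
  resp <- image[1:(nr - 2), 2:(nc - 1), drop = FALSE] +
    image[3:nr, 2:(nc - 1), drop = FALSE] +
    image[2:(nr - 1), 1:(nc - 2), drop = FALSE] +
    image[2:(nr - 1), 3:nc, drop = FALSE] -
    4 * core
  mean((resp - mean(resp))^2)
}

#' Select the clearest plane of a Z-stack
#'
#' Scores every focal plane with [laplacian_sharpness()] and returns the
#' plane with the maximal score. Ties are broken by the lowest plane index so
#' reruns are deterministic.
#'
#' @param planes A list of intensity matrices (ordered by focal offset), or a
#'   `pn_zstack` object as returned by [zstack()].
#' @return A list with `index` (1-based plane index), `image` (the selected
#'   matrix) and `sharpness` (numeric vector of all plane scores).
#' @seealso [select_focal_planes()] for the manifest-driven vectorised form.
#' @export
select_clearest_plane <- function(planes) {
  if (inherits(planes, "pn_zstack")) planes <- planes$planes
  if (!is.list(planes) || length(planes) == 0) {
    stop("planes must be a non-empty list of image matrices", call. = FALSE)
  }
  scores <- vapply(planes, laplacian_sharpness, numeric(1))
  idx <- which.max(scores) # which.max returns the first maximum: low-index tie-break
  list(index = idx, image = planes[[idx]], sharpness = scores)
}

#' Construct a Z-stack record
#'
#' Bundles the focal planes of one embryo at one time point together with
#' their focal offsets. The default offsets are the 11 focal segments of a
#' time-lapse incubator, -75 to 75 um in 15 um steps; any plane count >= 1 is
#' accepted.
#'
#' @param planes List of intensity matrices, all with identical dimensions.
#' @param embryo_id Identifier.
#' @param time_h Hours post-ICSI (non-negative).
#' @param plane_offsets_um Strictly increasing numeric vector, one offset per
#'   plane.
#' @return An object of class `pn_zstack`.
#' @export
zstack <- function(planes, embryo_id = "embryo", time_h = 0,
                   plane_offsets_um = default_plane_offsets(length(planes))) {
  stopifnot(is.list(planes), length(planes) >= 1)
  dims <- vapply(planes, function(p) dim(as_gray_matrix(p)), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all planes of a Z-stack must share identical dimensions", call. = FALSE)
  }
  if (length(plane_offsets_um) != length(planes)) {
    stop("plane_offsets_um must have one entry per plane", call. = FALSE)
  }
  if (any(diff(plane_offsets_um) <= 0)) {
    stop("plane_offsets_um must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(time_h) || time_h < 0) stop("time_h must be >= 0", call. = FALSE)
  structure(
    list(embryo_id = embryo_id, time_h = time_h, planes = planes,
         plane_offsets_um = plane_offsets_um),
    class = "pn_zstack"
  )
}

default_plane_offsets <- function(n) {
  (seq_len(n) - (n + 1) / 2) * 15  # 15 um focal segments, centred on 0
}

#' Select focal planes across a stack manifest
#'
#' Manifest-driven focal selection: reads every plane image listed in the
#' manifest, groups rows by embryo and time point, and keeps the sharpest
#' plane of each group. TIFF and PNG files are supported.
#'
#' @param manifest Data frame with columns `embryo_id`, `time_h`,
#'   `plane_offset_um`, `path` (one row per plane image).
#' @return A tibble with one row per (embryo_id, time_h): the selected
#'   `plane_index` (1-based within the offset-ordered stack),
#'   `plane_offset_um`, `sharpness` and `path`.
#' @export
select_focal_planes <- function(manifest) {
  need <- c("embryo_id", "time_h", "plane_offset_um", "path")
  check_columns(manifest, need, "manifest")
  manifest |>
    dplyr::group_by(.data$embryo_id, .data$time_h) |>
    dplyr::arrange(.data$plane_offset_um, .by_group = TRUE) |>
    dplyr::group_modify(function(g, key) {
      planes <- lapply(g$path, read_plane_image)
      sel <- select_clearest_plane(planes)
      tibble::tibble(
        plane_index = sel$index,
        plane_offset_um = g$plane_offset_um[sel$index],
        sharpness = sel$sharpness[sel$index],
        path = g$path[sel$index]
      )
    }) |>
    dplyr::ungroup()
}

# Read a single-plane image file into a grayscale matrix.
read_plane_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "tif" = ,
    "tiff" = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    "png" = {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop("reading PNG requires the 'png' package", call. = FALSE)
      }
      png::readPNG(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  as_gray_matrix(img)
}

# Collapse colour arrays to luma grayscale; pass matrices through.
as_gray_matrix <- function(image) {
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) == 3 && d[3] >= 3) {
    return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  }
  if (length(d) == 3 && d[3] == 1) return(image[, , 1])
  stop("image must be a matrix or an array with a colour dimension", call. = FALSE)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}
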