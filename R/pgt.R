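#' Parse a PGT result string into chromosomal errors
#'
#' Parses the compact karyotype-style notation of preimplantation genetic
#' testing (PGT) reports into a table of chromosomal errors. Recognised
#' aberration terms:
#' \itemize{
#' \item whole-chromosome gains: `+22(x3)`, `+22`
#' \item whole-chromosome losses: `(-21)`, `-21`
#' \item whole-chromosome mosaics: `+mosaic (22) (33%)`
#' \item segmental dup/del with band range and size:
#'   `dup (16) (p13.3p13.13) (5.7 Mb)`, optionally with a trailing
#'   `(mos, 50%)` mosaic annotation
#' \item arm-style segmental calls with copy number:
#'   `+4q (q12q31.1, ~89 Mb, x3)` (three copies, a duplication),
#'   `9p (p20p21.1, ~32 Mb, x1, mos, ~50%)` (one copy, a mosaic deletion)
#' }
#' A bare `46 XN` / `46, XN` / `46XN` prefix parses to an empty error list.
#' The grammar is whitespace- and case-tolerant and accepts the Unicode
#' minus, multiplication and arrow signs interchangeably with their ASCII
#' forms, and both `Mb` and `m` for megabases (`kb` is converted). An
#' unrecognised term is an error naming the offending token, never a silent
#' skip.
#'
#' @param raw Non-empty PGT result string.
#' @return A tibble with one row per error: `chromosome` (character,
#'   `"1"`..`"22"`, `"X"`, `"Y"`), `kind` (`gain`/`loss` whole-chromosome,
#'   `dup`/`del` segmental), `band` (band-range text, `NA` for
#'   whole-chromosome events), `size_mb` (`NA` likewise), `mosaic_pct`
#'   (`NA` for non-mosaic events).
#' @examples
#' parse_pgt_string("47, XN, +22(×3)")
#' parse_pgt_string("46, XN, dup (16) (p13.3p13.13) (5.7 Mb)")
#' @export
parse_pgt_string <- function(raw) {
  if (!is.character(raw) || length(raw) != 1 || !nzchar(trimws(raw))) {
    stop("raw PGT string must be a non-empty string", call. = FALSE)
  }
  s <- normalise_pgt(raw)
  tokens <- split_top_level(s)
  tokens <- tokens[nzchar(tokens)]
  errors <- purrr::map(tokens, parse_pgt_token)
  dplyr::bind_rows(empty_chrom_errors(), purrr::compact(errors))
}

empty_chrom_errors <- function() {
  tibble::tibble(chromosome = character(), kind = character(),
                 band = character(), size_mb = numeric(),
                 mosaic_pct = numeric())
}

normalise_pgt <- function(s) {
  s <- gsub("−", "-", s)       # unicode minus
  s <- gsub("×", "x", s)       # multiplication sign
  s <- gsub("→", "->", s)      # arrow
  s <- gsub("≈|~", "", s)      # "approximately" markers
  s <- gsub(" ", " ", s)       # non-breaking space
  trimws(s)
}

# Split on commas that are not inside parentheses.
split_top_level <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  cuts <- which(chars == "," & depth == 0)
  starts <- c(1, cuts + 1)
  ends <- c(cuts - 1, length(chars))
  vapply(seq_along(starts), function(i) {
    trimws(paste(chars[starts[i]:ends[i]], collapse = ""))
  }, character(1))
}

chrom_rx <- "(\\d{1,2}|X|Y)"

# Parse one comma-separated term; NULL for karyotype-prefix tokens.
parse_pgt_token <- function(tok) {
  t <- trimws(tok)
  # karyotype prefix: "46", "XN", "46XN", "46 XN"
  if (grepl("^\\d{2}\\s*(X[NXY])?$", t, ignore.case = TRUE) ||
      grepl("^X[NXY]$", t, ignore.case = TRUE)) {
    return(NULL)
  }
  # whole-chromosome mosaic: "+mosaic (22) (33%)" / "- mos (22) (33%)"
  m <- stringr::str_match(
    t, stringr::regex(paste0("^([+-])?\\s*mos(?:aic)?\\s*\\(", chrom_rx,
                             "\\)\\s*\\((\\d+(?:\\.\\d+)?)\\s*%\\)$"),
                      ignore_case = TRUE))
  if (!is.na(m[1, 1])) {
    kind <- if (!is.na(m[1, 2]) && m[1, 2] == "-") "loss" else "gain"
    return(chrom_error(m[1, 3], kind, mosaic_pct = as.numeric(m[1, 4])))
  }
  # whole-chromosome gain: "+22(x3)" / "+22"
  m <- stringr::str_match(
    t, stringr::regex(paste0("^\\+\\s*", chrom_rx,
                             "\\s*(?:\\(\\s*x\\s*(\\d+)\\s*\\))?$"),
                      ignore_case = TRUE))
  if (!is.na(m[1, 1])) return(chrom_error(m[1, 2], "gain"))
  # whole-chromosome loss: "(-21)" / "-21"
  m <- stringr::str_match(
    t, stringr::regex(paste0("^\\(?\\s*-\\s*", chrom_rx, "\\s*\\)?$"),
                      ignore_case = TRUE))
  if (!is.na(m[1, 1])) return(chrom_error(m[1, 2], "loss"))
  # named segmental: "dup (16) (p13.3p13.13) (5.7 Mb)" [+ "(mos, 50%)"]
  m <- stringr::str_match(
    t, stringr::regex(paste0(
      "^(dup|del)\\s*\\(", chrom_rx, "\\)\\s*",
      "\\(([pq][\\d.]+(?:->)?(?:[pq][\\d.]+|[pq]?ter))\\)\\s*",
      "\\((\\d+(?:\\.\\d+)?)\\s*(Mb|m|kb)\\)",
      "(?:\\s*\\(\\s*mos(?:aic)?\\s*,?\\s*(\\d+(?:\\.\\d+)?)\\s*%\\s*\\))?$"),
      ignore_case = TRUE))
  if (!is.na(m[1, 1])) {
    return(chrom_error(m[1, 3], tolower(m[1, 2]), band = m[1, 4],
                       size_mb = size_in_mb(m[1, 5], m[1, 6]),
                       mosaic_pct = as.numeric(m[1, 7])))
  }
  # arm-style: "+4q (q12q31.1, 89 Mb, x3)" / "9p (p20p21.1, 32 Mb, x1, mos, 50%)"
  m <- stringr::str_match(
    t, stringr::regex(paste0("^([+-])?", chrom_rx,
                             "([pq])\\s*\\(([^()]*)\\)$"),
                      ignore_case = TRUE))
  if (!is.na(m[1, 1])) {
    return(parse_arm_term(m[1, 2], m[1, 3], m[1, 4], m[1, 5], tok))
  }
  stop("unrecognized PGT term: '", tok, "'", call. = FALSE)
}

parse_arm_term <- function(sign, chrom, arm, inner, tok) {
  parts <- trimws(strsplit(inner, ",")[[1]])
  band <- NA_character_
  size_mb <- NA_real_
  copies <- NA_integer_
  mosaic_pct <- NA_real_
  saw_mos <- FALSE
  for (p in parts) {
    if (grepl("^[pq][\\d.]+(->)?([pq][\\d.]+|[pq]?ter)$", p,
              ignore.case = TRUE, perl = TRUE)) {
      band <- p
    } else if (grepl("^\\d+(\\.\\d+)?\\s*(Mb|m|kb)$", p,
                     ignore.case = TRUE, perl = TRUE)) {
      mm <- stringr::str_match(p, stringr::regex(
        "^(\\d+(?:\\.\\d+)?)\\s*(Mb|m|kb)$", ignore_case = TRUE))
      size_mb <- size_in_mb(mm[1, 2], mm[1, 3])
    } else if (grepl("^x\\s*\\d+$", p, ignore.case = TRUE, perl = TRUE)) {
      copies <- as.integer(sub("^x\\s*", "", p, ignore.case = TRUE))
    } else if (grepl("^mos(aic)?$", p, ignore.case = TRUE)) {
      saw_mos <- TRUE
    } else if (grepl("^\\d+(\\.\\d+)?\\s*%$", p, perl = TRUE)) {
      mosaic_pct <- as.numeric(sub("%", "", p))
    } else {
      stop("unrecognized PGT term: '", tok, "' (component '", p, "')",
           call. = FALSE)
    }
  }
  if (is.na(band)) {
    stop("unrecognized PGT term: '", tok, "' (missing band range)",
         call. = FALSE)
  }
  kind <- if (!is.na(copies)) {
    if (copies >= 3) "dup" else "del"
  } else if (identical(sign, "+")) "dup" else "del"
  if (saw_mos && is.na(mosaic_pct)) mosaic_pct <- NA_real_
  chrom_error(chrom, kind, band = band, size_mb = size_mb,
              mosaic_pct = if (saw_mos || !is.na(mosaic_pct)) mosaic_pct else NA_real_)
}

size_in_mb <- function(value, unit) {
  v <- as.numeric(value)
  if (tolower(unit) == "kb") v / 1000 else v
}

chrom_error <- function(chromosome, kind, band = NA_character_,
                        size_mb = NA_real_, mosaic_pct = NA_real_) {
  tibble::tibble(chromosome = toupper(as.character(chromosome)), kind = kind,
                 band = band, size_mb = size_mb, mosaic_pct = mosaic_pct)
}

#' Classify a parsed error list into a chromosomal category
#'
#' Implements the seven-way outcome classification used for embryo PGT
#' results. With `W` = non-mosaic whole-chromosome errors (gain/loss), `S` =
#' non-mosaic segmental errors (dup/del) and `M` = any mosaic error:
#' \itemize{
#' \item `chromosome_normal`: no errors (46 XN)
#' \item `sole_mosaic`: every error is mosaic
#' \item `sole_aneuploidy`: W only
#' \item `sole_del_dup`: S only
#' \item `euploidy_with_errors`: S plus M, no W
#' \item `aneuploidy_with_errors`: W plus exactly one of S or M
#' \item `complex`: W, S and M together
#' }
#'
#' @param errors Error tibble from [parse_pgt_string()].
#' @return A single category string.
#' @export
classify_karyotype <- function(errors) {
  if (nrow(errors) == 0) return("chromosome_normal")
  is_mosaic <- !is.na(errors$mosaic_pct)
  if (all(is_mosaic)) return("sole_mosaic")
  nm <- errors[!is_mosaic, , drop = FALSE]
  has_w <- any(nm$kind %in% c("gain", "loss"))
  has_s <- any(nm$kind %in% c("dup", "del"))
  has_m <- any(is_mosaic)
  if (has_w) {
    if (has_s && has_m) return("complex")
    if (has_s || has_m) return("aneuploidy_with_errors")
    return("sole_aneuploidy")
  }
  if (has_s && has_m) return("euploidy_with_errors")
  if (has_s) return("sole_del_dup")
  "sole_mosaic"
}

#' Is a category in the chromosome-normal analysis group?
#'
#' `chromosome_normal` and `sole_mosaic` embryos are pooled into one
#' outcome group for rank statistics: sole mosaicism is attributed to
#' post-zygotic mitotic segregation errors rather than to the gametes, so it
#' does not count against the oocyte or sperm.
#'
#' @param category Category string(s) from [classify_karyotype()].
#' @return Logical vector.
#' @export
is_normal_group <- function(category) {
  category %in% c("chromosome_normal", "sole_mosaic")
}

#' Alternative trichotomy labelling
#'
#' The coarser normal/deletion/duplication outcome labelling explored as an
#' early design: `normal` for no errors, otherwise `deletion` if any
#' loss/del is present (taking precedence), else `duplication`. Exposed for
#' comparison only; default statistics use [classify_karyotype()].
#'
#' @inheritParams classify_karyotype
#' @return One of `"normal"`, `"deletion"`, `"duplication"`.
#' @export
classify_trichotomy <- function(errors) {
  if (nrow(errors) == 0) return("normal")
  if (any(errors$kind %in% c("loss", "del"))) return("deletion")
  "duplication"
}

#' Serialize a parsed error list back to PGT notation
#'
#' Canonical re-serialization of a [parse_pgt_string()] table; parsing the
#' output reproduces the same error table (round-trip stability).
#'
#' @inheritParams classify_karyotype
#' @return A single PGT string.
#' @export
format_pgt_string <- function(errors) {
  nm_whole <- is.na(errors$mosaic_pct) & errors$kind %in% c("gain", "loss")
  count <- 46 + sum(errors$kind[nm_whole] == "gain") -
    sum(errors$kind[nm_whole] == "loss")
  terms <- purrr::pmap_chr(errors, function(chromosome, kind, band, size_mb,
                                            mosaic_pct) {
    if (kind %in% c("gain", "loss")) {
      if (!is.na(mosaic_pct)) {
        sprintf("%smosaic (%s) (%g%%)", if (kind == "gain") "+" else "-",
                chromosome, mosaic_pct)
      } else if (kind == "gain") {
        sprintf("+%s(x3)", chromosome)
      } else {
        sprintf("(-%s)", chromosome)
      }
    } else {
      base <- sprintf("%s (%s) (%s)", kind, chromosome,
                      if (is.na(size_mb)) band else
                        sprintf("%s) (%g Mb", band, size_mb))
      if (!is.na(mosaic_pct)) paste0(base, sprintf(" (mos, %g%%)", mosaic_pct))
      else base
    }
  })
  paste(c(sprintf("%d, XN", count), terms), collapse = ", ")
}

#' Parental-coincidence call for PGT-SR embryos
#'
#' For structural-rearrangement carriers, decides whether an embryo's
#' chromosomal errors involve the chromosomes rearranged in the carrier
#' parent's somatic karyotype (`coincident` — an inherited-type error),
#' involve only other chromosomes (`inconsistent` — a novel error), or
#' cannot be assessed (`not_applicable`: no errors, or sole mosaicism, which
#' is attributed to mitosis). Matching is at whole-chromosome resolution.
#'
#' @param errors Error tibble from [parse_pgt_string()] (or a raw PGT string).
#' @param parental_karyotype Carrier somatic karyotype text, e.g.
#'   `"46, XX, t(1,16)(q42:q12)"`; translocations (`t`, `rob`), inversions
#'   (`inv`) and derivatives (`der`) contribute their chromosomes.
#' @return One of `"coincident"`, `"inconsistent"`, `"not_applicable"`.
#' @export
parental_coincidence <- function(errors, parental_karyotype) {
  rearranged <- parental_rearranged_set(parental_karyotype)
  if (is.character(errors)) errors <- parse_pgt_string(errors)
  if (nrow(errors) == 0 || classify_karyotype(errors) == "sole_mosaic") {
    return("not_applicable")
  }
  if (any(errors$chromosome %in% rearranged)) "coincident" else "inconsistent"
}

# Chromosomes involved in the rearrangements of a somatic karyotype string.
parental_rearranged_set <- function(karyotype) {
  if (!is.character(karyotype) || length(karyotype) != 1 ||
      !nzchar(trimws(karyotype))) {
    stop("parental karyotype must be a non-empty string", call. = FALSE)
  }
  s <- normalise_pgt(karyotype)
  hits <- stringr::str_match_all(
    s, stringr::regex("\\b(t|rob|inv|der)\\s*\\(([^)]*)\\)",
                      ignore_case = TRUE))[[1]]
  if (nrow(hits) == 0) {
    stop("unparseable parental karyotype (no rearrangement found): '",
         karyotype, "'", call. = FALSE)
  }
  chroms <- unlist(lapply(hits[, 3], function(inner) {
    parts <- trimws(strsplit(inner, "[,;]")[[1]])
    parts[grepl("^(\\d{1,2}|X|Y)$", parts, ignore.case = TRUE)]
  }))
  if (length(chroms) == 0) {
    stop("unparseable parental karyotype (no chromosomes in rearrangement): '",
         karyotype, "'", call. = FALSE)
  }
  unique(toupper(chroms))
}

#' Classify a table of PGT results
#'
#' Cohort wrapper: parses every `pgt_string`, attaches `category` and
#' `normal_group`, and, where a `parental_karyotype` and a `propositus`
#' other than `"none"` are given, the parental `coincidence` call.
#'
#' @param pgt Data frame with columns `embryo_id`, `pgt_string`, optionally
#'   `patient_id`, `propositus` (`female`/`male`/`none`) and
#'   `parental_karyotype`.
#' @return The input tibble plus `category`, `normal_group`, `coincidence`.
#' @export
classify_pgt <- function(pgt) {
  check_columns(pgt, c("embryo_id", "pgt_string"), "pgt")
  parsed <- purrr::map(pgt$pgt_string, parse_pgt_string)
  pgt$category <- purrr::map_chr(parsed, classify_karyotype)
  pgt$normal_group <- is_normal_group(pgt$category)
  has_parent <- "parental_karyotype" %in% names(pgt) &&
    "propositus" %in% names(pgt)
  pgt$coincidence <- if (has_parent) {
    purrr::pmap_chr(
      list(parsed, pgt$parental_karyotype, pgt$propositus),
      function(err, kar, prop) {
        if (is.na(prop) || prop == "none" || is.na(kar) || !nzchar(kar)) {
          NA_character_
        } else {
          parental_coincidence(err, kar)
        }
      })
  } else {
    NA_character_
  }
  tibble::as_tibble(pgt)
}
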