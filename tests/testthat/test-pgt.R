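# The canonical notation examples of each outcome category, with their
# expected classifications.
category_examples <- tibble::tribble(
  ~pgt_string, ~category,
  "46 XN", "chromosome_normal",
  "46XN, + mosaic (22) (33%)", "sole_mosaic",
  "46 XN, dup (16) (p13.3p13.13) (5.7 Mb) (mos, 50%)", "sole_mosaic",
  "47, XN, +22(×3)", "sole_aneuploidy",
  "46, XN, dup (16) (p13.3p13.13) (5.7 Mb)", "sole_del_dup",
  "47, XN, +22(×3), dup (16) (p13.3p13.13) (5.7 Mb)", "aneuploidy_with_errors",
  "47, XN, +22(×3), +mosaic (22) (33%)", "aneuploidy_with_errors",
  "46, XN, dup (16) (p13.3p13.13) (5.7 Mb), +mosaic (22) (33%)", "euploidy_with_errors",
  paste0("45, XN, (−21), +4q (q12q31.1, ≈89 Mb, ×3), ",
         "9p (p20p21.1, ≈32 Mb, ×1, mos, ≈50%)"), "complex"
)

test_that("the canonical example strings parse to the expected errors", {
  expect_equal(nrow(parse_pgt_string("46 XN")), 0)
  expect_equal(nrow(parse_pgt_string("46, XN")), 0)

  e <- parse_pgt_string("47, XN, +22(×3)")
  expect_equal(e$chromosome, "22")
  expect_equal(e$kind, "gain")
  expect_true(is.na(e$mosaic_pct))

  e <- parse_pgt_string("46, XN, dup (16) (p13.3p13.13) (5.7 Mb)")
  expect_equal(e$kind, "dup")
  expect_equal(e$chromosome, "16")
  expect_equal(e$band, "p13.3p13.13")
  expect_equal(e$size_mb, 5.7)

  e <- parse_pgt_string("46XN, + mosaic (22) (33%)")
  expect_equal(e$kind, "gain")
  expect_equal(e$mosaic_pct, 33)

  e <- parse_pgt_string(
    "45, XN, (−21), +4q (q12q31.1, ≈89 Mb, ×3), 9p (p20p21.1, ≈32 Mb, ×1, mos, ≈50%)")
  expect_equal(e$kind, c("loss", "dup", "del"))
  expect_equal(e$chromosome, c("21", "4", "9"))
  expect_equal(e$size_mb, c(NA, 89, 32))
  expect_equal(e$mosaic_pct, c(NA, NA, 50))

  # arrow band ranges and the lowercase megabase unit
  e <- parse_pgt_string(
    "46, XN, +1q (q42.12→qter, ≈23.9 m, ×3), −16q (q12.1→q24.3, ≈39 m, ×1)")
  expect_equal(e$kind, c("dup", "del"))
  expect_equal(e$chromosome, c("1", "16"))
  expect_equal(e$size_mb, c(23.9, 39))
})

test_that("unrecognised terms fail loudly, carrying the token", {
  expect_error(parse_pgt_string("46, XN, frobnicate (3)"), "frobnicate")
  expect_error(parse_pgt_string("46, XN, +4q (banana)"), "banana")
  expect_error(parse_pgt_string(""), "non-empty")
})

test_that("every canonical example classifies to its stated category", {
  for (i in seq_len(nrow(category_examples))) {
    expect_equal(
      classify_karyotype(parse_pgt_string(category_examples$pgt_string[i])),
      category_examples$category[i],
      label = category_examples$pgt_string[i]
    )
  }
})

test_that("normal-group membership pools chromosome-normal and sole mosaic", {
  expect_true(is_normal_group("chromosome_normal"))
  expect_true(is_normal_group("sole_mosaic"))
  expect_false(any(is_normal_group(c("sole_aneuploidy", "sole_del_dup",
                                     "aneuploidy_with_errors",
                                     "euploidy_with_errors", "complex"))))
})

test_that("parse -> serialize -> parse is a fixed point on the examples", {
  for (s in category_examples$pgt_string) {
    once <- parse_pgt_string(s)
    again <- parse_pgt_string(format_pgt_string(once))
    expect_equal(again, once, label = s)
  }
})

test_that("classification partitions randomly generated error lists", {
  set.seed(53)
  cats <- c("chromosome_normal", "sole_mosaic", "sole_aneuploidy",
            "sole_del_dup", "aneuploidy_with_errors", "euploidy_with_errors",
            "complex")
  for (i in 1:200) {
    n <- sample(0:4, 1)
    errors <- tibble::tibble(
      chromosome = as.character(sample(1:22, n, replace = TRUE)),
      kind = sample(c("gain", "loss", "dup", "del"), n, replace = TRUE),
      band = NA_character_, size_mb = NA_real_,
      mosaic_pct = ifelse(runif(n) < 0.4, runif(n, 10, 90), NA_real_)
    )
    errors$band[errors$kind %in% c("dup", "del")] <- "q11q22.1"
    got <- classify_karyotype(errors)
    expect_length(got, 1)
    expect_in(got, cats)
  }
})

test_that("synthesised strings always classify to their target category", {
  set.seed(59)
  cats <- c("chromosome_normal", "sole_mosaic", "sole_aneuploidy",
            "sole_del_dup", "aneuploidy_with_errors", "euploidy_with_errors",
            "complex")
  for (i in 1:30) {
    for (cat in cats) {
      s <- getFromNamespace("synth_pgt_string", "pnquant")(cat)
      expect_equal(classify_karyotype(parse_pgt_string(s)), cat, label = s)
    }
  }
})

test_that("parental coincidence matches the worked translocation pair", {
  parental <- "46, XX, t(1,16)(q42:q12)"
  embryo <- "46, XN, +1q (q42.12→qter, ≈23.9 m, ×3), −16q (q12.1→q24.3, ≈39 m, ×1)"
  expect_equal(parental_coincidence(embryo, parental), "coincident")
  expect_equal(parental_coincidence("47, XN, +22(×3)", parental),
               "inconsistent")
  expect_equal(parental_coincidence("46 XN", parental), "not_applicable")
  expect_equal(parental_coincidence("46XN, + mosaic (22) (33%)", parental),
               "not_applicable")
  expect_error(parental_coincidence("46 XN", "46, XX"), "unparseable")
})

test_that("the trichotomy labelling is exposed but coarse", {
  expect_equal(classify_trichotomy(parse_pgt_string("46 XN")), "normal")
  expect_equal(classify_trichotomy(parse_pgt_string("47, XN, +22(×3)")),
               "duplication")
  expect_equal(
    classify_trichotomy(
      parse_pgt_string("45, XN, (−21), +4q (q12q31.1, ≈89 Mb, ×3)")),
    "deletion")
})

test_that("cohort-level classification adds the derived columns", {
  df <- tibble::tibble(
    embryo_id = c("E1", "E2", "E3"),
    patient_id = "P1",
    pgt_string = c("46 XN", "47, XN, +22(×3)",
                   "46, XN, +1q (q42.12→qter, 23.9 m, ×3)"),
    propositus = c("none", "female", "female"),
    parental_karyotype = c(NA, "46, XX, t(1,16)(q42:q12)",
                           "46, XX, t(1,16)(q42:q12)")
  )
  out <- classify_pgt(df)
  expect_equal(out$category,
               c("chromosome_normal", "sole_aneuploidy", "sole_del_dup"))
  expect_equal(out$normal_group, c(TRUE, FALSE, FALSE))
  expect_equal(out$coincidence, c(NA, "inconsistent", "coincident"))
})
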