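test_that("matching-ratio parse (ceiling) and display (floor) are inverse", {
  expect_equal(min_matches_from_ratio(0.18, 11), 2L)
  expect_equal(min_matches_from_ratio(0.27, 11), 3L)
  expect_equal(min_matches_from_ratio(1.0, 5), 5L)
  expect_error(min_matches_from_ratio(0, 5), "\\(0, 1\\]")
  expect_error(min_matches_from_ratio(1.2, 5), "\\(0, 1\\]")

  expect_equal(display_ratio(2, 11), 18L)
  expect_equal(display_ratio(3, 11), 27L)
  expect_equal(display_ratio(7, 7), 100L)
  expect_error(display_ratio(8, 7), "k <= m")

  # exhaustive round-trip over all 1 <= k <= m <= 50
  for (m in 1:50) {
    for (k in 1:m) {
      expect_identical(min_matches_from_ratio(display_ratio(k, m) / 100, m),
                       k)
    }
  }
})

test_that("match_count evaluates the printed conditions record by record", {
  pat <- printed_pattern(k = 2L)
  rec <- list(lvef = 50, contrast_volume = 120, age = 60)
  # lvef <= 56.6 and contrast_volume > 79.5 hold; age <= 58.5 fails;
  # the remaining seven variables are absent, hence unmatched
  expect_equal(match_count(pat, rec), 2L)
  expect_equal(match_fraction(pat, rec), 0.2)

  none <- list(lvef = NA, age = NA)
  expect_equal(match_count(pat, none), 0L)
  expect_equal(match_fraction(pat, none), 0)

  full <- list(lvef = 40, pre_peak_creatinine = 170, gfr = 20,
               urgent_pci = "Yes", iabp = "Yes", contrast_volume = 150,
               age = 50, hdl_c = 0.5, hypertension = "Yes", anemia = "Yes")
  expect_equal(match_count(pat, full), 10L)
  expect_equal(match_fraction(pat, full), 1.0)

  # boundary semantics: <= inclusive, > exclusive
  expect_equal(match_count(pat, list(lvef = 56.6)), 1L)
  expect_equal(match_count(pat, list(contrast_volume = 79.5)), 0L)
})

test_that("predict applies the k-of-m threshold", {
  rec <- list(lvef = 50, contrast_volume = 120, age = 60)
  expect_true(predict(printed_pattern(2L), rec))
  expect_false(predict(printed_pattern(3L), rec))
  expect_true(predict(printed_pattern(1L), list(anemia = "Yes")))

  # predict(record) == (match_fraction >= k/m), exactly
  set.seed(17)
  df <- data.frame(lvef = rnorm(100, 60, 10),
                   age = rnorm(100, 64, 11),
                   contrast_volume = rnorm(100, 130, 60),
                   anemia = sample(c("Yes", "No"), 100, TRUE),
                   stringsAsFactors = FALSE)
  for (k in c(1L, 2L, 4L)) {
    pat <- pattern("aki", list(condition("lvef", "<=", 56.6),
                               condition("age", "<=", 58.5),
                               condition("contrast_volume", ">", 79.5),
                               condition("anemia", "==", "Yes")), k)
    expect_identical(predict(pat, df),
                     match_fraction(pat, df) >= k / 4)
  }
})

test_that("raising k shrinks the positive set; dropping a condition never raises counts", {
  set.seed(23)
  df <- data.frame(lvef = rnorm(200, 60, 10),
                   age = rnorm(200, 64, 11),
                   contrast_volume = rnorm(200, 130, 60),
                   stringsAsFactors = FALSE)
  conds <- list(condition("lvef", "<=", 56.6),
                condition("age", "<=", 58.5),
                condition("contrast_volume", ">", 79.5))
  prev <- NULL
  for (k in 1:3) {
    pos <- predict(pattern("aki", conds, k), df)
    if (!is.null(prev)) expect_true(all(pos <= prev))  # subset as k rises
    prev <- pos
  }
  full_counts <- match_count(pattern("aki", conds, 1L), df)
  for (drop in 1:3) {
    reduced <- pattern("aki", conds[-drop], 1L)
    expect_true(all(match_count(reduced, df) <= full_counts))
  }
})

test_that("pattern JSON round-trips losslessly and validates its fields", {
  pat <- printed_pattern(2L)
  pat$history <- list(history_entry("pre", m = 10, k = 2, objective = 0.17,
                                    conditions = pat$conditions,
                                    timestamp = "2021-01-01T00:00:00Z"))
  path <- withr::local_tempfile(fileext = ".json")
  write_pattern(pat, path)
  back <- read_pattern(path)
  expect_equal(back, pat)

  doc <- pattern_to_list(pat)
  doc$min_matches <- NULL
  expect_error(pattern_from_list(doc), "min_matches")
  doc2 <- pattern_to_list(pat)
  doc2$conditions[[1]]$comparator <- NULL
  expect_error(pattern_from_list(doc2), "comparator")

  # a hand-written document: k authoritative, ratio derived
  eleven <- c(printed_conditions(), list(condition("diabetes", "==", "Yes")))
  hand <- list(target = list(variable = "aki", positive_class = "Yes"),
               conditions = lapply(eleven, unclass),
               min_matches = 2, mode_tag = "pre")
  p11 <- pattern_from_list(hand)
  expect_equal(display_ratio(p11$min_matches, length(p11$conditions)), 18L)
})

test_that("pattern constructor enforces its invariants", {
  conds <- printed_conditions()
  expect_error(pattern("aki", conds, 0), "min_matches")
  expect_error(pattern("aki", conds, 11), "min_matches")
  expect_error(pattern("aki", c(conds, conds[1]), 1), "distinct")
  expect_error(condition("age", "==", 5), NA)  # category coerced is fine
  expect_error(condition("age", "<=", "old"), "numeric")
})
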