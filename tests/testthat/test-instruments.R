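# Questionnaire scoring against arithmetic oracles.

make_sheet <- function(spec, value, timepoint = NA) {
  response_sheet("R01", spec$name,
                 stats::setNames(as.list(rep(value, length(spec$items))),
                                 names(spec$items)),
                 timepoint)
}

# positive-pole extreme respecting each item's orientation
positive_sheet <- function(spec) {
  ans <- lapply(spec$items, function(it)
    if (it$reverse) spec$scale_min else spec$scale_max)
  response_sheet("R01", spec$name, ans)
}

test_that("AttrakDiff2: middle step scores 0, positive pole scores +3, mixed sheets match hand arithmetic", {
  spec <- load_instrument("attrakdiff2")
  mid <- score_attrakdiff(make_sheet(spec, 4), spec)
  for (s in c("PQ", "HQI", "HQS", "ATT")) expect_equal(mid[[s]], 0)
  top <- score_attrakdiff(positive_sheet(spec), spec)
  for (s in c("PQ", "HQI", "HQS", "ATT")) expect_equal(top[[s]], 3)

  # mixed sheet vs an independently hand-computed mean
  set.seed(101)
  for (rep in 1:20) {
    raw <- sample(1:7, 28, replace = TRUE)
    names(raw) <- names(spec$items)
    sc <- score_attrakdiff(response_sheet("R", spec$name, as.list(raw)), spec)
    for (sub in c("PQ", "HQI", "HQS", "ATT")) {
      ids <- names(spec$items)[vapply(spec$items, function(it)
        it$subscale == sub, logical(1))]
      vals <- vapply(ids, function(id) {
        v <- raw[[id]]
        if (spec$items[[id]]$reverse) v <- 8 - v
        v - 4
      }, numeric(1))
      expect_equal(sc[[sub]], mean(vals))
      expect_true(sc[[sub]] >= -3 && sc[[sub]] <= 3)
    }
  }
})

test_that("AttrakDiff2 handles missing and invalid items per contract", {
  spec <- load_instrument("attrakdiff2")
  sheet <- make_sheet(spec, 4)
  sheet$answers[["PQ1"]] <- NULL
  expect_warning(sc <- score_attrakdiff(sheet, spec), "missing")
  expect_equal(sc$PQ, 0)          # excluded-mean of the remaining 6 items
  expect_identical(sc$n_missing, 1L)
  bad <- make_sheet(spec, 4)
  bad$answers[["PQ2"]] <- 9
  expect_error(score_attrakdiff(bad, spec), class = "painsim_config_error",
               regexp = "PQ2")
})

test_that("reverse keying is an involution", {
  for (bounds in list(c(1, 7), c(0, 5))) {
    raw <- seq(bounds[1], bounds[2])
    expect_equal(reverse_key(reverse_key(raw, bounds[1], bounds[2]),
                             bounds[1], bounds[2]), raw)
  }
})

test_that("knowledge test scores proportion correct; do-not-know and blanks count incorrect", {
  spec <- load_instrument("pakppm")
  all_correct <- response_sheet("R", "pakppm",
    lapply(spec$items, `[[`, "correct"))
  expect_equal(score_proportion_correct(all_correct, spec)$percent, 100)
  expect_equal(score_proportion_correct(make_sheet(spec, "f"), spec)$percent, 0)
  # 9 correct of 15 -> 60%
  nine <- lapply(spec$items, `[[`, "correct")
  for (id in names(nine)[10:15]) nine[[id]] <- "f"
  expect_equal(score_proportion_correct(
    response_sheet("R", "pakppm", nine), spec)$percent, 60)
  # unanswered items count incorrect and are flagged
  some <- lapply(spec$items, `[[`, "correct")
  some[["K1"]] <- NULL
  sc <- score_proportion_correct(response_sheet("R", "pakppm", some), spec)
  expect_equal(sc$percent, 100 * 14 / 15)
  expect_identical(sc$n_unanswered, 1L)
})

test_that("Likert scoring matches brute-force aggregation and respects bounds", {
  spec <- load_instrument("bqii")
  expect_equal(score_likert(make_sheet(spec, 0), spec)$total, 0)
  all5 <- score_likert(make_sheet(spec, 5), spec)
  expect_equal(all5$total, 5)
  for (s in all5$subscales) expect_equal(s, 5)

  set.seed(202)
  for (rep in 1:20) {
    raw <- sample(0:5, 27, replace = TRUE)
    names(raw) <- names(spec$items)
    sc <- score_likert(response_sheet("R", "bqii", as.list(raw)), spec)
    expect_equal(sc$total, mean(raw))
    for (sub in vapply(spec$subscales, `[[`, "", "id")) {
      ids <- names(spec$items)[vapply(spec$items, function(it)
        it$subscale == sub, logical(1))]
      expect_equal(sc$subscales[[sub]], mean(raw[ids]))
      expect_true(sc$subscales[[sub]] >= 0 && sc$subscales[[sub]] <= 5)
    }
  }
  bad <- make_sheet(spec, 2)
  bad$answers[["BQ13"]] <- 7
  expect_error(score_likert(bad, spec), class = "painsim_config_error",
               regexp = "BQ13")
})

test_that("POP-MGS reports per-item values alongside subscale means", {
  spec <- load_instrument("popmgs")
  raw <- stats::setNames(as.list(c(2, 3, 4, 5, 1, 0, 5, 5, 4, 3, 2, 1)),
                         names(spec$items))
  sc <- score_likert(response_sheet("R", "popmgs", raw), spec)
  expect_identical(unname(unlist(sc$items)), c(2, 3, 4, 5, 1, 0, 5, 5, 4, 3, 2, 1))
  expect_equal(sc$subscales$ease_of_use, mean(c(2, 3, 4, 5, 1, 0)))
  expect_equal(sc$subscales$usefulness, mean(c(5, 5, 4, 3, 2, 1)))
})

test_that("instrument definitions enforce the instruments' structural invariants", {
  dir <- withr::local_tempdir()
  bad <- jsonlite::read_json(
    file.path(default_config_dir(), "instruments", "attrakdiff2.json"),
    simplifyVector = FALSE)
  bad$items <- bad$items[1:27]
  f <- file.path(dir, "attrakdiff2.json")
  jsonlite::write_json(bad, f, auto_unbox = TRUE)
  expect_error(load_instrument(f), class = "painsim_config_error",
               regexp = "28 items")
})

test_that("long-format response CSVs round-trip into sheets", {
  model <- respondent_model(n = 4, seed = 5)
  gen <- generate_respondents(model)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(gen$long, f, row.names = FALSE)
  sheets <- read_responses(f)
  expect_length(sheets, 8L)     # 4 respondents x 2 timepoints
  spec <- load_instrument("pakppm")
  direct <- score_proportion_correct(gen$pre[[1]], spec)$percent
  rid <- gen$pre[[1]]$respondent
  via_csv <- Filter(function(s) s$respondent == rid && s$timepoint == "pre",
                    sheets)[[1]]
  expect_equal(score_proportion_correct(via_csv, spec)$percent, direct)
})
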