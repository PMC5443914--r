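# Declarative questionnaire scoring. Instruments are defined in JSON
# (packaged defaults under extdata/instruments/) and scored from
# per-respondent response sheets. Three scorer families cover the four
# study instruments: semantic differential (AttrakDiff2), Likert
# (POP-MGS, BQ-II) and multiple choice (PAK-PPM).

#' Load an instrument definition
#'
#' @param name one of `"attrakdiff2"`, `"popmgs"`, `"bqii"`, `"pakppm"`,
#'   or a path to a JSON definition following the same schema.
#' @return object of class `instrument_spec`.
#' @export
load_instrument <- function(name) {
  path <- if (file.exists(name)) name else
    file.path(default_config_dir(), "instruments", paste0(name, ".json"))
  raw <- read_json_config(path, "instrument")
  nm <- need(raw, "name", "instrument")
  type <- need(raw, "type", "instrument")
  if (!type %in% c("semantic_differential", "likert", "multiple_choice"))
    config_error("instrument '%s': unknown type '%s'", nm, type)
  items <- need(raw, "items", "instrument")
  spec <- list(name = nm, type = type,
               items = lapply(items, function(it) {
                 list(id = need(it, "id", "item"),
                      subscale = it$subscale %||% NA_character_,
                      reverse = isTRUE(it$reverse),
                      correct = it$correct %||% NA_character_,
                      left = it$left %||% NA_character_,
                      right = it$right %||% NA_character_)
               }),
               subscales = lapply(raw$subscales %||% list(), function(s)
                 list(id = need(s, "id", "subscale"),
                      label = s$label %||% s$id,
                      aggregation = s$aggregation %||% "mean")),
               scale_min = raw$scale_min %||% NA,
               scale_max = raw$scale_max %||% NA,
               n_options = raw$n_options %||% NA,
               do_not_know_option = raw$do_not_know_option %||% NA_character_,
               report_total = isTRUE(raw$report_total))
  ids <- vapply(spec$items, `[[`, "", "id")
  if (anyDuplicated(ids))
    config_error("instrument '%s': duplicated item ids", nm)
  names(spec$items) <- ids
  # structural invariants of the four known instruments
  k <- length(spec$items)
  check <- function(cond, msg)
    if (!cond) config_error("instrument '%s': %s", nm, msg)
  if (nm == "attrakdiff2") {
    check(k == 28L && length(spec$subscales) == 4L,
          "must have 28 items in 4 subscales")
    tab <- table(vapply(spec$items, `[[`, "", "subscale"))
    check(all(tab == 7L), "each subscale must have exactly 7 items")
    check(spec$scale_min == 1 && spec$scale_max == 7, "must use a 7-step scale")
  } else if (nm == "popmgs") {
    check(k == 12L && spec$scale_min == 0 && spec$scale_max == 5,
          "must have 12 items on a 0-5 scale")
  } else if (nm == "bqii") {
    check(k == 27L && length(spec$subscales) == 4L &&
            spec$scale_min == 0 && spec$scale_max == 5,
          "must have 27 items on a 0-5 scale in 4 subscales")
  } else if (nm == "pakppm") {
    check(k == 15L && spec$n_options == 6, "must have 15 items with 6 options")
    check(all(!is.na(vapply(spec$items, `[[`, "", "correct"))),
          "every item needs exactly one correct option")
  }
  structure(spec, class = "instrument_spec")
}

#' Construct a response sheet
#'
#' @param respondent respondent id.
#' @param instrument instrument name.
#' @param answers named vector/list mapping item id to the raw response
#'   (a number for scaled items, an option letter for multiple choice).
#' @param timepoint `"pre"`, `"post"` or `NA`.
#' @return object of class `response_sheet`.
#' @export
response_sheet <- function(respondent, instrument, answers, timepoint = NA_character_) {
  structure(list(respondent = as.character(respondent),
                 instrument = as.character(instrument),
                 answers = as.list(answers),
                 timepoint = as.character(timepoint)),
            class = "response_sheet")
}

#' Read response sheets from a long-format CSV
#'
#' Expected columns: `respondent`, `instrument`, `timepoint`, `item`,
#' `answer`.
#'
#' @param path CSV path.
#' @return list of [response_sheet()] objects, one per
#'   respondent-instrument-timepoint combination.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) config_error("responses file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("respondent", "instrument", "timepoint", "item", "answer")
  if (!all(needed %in% names(df)))
    config_error("responses file %s must have columns: %s",
                 path, paste(needed, collapse = ", "))
  key <- interaction(df$respondent, df$instrument, df$timepoint, drop = TRUE)
  lapply(split(df, key), function(g)
    response_sheet(g$respondent[1], g$instrument[1],
                   stats::setNames(as.list(g$answer), g$item),
                   g$timepoint[1]))
}

# raw answers for the spec's items, NA where missing
sheet_values <- function(sheet, spec) {
  ids <- names(spec$items)
  vals <- sheet$answers[ids]
  vals[vapply(vals, is.null, logical(1))] <- NA
  stats::setNames(vals, ids)
}

#' Reverse-key a raw response
#'
#' An involution: applying it twice restores the raw value.
#' @param raw numeric response(s).
#' @param scale_min,scale_max the item's scale bounds.
#' @return reversed value(s).
#' @export
reverse_key <- function(raw, scale_min, scale_max) scale_min + scale_max - raw

#' Score an AttrakDiff2 sheet
#'
#' Raw 7-step responses are centred to -3..+3 (reversal applied per the
#' instrument definition); each subscale score is the mean of its 7
#' items. Missing items are excluded from their subscale mean with a
#' warning.
#'
#' @param sheet a [response_sheet()] with the 28 raw responses (1-7).
#' @param spec the `attrakdiff2` [load_instrument()] definition.
#' @return named list of subscale scores (`PQ`, `HQI`, `HQS`, `ATT`),
#'   each in `[-3, 3]`, plus `n_missing`.
#' @export
score_attrakdiff <- function(sheet, spec = load_instrument("attrakdiff2")) {
  if (spec$type != "semantic_differential")
    config_error("score_attrakdiff: '%s' is not a semantic differential", spec$name)
  vals <- sheet_values(sheet, spec)
  mid <- (spec$scale_min + spec$scale_max) / 2
  mapped <- vapply(names(vals), function(id) {
    v <- suppressWarnings(as.numeric(vals[[id]]))
    if (is.na(v)) return(NA_real_)
    if (v < spec$scale_min || v > spec$scale_max)
      config_error("item '%s': response %s outside scale [%d, %d]",
                   id, v, spec$scale_min, spec$scale_max)
    if (spec$items[[id]]$reverse) v <- reverse_key(v, spec$scale_min, spec$scale_max)
    v - mid
  }, numeric(1))
  n_missing <- sum(is.na(mapped))
  if (n_missing > 0)
    warning(sprintf("respondent %s: %d missing item(s) excluded from subscale means",
                    sheet$respondent, n_missing))
  sub <- vapply(spec$subscales, function(s) {
    ids <- names(spec$items)[vapply(spec$items, function(it)
      identical(it$subscale, s$id), logical(1))]
    mean(mapped[ids], na.rm = TRUE)
  }, numeric(1))
  out <- as.list(sub)
  names(out) <- vapply(spec$subscales, `[[`, "", "id")
  out$n_missing <- n_missing
  out
}

#' Score a multiple-choice knowledge sheet as percent correct
#'
#' "Do not know" and unanswered items count as incorrect.
#'
#' @param sheet a [response_sheet()] with option letters.
#' @param spec the `pakppm` [load_instrument()] definition.
#' @return list with `percent` (0-100), `n_correct`, `n_items`,
#'   `n_unanswered`.
#' @export
score_proportion_correct <- function(sheet, spec = load_instrument("pakppm")) {
  if (spec$type != "multiple_choice")
    config_error("score_proportion_correct: '%s' is not multiple choice", spec$name)
  vals <- sheet_values(sheet, spec)
  correct <- vapply(names(vals), function(id) {
    a <- vals[[id]]
    !is.na(a) && identical(as.character(a), spec$items[[id]]$correct)
  }, logical(1))
  n_un <- sum(vapply(vals, function(a) is.na(a) || !nzchar(as.character(a)),
                     logical(1)))
  list(percent = 100 * sum(correct) / length(correct),
       n_correct = sum(correct), n_items = length(correct),
       n_unanswered = n_un)
}

#' Score a Likert sheet
#'
#' Subscale scores are means of their items after reverse-keying;
#' instruments flagged `report_total` (BQ-II) also get a total mean, and
#' instruments flagged `report_items` (POP-MGS) return the per-item
#' values. Out-of-scale answers raise a validation error naming the
#' item.
#'
#' @param sheet a [response_sheet()].
#' @param spec a Likert [load_instrument()] definition.
#' @return list with `subscales`, optional `total`, optional `items`,
#'   and `n_missing`.
#' @export
score_likert <- function(sheet, spec) {
  if (spec$type != "likert")
    config_error("score_likert: '%s' is not a Likert instrument", spec$name)
  vals <- sheet_values(sheet, spec)
  mapped <- vapply(names(vals), function(id) {
    v <- suppressWarnings(as.numeric(vals[[id]]))
    if (is.na(v)) return(NA_real_)
    if (v < spec$scale_min || v > spec$scale_max)
      config_error("item '%s': response %s outside scale [%d, %d]",
                   id, v, spec$scale_min, spec$scale_max)
    if (spec$items[[id]]$reverse) v <- reverse_key(v, spec$scale_min, spec$scale_max)
    v
  }, numeric(1))
  sub <- vapply(spec$subscales, function(s) {
    ids <- names(spec$items)[vapply(spec$items, function(it)
      identical(it$subscale, s$id), logical(1))]
    mean(mapped[ids], na.rm = TRUE)
  }, numeric(1))
  names(sub) <- vapply(spec$subscales, `[[`, "", "id")
  out <- list(subscales = as.list(sub), n_missing = sum(is.na(mapped)))
  if (spec$report_total) out$total <- mean(mapped, na.rm = TRUE)
  out$items <- as.list(mapped)
  out
}
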