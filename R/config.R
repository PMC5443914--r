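# Validated loading of the game's structured-text configuration files.
# Every loader raises a `painsim_config_error` describing the offending
# field, so a bad file fails closed before any simulation state exists.

#' Directory holding the built-in default configuration
#' @return path to the packaged `extdata` directory.
#' @export
default_config_dir <- function() {
  system.file("extdata", package = "painsim", mustWork = TRUE)
}

read_json_config <- function(path, what) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    config_error("%s file not found: %s", what, paste(path, collapse = ", "))
  out <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) config_error("%s file %s is not valid JSON: %s",
                                     what, path, conditionMessage(e)))
  out
}

need <- function(x, field, what, id = NULL) {
  if (is.null(x[[field]]))
    config_error("%s%s: missing field '%s'", what,
                 if (is.null(id)) "" else paste0(" '", id, "'"), field)
  x[[field]]
}

pos_int <- function(v, field, what, id = NULL) {
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0 ||
      v != round(v))
    config_error("%s%s: '%s' must be a positive integer", what,
                 if (is.null(id)) "" else paste0(" '", id, "'"), field)
  as.integer(v)
}

# medications ---------------------------------------------------------------

#' Construct and validate a medication specification
#'
#' @param id short name used in dose actions and telemetry.
#' @param tablet_strength label-only dose text (e.g. "500 mg").
#' @param max_tablets_per_dose,max_tablets_per_day dosing limits.
#' @param min_dose_interval minimum in-game minutes between doses.
#' @param onset,time_to_peak,effect_duration relief kinetics in in-game
#'   minutes; must satisfy `onset < time_to_peak < effect_duration`.
#' @param peak_relief NRS points of relief per tablet at the peak, in (0, 10].
#' @param side_effect_rules list of rules, each with `effect_id` (one of
#'   nausea, drowsiness, constipation, stomach_irritation), `metric`
#'   (`"tablets_in_effect"` or `"daily_tablets"`), `threshold` (count that
#'   triggers, >= 1) and `duration` (minutes > 0).
#' @return object of class `medication_spec`.
#' @export
medication_spec <- function(id, tablet_strength = "", max_tablets_per_dose,
                            max_tablets_per_day, min_dose_interval,
                            onset, time_to_peak, effect_duration,
                            peak_relief, side_effect_rules = list()) {
  what <- "medication"
  spec <- list(
    id = as.character(id),
    tablet_strength = as.character(tablet_strength),
    max_tablets_per_dose = pos_int(max_tablets_per_dose, "max_tablets_per_dose", what, id),
    max_tablets_per_day = pos_int(max_tablets_per_day, "max_tablets_per_day", what, id),
    min_dose_interval = pos_int(min_dose_interval, "min_dose_interval", what, id),
    onset = pos_int(onset, "onset", what, id),
    time_to_peak = pos_int(time_to_peak, "time_to_peak", what, id),
    effect_duration = pos_int(effect_duration, "effect_duration", what, id),
    peak_relief = peak_relief,
    side_effect_rules = side_effect_rules)
  if (!(spec$onset < spec$time_to_peak && spec$time_to_peak < spec$effect_duration))
    config_error("medication '%s': need onset < time_to_peak < effect_duration", id)
  if (!is.numeric(peak_relief) || length(peak_relief) != 1L ||
      peak_relief <= 0 || peak_relief > 10)
    config_error("medication '%s': peak_relief must be in (0, 10]", id)
  known_fx <- c("nausea", "drowsiness", "constipation", "stomach_irritation")
  spec$side_effect_rules <- lapply(side_effect_rules, function(r) {
    fx <- need(r, "effect_id", what, id)
    if (!fx %in% known_fx)
      config_error("medication '%s': unknown effect_id '%s'", id, fx)
    metric <- need(r, "metric", what, id)
    if (!metric %in% c("tablets_in_effect", "daily_tablets"))
      config_error("medication '%s': unknown trigger metric '%s'", id, metric)
    list(effect_id = fx, metric = metric,
         threshold = pos_int(need(r, "threshold", what, id), "threshold", what, id),
         duration = pos_int(need(r, "duration", what, id), "duration", what, id))
  })
  structure(spec, class = "medication_spec")
}

#' Load the medication table
#' @param path JSON file with a `medications` array (see packaged default).
#' @return named list of [medication_spec()] objects.
#' @export
load_medications <- function(path = file.path(default_config_dir(), "medications.json")) {
  raw <- read_json_config(path, "medications")
  meds <- raw$medications
  if (is.null(meds) || length(meds) == 0L)
    config_error("medications file %s: empty or missing 'medications' array", path)
  specs <- lapply(meds, function(m) {
    do.call(medication_spec, m[setdiff(names(m), "_comment")])
  })
  stats::setNames(specs, vapply(specs, `[[`, "", "id"))
}

# model parameters ----------------------------------------------------------

#' Load pain-model parameters
#'
#' Validates that `dt` divides 1440, `relief_cap <= 10`, and that the
#' baseline curve supplies anchors for days 1-3.
#' @param path JSON parameter file (see packaged default for the schema).
#' @return list of class `pain_model_params`.
#' @export
load_model_params <- function(path = file.path(default_config_dir(), "model_params.json")) {
  raw <- read_json_config(path, "model_params")
  dt <- pos_int(need(raw, "dt", "model_params"), "dt", "model_params")
  if (1440L %% dt != 0L)
    config_error("model_params: dt (%d) must divide 1440", dt)
  cap <- need(raw, "relief_cap", "model_params")
  if (!is.numeric(cap) || cap <= 0 || cap > 10)
    config_error("model_params: relief_cap must be in (0, 10]")
  rate <- need(raw, "relaxation_rate", "model_params")
  if (!is.numeric(rate) || rate <= 0)
    config_error("model_params: relaxation_rate must be > 0")
  bc <- need(raw, "baseline_curve", "model_params")
  hours <- unlist(need(bc, "anchor_hours", "baseline_curve"))
  days <- lapply(paste0("day", 1:3), function(d) {
    v <- unlist(need(bc, d, "baseline_curve"))
    if (length(v) != length(hours))
      config_error("baseline_curve: %s has %d anchors, expected %d",
                   d, length(v), length(hours))
    if (any(v < 0 | v > 10))
      config_error("baseline_curve: %s anchors must lie in [0, 10]", d)
    v
  })
  mono <- raw$monologue
  structure(list(
    dt = dt,
    relief_cap = as.numeric(cap),
    relaxation_rate = as.numeric(rate),
    anchor_hours = as.numeric(hours),
    baseline = days,                       # list of numeric vectors, day 1..3
    mobility_min = as.numeric(raw$mobility_min %||% 0.2),
    immobility_threshold = as.numeric(raw$immobility_threshold %||% 9),
    consult_hold_minutes = as.numeric(raw$consult_hold_minutes %||% 180),
    monologue = list(
      enabled = isTRUE(mono$enabled %||% TRUE),
      flavor_rate = as.numeric(mono$flavor_rate %||% 0.02))
  ), class = "pain_model_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# activities / tasks --------------------------------------------------------

#' Load the activity catalog
#' @param path JSON file with an `activities` array.
#' @return named list of activity records.
#' @export
load_activities <- function(path = file.path(default_config_dir(), "activities.json")) {
  raw <- read_json_config(path, "activities")
  acts <- raw$activities
  if (is.null(acts) || length(acts) == 0L)
    config_error("activities file %s: empty or missing 'activities' array", path)
  kinds <- c("chore", "selfcare", "rest", "distraction")
  out <- lapply(acts, function(a) {
    id <- need(a, "id", "activity")
    kind <- need(a, "kind", "activity", id)
    if (!kind %in% kinds)
      config_error("activity '%s': unknown kind '%s'", id, kind)
    dur <- pos_int(need(a, "duration", "activity", id), "duration", "activity", id)
    pe <- need(a, "pain_effect", "activity", id)
    if (!is.numeric(pe) || abs(pe) > 3)
      config_error("activity '%s': |pain_effect| must be <= 3", id)
    list(id = id, kind = kind, duration = dur, pain_effect = as.numeric(pe),
         requires_movement = isTRUE(a$requires_movement),
         counts_toward_tasks = isTRUE(a$counts_toward_tasks))
  })
  stats::setNames(out, vapply(out, `[[`, "", "id"))
}

#' Load per-day required task lists
#' @param path JSON object mapping day index ("1".."3") to activity ids.
#' @param activities catalog from [load_activities()], used for validation.
#' @return list of character vectors indexed by day.
#' @export
load_tasks <- function(path = file.path(default_config_dir(), "tasks.json"),
                       activities = NULL) {
  raw <- read_json_config(path, "tasks")
  out <- lapply(as.character(1:3), function(d) {
    ids <- unlist(raw[[d]] %||% list())
    if (!is.null(activities)) {
      bad <- setdiff(ids, names(activities))
      if (length(bad))
        config_error("tasks day %s references unknown activities: %s",
                     d, paste(bad, collapse = ", "))
    }
    as.character(ids)
  })
  stats::setNames(out, as.character(1:3))
}

# goals ---------------------------------------------------------------------

#' Load day goals, star thresholds and the unmanageable-event config
#' @param path JSON goal file (see packaged default).
#' @return list with elements `goals` (by day), `star_thresholds`,
#'   `unmanageable_event`.
#' @export
load_goals <- function(path = file.path(default_config_dir(), "goals.json")) {
  raw <- read_json_config(path, "goals")
  gl <- need(raw, "goals", "goals")
  goals <- lapply(gl, function(g) {
    day <- pos_int(need(g, "day_index", "goal"), "day_index", "goal")
    kind <- need(g, "kind", "goal", day)
    if (!kind %in% c("minimize_doses", "pain_under_threshold"))
      config_error("goal day %d: unknown kind '%s'", day, kind)
    out <- list(day_index = day, kind = kind,
                description = as.character(g$description %||% ""))
    if (kind == "pain_under_threshold") {
      thr <- need(g, "threshold", "goal", day)
      if (!is.numeric(thr) || thr < 0 || thr > 10)
        config_error("goal day %d: threshold must be an NRS value in [0, 10]", day)
      out$threshold <- as.numeric(thr)
    } else {
      out$dose_ceiling <- pos_int(g$dose_ceiling %||% 12, "dose_ceiling", "goal", day)
    }
    out
  })
  goals <- stats::setNames(goals, vapply(goals, function(g) as.character(g$day_index), ""))
  st <- raw$star_thresholds %||% list(three = 0.95, two = 0.6)
  if (!is.numeric(st$three) || !is.numeric(st$two) || st$three <= st$two)
    config_error("goals: star_thresholds need three > two")
  ev <- raw$unmanageable_event %||% list()
  p <- as.numeric(ev$probability %||% 0.3)
  if (p < 0 || p > 1)
    config_error("goals: unmanageable_event probability must be in [0, 1]")
  list(goals = goals,
       star_thresholds = list(three = as.numeric(st$three), two = as.numeric(st$two)),
       unmanageable_event = list(probability = p,
                                 pain_floor = as.numeric(ev$pain_floor %||% 8),
                                 post_consult_pain = as.numeric(ev$post_consult_pain %||% 5)))
}

#' Load a complete game configuration
#'
#' Reads `medications.json`, `model_params.json`, `activities.json`,
#' `tasks.json` and `goals.json` from one directory (defaults to the
#' packaged configuration) and cross-validates them.
#'
#' @param dir configuration directory.
#' @param overrides optional named list replacing whole sections after
#'   loading (e.g. `list(goals = my_goals)`), used mainly by tests.
#' @return list of class `game_config`.
#' @export
load_game_config <- function(dir = default_config_dir(), overrides = NULL) {
  meds <- load_medications(file.path(dir, "medications.json"))
  params <- load_model_params(file.path(dir, "model_params.json"))
  acts <- load_activities(file.path(dir, "activities.json"))
  tasks <- load_tasks(file.path(dir, "tasks.json"), acts)
  goals <- load_goals(file.path(dir, "goals.json"))
  cfg <- list(medications = meds, params = params, activities = acts,
              tasks = tasks, goals = goals)
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  structure(cfg, class = "game_config")
}
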