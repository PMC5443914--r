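# Three-day game session: daily goals scored as 1-3 stars, the random
# unmanageable-pain event, the help-line consult, and the avatar's
# inner monologue.

#' Schedule the day's unmanageable-pain event
#'
#' One draw per day: with the configured probability an episode is
#' scheduled at a uniformly drawn minute of the current day. When the
#' scheduled minute is reached (by [sim_step()]) the avatar's pain is
#' forced to at least the configured floor (default NRS 8) and stops
#' responding to medication until [consult_help()] is called. Two
#' uniform draws are consumed from the session RNG regardless of the
#' outcome, so trajectories with different probabilities stay aligned.
#'
#' If an episode is still active (carried over from the previous day
#' because the player never consulted), no new event is scheduled but
#' the draws are still consumed.
#'
#' @param sim a `painsim_sim`.
#' @param cfg event configuration; defaults to the loaded goals file.
#' @return the simulation with `event_time` set (or `NA`).
#' @export
maybe_trigger_unmanageable <- function(sim, cfg = sim$config$goals$unmanageable_event) {
  d <- sim_draw(sim, function() runif(2))
  sim <- d$sim
  u <- d$value
  if (isTRUE(sim$unmanageable_active)) {
    sim$event_time <- NA_real_
    return(sim)
  }
  sim$event_fired <- FALSE
  if (u[1] < cfg$probability) {
    dt <- sim$config$params$dt
    minute <- floor(u[2] * (1440 / dt)) * dt
    sim$event_time <- (day_of(sim$clock) - 1L) * 1440 + minute
  } else {
    sim$event_time <- NA_real_
  }
  sim
}

#' Call the help line
#'
#' Always available. Clears an active unmanageable-pain episode; if pain
#' exceeds the configured post-consult level (default NRS 5) it is set
#' to exactly that level, otherwise left unchanged (helpful advice never
#' worsens pain). A transient "advice" relief offset holds the pain
#' attractor near the post-consult level for `consult_hold_minutes`, so
#' the benefit of the consultation persists rather than evaporating on
#' the next step. Idempotent on pain when called twice in a row.
#'
#' @param sim a `painsim_sim`.
#' @return the updated simulation, with a `consult` telemetry entry.
#' @export
consult_help <- function(sim) {
  ev <- sim$config$goals$unmanageable_event
  p <- sim$config$params
  before <- sim$pain
  sim <- log_add(sim, sim$clock, "consult", list(pain_before = before))
  sim$unmanageable_active <- FALSE
  if (before > ev$post_consult_pain) {
    sim$pain <- ev$post_consult_pain
    sim$mobility <- mobility_factor(sim$pain, p$mobility_min)
    adv <- max(0, baseline_pain_at(p, sim$clock) - ev$post_consult_pain)
    if (adv > 0)
      sim$effects[[length(sim$effects) + 1L]] <-
        list(id = ".advice", magnitude = -adv, t_start = sim$clock,
             t_end = sim$clock + p$consult_hold_minutes)
  }
  sim
}

# inner monologue -----------------------------------------------------------

.flavor_messages <- c(
  "Maybe something good is on television.",
  "The house is so quiet today.",
  "I should remember to drink some water.",
  "A little fresh air by the window would be nice.")

#' One inner-monologue evaluation
#'
#' Emits a status message when medication relief starts rising after a
#' dose or when pain crosses a configured zone boundary (above 8:
#' thinking of calling for help; at or below 2: feeling good); otherwise
#' a random flavour message at the configured `flavor_rate`. Two uniform
#' draws are consumed per call regardless of outcome, keeping the RNG
#' stream aligned across counterfactual runs.
#'
#' @param sim a `painsim_sim`.
#' @param relief current applied medication relief (NRS points).
#' @return the simulation; an emitted message is appended to the log as
#'   a `monologue` entry.
#' @export
monologue_step <- function(sim, relief = sim$last_relief) {
  d <- sim_draw(sim, function() runif(2))
  sim <- d$sim
  u <- d$value
  zone <- if (sim$pain >= 8) "high" else if (sim$pain <= 2) "low" else "mid"
  msg <- NULL
  kind <- NULL
  if (isTRUE(sim$med_msg_armed) && relief > sim$last_relief + 1e-9) {
    msg <- "The medication seems to be kicking in."
    kind <- "status"
    sim$med_msg_armed <- FALSE
  } else if (!identical(zone, sim$pain_zone %||% "mid") && zone != "mid") {
    msg <- if (zone == "high")
      "This pain is getting really bad. Maybe I should call for help." else
      "I am feeling pretty good right now."
    kind <- "status"
  } else if (u[1] < sim$config$params$monologue$flavor_rate) {
    msg <- .flavor_messages[1L + floor(u[2] * length(.flavor_messages))]
    kind <- "flavor"
  }
  sim$pain_zone <- zone
  if (!is.null(msg))
    sim <- log_add(sim, sim$clock, "monologue", list(kind = kind, text = msg))
  sim
}

# actions -------------------------------------------------------------------

apply_action <- function(sim, action, step_i) {
  if (is.null(action)) action <- list(type = "idle")
  if (!is.list(action) || is.null(action$type))
    scripting_error("policy emitted a malformed action at step %d", step_i)
  switch(action$type,
    idle = sim,
    dose = take_dose(sim, action$med_id, action$tablets),
    activity = perform_activity(sim, action$id),
    consult = consult_help(sim),
    scripting_error("policy emitted unknown action type '%s' at step %d",
                    action$type, step_i))
}

#' Run one 24-hour game day
#'
#' Simulates exactly 1440 in-game minutes (09:00 to 09:00), driven by a
#' policy. At the start of the day the task list is reset and the
#' unmanageable-pain event is scheduled ([maybe_trigger_unmanageable()]).
#' The policy is consulted whenever the avatar is free; an action that
#' does not advance the clock (a dose, a consult, a refusal) is followed
#' by one idle step so a day always terminates.
#'
#' @param sim a `painsim_sim` with the clock at 09:00 of some day.
#' @param policy a policy object (see [builtin_policies()] or
#'   [make_policy()]).
#' @return `list(sim = <end state>, log = <the day's telemetry entries>)`.
#' @export
run_day <- function(sim, policy) {
  if (!inherits(policy, "painsim_policy"))
    scripting_error("run_day: policy must be a painsim_policy")
  if (sim$clock %% 1440 != 0)
    contract_error("run_day: clock must be at 09:00 (got %s)", sim$clock)
  day <- day_of(sim$clock)
  day_end <- day * 1440
  sim$tasklist <- new_tasklist(day, sim$config$tasks[[as.character(day)]] %||% character(0))
  sim <- maybe_trigger_unmanageable(sim)
  d <- sim_draw(sim, function() sample.int(2147483646L, 1L))
  sim <- d$sim
  if (is.function(policy$reset)) policy$reset(d$value)
  step_i <- 0L
  while (sim$clock < day_end) {
    step_i <- step_i + 1L
    action <- policy$decide(sim)
    before <- sim$clock
    sim <- apply_action(sim, action, step_i)
    if (sim$clock == before) sim <- sim_step(sim)
  }
  list(sim = sim, log = day_log(sim, day))
}

#' Score a day against its goal
#'
#' `pain_under_threshold` days: the achieved fraction is the fraction of
#' sampled minutes with pain *strictly* under the threshold (a literal
#' reading of "keep pain under N"). `minimize_doses` days: the fraction
#' decreases linearly from 1 at zero tablets to 0 at the configured
#' ceiling. Stars: 3 at fraction >= 0.95, 2 at >= 0.6, else 1. Task
#' completion is reported separately and does not enter the rating.
#'
#' @param day_log a complete day's telemetry (from [run_day()] or
#'   [day_log()]).
#' @param goal a goal record from [load_goals()].
#' @param star_thresholds list with `three` and `two` fractions.
#' @return object of class `star_rating` with fields `day_index`,
#'   `stars` (1-3), `achieved_fraction`, `kind` and `total_tablets`.
#' @export
evaluate_goal <- function(day_log, goal,
                          star_thresholds = list(three = 0.95, two = 0.6)) {
  samples <- Filter(function(e) e$kind == "pain_sample", day_log)
  if (length(samples) < 2L)
    contract_error("evaluate_goal: incomplete day log (%d pain samples)",
                   length(samples))
  times <- vapply(samples, `[[`, numeric(1), "time")
  dtt <- diff(times)
  if (any(dtt <= 0) || length(unique(dtt)) != 1L)
    contract_error("evaluate_goal: pain samples not on a regular grid")
  if (times[length(times)] - times[1L] != 1440 || times[1L] %% 1440 != 0)
    contract_error("evaluate_goal: log does not cover one full day")
  pain <- vapply(samples, function(e) e$payload$pain, numeric(1))
  tablets <- sum(vapply(Filter(function(e) e$kind == "dose", day_log),
                        function(e) e$payload$tablets, numeric(1)), 0)
  frac <- switch(goal$kind,
    pain_under_threshold = mean(pain < goal$threshold),
    minimize_doses = max(0, 1 - tablets / goal$dose_ceiling),
    config_error("unknown goal kind '%s'", goal$kind))
  stars <- if (frac >= star_thresholds$three) 3L
           else if (frac >= star_thresholds$two) 2L else 1L
  structure(list(day_index = goal$day_index, stars = stars,
                 achieved_fraction = frac, kind = goal$kind,
                 total_tablets = tablets),
            class = "star_rating")
}

#' @export
print.star_rating <- function(x, ...) {
  cat(sprintf("Day %d [%s]: %s (achieved %.1f%%, %d tablets)\n",
              x$day_index, x$kind,
              paste(rep("*", x$stars), collapse = ""),
              100 * x$achieved_fraction, as.integer(x$total_tablets)))
  invisible(x)
}

#' Run a full game session
#'
#' A session is three consecutive in-game days, each with its own goal,
#' ending in a star rating and a task report.
#'
#' @param config a `game_config`.
#' @param policy a policy object.
#' @param seed session seed; all randomness derives from it.
#' @param days number of days (default and maximum 3).
#' @return list of class `painsim_session` with `sim`, `ratings` (one
#'   `star_rating` per day), `day_logs` and `tasks`.
#' @export
run_session <- function(config, policy, seed = 1L, days = 3L) {
  days <- pos_int(days, "days", "run_session")
  if (days > 3L) config_error("run_session: a session has at most 3 days")
  sim <- sim_init(config, seed)
  ratings <- vector("list", days)
  logs <- vector("list", days)
  tasks <- vector("list", days)
  for (day in seq_len(days)) {
    res <- run_day(sim, policy)
    sim <- res$sim
    goal <- config$goals$goals[[as.character(day)]]
    ratings[[day]] <- evaluate_goal(res$log, goal, config$goals$star_thresholds)
    logs[[day]] <- res$log
    tasks[[day]] <- list(required = sim$tasklist$required,
                         completed = sim$tasklist$completed)
  }
  structure(list(sim = sim, ratings = ratings, day_logs = logs, tasks = tasks),
            class = "painsim_session")
}

#' @export
print.painsim_session <- function(x, ...) {
  cat(sprintf("painsim session: %d day(s), %d telemetry entries\n",
              length(x$ratings), length(x$sim$log)))
  for (r in x$ratings) print(r)
  invisible(x)
}
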