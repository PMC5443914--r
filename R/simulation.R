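# Discrete-time pain dynamics for one avatar. Time is measured in
# in-game minutes since 09:00 of day 1; each day is exactly 1440
# minutes. At every step of `dt` minutes the pain level relaxes toward
# an attractor
#
#   target = clamp(baseline(t) - min(relief_cap, sum of dose reliefs)
#                              + activity offset, 0, 10)
#
# with per-step pull 1 - exp(-relaxation_rate * dt), and is clamped to
# the 0-10 numeric rating scale. During an unmanageable-pain episode
# medication relief is ignored and pain is floored at the configured
# NRS floor (8) until a help-line consult clears it.

day_of <- function(clock) as.integer(clock %/% 1440) + 1L

#' Baseline (no-intervention) pain at a clock time
#'
#' Piecewise-linear interpolation of the per-day anchor values; beyond
#' day 3 the final anchor is held.
#'
#' @param params `pain_model_params` from [load_model_params()].
#' @param clock in-game minutes since 09:00 of day 1.
#' @return NRS value in `[0, 10]`.
#' @export
baseline_pain_at <- function(params, clock) {
  day <- min(day_of(clock), length(params$baseline))
  hours <- (clock - (day - 1L) * 1440) / 60
  stats::approx(params$anchor_hours, params$baseline[[day]],
                xout = clamp(hours, min(params$anchor_hours), max(params$anchor_hours)),
                rule = 2)$y
}

#' Mobility factor as a function of pain
#'
#' Linear from 1 at pain 0 down to `floor` (default 0.2) at pain 10.
#' Activities that require movement take `duration / mobility` minutes.
#'
#' @param pain NRS value in `[0, 10]` (vectorised).
#' @param floor mobility at pain 10; must lie in (0, 1].
#' @return factor in `(0, 1]`, non-increasing in pain.
#' @export
mobility_factor <- function(pain, floor = 0.2) {
  if (any(!is.finite(pain)) || any(pain < 0) || any(pain > 10))
    contract_error("mobility_factor: pain must lie in [0, 10]")
  1 - (1 - floor) * pain / 10
}

#' Initialise a simulation
#'
#' @param config a `game_config` from [load_game_config()].
#' @param seed integer seed for the session RNG; every stochastic draw
#'   (event scheduling, monologue, random policies) flows through it.
#' @param start_day first day to simulate (1-3); pain starts at that
#'   day's baseline.
#' @return object of class `painsim_sim` holding the avatar state, the
#'   append-only telemetry log and the RNG state.
#' @export
sim_init <- function(config, seed = 1L, start_day = 1L) {
  if (!inherits(config, "game_config"))
    config_error("sim_init: config must come from load_game_config()")
  start_day <- pos_int(start_day, "start_day", "sim_init")
  clock <- (start_day - 1L) * 1440
  pain <- baseline_pain_at(config$params, clock)
  sim <- structure(list(
    config = config,
    clock = clock,
    day_index = start_day,
    pain = pain,
    baseline_pain = pain,
    mobility = mobility_factor(pain, config$params$mobility_min),
    doses = list(),            # accepted dose_event records
    effects = list(),          # transient activity/advice offsets
    side_effects = list(),     # effect_id -> expiry time
    unmanageable_active = FALSE,
    event_time = NA_real_,     # scheduled unmanageable-event minute
    event_fired = FALSE,
    last_relief = 0,
    med_msg_armed = FALSE,
    tasklist = NULL,
    rng = rng_state(seed),
    log = list()
  ), class = "painsim_sim")
  log_add(sim, clock, "pain_sample",
          list(pain = pain, relief = 0, baseline = pain))
}

# summed offset of transient effects active at time t
# (negative = relieving, from rest/distraction or post-consult advice)
activity_offset <- function(sim, t) {
  if (length(sim$effects) == 0L) return(0)
  sum(vapply(sim$effects, function(e) {
    if (t >= e$t_start && t < e$t_end) e$magnitude else 0
  }, numeric(1)))
}

#' Advance the simulation by one time step
#'
#' Applies the relaxation dynamics described above, triggers a scheduled
#' unmanageable-pain event when its minute is reached, expires side
#' effects and transient activity offsets, updates mobility, appends a
#' pain sample to the log and (when enabled) emits inner-monologue
#' messages.
#'
#' @param sim a `painsim_sim`.
#' @return the advanced simulation.
#' @export
sim_step <- function(sim) {
  p <- sim$config$params
  ev <- sim$config$goals$unmanageable_event
  dt <- p$dt
  t0 <- sim$clock
  t1 <- t0 + dt

  if (!sim$event_fired && !is.na(sim$event_time) && t0 >= sim$event_time) {
    sim$event_fired <- TRUE
    sim$unmanageable_active <- TRUE
    sim$pain <- max(sim$pain, ev$pain_floor)
    sim <- log_add(sim, t0, "event_trigger", list(pain = sim$pain))
  }

  relief_med <- if (sim$unmanageable_active) 0 else
    min(p$relief_cap, total_dose_relief(sim, t0))
  target <- clamp(baseline_pain_at(p, t0) - relief_med + activity_offset(sim, t0),
                  0, 10)
  pull <- 1 - exp(-p$relaxation_rate * dt)
  pain <- clamp(sim$pain + pull * (target - sim$pain), 0, 10)
  if (sim$unmanageable_active) pain <- max(pain, ev$pain_floor)

  sim$pain <- pain
  sim$clock <- t1
  sim$day_index <- day_of(t1)
  sim$baseline_pain <- baseline_pain_at(p, t1)
  sim$mobility <- mobility_factor(pain, p$mobility_min)

  # expire side effects
  if (length(sim$side_effects)) {
    gone <- names(sim$side_effects)[vapply(sim$side_effects, function(x) x <= t1, logical(1))]
    for (fx in gone) {
      sim <- log_add(sim, t1, "side_effect_end", list(effect_id = fx))
      sim$side_effects[[fx]] <- NULL
    }
  }
  # drop finished transient effects
  if (length(sim$effects))
    sim$effects <- Filter(function(e) e$t_end > t1, sim$effects)

  sim <- log_add(sim, t1, "pain_sample",
                 list(pain = pain, relief = relief_med, baseline = sim$baseline_pain))
  if (p$monologue$enabled) sim <- monologue_step(sim, relief_med)
  sim$last_relief <- relief_med
  sim
}

#' Take a dose of medication
#'
#' Validates the dose against `max_tablets_per_dose`,
#' `max_tablets_per_day` and `min_dose_interval`; a violating dose is
#' *refused* — the refusal is appended to the telemetry log and the dose
#' list is left unchanged. An accepted dose is logged and the
#' medication's side-effect rules are evaluated immediately (the
#' just-swallowed tablets count toward `tablets_in_effect` triggers).
#'
#' @param sim a `painsim_sim`.
#' @param med_id medication id; unknown ids raise a configuration error.
#' @param tablets positive integer.
#' @return the updated simulation.
#' @export
take_dose <- function(sim, med_id, tablets) {
  spec <- sim$config$medications[[med_id]]
  if (is.null(spec)) config_error("unknown medication '%s'", med_id)
  tablets <- pos_int(tablets, "tablets", "dose", med_id)
  t <- sim$clock

  refuse <- function(reason) {
    log_add(sim, t, "refusal",
            list(what = "dose", med_id = med_id, tablets = tablets,
                 reason = reason))
  }
  if (tablets > spec$max_tablets_per_dose)
    return(refuse("max_tablets_per_dose"))
  if (tablets_today(sim, med_id, t) + tablets > spec$max_tablets_per_day)
    return(refuse("max_tablets_per_day"))
  last <- NA_real_
  for (d in sim$doses) if (d$med_id == med_id) last <- d$time_taken
  if (!is.na(last) && t - last < spec$min_dose_interval)
    return(refuse("min_dose_interval"))

  dose <- dose_event(med_id, tablets, t, spec)
  sim$doses[[length(sim$doses) + 1L]] <- dose
  sim <- log_add(sim, t, "dose",
                 list(med_id = med_id, tablets = tablets))
  sim$med_msg_armed <- TRUE

  for (rule in spec$side_effect_rules) {
    val <- switch(rule$metric,
                  tablets_in_effect = tablets_loaded(sim, med_id, t),
                  daily_tablets = tablets_today(sim, med_id, t))
    if (val >= rule$threshold) {
      expiry <- t + rule$duration
      already <- !is.null(sim$side_effects[[rule$effect_id]])
      sim$side_effects[[rule$effect_id]] <-
        max(expiry, sim$side_effects[[rule$effect_id]] %||% -Inf)
      if (!already)
        sim <- log_add(sim, t, "side_effect_onset",
                       list(effect_id = rule$effect_id, until = expiry))
    }
  }
  sim
}

# helper used by policies: would take_dose accept this dose now?
#' Check whether a dose would be accepted under the dosing limits
#' @inheritParams take_dose
#' @return `TRUE` if [take_dose()] would accept the dose at the current clock.
#' @export
can_dose <- function(sim, med_id, tablets) {
  spec <- sim$config$medications[[med_id]]
  if (is.null(spec)) config_error("unknown medication '%s'", med_id)
  if (tablets > spec$max_tablets_per_dose) return(FALSE)
  if (tablets_today(sim, med_id) + tablets > spec$max_tablets_per_day) return(FALSE)
  last <- NA_real_
  for (d in sim$doses) if (d$med_id == med_id) last <- d$time_taken
  if (!is.na(last) && sim$clock - last < spec$min_dose_interval) return(FALSE)
  TRUE
}
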