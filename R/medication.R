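# Analgesic relief kinetics. Each dose contributes a piecewise-linear
# relief curve: zero until `onset`, linear rise to tablets * peak_relief
# at `time_to_peak`, linear decay back to zero at `effect_duration`.
# The triangle is the simplest continuous curve with the required
# "relief begins after an onset time and wears off" behaviour, and its
# area is available in closed form for oracle tests.

#' Construct a dose event
#'
#' @param med_id medication id (must exist in the medication table).
#' @param tablets positive integer number of tablets taken at once.
#' @param time_taken in-game minutes since 09:00 of day 1.
#' @param spec optional [medication_spec()]; when given, `tablets` is
#'   validated against `max_tablets_per_dose`.
#' @return object of class `dose_event`.
#' @export
dose_event <- function(med_id, tablets, time_taken, spec = NULL) {
  tablets <- pos_int(tablets, "tablets", "dose", med_id)
  if (!is.numeric(time_taken) || time_taken < 0)
    contract_error("dose '%s': time_taken must be >= 0", med_id)
  if (!is.null(spec) && tablets > spec$max_tablets_per_dose)
    contract_error("dose '%s': %d tablets exceeds max_tablets_per_dose (%d)",
                   med_id, tablets, spec$max_tablets_per_dose)
  structure(list(med_id = as.character(med_id), tablets = tablets,
                 time_taken = as.numeric(time_taken)),
            class = "dose_event")
}

#' Relief contributed by one dose at a given time
#'
#' @param dose a [dose_event()].
#' @param spec the matching [medication_spec()].
#' @param t in-game minutes (vectorised); must satisfy `t >= time_taken`.
#' @return NRS points of relief (non-negative), continuous in `t`.
#' @export
dose_relief <- function(dose, spec, t) {
  if (is.null(spec)) config_error("unknown medication '%s'", dose$med_id)
  e <- t - dose$time_taken
  if (any(e < 0)) contract_error("dose_relief: t precedes time_taken")
  peak <- dose$tablets * spec$peak_relief
  up <- (e - spec$onset) / (spec$time_to_peak - spec$onset)
  down <- (spec$effect_duration - e) / (spec$effect_duration - spec$time_to_peak)
  r <- ifelse(e < spec$onset, 0,
       ifelse(e < spec$time_to_peak, peak * up,
       ifelse(e < spec$effect_duration, peak * down, 0)))
  pmax(0, r)
}

# summed relief of all logged doses at time t (uncapped)
total_dose_relief <- function(sim, t) {
  if (length(sim$doses) == 0L) return(0)
  sum(vapply(sim$doses, function(d) {
    if (t < d$time_taken) return(0)
    dose_relief(d, sim$config$medications[[d$med_id]], t)
  }, numeric(1)))
}

#' Tablets of a medication currently in effect
#'
#' Mirrors the in-game medication board: counts tablets of doses whose
#' elapsed time lies in `[onset, effect_duration)`.
#'
#' @param sim a simulation object (see [sim_init()]).
#' @param med_id medication id.
#' @param at time to evaluate at; defaults to the simulation clock.
#' @return integer tablet count.
#' @export
tablets_in_effect <- function(sim, med_id, at = sim$clock) {
  spec <- sim$config$medications[[med_id]]
  if (is.null(spec)) config_error("unknown medication '%s'", med_id)
  n <- 0L
  for (d in sim$doses) {
    if (d$med_id != med_id) next
    e <- at - d$time_taken
    if (e >= spec$onset && e < spec$effect_duration) n <- n + d$tablets
  }
  n
}

# tablets swallowed and not yet worn off (elapsed in [0, effect_duration));
# used by side-effect triggers so the triggering dose itself counts
tablets_loaded <- function(sim, med_id, at = sim$clock) {
  spec <- sim$config$medications[[med_id]]
  n <- 0L
  for (d in sim$doses) {
    if (d$med_id != med_id) next
    e <- at - d$time_taken
    if (e >= 0 && e < spec$effect_duration) n <- n + d$tablets
  }
  n
}

#' Tablets of a medication taken during the current day
#'
#' Counts tablets of every dose taken in the in-game day containing
#' `at`; the quantity the daily dosing limit is checked against.
#'
#' @inheritParams tablets_in_effect
#' @return integer tablet count.
#' @export
tablets_today <- function(sim, med_id, at = sim$clock) {
  day <- at %/% 1440
  n <- 0L
  for (d in sim$doses) {
    if (d$med_id == med_id && d$time_taken %/% 1440 == day) n <- n + d$tablets
  }
  n
}
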