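# Activities of everyday life: chores and self-care that the task list
# requires, plus rest and distraction that relieve pain while performed.
# An activity's pain_effect acts as a transient offset fed through the
# same relaxation dynamics as medication relief, so a single dynamical
# mechanism covers both.

#' Create a task list for a day
#' @param day_index 1-3.
#' @param required character vector of required activity ids.
#' @return object of class `task_list`.
#' @export
new_tasklist <- function(day_index, required) {
  structure(list(day_index = as.integer(day_index),
                 required = as.character(required),
                 completed = character(0)),
            class = "task_list")
}

#' Tasks still to do
#' @param tasklist a [new_tasklist()] object.
#' @return required-but-uncompleted activity ids, in required order.
#' @export
remaining_tasks <- function(tasklist) {
  if (!inherits(tasklist, "task_list"))
    contract_error("remaining_tasks: not a task_list")
  tasklist$required[!tasklist$required %in% tasklist$completed]
}

#' Perform an activity
#'
#' Advances the clock by the activity's duration — inflated by
#' `1 / mobility` (mobility at the start of the activity) when the
#' activity requires movement, and rounded up to whole `dt` steps. The
#' activity's `pain_effect` is applied as a transient offset for its
#' duration. Chores and self-care marked `counts_toward_tasks` complete
#' the matching task. A movement activity attempted at pain at or above
#' the immobility threshold (default 9) is refused and logged, leaving
#' the state unchanged. Activities are truncated at the end of the
#' current day (the day ends after a preset amount of in-game time,
#' whatever the avatar is doing).
#'
#' @param sim a `painsim_sim`.
#' @param activity_id id from the activity catalog.
#' @return the updated simulation.
#' @export
perform_activity <- function(sim, activity_id) {
  act <- sim$config$activities[[activity_id]]
  if (is.null(act)) config_error("unknown activity '%s'", activity_id)
  p <- sim$config$params
  t <- sim$clock

  if (act$requires_movement && sim$pain >= p$immobility_threshold)
    return(log_add(sim, t, "refusal",
                   list(what = "activity", id = activity_id,
                        reason = "immobile")))

  dur <- act$duration
  if (act$requires_movement) dur <- dur / sim$mobility
  dur <- ceiling(dur / p$dt) * p$dt
  end <- min(t + dur, day_of(t) * 1440)

  cls <- if (act$pain_effect < 0) "relieving"
         else if (act$pain_effect > 0) "impairing" else "neutral"
  sim <- log_add(sim, t, "activity",
                 list(id = activity_id, kind = act$kind,
                      pain_effect = act$pain_effect,
                      duration = end - t, class = cls))
  sim$effects[[length(sim$effects) + 1L]] <-
    list(id = activity_id, magnitude = act$pain_effect, t_start = t, t_end = end)

  if (act$counts_toward_tasks && !is.null(sim$tasklist) &&
      activity_id %in% sim$tasklist$required &&
      !activity_id %in% sim$tasklist$completed)
    sim$tasklist$completed <- c(sim$tasklist$completed, activity_id)

  while (sim$clock < end) sim <- sim_step(sim)
  sim
}
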