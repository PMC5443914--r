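# Scripted player policies: each operationalises one pain-management
# strategy the game is meant to let players explore — from taking no
# medication at all, through PRN dosing (waiting until pain is severe),
# to regular scheduled dosing, the strategy the game teaches.

#' Create a policy object
#'
#' @param id short policy name.
#' @param decide function `(sim) -> action`, where an action is a list
#'   with `type` in `idle`, `dose` (`med_id`, `tablets`), `activity`
#'   (`id`) or `consult`.
#' @param reset optional function `(seed)` called at the start of every
#'   day with a seed drawn from the session RNG (used by stochastic
#'   policies).
#' @return object of class `painsim_policy`.
#' @export
make_policy <- function(id, decide, reset = NULL) {
  if (!is.function(decide)) config_error("policy '%s': decide must be a function", id)
  structure(list(id = id, decide = decide, reset = reset),
            class = "painsim_policy")
}

act_idle <- list(type = "idle")

# first still-required task whose activity is currently performable
next_task_action <- function(sim) {
  if (is.null(sim$tasklist)) return(NULL)
  for (id in remaining_tasks(sim$tasklist)) {
    act <- sim$config$activities[[id]]
    if (is.null(act)) next
    if (act$requires_movement && sim$pain >= sim$config$params$immobility_threshold)
      next
    return(list(type = "activity", id = id))
  }
  NULL
}

# consult as soon as an unmanageable episode is active; used by every
# sensible builtin policy
consult_if_needed <- function(sim) {
  if (isTRUE(sim$unmanageable_active)) list(type = "consult") else NULL
}

policy_no_med <- function() {
  make_policy("no_med", function(sim) {
    consult_if_needed(sim) %||% next_task_action(sim) %||%
      list(type = "activity", id = "rest_sofa")
  })
}

policy_prn <- function(trigger = 7, med_id = "paracetamol_codeine", tablets = 2L) {
  make_policy("prn_wait_for_severe", function(sim) {
    a <- consult_if_needed(sim)
    if (!is.null(a)) return(a)
    if (sim$pain >= trigger && can_dose(sim, med_id, tablets))
      return(list(type = "dose", med_id = med_id, tablets = tablets))
    next_task_action(sim) %||% list(type = "activity", id = "rest_sofa")
  })
}

policy_scheduled <- function() {
  # paracetamol 2 tablets four times a day, ibuprofen once every 8 hours:
  # regular dosing within the configured limits
  para_slots <- c(0, 360, 720, 1080)
  ibu_slots <- c(60, 540, 1020)
  make_policy("scheduled_dosing", function(sim) {
    a <- consult_if_needed(sim)
    if (!is.null(a)) return(a)
    minute <- sim$clock %% 1440
    n_para <- tablets_today(sim, "paracetamol") / 2
    if (n_para < length(para_slots) && minute >= para_slots[n_para + 1] &&
        can_dose(sim, "paracetamol", 2L))
      return(list(type = "dose", med_id = "paracetamol", tablets = 2L))
    n_ibu <- tablets_today(sim, "ibuprofen")
    if (n_ibu < length(ibu_slots) && minute >= ibu_slots[n_ibu + 1] &&
        can_dose(sim, "ibuprofen", 1L))
      return(list(type = "dose", med_id = "ibuprofen", tablets = 1L))
    next_task_action(sim) %||% list(type = "activity", id = "rest_sofa")
  })
}

policy_rest_distract <- function() {
  make_policy("rest_and_distract", function(sim) {
    a <- consult_if_needed(sim)
    if (!is.null(a)) return(a)
    if (sim$pain < 4) {
      t <- next_task_action(sim)
      if (!is.null(t)) return(t)
    }
    hours <- (sim$clock %% 1440) %/% 60
    list(type = "activity",
         id = c("rest_sofa", "watch_tv", "lie_in_bed", "use_computer")[hours %% 4 + 1])
  })
}

policy_random <- function() {
  st <- new.env(parent = emptyenv())
  st$rng <- rng_state(0)
  make_policy(
    "random",
    decide = function(sim) {
      cands <- list(act_idle, list(type = "consult"))
      for (a in sim$config$activities) {
        if (a$requires_movement && sim$pain >= sim$config$params$immobility_threshold)
          next
        cands[[length(cands) + 1L]] <- list(type = "activity", id = a$id)
      }
      for (m in sim$config$medications) {
        if (can_dose(sim, m$id, 1L))
          cands[[length(cands) + 1L]] <- list(type = "dose", med_id = m$id,
                                              tablets = 1L)
      }
      r <- with_rng(st$rng, function() runif(1))
      st$rng <- r$state
      cands[[1L + floor(r$value * length(cands))]]
    },
    reset = function(seed) st$rng <- rng_state(seed))
}

#' Built-in player policies
#'
#' * `no_med`: never doses; does the daily tasks, rests otherwise.
#' * `prn_wait_for_severe`: doses only once pain reaches NRS 7 —
#'   the "wait until it is intolerable" strategy the game warns against.
#' * `scheduled_dosing`: regular within-limits dosing at fixed times.
#' * `rest_and_distract`: non-pharmacological management only.
#' * `random`: uniformly random legal actions (fuzzing; reseeded from
#'   the session RNG each day).
#'
#' All policies call the help line as soon as an unmanageable-pain
#' episode starts.
#'
#' @return named list of `painsim_policy` objects.
#' @export
builtin_policies <- function() {
  list(no_med = policy_no_med(),
       prn_wait_for_severe = policy_prn(),
       scheduled_dosing = policy_scheduled(),
       rest_and_distract = policy_rest_distract(),
       random = policy_random())
}
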