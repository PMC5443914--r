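# Shared fixtures. The default configuration is loaded once per test
# run; tests that need determinism disable the random unmanageable
# event through an override.

.cfg_cache <- new.env(parent = emptyenv())

test_config <- function() {
  if (is.null(.cfg_cache$cfg)) .cfg_cache$cfg <- load_game_config()
  .cfg_cache$cfg
}

# default config with the unmanageable event switched off (and,
# optionally, further nested overrides merged in)
quiet_config <- function(overrides = NULL) {
  cfg <- load_game_config(overrides = utils::modifyList(
    list(goals = list(unmanageable_event = list(probability = 0))),
    overrides %||% list()))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# synthetic complete day log: constant pain, optional dose entries
constant_day_log <- function(pain, day = 2L, dt = 60, tablets_at = numeric(0)) {
  lo <- (day - 1L) * 1440
  times <- seq(lo, lo + 1440, by = dt)
  log <- lapply(times, function(t)
    list(time = t, kind = "pain_sample",
         payload = list(pain = pain, relief = 0, baseline = pain)))
  for (tt in tablets_at)
    log[[length(log) + 1L]] <- list(time = lo + tt, kind = "dose",
                                    payload = list(med_id = "paracetamol",
                                                   tablets = 1L))
  log[order(vapply(log, `[[`, numeric(1), "time"))]
}

# policy replaying a fixed schedule of actions keyed by minute-of-day;
# idles (or rests) otherwise. Non-advancing actions fire at most once.
script_policy <- function(schedule, filler = list(type = "idle")) {
  st <- new.env(parent = emptyenv())
  st$done <- rep(FALSE, length(schedule))
  make_policy(
    "script",
    decide = function(sim) {
      minute <- sim$clock %% 1440
      for (i in seq_along(schedule)) {
        if (!st$done[i] && minute >= schedule[[i]]$minute) {
          st$done[i] <- TRUE
          return(schedule[[i]]$action)
        }
      }
      filler
    },
    reset = function(seed) st$done <- rep(FALSE, length(schedule)))
}

idle_policy <- function() make_policy("idle", function(sim) list(type = "idle"))

# policy that takes every allowed dose of every medication and never
# consults (used for the unmanageable-episode floor checks)
max_dosing_policy <- function(rest = FALSE) {
  make_policy("max_dosing", function(sim) {
    for (m in sim$config$medications) {
      n <- m$max_tablets_per_dose
      if (can_dose(sim, m$id, n))
        return(list(type = "dose", med_id = m$id, tablets = n))
    }
    if (rest) list(type = "activity", id = "rest_sofa") else list(type = "idle")
  })
}

# relief top-up: whenever applied medication relief dips below the
# threshold, take the next available within-limits dose (strongest
# first); rest in bed otherwise. The strongest legal pain-suppression
# script, robust to schedule drift across the day boundary.
coverage_dosing_policy <- function(threshold = 4) {
  make_policy("coverage_dosing", function(sim) {
    if (sim$last_relief < threshold)
      for (med in c("paracetamol_codeine", "tramadol", "paracetamol",
                    "ibuprofen")) {
        n <- sim$config$medications[[med]]$max_tablets_per_dose
        if (can_dose(sim, med, n))
          return(list(type = "dose", med_id = med, tablets = n))
      }
    list(type = "activity", id = "lie_in_bed")
  })
}

pain_samples <- function(entries) {
  s <- Filter(function(e) e$kind == "pain_sample", entries)
  data.frame(time = vapply(s, `[[`, numeric(1), "time"),
             pain = vapply(s, function(e) e$payload$pain, numeric(1)),
             relief = vapply(s, function(e) e$payload$relief, numeric(1)))
}

entries_of_kind <- function(entries, kind)
  Filter(function(e) e$kind == kind, entries)

# independent enumeration oracle for the signed-rank test: loop over
# every sign assignment explicitly (no shared code with the package)
oracle_signed_rank <- function(pre, post, alternative = "two.sided") {
  d <- post - pre
  d <- d[d != 0]
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  sums <- as.vector(signs %*% r)
  p_ge <- mean(sums >= W - 1e-9)
  p_le <- mean(sums <= W + 1e-9)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}
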