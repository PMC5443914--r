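# Core dynamics: bounds, determinism, monotonicity, dosing guards,
# side-effect triggers, the unmanageable-pain contract.

test_that("mobility decreases linearly with pain and rejects out-of-range input", {
  expect_identical(mobility_factor(0), 1)
  expect_lt(mobility_factor(10), mobility_factor(0))
  grid <- seq(0, 10, by = 0.5)
  m <- mobility_factor(grid)
  expect_true(all(diff(m) <= 0))
  expect_true(all(m > 0 & m <= 1))
  expect_error(mobility_factor(-0.1), class = "painsim_contract_error")
  expect_error(mobility_factor(10.5), class = "painsim_contract_error")
})

test_that("pain stays in [0, 10] for a full random-policy day and relief never exceeds the cap", {
  cfg <- test_config()
  res <- run_day(sim_init(cfg, seed = 101), builtin_policies()$random)
  s <- pain_samples(res$log)
  expect_true(all(s$pain >= 0 & s$pain <= 10))
  expect_true(all(s$relief <= cfg$params$relief_cap + 1e-12))
  expect_true(all(s$relief >= 0))
})

test_that("identical seed and action sequence give bit-identical trajectories", {
  cfg <- test_config()
  go <- function() {
    sim <- sim_init(cfg, seed = 55)
    sim <- take_dose(sim, "ibuprofen", 1L)
    for (i in 1:50) sim <- sim_step(sim)
    sim <- take_dose(sim, "paracetamol", 2L)
    for (i in 1:50) sim <- sim_step(sim)
    sim
  }
  expect_identical(go()$log, go()$log)
})

test_that("one within-limits dose never increases pain at any step (paired simulation)", {
  cfg <- quiet_config()
  run <- function(dose_step) {
    sim <- sim_init(cfg, seed = 9)
    for (i in 1:200) {
      if (!is.na(dose_step) && i == dose_step)
        sim <- take_dose(sim, "paracetamol_codeine", 2L)
      sim <- sim_step(sim)
    }
    pain_samples(sim$log)$pain
  }
  without <- run(NA)
  with <- run(25)
  expect_true(all(with <= without + 1e-12))
  expect_lt(min(with - without), -0.5)  # the dose actually does something
})

test_that("dosing guards refuse (and log) over-limit doses without changing state", {
  cfg <- quiet_config()
  sim <- sim_init(cfg, seed = 2)
  sim <- take_dose(sim, "paracetamol", 2L)
  expect_length(sim$doses, 1L)
  # second dose inside min_dose_interval: refused, dose list unchanged
  sim <- sim_step(sim)
  sim <- take_dose(sim, "paracetamol", 2L)
  expect_length(sim$doses, 1L)
  ref <- entries_of_kind(sim$log, "refusal")
  expect_length(ref, 1L)
  expect_identical(ref[[1]]$payload$reason, "min_dose_interval")
  # exceeding max_tablets_per_dose
  sim <- take_dose(sim, "ibuprofen", 2L)
  expect_identical(tail(entries_of_kind(sim$log, "refusal"), 1)[[1]]$payload$reason,
                   "max_tablets_per_dose")
  # exceeding max_tablets_per_day (ibuprofen: 3/day, interval 360)
  sim2 <- sim_init(cfg, seed = 2)
  for (k in 0:2) {
    sim2$clock <- k * 360
    sim2 <- take_dose(sim2, "ibuprofen", 1L)
  }
  sim2$clock <- 3 * 360
  sim2 <- take_dose(sim2, "ibuprofen", 1L)
  expect_identical(tail(entries_of_kind(sim2$log, "refusal"), 1)[[1]]$payload$reason,
                   "max_tablets_per_day")
  expect_error(take_dose(sim, "morphine", 1L), class = "painsim_config_error")
})

test_that("excessive codeine triggers nausea; triggers match brute-force re-evaluation", {
  cfg <- quiet_config()
  sim <- sim_init(cfg, seed = 3)
  sim <- take_dose(sim, "paracetamol_codeine", 2L)   # 2 loaded < 3
  expect_null(sim$side_effects$nausea)
  sim$clock <- 240                                    # past min interval
  sim <- take_dose(sim, "paracetamol_codeine", 2L)   # 4 loaded >= 3
  expect_false(is.null(sim$side_effects$nausea))
  expect_identical(entries_of_kind(sim$log, "side_effect_onset")[[1]]$payload$effect_id,
                   "nausea")

  # soundness: every onset in a random day is justified by re-counting
  # the logged doses against the rules, and vice versa
  res <- run_day(sim_init(test_config(), seed = 77), builtin_policies()$random)
  doses <- entries_of_kind(res$log, "dose")
  onsets <- entries_of_kind(res$log, "side_effect_onset")
  justified <- function(fx, t) {
    for (d in doses) {
      if (d$time != t) next
      spec <- test_config()$medications[[d$payload$med_id]]
      for (rule in spec$side_effect_rules) {
        if (rule$effect_id != fx) next
        val <- if (rule$metric == "daily_tablets") {
          sum(vapply(doses, function(x)
            if (x$payload$med_id == d$payload$med_id &&
                x$time <= t && x$time %/% 1440 == t %/% 1440)
              x$payload$tablets else 0L, numeric(1)))
        } else {
          sum(vapply(doses, function(x) {
            el <- t - x$time
            if (x$payload$med_id == d$payload$med_id && el >= 0 &&
                el < spec$effect_duration) x$payload$tablets else 0L
          }, numeric(1)))
        }
        if (val >= rule$threshold) return(TRUE)
      }
    }
    FALSE
  }
  for (o in onsets)
    expect_true(justified(o$payload$effect_id, o$time))
})

test_that("during an unmanageable episode pain stays >= 8 despite maximal dosing", {
  cfg <- load_game_config(overrides = list(
    goals = list(unmanageable_event = list(probability = 1))))
  sim <- sim_init(cfg, seed = 11)
  res <- run_day(sim, max_dosing_policy())
  trig <- entries_of_kind(res$log, "event_trigger")
  expect_length(trig, 1L)
  s <- pain_samples(res$log)
  after <- s[s$time > trig[[1]]$time, ]
  expect_gte(nrow(after), 1L)
  expect_true(all(after$pain >= 8))
  expect_true(all(after$relief == 0))   # "does not respond to pain medication"
})
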