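# Append-only telemetry and its after-action-review projection: the
# debriefing overlays the day's pain curve with classified nodes —
# doses, pain-relieving activities (rest/distraction) and
# pain-impairing activities (chores under pain), with an outline on
# nodes that fell inside an active side-effect window.

log_add <- function(sim, time, kind, payload) {
  n <- length(sim$log)
  if (n > 0L && time < sim$log[[n]]$time)
    contract_error("telemetry: entry at t=%s would precede t=%s",
                   time, sim$log[[n]]$time)
  sim$log[[n + 1L]] <- list(time = as.numeric(time), kind = kind,
                            payload = payload)
  sim
}

#' Extract one day's telemetry entries
#'
#' A day's log spans `[ (day-1)*1440, day*1440 ]` inclusive: the pain
#' sample on the 09:00 boundary belongs to both adjoining days, so every
#' complete day carries `1440/dt + 1` samples.
#'
#' @param sim a `painsim_sim`.
#' @param day day index (1-3).
#' @return list of log entries.
#' @export
day_log <- function(sim, day) {
  lo <- (day - 1) * 1440
  hi <- day * 1440
  # entries logged exactly at the end boundary belong to the next day
  # (the day's action loop has already exited), except the shared
  # boundary pain sample
  Filter(function(e) e$time >= lo && e$time <= hi &&
           !(e$time == hi && e$kind != "pain_sample"),
         sim$log)
}

#' Full telemetry as a data frame
#' @param sim a `painsim_sim` (or a list of log entries).
#' @return data frame with columns `time`, `kind`, `detail` (compact
#'   payload rendering).
#' @export
telemetry_frame <- function(sim) {
  entries <- if (inherits(sim, "painsim_sim")) sim$log else sim
  data.frame(
    time = vapply(entries, `[[`, numeric(1), "time"),
    kind = vapply(entries, `[[`, "", "kind"),
    detail = vapply(entries, function(e)
      paste(names(e$payload),
            vapply(e$payload, function(v) paste(format(v), collapse = "/"), ""),
            sep = "=", collapse = " "), ""),
    stringsAsFactors = FALSE)
}

# side-effect intervals [onset, end) reconstructed from a log
side_effect_intervals <- function(entries) {
  ons <- Filter(function(e) e$kind == "side_effect_onset", entries)
  if (!length(ons)) return(data.frame(effect_id = character(0),
                                      start = numeric(0), end = numeric(0)))
  data.frame(
    effect_id = vapply(ons, function(e) e$payload$effect_id, ""),
    start = vapply(ons, `[[`, numeric(1), "time"),
    end = vapply(ons, function(e) e$payload$until, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Export the pain/relief trajectory as CSV
#'
#' @param sim a `painsim_sim`.
#' @param path output CSV path.
#' @return the written data frame, invisibly. Columns: `day`,
#'   `clock_min` (minute of day), `pain`, `relief_total`,
#'   `active_side_effects` (semicolon-joined ids).
#' @export
export_trajectory <- function(sim, path) {
  samples <- Filter(function(e) e$kind == "pain_sample", sim$log)
  iv <- side_effect_intervals(sim$log)
  t <- vapply(samples, `[[`, numeric(1), "time")
  fx <- vapply(t, function(tt) {
    act <- iv$effect_id[iv$start <= tt & tt < iv$end]
    paste(unique(act), collapse = ";")
  }, "")
  df <- data.frame(
    day = day_of(pmax(0, t - 1e-9)),
    clock_min = t %% 1440 + ifelse(t > 0 & t %% 1440 == 0, 1440, 0),
    pain = vapply(samples, function(e) e$payload$pain, numeric(1)),
    relief_total = vapply(samples, function(e) e$payload$relief, numeric(1)),
    active_side_effects = fx,
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Build the after-action-review timeline for one day
#'
#' @param day_log a day's entries from [day_log()] or [run_day()].
#' @return object of class `painsim_timeline`: `pain_curve` (data frame
#'   `time`, `pain`) and `nodes` (data frame `time`, `node_class` in
#'   dose/relieving/impairing, `side_effect_outline`, `label`). Neutral
#'   activities (`pain_effect == 0`) produce no node.
#' @export
build_timeline <- function(day_log) {
  times <- vapply(day_log, `[[`, numeric(1), "time")
  if (is.unsorted(times))
    contract_error("build_timeline: log entries are not time-ordered")
  samples <- Filter(function(e) e$kind == "pain_sample", day_log)
  pain_curve <- data.frame(
    time = vapply(samples, `[[`, numeric(1), "time"),
    pain = vapply(samples, function(e) e$payload$pain, numeric(1)))
  iv <- side_effect_intervals(day_log)
  in_side_effect <- function(tt)
    any(iv$start <= tt & tt < iv$end)
  nodes <- list()
  for (e in day_log) {
    node <- NULL
    if (e$kind == "dose") {
      node <- list(time = e$time, node_class = "dose",
                   label = sprintf("%s x%d", e$payload$med_id, e$payload$tablets))
    } else if (e$kind == "activity" && e$payload$class != "neutral") {
      node <- list(time = e$time, node_class = e$payload$class,
                   label = e$payload$id)
    }
    if (!is.null(node)) {
      node$side_effect_outline <- in_side_effect(node$time)
      nodes[[length(nodes) + 1L]] <- node
    }
  }
  nodes_df <- if (length(nodes)) {
    data.frame(
      time = vapply(nodes, `[[`, numeric(1), "time"),
      node_class = vapply(nodes, `[[`, "", "node_class"),
      side_effect_outline = vapply(nodes, `[[`, logical(1), "side_effect_outline"),
      label = vapply(nodes, `[[`, "", "label"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(time = numeric(0), node_class = character(0),
               side_effect_outline = logical(0), label = character(0),
               stringsAsFactors = FALSE)
  }
  structure(list(pain_curve = pain_curve, nodes = nodes_df),
            class = "painsim_timeline")
}

#' Export an after-action review
#'
#' JSON export is canonical and round-trips through [import_review()];
#' CSV export stacks the curve samples and the nodes with a `row_type`
#' discriminator (one row per curve sample plus one per node).
#'
#' @param timeline a `painsim_timeline`.
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_review <- function(timeline, path, format = c("json", "csv")) {
  if (!inherits(timeline, "painsim_timeline"))
    contract_error("export_review: not a painsim_timeline")
  format <- tryCatch(match.arg(format),
                     error = function(e) config_error("unknown review format"))
  if (format == "json") {
    jsonlite::write_json(
      list(schema = "painsim.review", version = 1L,
           pain_curve = timeline$pain_curve, nodes = timeline$nodes),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    curve <- data.frame(row_type = "pain_sample",
                        time = timeline$pain_curve$time,
                        pain = timeline$pain_curve$pain,
                        node_class = NA_character_,
                        side_effect_outline = NA,
                        label = NA_character_)
    nd <- timeline$nodes
    nodes <- data.frame(row_type = rep("node", nrow(nd)),
                        time = nd$time, pain = NA_real_,
                        node_class = nd$node_class,
                        side_effect_outline = nd$side_effect_outline,
                        label = nd$label)
    utils::write.csv(rbind(curve, nodes), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON review export
#' @param path file written by [export_review()] with `format = "json"`.
#' @return a `painsim_timeline`.
#' @export
import_review <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$schema, "painsim.review"))
    config_error("%s is not a painsim review file", path)
  nodes <- raw$nodes
  if (length(nodes) == 0L || is.null(nrow(nodes)) || nrow(nodes) == 0L)
    nodes <- data.frame(time = numeric(0), node_class = character(0),
                        side_effect_outline = logical(0), label = character(0),
                        stringsAsFactors = FALSE)
  structure(list(pain_curve = as.data.frame(raw$pain_curve),
                 nodes = as.data.frame(nodes)),
            class = "painsim_timeline")
}

#' Plot an after-action review timeline
#'
#' Base-graphics rendering of the debriefing overlay: the pain curve as
#' a black line, doses in orange, relieving activities in green,
#' impairing activities in red; yellow halos mark nodes inside a
#' side-effect window.
#'
#' @param x a `painsim_timeline`.
#' @param ... passed to `plot()`.
#' @export
plot.painsim_timeline <- function(x, ...) {
  plot(x$pain_curve$time / 60, x$pain_curve$pain, type = "l",
       ylim = c(0, 10), xlab = "hours since 09:00", ylab = "pain (NRS)",
       ...)
  if (nrow(x$nodes)) {
    y <- stats::approx(x$pain_curve$time, x$pain_curve$pain,
                       xout = x$nodes$time, rule = 2)$y
    halo <- x$nodes$side_effect_outline
    if (any(halo))
      points(x$nodes$time[halo] / 60, y[halo], pch = 21, cex = 2.2, bg = "yellow")
    cols <- c(dose = "orange", relieving = "forestgreen", impairing = "red")
    points(x$nodes$time / 60, y, pch = 19, col = cols[x$nodes$node_class])
  }
  invisible(x)
}

# JSON (de)serialisation of a full telemetry log, used by the CLI so a
# run can be reviewed later without re-simulating
write_telemetry <- function(sim, path) {
  jsonlite::write_json(list(schema = "painsim.telemetry", version = 1L,
                            entries = sim$log),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_telemetry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(raw$schema, "painsim.telemetry"))
    config_error("%s is not a painsim telemetry file", path)
  lapply(raw$entries, function(e)
    list(time = as.numeric(e$time), kind = e$kind, payload = e$payload))
}
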