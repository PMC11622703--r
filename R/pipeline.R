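# End-to-end study pipeline: simulate (or accept) a cohort -> per-resident
# per-phase metrics -> paired phase contrasts -> report. All randomness
# flows from the single config seed, so a run is deterministic.

#' Default study configuration
#'
#' Mirrors the three-phase baseline-intervention design: 11 residents, a
#' 4-week static baseline, 12 weeks of dynamic lighting analyzed as weeks
#' 5-10 and 10-16, weekly QUALIDEM panels, and the packaged thresholds and
#' anchors. Any element can be overridden via `...` or by editing the
#' returned list.
#'
#' @param seed master seed.
#' @param n_residents cohort size.
#' @param ... named overrides of top-level config entries.
#' @return a named list (class `study_config`).
#' @export
study_config <- function(seed = 1L, n_residents = 11, ...) {
  cfg <- list(
    seed = seed,
    n_residents = n_residents,
    start_date = "2023-03-06",
    tz = "Europe/London",
    effects = list(),            # list of intervention_effect()
    epoch_minutes = 15,
    night_window = c("22:00", "08:00"),
    theta = 10, min_run = 4, min_bout = 1,
    sunset = as.list(default_sunset_config()),
    melanopic_anchor = list(lux = 260, m_edi = 331, cs = 0.404),
    alpha = 0.05, alpha_norm = 0.05,
    qualidem_aggregator = "mean",   # phase value per resident
    sleep_aggregator = "median",
    qualidem_latent_sd = 0.25, qualidem_item_sd = 0.5,
    profile_overrides = list(),     # fields forced on every profile
    forced_nonparametric = character(0)) # parameters forced to rank branch
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = c("study_config", "list"))
}

#' Read a study configuration from YAML
#'
#' Effects may be given as a list of `{parameter, phase, delta}` entries.
#'
#' @param path YAML file.
#' @return `study_config` list.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$effects))
    raw$effects <- lapply(raw$effects, function(e)
      intervention_effect(e$parameter, e$phase, e$delta))
  do.call(study_config, raw)
}

#' Aggregate a per-week (or per-night) metric into per-phase values
#'
#' @param values data.table with columns `resident_id`, `week` (study
#'   week) and `value`.
#' @param plan a [phase_plan()].
#' @param aggregator `"mean"` or `"median"`.
#' @return data.table `resident_id`, `phase`, `value` (NA when a resident
#'   has no data in a phase).
#' @export
aggregate_phase <- function(values, plan, aggregator = c("mean",
                                                         "median")) {
  aggregator <- match.arg(aggregator)
  f <- if (aggregator == "mean") mean else median
  ph <- vapply(values$week, function(w) {
    for (p in names(plan$phases)) if (w %in% plan$phases[[p]]) return(p)
    NA_character_
  }, character(1))
  dt <- data.table::data.table(resident_id = values$resident_id,
                               phase = ph, value = values$value)
  dt <- dt[!is.na(phase)]
  if (nrow(dt) == 0L) stop("no values fall inside any phase")
  dt[, .(value = f(value, na.rm = TRUE)), by = .(resident_id, phase)]
}

# wide per-resident matrix of one metric across phases
phase_wide <- function(per_phase) {
  data.table::dcast(per_phase, resident_id ~ phase, value.var = "value")
}

#' Run the full study pipeline on a synthetic cohort
#'
#' Simulates the cohort defined by `config`, computes per-resident
#' per-phase rest-activity metrics (IS, IV, RA), pre-sunset (sundowning)
#' activity, sleep summaries, QUALIDEM subscale scores (A-H analyzed, I/J
#' reported only), and per-phase dynamic-lighting exposure, then runs the
#' gated paired contrasts of each dynamic phase against baseline.
#'
#' @param config a [study_config()] (or path to a YAML accepted by
#'   [read_study_config()]).
#' @param out_dir optional directory; when given, all tables are written
#'   as CSVs plus a JSON report.
#' @param verbose log thresholds and progress via `message()`.
#' @return object of class `study_report`: list with `metrics`
#'   (per-resident per-phase values), `sleep`, `qualidem`, `exposure`,
#'   `comparisons` (the contrast table), `truth`, `plan`, `config`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      verbose = FALSE) {
  if (is.character(config)) config <- read_study_config(config)
  plan <- phase_plan(start_date = config$start_date, tz = config$tz)
  say <- function(...) if (verbose) message(sprintf(...))
  say("phases: %s", paste(names(plan$phases), collapse = ", "))
  say("thresholds: theta=%g min_run=%d min_bout=%d night=%s-%s",
      config$theta, config$min_run, config$min_bout,
      config$night_window[1], config$night_window[2])

  profiles <- default_cohort_profiles(config$n_residents)
  if (length(config$profile_overrides))
    profiles <- lapply(profiles, function(p) {
      p[names(config$profile_overrides)] <- config$profile_overrides
      p
    })
  cohort <- simulate_cohort(profiles, config$effects, seed = config$seed,
                            plan = plan,
                            epoch_minutes = config$epoch_minutes,
                            qualidem_latent_sd = config$qualidem_latent_sd,
                            qualidem_item_sd = config$qualidem_item_sd)
  ids <- vapply(profiles, `[[`, character(1), "resident_id")
  phases <- names(plan$phases)

  # --- rest-activity + sundowning, per resident per phase ---------------
  act <- cohort$activity
  act[, phase := phase_of(epoch_start, plan)]
  rhythm <- list(); sundown <- list(); sleep_nights <- list()
  for (id in ids) for (p in phases) {
    a <- act[resident_id == id & phase == p]
    rm <- rhythm_metrics(a, config$epoch_minutes)
    rm[, `:=`(resident_id = id, phase = p)]
    rhythm[[length(rhythm) + 1L]] <- rm
    sd_ <- sundowning_activity(
      a, p, stats::setNames(unlist(config$sunset), names(config$sunset)))
    sd_[, resident_id := id]
    sundown[[length(sundown) + 1L]] <- sd_
    ns <- score_nights(a, night_window = config$night_window,
                       theta = config$theta, min_run = config$min_run,
                       min_bout = config$min_bout,
                       epoch_minutes = config$epoch_minutes)
    ns[, `:=`(resident_id = id, phase = p)]
    sleep_nights[[length(sleep_nights) + 1L]] <- ns
  }
  rhythm <- data.table::rbindlist(rhythm)
  sundown <- data.table::rbindlist(sundown)
  sleep_nights <- data.table::rbindlist(sleep_nights)

  sleep_summary <- data.table::rbindlist(lapply(phases, function(p)
    summarize_sleep(sleep_nights[phase == p], p)))
  # per-resident per-phase sleep values for the paired contrasts
  agg_f <- if (config$sleep_aggregator == "mean") mean else median
  sleep_res <- sleep_nights[scored == TRUE, .(
    disturbances = as.numeric(agg_f(n_disturbances)),
    bout_minutes = as.numeric(agg_f(unlist(bout_lengths))),
    total_sleep_hours = as.numeric(agg_f(total_sleep_hours))),
    by = .(resident_id, phase)]

  # --- QUALIDEM ----------------------------------------------------------
  scores <- score_qualidem_panel(cohort$qualidem)
  q_agg <- data.table::rbindlist(lapply(
    sort(unique(scores$subscale)), function(s) {
      ap <- aggregate_phase(scores[subscale == s,
                                   .(resident_id, week, value = score)],
                            plan, config$qualidem_aggregator)
      ap[, subscale := s]
      ap
    }))

  # --- exposure ----------------------------------------------------------
  occ <- cohort$occupancy
  occ[, phase := phase_of(epoch_start, plan)]
  exposure <- data.table::rbindlist(lapply(phases, function(p) {
    per <- data.table::rbindlist(lapply(ids, function(id)
      exposure_summary(occ[resident_id == id & phase == p],
                       cohort$switches[resident_id == id], p)))
    data.table::data.table(
      phase = p,
      pct_time_in_rooms = mean(per$pct_time_in_rooms),
      pct_lights_on_while_present = mean(per$pct_lights_on_while_present),
      pct_dynamic_exposure = mean(per$pct_dynamic_exposure))
  }))

  # --- paired contrasts --------------------------------------------------
  contrasts <- c("baseline vs weeks5_10", "baseline vs weeks10_16")
  cmp <- list()
  add_cmp <- function(wide, parameter) {
    for (ct in contrasts) {
      p2 <- sub("baseline vs ", "", ct)
      if (!all(c("baseline", p2) %in% names(wide))) next
      if (sum(complete.cases(wide$baseline, wide[[p2]])) < 3) next
      forced <- if (parameter %in% config$forced_nonparametric)
        "nonparametric" else NULL
      cmp[[length(cmp) + 1L]] <<- paired_compare(
        wide$baseline, wide[[p2]], parameter = parameter, contrast = ct,
        forced_branch = forced, alpha_norm = config$alpha_norm)
    }
  }
  for (m in c("IS", "IV", "RA")) {
    w <- phase_wide(rhythm[, .(resident_id, phase, value = get(m))])
    add_cmp(w, m)
  }
  add_cmp(phase_wide(sundown[, .(resident_id, phase,
                                 value = mean_activity_pct)]),
          "sundowning_activity")
  for (m in c("disturbances", "bout_minutes", "total_sleep_hours")) {
    w <- phase_wide(sleep_res[, .(resident_id, phase, value = get(m))])
    add_cmp(w, paste0("sleep_", m))
  }
  for (s in LETTERS[1:8]) {
    w <- phase_wide(q_agg[subscale == s,
                          .(resident_id, phase, value)])
    add_cmp(w, paste0("qualidem_", s))
  }
  comparisons <- data.table::rbindlist(cmp)
  comparisons[, significant := !is.na(p_value) & p_value < config$alpha]

  report <- structure(list(
    metrics = rhythm, sundowning = sundown, sleep_nights = sleep_nights,
    sleep_residents = sleep_res, sleep_summary = sleep_summary,
    qualidem_scores = scores, qualidem_phase = q_agg,
    exposure = exposure, comparisons = comparisons,
    truth = cohort$truth, plan = plan, config = config),
    class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", length(unique(x$metrics$resident_id)),
      "residents,", nrow(x$comparisons), "phase contrasts\n")
  sig <- x$comparisons[significant == TRUE]
  cat("Significant contrasts at alpha =", x$config$alpha, ":",
      nrow(sig), "\n")
  if (nrow(sig)) print(sig[, .(parameter, contrast, test,
                               p_value = signif(p_value, 3),
                               effect_size = signif(effect_size, 3),
                               effect_label)])
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes per-table CSVs, a JSON summary and a small markdown contrast
#' table (parameter, contrast, P, effect size, label) under `dir`.
#'
#' @param report a `study_report`.
#' @param dir output directory.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(dt, f) data.table::fwrite(dt, file.path(dir, f))
  w(report$metrics, "rhythm_metrics.csv")
  w(report$sundowning, "sundowning.csv")
  sn <- data.table::copy(report$sleep_nights)
  sn[, bout_lengths := vapply(bout_lengths, paste, character(1),
                              collapse = ";")]
  w(sn, "sleep_nights.csv")
  w(report$sleep_residents, "sleep_residents.csv")
  w(report$sleep_summary, "sleep_summary.csv")
  w(report$qualidem_scores, "qualidem_scores.csv")
  w(report$qualidem_phase, "qualidem_phase.csv")
  w(report$exposure, "exposure.csv")
  w(report$comparisons, "comparisons.csv")
  md <- c("| parameter | contrast | test | P | effect size | label |",
          "|---|---|---|---|---|---|",
          sprintf("| %s | %s | %s | %.3g | %.3g | %s |",
                  report$comparisons$parameter,
                  report$comparisons$contrast, report$comparisons$test,
                  report$comparisons$p_value,
                  report$comparisons$effect_size,
                  report$comparisons$effect_label))
  writeLines(md, file.path(dir, "comparisons.md"))
  jsonlite::write_json(
    list(seed = report$config$seed,
         alpha = report$config$alpha,
         n_residents = report$config$n_residents,
         exposure = report$exposure,
         significant = report$comparisons[significant == TRUE,
                                          .(parameter, contrast, p_value,
                                            effect_size, effect_label)]),
    file.path(dir, "report.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}
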