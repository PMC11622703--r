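# Lighting program and melanopic quantities.
#
# The luminaire's spectral power distribution is not available, so both
# melanopic pathways are anchored scalars on top of the photopic schedule:
# the melanopic ratio (M-EDI lux per photopic lux) and circadian light per
# lux (CL_A/lux) are config values whose defaults are anchored at the
# dimmest scheduled level (260 lux -> M-EDI 331, CS 0.404). The circadian
# stimulus model is the standard saturating form
#
#   CS = 0.7 * (1 - 1 / (1 + (CL_A / 355.7)^1.1026))
#
# A single anchored CL_A/lux cannot reproduce every schedule level exactly
# because the scheduled colour temperature (and hence spectrum) varies with
# level; the residual at the brightest level is ~0.002 CS and is accepted,
# not hidden.

.cs_sat <- list(cap = 0.7, half = 355.7, exponent = 1.1026)

#' Dynamic-lighting daily schedule
#'
#' The default is the packaged tunable-white intervention program: a warm
#' morning ramp, a cool bright midday block, and a warm dim evening
#' (photopic lux at eye level, CCT in kelvin, luminaire output percent).
#'
#' @param path optional YAML file with fields `start`, `end`, `lux`, `cct`,
#'   `output_pct` per entry; defaults to the packaged schedule.
#' @return data.frame of class `lighting_schedule` with numeric
#'   `start`/`end` clock hours, `lux`, `cct`, `output_pct`.
#' @export
lighting_schedule <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dynamic_schedule.yaml",
                        package = "circalux", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  df <- do.call(rbind, lapply(raw$schedule, function(e)
    data.frame(start = parse_clock(e$start), end = parse_clock(e$end),
               lux = e$lux, cct = e$cct, output_pct = e$output_pct)))
  df <- df[order(df$start), ]
  if (nrow(df) == 0L) stop("empty lighting schedule")
  if (any(df$lux <= 0) || any(df$cct < 1000 | df$cct > 20000))
    stop("schedule entries out of range")
  if (any(head(df$end, -1) > tail(df$start, -1)))
    stop("schedule entries overlap")
  rownames(df) <- NULL
  class(df) <- c("lighting_schedule", "data.frame")
  df
}

#' Scheduled lighting at a clock time
#'
#' Looks up the entry whose half-open `[start, end)` interval contains `t`.
#' Before the first entry the first entry's values are held; at or after
#' the last entry's end, the last entry's values are held (until
#' lights-off, which the switch log governs).
#'
#' @param t clock time: `"HH:MM"` string or numeric fractional hours.
#' @param schedule a [lighting_schedule()].
#' @return one-row data.frame `start`, `end`, `lux`, `cct`, `output_pct`.
#' @export
schedule_lookup <- function(t, schedule = lighting_schedule()) {
  if (nrow(schedule) == 0L) stop("empty lighting schedule")
  h <- if (is.character(t)) parse_clock(t) else as.numeric(t)
  i <- which(schedule$start <= h & h < schedule$end)
  if (length(i) == 0L)
    i <- if (h < schedule$start[1]) 1L else nrow(schedule)
  schedule[i[1], , drop = FALSE]
}

#' Melanopic equivalent daylight illuminance
#'
#' M-EDI is exactly linear in photopic illuminance for a fixed spectrum:
#' `m_edi = illuminance * melanopic_ratio`. The default ratio is anchored
#' at the 260 lux -> 331 M-EDI schedule level.
#'
#' @param illuminance photopic lux (> 0).
#' @param melanopic_ratio M-EDI lux per photopic lux (> 0).
#' @param round_lux report to the nearest integer lux (the schedule table's
#'   print precision)?
#' @return M-EDI lux.
#' @export
melanopic_edi <- function(illuminance, melanopic_ratio = 331 / 260,
                          round_lux = FALSE) {
  if (any(illuminance <= 0) || melanopic_ratio <= 0)
    stop("illuminance and melanopic_ratio must be positive")
  m <- illuminance * melanopic_ratio
  if (round_lux) round(m) else m
}

#' Circadian stimulus from circadian light
#'
#' The saturating dose-response `CS = 0.7 * (1 - 1/(1 + (CL_A/355.7)^1.1026))`:
#' strictly increasing in CL_A, 0 at 0, half the 0.7 saturation cap at
#' CL_A = 355.7.
#'
#' @param cl_a circadian light (model units, >= 0).
#' @return CS in `[0, 0.7)`.
#' @export
circadian_stimulus <- function(cl_a) {
  if (any(cl_a < 0)) stop("cl_a must be nonnegative")
  k <- .cs_sat
  k$cap * (1 - 1 / (1 + (cl_a / k$half)^k$exponent))
}

#' Invert the circadian stimulus saturation formula
#'
#' Closed-form inverse used to anchor CL_A/lux from a known (lux, CS) pair.
#'
#' @param cs circadian stimulus, strictly inside `(0, 0.7)`.
#' @return CL_A such that `circadian_stimulus(cl_a) == cs`.
#' @export
invert_cs <- function(cs) {
  k <- .cs_sat
  if (any(cs <= 0 | cs >= k$cap))
    stop("cs must lie strictly inside (0, ", k$cap, ")")
  k$half * (k$cap / (k$cap - cs) - 1)^(1 / k$exponent)
}

#' Circadian light per photopic lux, anchored at a schedule level
#'
#' @param anchor_lux,anchor_cs the known pair (defaults: the 260-lux
#'   schedule level at CS 0.404).
#' @return CL_A per photopic lux.
#' @export
cl_a_per_lux <- function(anchor_lux = 260, anchor_cs = 0.404) {
  invert_cs(anchor_cs) / anchor_lux
}

#' Melanopic metrics for an illuminance level
#'
#' @param illuminance photopic lux.
#' @param melanopic_ratio see [melanopic_edi()].
#' @param cla_per_lux see [cl_a_per_lux()].
#' @return one-row data.frame `illuminance`, `cl_a`, `cs` (3 decimals,
#'   the table print precision), `m_edi` (integer lux), plus unrounded
#'   `cs_raw`, `m_edi_raw`.
#' @export
lighting_metrics <- function(illuminance,
                             melanopic_ratio = 331 / 260,
                             cla_per_lux = cl_a_per_lux()) {
  cl_a <- illuminance * cla_per_lux
  cs <- circadian_stimulus(cl_a)
  m <- melanopic_edi(illuminance, melanopic_ratio)
  data.frame(illuminance = illuminance, cl_a = cl_a,
             cs = round(cs, 3), m_edi = round(m),
             cs_raw = cs, m_edi_raw = m)
}

#' Per-phase dynamic-lighting exposure summary
#'
#' Exposure accounting over one study phase, under the study's stated
#' assumption that time not spent in the (sensored) own room is spent under
#' fully dynamic common-area lighting:
#' * `pct_time_in_rooms`: mean occupancy fraction x 100;
#' * `pct_lights_on_while_present`: share of present time with the room's
#'   switch on x 100;
#' * `pct_dynamic_exposure`: `(present & on) + absent`, x 100, during the
#'   dynamic phases; 0 by definition during the static baseline.
#'
#' @param occupancy data.table (`epoch_start`, `present_fraction`,
#'   `room_id`) restricted to, or labelled for, one phase.
#' @param switches switch-event data.table (`timestamp`, `room_id`,
#'   `state` in `on`/`off`), covering the phase.
#' @param phase `"baseline"`, `"weeks5_10"` or `"weeks10_16"`.
#' @return one-row data.table `phase`, `pct_time_in_rooms`,
#'   `pct_lights_on_while_present`, `pct_dynamic_exposure`.
#' @export
exposure_summary <- function(occupancy, switches, phase) {
  if (!phase %in% c("baseline", "weeks5_10", "weeks10_16"))
    stop("unknown phase: ", phase)
  if (nrow(occupancy) == 0L) stop("empty occupancy series")
  if (nrow(switches) == 0L ||
      min(switches$timestamp) > max(occupancy$epoch_start))
    stop("switch log does not cover the phase")
  sw <- switches[order(timestamp)]
  idx <- findInterval(as.numeric(occupancy$epoch_start),
                      as.numeric(sw$timestamp))
  on <- idx >= 1L & sw$state[pmax(idx, 1L)] == "on"
  pres <- occupancy$present_fraction
  p_in <- mean(pres)
  p_on_given_present <- if (sum(pres) > 0) sum(pres * on) / sum(pres) else 0
  dyn <- if (phase == "baseline") 0 else
    sum(pres * on) / length(pres) + mean(1 - pres)
  data.table::data.table(
    phase = phase,
    pct_time_in_rooms = 100 * p_in,
    pct_lights_on_while_present = 100 * p_on_given_present,
    pct_dynamic_exposure = 100 * dyn)
}
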