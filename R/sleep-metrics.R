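# Nightly sleep metrics from the 15-minute activity series: rest-period
# detection by run-length rules, disturbance bout counting, total sleep and
# wake time, and the median-of-medians phase summary.
#
# All thresholds are configuration, not constants: the night window default
# (22:00-08:00) brackets typical care-home settling and the latest observed
# wake times; theta is on the normalized activity percentage scale.

#' Epochs of one night's analysis window
#'
#' @param activity activity data.table (`epoch_start`, `activity_pct`).
#' @param night_of `Date` of the evening that owns the night.
#' @param night_window length-2 `"HH:MM"` clock times (evening start,
#'   morning end).
#' @return data.table of the window's epochs, ordered.
#' @export
night_epochs <- function(activity, night_of,
                         night_window = c("22:00", "08:00")) {
  w0 <- parse_clock(night_window[1]); w1 <- parse_clock(night_window[2])
  tz <- attr(activity$epoch_start, "tzone")
  start <- as.POSIXct(paste(night_of, "00:00:00"), tz = tz) + w0 * 3600
  end <- as.POSIXct(paste(night_of + 1, "00:00:00"), tz = tz) + w1 * 3600
  out <- activity[epoch_start >= start & epoch_start < end]
  data.table::setorder(out, epoch_start)
  out[]
}

#' Detect the nightly rest period
#'
#' Rest onset is the start of the first run of at least `min_run`
#' consecutive epochs with activity below `theta` inside the night window;
#' rest offset is the end (exclusive) of the last such run. Nights with no
#' qualifying run are flagged unscored.
#'
#' @param night data.table of one night's epochs (see [night_epochs()]).
#' @param theta rest threshold on the activity percentage (0-100).
#' @param min_run minimum run length in epochs to qualify as rest.
#' @param epoch_minutes epoch length in minutes.
#' @return list `(scored, rest_onset, rest_offset)`; `scored = FALSE` with
#'   `NA` bounds when no run qualifies or the window has no epochs.
#' @export
detect_rest_period <- function(night, theta = 10, min_run = 4,
                               epoch_minutes = 15) {
  if (theta < 0 || theta > 100) stop("theta must be in [0, 100]")
  if (nrow(night) == 0L)
    return(list(scored = FALSE, rest_onset = NA, rest_offset = NA))
  r <- rle(night$activity_pct < theta)
  qualifying <- which(r$values & r$lengths >= min_run)
  if (length(qualifying) == 0L)
    return(list(scored = FALSE, rest_onset = NA, rest_offset = NA))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  onset_i <- starts[qualifying[1]]
  offset_i <- ends[qualifying[length(qualifying)]]
  list(scored = TRUE,
       rest_onset = night$epoch_start[onset_i],
       rest_offset = night$epoch_start[offset_i] + epoch_minutes * 60)
}

#' Count sleep disturbances within a rest period
#'
#' A disturbance is a maximal run of consecutive epochs with activity above
#' `theta` inside `[rest_onset, rest_offset)`, lasting at least `min_bout`
#' epochs.
#'
#' @inheritParams detect_rest_period
#' @param rest list from [detect_rest_period()].
#' @param min_bout minimum bout length in epochs.
#' @return list `(n_disturbances, bout_lengths)` with bout lengths in
#'   minutes.
#' @export
count_disturbances <- function(night, rest, theta = 10, min_bout = 1,
                               epoch_minutes = 15) {
  if (theta < 0 || theta > 100) stop("theta must be in [0, 100]")
  if (!isTRUE(rest$scored))
    return(list(n_disturbances = NA_integer_, bout_lengths = numeric(0)))
  seg <- night[epoch_start >= rest$rest_onset &
                 epoch_start < rest$rest_offset]
  r <- rle(seg$activity_pct > theta)
  keep <- r$values & r$lengths >= min_bout
  lens <- r$lengths[keep] * epoch_minutes
  list(n_disturbances = sum(keep), bout_lengths = as.numeric(lens))
}

#' Total sleep hours and wake time of a night
#'
#' Total sleep is the rest span minus the summed disturbance bout minutes;
#' wake time is the clock time of the rest offset.
#'
#' @param rest list from [detect_rest_period()].
#' @param bouts list from [count_disturbances()].
#' @return list `(total_sleep_hours, wake_time)`; `wake_time` is fractional
#'   clock hours. `NA`s for unscored nights.
#' @export
total_sleep_and_wake <- function(rest, bouts) {
  if (!isTRUE(rest$scored))
    return(list(total_sleep_hours = NA_real_, wake_time = NA_real_))
  span_h <- as.numeric(difftime(rest$rest_offset, rest$rest_onset,
                                units = "hours"))
  list(total_sleep_hours = span_h - sum(bouts$bout_lengths) / 60,
       wake_time = clock_hours(rest$rest_offset))
}

#' Score every night of an activity series
#'
#' @param activity activity data.table for one resident.
#' @param nights `Date` vector of evenings to score; defaults to all whole
#'   nights covered by the series.
#' @param night_window,theta,min_run,min_bout,epoch_minutes see
#'   [detect_rest_period()] and [count_disturbances()].
#' @return data.table of night records: `night_of`, `scored`, `rest_onset`,
#'   `rest_offset`, `n_disturbances`, `bout_lengths` (list column,
#'   minutes), `median_bout_minutes`, `total_sleep_hours`, `wake_time`.
#' @export
score_nights <- function(activity, nights = NULL,
                         night_window = c("22:00", "08:00"), theta = 10,
                         min_run = 4, min_bout = 1, epoch_minutes = 15) {
  if (is.null(nights)) {
    d <- local_date(activity$epoch_start)
    nights <- seq(min(d), max(d) - 1, by = 1)
  }
  recs <- lapply(nights, function(nd) {
    ne <- night_epochs(activity, nd, night_window)
    rest <- detect_rest_period(ne, theta, min_run, epoch_minutes)
    bouts <- count_disturbances(ne, rest, theta, min_bout, epoch_minutes)
    tsw <- total_sleep_and_wake(rest, bouts)
    data.table::data.table(
      night_of = nd, scored = isTRUE(rest$scored),
      rest_onset = if (isTRUE(rest$scored)) rest$rest_onset else
        as.POSIXct(NA),
      rest_offset = if (isTRUE(rest$scored)) rest$rest_offset else
        as.POSIXct(NA),
      n_disturbances = bouts$n_disturbances,
      bout_lengths = list(bouts$bout_lengths),
      median_bout_minutes = if (length(bouts$bout_lengths))
        median(bouts$bout_lengths) else NA_real_,
      total_sleep_hours = tsw$total_sleep_hours,
      wake_time = tsw$wake_time)
  })
  data.table::rbindlist(recs)
}

#' Phase-level sleep summary across residents
#'
#' Per-resident medians over scored nights, then the group median over
#' residents (median-of-medians, chosen over means to limit skew from
#' heterogeneous sleepers). `exclude` supports leave-one-out reruns (e.g.
#' dropping a resident on sleep medication).
#'
#' @param night_records data.table of night records with a `resident_id`
#'   column (rbind of [score_nights()] outputs).
#' @param phase label to attach.
#' @param exclude character vector of resident_ids to drop.
#' @return one-row data.table: `phase`, `n_residents`,
#'   `median_disturbances`, `median_bout_minutes`,
#'   `median_total_sleep_hours`, `median_wake_time`.
#' @export
summarize_sleep <- function(night_records, phase = NA_character_,
                            exclude = character(0)) {
  nr <- night_records[scored == TRUE & !resident_id %in% exclude]
  if (nrow(nr) == 0L) stop("no scored nights to summarize")
  per <- nr[, .(
    disturbances = as.numeric(median(n_disturbances)),
    bout = as.numeric(median(unlist(bout_lengths))),
    sleep = as.numeric(median(total_sleep_hours)),
    wake = as.numeric(median(wake_time))), by = resident_id]
  data.table::data.table(
    phase = phase, n_residents = nrow(per),
    median_disturbances = median(per$disturbances),
    median_bout_minutes = median(per$bout, na.rm = TRUE),
    median_total_sleep_hours = median(per$sleep),
    median_wake_time = median(per$wake))
}
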