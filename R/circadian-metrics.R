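# Nonparametric circadian rest-activity statistics on the 15-minute
# activity series, using the standard actigraphy definitions with hourly
# binning (p = 24):
#
#   IS = N * sum_h (xbar_h - xbar)^2 / (p * sum_i (x_i - xbar)^2)
#   IV = N * sum_i (x_i - x_{i-1})^2 / ((N - 1) * sum_i (x_i - xbar)^2)
#   RA = (M10 - L5) / (M10 + L5)
#
# where x_i are the hourly means, xbar_h the 24 hour-of-day means, and
# M10/L5 the means of the 10 most / 5 least active *consecutive* hours of
# the average 24 h profile (windows wrap midnight).

#' Hourly binning of a 15-minute activity series
#'
#' Within-hour means of the epoch values; hours with less than
#' `min_coverage` of their expected epochs are dropped (explicit missing,
#' with N adjusted in the downstream statistics).
#'
#' @param activity data.table (`epoch_start`, `activity_pct`).
#' @param epoch_minutes epoch length in minutes.
#' @param min_coverage minimum fraction of an hour's epochs that must be
#'   present.
#' @return data.table `day` (`Date`), `hour` (0-23), `value` (mean
#'   activity), ordered chronologically.
#' @export
hourly_bins <- function(activity, epoch_minutes = 15, min_coverage = 0.5) {
  per_hour <- 60 / epoch_minutes
  dt <- data.table::data.table(
    day = local_date(activity$epoch_start),
    hour = as.POSIXlt(activity$epoch_start)$hour,
    value = activity$activity_pct)
  out <- dt[!is.na(value),
            .(value = mean(value), n = .N), by = .(day, hour)]
  out <- out[n >= min_coverage * per_hour][, n := NULL]
  data.table::setorder(out, day, hour)
  out[]
}

#' Interdaily stability (IS)
#'
#' Ratio of the variance of the average 24 h profile to the total variance
#' of the hourly series; 1 for a perfectly repeated daily rhythm, 0 for
#' noise. Flagged `NA` (with attribute `flag = "zero_variance"`) for a
#' constant series.
#'
#' @param activity data.table (`epoch_start`, `activity_pct`).
#' @param epoch_minutes,min_coverage see [hourly_bins()].
#' @return IS in `[0, 1]` (or flagged `NA`).
#' @export
interdaily_stability <- function(activity, epoch_minutes = 15,
                                 min_coverage = 0.5) {
  hb <- hourly_bins(activity, epoch_minutes, min_coverage)
  if (length(unique(hb$day)) < 2L)
    stop("IS requires at least 2 days of data")
  x <- hb$value
  n <- length(x)
  xbar <- mean(x)
  ss_tot <- sum((x - xbar)^2)
  if (ss_tot == 0)
    return(structure(NA_real_, flag = "zero_variance"))
  hm <- hb[, .(m = mean(value), n_h = .N), by = hour]
  # balanced hours reduce to the classic N * sum_h(.)^2 / (p * sum_i(.)^2);
  # the count-weighted form keeps IS <= 1 when hour coverage is unequal
  sum(hm$n_h * (hm$m - xbar)^2) / ss_tot
}

#' Intradaily variability (IV)
#'
#' Normalized mean squared successive difference of the hourly series;
#' low values indicate a smooth rhythm, high values a fragmented one.
#' Consecutive-hour differences are only taken within contiguous hourly
#' runs (gaps do not contribute spurious jumps).
#'
#' @inheritParams interdaily_stability
#' @return IV (nonnegative; the alternating extreme reaches 4), or flagged
#'   `NA` for a constant series.
#' @export
intradaily_variability <- function(activity, epoch_minutes = 15,
                                   min_coverage = 0.5) {
  hb <- hourly_bins(activity, epoch_minutes, min_coverage)
  x <- hb$value
  n <- length(x)
  if (n < 2L) stop("IV requires at least 2 hourly values")
  xbar <- mean(x)
  ss_tot <- sum((x - xbar)^2)
  if (ss_tot == 0)
    return(structure(NA_real_, flag = "zero_variance"))
  t_h <- as.numeric(hb$day) * 24 + hb$hour
  contiguous <- diff(t_h) == 1
  m <- sum(contiguous)            # valid successive pairs (= N-1 if no gaps)
  if (m < 1L) stop("IV requires at least one contiguous hourly pair")
  d2 <- diff(x)^2
  n * sum(d2[contiguous]) / (m * ss_tot)
}

#' Relative amplitude (RA) with M10 and L5
#'
#' M10/L5 are the means of the most active 10 and least active 5
#' consecutive hours of the average 24 h profile over the analysis span
#' (windows wrap midnight).
#'
#' @inheritParams interdaily_stability
#' @return list `(RA, M10, L5)`; RA flagged `NA` when `M10 + L5 == 0`.
#' @export
relative_amplitude <- function(activity, epoch_minutes = 15,
                               min_coverage = 0.5) {
  hb <- hourly_bins(activity, epoch_minutes, min_coverage)
  prof <- hb[, .(m = mean(value)), by = hour]
  if (nrow(prof) < 24L)
    stop("RA requires a complete 24 h average profile")
  data.table::setorder(prof, hour)
  m10 <- max(wrapped_window_means(prof$m, 10))
  l5 <- min(wrapped_window_means(prof$m, 5))
  ra <- if (m10 + l5 == 0) structure(NA_real_, flag = "zero_profile")
        else (m10 - l5) / (m10 + l5)
  list(RA = ra, M10 = m10, L5 = l5)
}

#' All rhythm metrics for one activity series
#'
#' @inheritParams interdaily_stability
#' @return one-row data.table `IS`, `IV`, `RA`, `M10`, `L5`, `n_days`.
#' @export
rhythm_metrics <- function(activity, epoch_minutes = 15,
                           min_coverage = 0.5) {
  ra <- relative_amplitude(activity, epoch_minutes, min_coverage)
  data.table::data.table(
    IS = as.numeric(interdaily_stability(activity, epoch_minutes,
                                         min_coverage)),
    IV = as.numeric(intradaily_variability(activity, epoch_minutes,
                                           min_coverage)),
    RA = as.numeric(ra$RA), M10 = ra$M10, L5 = ra$L5,
    n_days = length(unique(local_date(activity$epoch_start))))
}

#' Default phase-to-sunset mapping
#'
#' Sunset clock times per study phase (fixed representative values for the
#' three phases rather than an ephemeris): 20:00 for baseline, 21:00 for
#' weeks 5-10, 22:00 for weeks 10-16.
#'
#' @return named character vector of `"HH:MM"` times.
#' @export
default_sunset_config <- function() {
  c(baseline = "20:00", weeks5_10 = "21:00", weeks10_16 = "22:00")
}

#' Mean activity in the pre-sunset (sundowning) window
#'
#' Mean of all epoch activity values whose clock time falls in
#' `[sunset - window_hours, sunset)` across the series' days.
#'
#' @param activity data.table (`epoch_start`, `activity_pct`).
#' @param phase phase label (must be a name in `sunset_config`).
#' @param sunset_config named `"HH:MM"` vector, see
#'   [default_sunset_config()].
#' @param window_hours window length before sunset (hours).
#' @return one-row data.table `phase`, `sunset_time`, `window_hours`,
#'   `mean_activity_pct`, `n_epochs`.
#' @export
sundowning_activity <- function(activity, phase,
                                sunset_config = default_sunset_config(),
                                window_hours = 4) {
  if (!phase %in% names(sunset_config))
    stop("no configured sunset time for phase: ", phase)
  sunset <- parse_clock(sunset_config[[phase]])
  h <- clock_hours(activity$epoch_start)
  in_win <- h >= sunset - window_hours & h < sunset
  if (!any(in_win)) stop("no epochs inside the sundowning window")
  data.table::data.table(
    phase = phase, sunset_time = sunset_config[[phase]],
    window_hours = window_hours,
    mean_activity_pct = mean(activity$activity_pct[in_win]),
    n_epochs = sum(in_win))
}
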