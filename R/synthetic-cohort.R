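# Synthetic cohort generator: seeded radar-frame streams, light-switch logs
# and weekly QUALIDEM panels with known circadian ground truth, so every
# downstream stage is testable without access to care records.
#
# The activity model is a clipped cosinor (mesor + amplitude * cos) plus
# Gaussian epoch noise, with night disturbances inserted as Poisson-count
# bouts of elevated activity inside the bed window. Cohort-scale simulation
# happens directly at the 15-minute-epoch level (the analytic aggregate of
# the frame model); 8 Hz frame emission is available for day-scale ranges to
# exercise the raw ingest path.

#' Resident simulation profile
#'
#' Ground-truth parameters for one simulated resident.
#'
#' @param resident_id unique id string.
#' @param mesor rhythm mean activity level (percent, 0-100).
#' @param amplitude cosinor amplitude (activity percent).
#' @param acrophase clock time of peak activity (hours from local midnight).
#' @param noise_sd per-epoch Gaussian noise SD (activity percent).
#' @param n_disturbances_per_night mean of the nightly Poisson disturbance
#'   count.
#' @param disturbance_bout_minutes mean disturbance bout length (minutes).
#' @param bed_window length-2 character `c(start, end)` clock times
#'   (`"HH:MM"`); start in the evening, end the following morning.
#' @param rest_level deterministic activity level (percent) the rhythm is
#'   attenuated to inside the bed window: sleep suppresses movement below
#'   what the raw cosinor would give. Disturbance bouts override it.
#' @param night_noise_factor multiplier on `noise_sd` inside the bed
#'   window (movement noise is smaller during rest).
#' @param room_occupancy_fraction long-run fraction of daytime spent in the
#'   resident's own (sensored) flat, 0-1.
#' @param lights_on_given_present probability that, on a given day, the
#'   resident's room lighting is switched on across their waking hours.
#' @return an object of class `resident_profile` (a named list).
#' @export
resident_profile <- function(resident_id,
                             mesor = 30, amplitude = 25, acrophase = 14,
                             noise_sd = 10,
                             n_disturbances_per_night = 2,
                             disturbance_bout_minutes = 30,
                             bed_window = c("22:30", "07:00"),
                             rest_level = 2, night_noise_factor = 0.25,
                             room_occupancy_fraction = 0.6,
                             lights_on_given_present = 0.7) {
  stopifnot(is.character(resident_id), length(resident_id) == 1L,
            mesor >= 0, mesor <= 100, amplitude >= 0,
            noise_sd >= 0, n_disturbances_per_night >= 0,
            disturbance_bout_minutes > 0,
            room_occupancy_fraction >= 0, room_occupancy_fraction <= 1,
            lights_on_given_present >= 0, lights_on_given_present <= 1)
  bw <- vapply(bed_window, parse_clock, numeric(1))
  if (!(bw[1] > 12 && bw[2] < 12))
    stop("bed_window must start in the evening and end in the morning")
  stopifnot(rest_level >= 0, night_noise_factor >= 0)
  structure(list(resident_id = resident_id, mesor = mesor,
                 amplitude = amplitude, acrophase = acrophase,
                 noise_sd = noise_sd,
                 n_disturbances_per_night = n_disturbances_per_night,
                 disturbance_bout_minutes = disturbance_bout_minutes,
                 bed_window = unname(bw),
                 rest_level = rest_level,
                 night_noise_factor = night_noise_factor,
                 room_occupancy_fraction = room_occupancy_fraction,
                 lights_on_given_present = lights_on_given_present),
            class = "resident_profile")
}

#' Default cohort profiles
#'
#' A deterministic set of `n` resident profiles with mild between-resident
#' heterogeneity, mirroring a small single-site dementia-care cohort
#' (default n = 11, the deployment size the pipeline is designed around).
#'
#' @param n number of residents.
#' @return list of [resident_profile()].
#' @export
default_cohort_profiles <- function(n = 11) {
  lapply(seq_len(n), function(i) {
    resident_profile(
      resident_id = sprintf("resident_%02d", i),
      mesor     = 28 + (i %% 5),
      amplitude = 22 + (i %% 4) * 2,
      acrophase = 13.5 + (i %% 3) * 0.5,
      noise_sd  = 9 + (i %% 3),
      n_disturbances_per_night = 1.5 + (i %% 3) * 0.5,
      disturbance_bout_minutes = 30,
      room_occupancy_fraction  = 0.55 + (i %% 4) * 0.05)
  })
}

#' Intervention effect on a generator parameter
#'
#' A signed shift `delta` injected into the ground-truth generator for one
#' downstream metric during one study phase. Supported parameters:
#' `"IS"`, `"IV"`, `"RA"`, `"sleep_disturbances"`, and QUALIDEM subscales
#' `"qualidem_A"` ... `"qualidem_J"` (delta in units of the weekly latent SD).
#'
#' @param parameter metric name (see above).
#' @param phase one of `"baseline"`, `"weeks5_10"`, `"weeks10_16"`.
#' @param delta signed shift applied to the metric's ground truth.
#' @return object of class `intervention_effect`.
#' @export
intervention_effect <- function(parameter, phase, delta) {
  ok <- c("IS", "IV", "RA", "sleep_disturbances",
          paste0("qualidem_", LETTERS[1:10]))
  if (!parameter %in% ok)
    stop("unknown effect parameter: ", parameter)
  if (!phase %in% c("baseline", "weeks5_10", "weeks10_16"))
    stop("phase must be one of baseline/weeks5_10/weeks10_16")
  structure(list(parameter = parameter, phase = phase, delta = delta),
            class = "intervention_effect")
}

# ---- analytic ground-truth maps ------------------------------------------

#' Clipped cosinor activity curve
#'
#' @param hours clock hours (numeric, may exceed 24; evaluated mod 24).
#' @param mesor,amplitude,acrophase cosinor parameters as in
#'   [resident_profile()].
#' @return activity percent, clipped to `[0, 100]`.
#' @export
cosinor_activity <- function(hours, mesor, amplitude, acrophase) {
  pmin(100, pmax(0, mesor + amplitude * cos(2 * pi * (hours - acrophase) / 24)))
}

# deterministic part of the generator on the 15-minute epoch grid of one
# day: clipped cosinor, attenuated to rest_level inside the bed window
profile_epoch_truth <- function(profile) {
  h <- seq(0, 23.75, by = 0.25)
  a <- cosinor_activity(h, profile$mesor, profile$amplitude,
                        profile$acrophase)
  bw <- profile$bed_window
  in_bed <- h >= bw[1] | h < bw[2]
  a[in_bed] <- pmin(a[in_bed], profile$rest_level)
  sd_factor <- ifelse(in_bed, profile$night_noise_factor, 1)
  list(hours = h, value = a, in_bed = in_bed, sd_factor = sd_factor)
}

# 24 hourly means of the deterministic generator profile
profile_hourly_means <- function(profile) {
  tr <- profile_epoch_truth(profile)
  as.numeric(tapply(tr$value, rep(0:23, each = 4), mean))
}

# mean of a N(m, s) variable clipped below at 0 (upper clip at 100 is
# negligible at the levels the generator uses)
clipped_normal_mean <- function(m, s) {
  ifelse(s > 0, m * stats::pnorm(m / s) + s * stats::dnorm(m / s), m)
}

# Expected observed epoch profile and variance components of the noisy
# generator: the deterministic gated cosinor mixed with the disturbance
# bout probability inside the bed window, with clipped-noise means. These
# are the values the downstream hourly-binned metrics estimate, so the
# recorded truth is sufficient to recompute expected IS/RA.
expected_components <- function(profile, disturb_level = 60) {
  tr <- profile_epoch_truth(profile)
  s_e <- profile$noise_sd * tr$sd_factor
  m_e <- clipped_normal_mean(tr$value, s_e)
  v_dist_e <- numeric(length(m_e))
  nb <- sum(tr$in_bed)
  lam <- profile$n_disturbances_per_night
  if (lam > 0 && nb > 0) {
    k <- 0:200
    e_len <- sum(pmax(1, k) *
                   stats::dpois(k, profile$disturbance_bout_minutes / 15))
    p <- min(1, lam * e_len / nb)
    md <- clipped_normal_mean(disturb_level, s_e[tr$in_bed])
    base <- m_e[tr$in_bed]
    m_e[tr$in_bed] <- (1 - p) * base + p * md
    v_dist_e[tr$in_bed] <- p * (1 - p) * (md - base)^2
  }
  hrs <- rep(0:23, each = 4)
  hourly <- as.numeric(tapply(m_e, hrs, mean))
  vh <- var_pop(hourly)
  # hourly-mean variance contributions (4 epochs per hour); disturbance
  # epochs come in runs of ~e_len epochs, so their contribution to the
  # hourly-mean variance carries the clustered-sampling inflation e_len
  c_noise <- mean(tapply(tr$sd_factor^2, hrs, mean)) / 4
  e_len_infl <- if (lam > 0 && nb > 0) min(4, e_len) else 1
  v_dist <- mean(tapply(v_dist_e, hrs, mean)) / 4 * e_len_infl
  list(hourly = hourly, vh = vh, c_noise = c_noise, v_dist = v_dist)
}

# expected RA of the observed (noisy, disturbed) series
theoretical_ra <- function(profile, disturb_level = 60) {
  prof <- expected_components(profile, disturb_level)$hourly
  m10 <- max(wrapped_window_means(prof, 10))
  l5  <- min(wrapped_window_means(prof, 5))
  if (m10 + l5 == 0) return(NA_real_)
  (m10 - l5) / (m10 + l5)
}

# mean over every w consecutive entries of a length-24 profile, wrapping
wrapped_window_means <- function(profile, w) {
  p2 <- c(profile, profile[seq_len(w - 1)])
  vapply(seq_along(profile), function(i) mean(p2[i:(i + w - 1)]), numeric(1))
}

# solve for the amplitude that attains a target expected RA
amplitude_for_ra <- function(target_ra, profile, disturb_level = 60) {
  if (is.na(target_ra) || target_ra <= 0 || target_ra >= 1)
    stop("target RA must lie strictly inside (0, 1)")
  f <- function(a) {
    p2 <- profile; p2$amplitude <- a
    theoretical_ra(p2, disturb_level) - target_ra
  }
  uniroot(f, lower = 1e-6, upper = 400, tol = 1e-10)$root
}

# expected IS of the hourly-binned observed series:
# Var_h / (Var_h + noise + disturbance mixture variance)
expected_is <- function(profile, disturb_level = 60) {
  cx <- expected_components(profile, disturb_level)
  cx$vh / (cx$vh + cx$c_noise * profile$noise_sd^2 + cx$v_dist)
}

var_pop <- function(x) mean((x - mean(x))^2)

# apply phase effects to a resident profile; returns the modified profile
apply_phase_effects <- function(profile, effects, phase) {
  eff <- Filter(function(e) e$phase == phase &&
                  e$parameter %in% c("IS", "IV", "RA", "sleep_disturbances"),
                effects)
  if (length(eff) == 0L) return(profile)
  pars <- vapply(eff, `[[`, character(1), "parameter")
  if (all(c("IS", "IV") %in% pars))
    stop("IS and IV effects both act through noise_sd; target one per phase")
  for (e in eff) {
    if (e$parameter == "RA") {
      base <- theoretical_ra(profile)
      profile$amplitude <- amplitude_for_ra(base + e$delta, profile)
    } else if (e$parameter == "IS") {
      cx <- expected_components(profile)
      target <- min(max(expected_is(profile) + e$delta, 1e-3), 0.999)
      # expected IS = vh / (vh + c_noise * sd^2 + v_dist): solve for sd;
      # when the disturbance mixture variance alone caps IS below the
      # target, zero the noise and damp the nightly disturbance rate too
      # (a rhythm-stabilizing intervention acts on both)
      v_new <- (cx$vh * (1 / target - 1) - cx$v_dist) / cx$c_noise
      if (!is.na(v_new) && v_new >= 0) {
        profile$noise_sd <- sqrt(v_new)
      } else {
        profile$noise_sd <- 0
        lam0 <- profile$n_disturbances_per_night
        g <- function(f) {
          p2 <- profile; p2$n_disturbances_per_night <- lam0 * f
          expected_is(p2) - target
        }
        if (g(1) >= 0) {
          # already above target with zero noise: leave disturbances alone
        } else {
          f <- uniroot(g, lower = 0, upper = 1, tol = 1e-8)$root
          profile$n_disturbances_per_night <- lam0 * f
        }
      }
    } else if (e$parameter == "IV") {
      hp <- profile_hourly_means(profile)
      mssd <- mean(diff(c(hp, hp[1]))^2)
      vs <- var_pop(hp)
      tr <- profile_epoch_truth(profile)
      c_noise <- mean(tapply(tr$sd_factor^2, rep(0:23, each = 4),
                             mean)) / 4
      v_noise <- profile$noise_sd^2 * c_noise
      base_iv <- (mssd + 2 * v_noise) / (vs + v_noise)
      target <- base_iv + e$delta
      v_new <- (target * vs - mssd) / (2 - target)
      if (is.na(v_new) || v_new < 0 || target >= 2)
        stop("IV effect delta outside the range reachable through noise_sd")
      profile$noise_sd <- sqrt(v_new / c_noise)
    } else if (e$parameter == "sleep_disturbances") {
      profile$n_disturbances_per_night <-
        max(0, profile$n_disturbances_per_night + e$delta)
    }
  }
  profile
}

# ---- epoch-level simulation ----------------------------------------------

#' Simulate one resident's activity at the 15-minute-epoch level
#'
#' Generates the ground-truth activity series the radar/ingest path would
#' produce for this resident: clipped cosinor + inserted night disturbance
#' bouts + Gaussian epoch noise, together with an epoch occupancy series and
#' a daily light-switch log. Disturbance bouts are placed greedily without
#' touching each other, and the *placed* bouts are recorded as truth.
#'
#' @param profile a [resident_profile()].
#' @param date_range length-2 `Date` vector `c(first_day, last_day)`,
#'   inclusive; must cover at least one whole day.
#' @param seed integer seed for this resident's substream.
#' @param tz Olson timezone.
#' @param epoch_minutes epoch length (minutes).
#' @param disturb_level activity percent a disturbance bout is raised to.
#' @return list with data.tables `activity` (`epoch_start`, `activity_pct`),
#'   `occupancy` (`epoch_start`, `present_fraction`, `room_id`), `switches`
#'   (`timestamp`, `room_id`, `state`), and `nights` (placed-bout truth:
#'   `night_of`, `n_disturbances`, `bout_minutes` list column).
#' @export
simulate_activity_epochs <- function(profile, date_range, seed,
                                     tz = "Europe/London",
                                     epoch_minutes = 15,
                                     disturb_level = 60) {
  date_range <- as.Date(date_range)
  if (length(date_range) != 2L || date_range[2] < date_range[1])
    stop("date_range must be c(first_day, last_day) with at least one day")
  set.seed(seed)
  t0 <- as.POSIXct(paste(date_range[1], "00:00:00"), tz = tz)
  t1 <- as.POSIXct(paste(date_range[2] + 1, "00:00:00"), tz = tz)
  ep <- seq(t0, t1, by = epoch_minutes * 60)
  ep <- ep[ep < t1]
  h <- clock_hours(ep)
  act <- cosinor_activity(h, profile$mesor, profile$amplitude,
                          profile$acrophase)

  # night disturbance bouts
  bw <- profile$bed_window
  nights_dates <- if (date_range[2] > date_range[1])
    seq(date_range[1], date_range[2] - 1, by = 1) else as.Date(character(0))
  in_bed <- h >= bw[1] | h < bw[2]
  act[in_bed] <- pmin(act[in_bed], profile$rest_level)
  night_id <- local_date(ep) - (h < 12)  # evening date owning the night
  nights <- vector("list", length(nights_dates))
  for (k in seq_along(nights_dates)) {
    d <- nights_dates[k]
    idx <- which(in_bed & night_id == d)
    n_draw <- rpois(1, profile$n_disturbances_per_night)
    placed <- integer(0)
    lens <- integer(0)
    occupied <- rep(FALSE, length(idx))
    if (n_draw > 0 && length(idx) > 2) {
      for (b in seq_len(n_draw)) {
        len <- max(1L, rpois(1, profile$disturbance_bout_minutes /
                               epoch_minutes))
        # keep bouts clear of the bed-window edges so they fall inside the
        # detectable rest period (rest onset/offset need a quiet run)
        margin <- 4L
        lo <- margin + 1L
        hi <- length(idx) - len - margin
        if (hi < lo) next
        cand <- sample(lo:hi)
        for (s in cand) {
          span <- s:(s + len - 1)
          guard <- max(1, s - 1):min(length(idx), s + len)
          if (!any(occupied[guard])) {
            occupied[span] <- TRUE
            placed <- c(placed, s)
            lens <- c(lens, len)
            break
          }
        }
      }
    }
    act[idx[occupied]] <- disturb_level
    nights[[k]] <- data.table::data.table(
      night_of = d, n_disturbances = length(placed),
      bout_minutes = list(sort(lens * epoch_minutes)))
  }
  nights <- if (length(nights)) data.table::rbindlist(nights) else
    data.table::data.table(night_of = as.Date(character(0)),
                           n_disturbances = integer(0),
                           bout_minutes = list())

  if (profile$noise_sd > 0) {
    sd_e <- profile$noise_sd *
      ifelse(in_bed, profile$night_noise_factor, 1)
    act <- act + rnorm(length(act), 0, sd_e)
  }
  act <- pmin(100, pmax(0, act))

  activity <- data.table::data.table(epoch_start = ep, activity_pct = act)

  # presence: two-state chain at epoch granularity, forced present in bed
  f <- profile$room_occupancy_fraction
  # two-state chain: mean in-room dwell 1 h (4 epochs); leave/return rates
  # chosen so the stationary presence fraction equals f (degenerate at 1)
  q_leave <- if (f >= 1) 0 else 1 / 4
  q_return <- if (f >= 1) 1 else min(1, (1 / 4) * f / (1 - f))
  pres <- logical(length(ep))
  state <- TRUE
  u <- runif(length(ep))
  for (i in seq_along(ep)) {
    if (in_bed[i]) state <- TRUE
    else state <- if (state) u[i] > q_leave else u[i] < q_return
    pres[i] <- state
  }
  room <- paste0("flat_", profile$resident_id)
  occupancy <- data.table::data.table(
    epoch_start = ep, present_fraction = as.numeric(pres), room_id = room)

  # light switch log: on across waking hours on a per-day Bernoulli basis
  days <- seq(date_range[1], date_range[2], by = 1)
  on_day <- runif(length(days)) < profile$lights_on_given_present
  sw <- list(data.table::data.table(
    timestamp = t0, room_id = room, state = "off"))
  for (k in seq_along(days)) {
    if (!on_day[k]) next
    on_t <- as.POSIXct(paste(days[k], "00:00:00"), tz = tz) + bw[2] * 3600
    off_t <- as.POSIXct(paste(days[k], "00:00:00"), tz = tz) + bw[1] * 3600
    sw[[length(sw) + 1L]] <- data.table::data.table(
      timestamp = c(on_t, off_t), room_id = room, state = c("on", "off"))
  }
  switches <- data.table::rbindlist(sw)
  data.table::setorder(switches, timestamp)

  list(activity = activity, occupancy = occupancy, switches = switches,
       nights = nights)
}

#' Simulate one resident's raw 8 Hz radar frame stream
#'
#' Emits positional frames while the resident is present in their (single,
#' sensored) flat. The path is circular pacing around the room centre with
#' a per-frame arc step set by the epoch's ground-truth activity, so the
#' summed x-y translation per epoch is an exact deterministic (and nearly
#' linear) function of the generating activity curve; position geometry is
#' plumbing, translation magnitude is what downstream analysis consumes.
#' Intended for day-scale ranges; cohort-scale simulation uses
#' [simulate_activity_epochs()].
#'
#' @inheritParams simulate_activity_epochs
#' @param frame_rate frames per second (nominal radar rate 8).
#' @param room_size side of the square room (metres).
#' @param metres_per_epoch translation emitted over one epoch at 100%
#'   activity.
#' @return list with data.table `frames` (`timestamp`, `sensor_id`,
#'   `resident_id`, `x`, `y`), plus the `activity`/`occupancy`/`switches`/
#'   `nights` ground truth from the epoch simulation.
#' @export
simulate_resident <- function(profile, date_range, seed,
                              tz = "Europe/London", epoch_minutes = 15,
                              frame_rate = 8, disturb_level = 60,
                              room_size = 5, metres_per_epoch = 40) {
  epochs <- simulate_activity_epochs(profile, date_range, seed, tz,
                                     epoch_minutes, disturb_level)
  set.seed(derive_seed(seed, 1L))
  dt_ep <- epochs$activity
  pres <- epochs$occupancy$present_fraction > 0
  n_per <- as.integer(epoch_minutes * 60 * frame_rate)
  sensor <- paste0("radar_", profile$resident_id)

  keep <- which(pres)
  # frame timestamps for present epochs
  offs <- seq(0, by = 1 / frame_rate, length.out = n_per)
  ts <- rep(as.numeric(dt_ep$epoch_start[keep]), each = n_per) +
    rep(offs, times = length(keep))
  step <- rep(dt_ep$activity_pct[keep] / 100 * metres_per_epoch / n_per,
              each = n_per)
  r <- room_size * 0.35
  phi <- runif(1, 0, 2 * pi) + cumsum(step) / r
  frames <- data.table::data.table(
    timestamp = structure(ts, class = c("POSIXct", "POSIXt"), tzone = tz),
    sensor_id = sensor, resident_id = profile$resident_id,
    x = room_size / 2 + r * cos(phi), y = room_size / 2 + r * sin(phi))
  c(list(frames = frames), epochs)
}

# ---- cohort --------------------------------------------------------------

#' Simulate a full study cohort
#'
#' Simulates every resident across the three study phases (effects applied
#' per phase), plus the weekly QUALIDEM panel, and records the generating
#' truth. Per-resident, per-phase substream seeds are derived from the
#' master seed by a fixed counter scheme, so individual residents are
#' independently reproducible.
#'
#' @param profiles list of [resident_profile()] (unique ids).
#' @param effects list of [intervention_effect()].
#' @param seed master integer seed.
#' @param plan a [phase_plan()].
#' @param item_map QUALIDEM item map (see [qualidem_item_map()]).
#' @param qualidem_latent_sd,qualidem_item_sd noise levels of the weekly
#'   QUALIDEM panel, see [simulate_qualidem_panel()].
#' @param ... passed to [simulate_activity_epochs()].
#' @return object of class `cohort_dataset`: data.tables `activity`,
#'   `occupancy`, `switches` (all with `resident_id`), `qualidem` (weekly
#'   item responses), and `truth` (per resident per phase generating
#'   parameters and expected metrics), plus the `plan`.
#' @export
simulate_cohort <- function(profiles, effects = list(), seed = 1L,
                            plan = phase_plan(),
                            item_map = qualidem_item_map(),
                            qualidem_latent_sd = 0.25,
                            qualidem_item_sd = 0.5, ...) {
  if (length(profiles) < 1L) stop("at least one resident profile required")
  ids <- vapply(profiles, `[[`, character(1), "resident_id")
  if (anyDuplicated(ids)) stop("duplicate resident_id in profiles")

  acts <- list(); occs <- list(); sws <- list(); truths <- list()
  nights <- list()
  for (i in seq_along(profiles)) {
    for (j in seq_along(plan$ranges)) {
      ph <- names(plan$ranges)[j]
      pr <- apply_phase_effects(profiles[[i]], effects, ph)
      r <- plan$ranges[[ph]]
      sub <- simulate_activity_epochs(
        pr, c(r[1], r[2] - 1), seed = derive_seed(seed, i * 100L + j),
        tz = plan$tz, ...)
      sub$activity[, resident_id := ids[i]]
      sub$occupancy[, resident_id := ids[i]]
      sub$switches[, resident_id := ids[i]]
      sub$nights[, `:=`(resident_id = ids[i], phase = ph)]
      acts[[length(acts) + 1L]] <- sub$activity
      occs[[length(occs) + 1L]] <- sub$occupancy
      sws[[length(sws) + 1L]] <- sub$switches
      nights[[length(nights) + 1L]] <- sub$nights
      truths[[length(truths) + 1L]] <- data.table::data.table(
        resident_id = ids[i], phase = ph,
        mesor = pr$mesor, amplitude = pr$amplitude,
        acrophase = pr$acrophase, noise_sd = pr$noise_sd,
        n_disturbances_per_night = pr$n_disturbances_per_night,
        expected_ra = theoretical_ra(pr),
        expected_is = expected_is(pr))
    }
  }
  qp <- simulate_qualidem_panel(profiles, effects,
                                n_weeks = max(unlist(plan$phases)),
                                seed = derive_seed(seed, 999983L),
                                item_map = item_map, plan = plan,
                                latent_week_sd = qualidem_latent_sd,
                                item_sd = qualidem_item_sd)
  structure(list(activity = data.table::rbindlist(acts),
                 occupancy = data.table::rbindlist(occs),
                 switches = data.table::rbindlist(sws),
                 qualidem = qp,
                 truth = list(parameters = data.table::rbindlist(truths),
                              nights = data.table::rbindlist(nights)),
                 plan = plan, seed = seed),
            class = "cohort_dataset")
}

#' Simulate a weekly QUALIDEM item-response panel
#'
#' Each resident has a latent mean per subscale on the item rating scale;
#' each week the subscale latent is drawn around that mean (SD
#' `latent_week_sd`), shifted by any injected effect (delta in units of the
#' weekly latent SD) during its phase, and item responses are drawn around
#' the weekly latent (SD `item_sd`), rounded and truncated to the item's
#' legal range. Negative-worded items are emitted pre-reversal, so scoring
#' (which reverses them) recovers the latent direction.
#'
#' @inheritParams simulate_cohort
#' @param n_weeks number of weekly panels.
#' @param latent_mean baseline latent mean on the rating scale.
#' @param latent_week_sd weekly latent SD (rating-scale units); effects are
#'   injected in units of this SD.
#' @param item_sd within-week item SD.
#' @return data.table with columns `resident_id`, `week`, one `item_*`
#'   column per instrument item.
#' @export
simulate_qualidem_panel <- function(profiles, effects = list(), n_weeks = 16,
                                    seed = 1L,
                                    item_map = qualidem_item_map(),
                                    plan = phase_plan(),
                                    latent_mean = 1.8,
                                    latent_week_sd = 0.25, item_sd = 0.5) {
  if (n_weeks < 1) stop("n_weeks must be >= 1")
  qeff <- Filter(function(e) startsWith(e$parameter, "qualidem_"), effects)
  subs <- unique(item_map$subscale)
  for (e in qeff) {
    s <- sub("qualidem_", "", e$parameter)
    if (!s %in% subs) stop("unknown QUALIDEM subscale in effects: ", s)
  }
  week_phase <- vapply(seq_len(n_weeks), function(w) {
    for (p in names(plan$phases)) if (w %in% plan$phases[[p]]) return(p)
    NA_character_
  }, character(1))

  set.seed(seed)
  ids <- vapply(profiles, `[[`, character(1), "resident_id")
  rows <- vector("list", length(ids) * n_weeks)
  k <- 0L
  for (i in seq_along(ids)) {
    for (w in seq_len(n_weeks)) {
      resp <- integer(nrow(item_map))
      for (s in subs) {
        delta <- 0
        for (e in qeff)
          if (sub("qualidem_", "", e$parameter) == s &&
              identical(e$phase, week_phase[w]))
            delta <- delta + e$delta
        lat <- latent_mean + delta * latent_week_sd +
          (if (latent_week_sd > 0) rnorm(1, 0, latent_week_sd) else 0)
        it <- which(item_map$subscale == s)
        contrib <- lat + (if (item_sd > 0) rnorm(length(it), 0, item_sd)
                          else 0)
        contrib <- pmin(item_map$max_rating[it],
                        pmax(0, round(contrib)))
        resp[it] <- ifelse(item_map$reverse[it],
                           item_map$max_rating[it] - contrib, contrib)
      }
      k <- k + 1L
      rows[[k]] <- c(list(resident_id = ids[i], week = w),
                     as.list(stats::setNames(resp, item_map$item)))
    }
  }
  data.table::rbindlist(rows)
}

# ---- writers -------------------------------------------------------------

#' Write a frame stream as JSON Lines
#'
#' One sample per line: ISO-8601 timestamp, sensor_id, resident_id, x, y.
#'
#' @param frames data.table as produced by [simulate_resident()].
#' @param path output file.
#' @export
write_frames_jsonl <- function(frames, path) {
  df <- data.frame(
    timestamp = format(frames$timestamp, "%Y-%m-%dT%H:%M:%OS3%z"),
    sensor_id = frames$sensor_id, resident_id = frames$resident_id,
    x = frames$x, y = frames$y)
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE, digits = NA)
  invisible(path)
}

#' Write cohort tables as CSV/JSON files
#'
#' Writes `activity.csv`, `occupancy.csv`, `switches.csv`, `qualidem.csv`
#' and `truth.json` under `dir`.
#'
#' @param cohort a `cohort_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%S%z")
  a <- data.table::copy(cohort$activity)[, epoch_start := iso(epoch_start)]
  o <- data.table::copy(cohort$occupancy)[, epoch_start := iso(epoch_start)]
  s <- data.table::copy(cohort$switches)[, timestamp := iso(timestamp)]
  data.table::fwrite(a, file.path(dir, "activity.csv"))
  data.table::fwrite(o, file.path(dir, "occupancy.csv"))
  data.table::fwrite(s, file.path(dir, "switches.csv"))
  data.table::fwrite(cohort$qualidem, file.path(dir, "qualidem.csv"))
  tr <- cohort$truth
  tr$nights <- data.table::copy(tr$nights)
  tr$nights[, bout_minutes := vapply(bout_minutes, paste, character(1),
                                     collapse = ";")]
  jsonlite::write_json(
    list(seed = cohort$seed,
         parameters = tr$parameters, nights = tr$nights),
    file.path(dir, "truth.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}
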