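test_that("profile and effect constructors enforce their invariants", {
  expect_s3_class(resident_profile("r1"), "resident_profile")
  expect_error(resident_profile("r1", bed_window = c("08:00", "22:00")),
               "evening")
  expect_error(resident_profile("r1", room_occupancy_fraction = 1.5))
  expect_error(intervention_effect("bogus", "baseline", 0.1), "unknown")
  expect_error(intervention_effect("RA", "weeks2_3", 0.1), "phase")
})

test_that("identical seeds reproduce identical datasets", {
  p <- resident_profile("r1")
  d <- as.Date(c("2023-03-06", "2023-03-09"))
  a1 <- simulate_activity_epochs(p, d, seed = 11)
  a2 <- simulate_activity_epochs(p, d, seed = 11)
  expect_identical(a1, a2)
  f1 <- simulate_resident(p, as.Date(c("2023-03-06", "2023-03-06")),
                          seed = 5, frame_rate = 2)
  f2 <- simulate_resident(p, as.Date(c("2023-03-06", "2023-03-06")),
                          seed = 5, frame_rate = 2)
  expect_identical(f1$frames, f2$frames)
  expect_false(identical(
    a1$activity,
    simulate_activity_epochs(p, d, seed = 12)$activity))
})

test_that("a noiseless periodic resident yields IS = 1 downstream", {
  p <- resident_profile("r1", noise_sd = 0, n_disturbances_per_night = 0)
  sim <- simulate_activity_epochs(p, as.Date(c("2023-03-06",
                                               "2023-03-12")), seed = 1)
  expect_equal(interdaily_stability(sim$activity), 1, tolerance = 1e-9)
  ra <- relative_amplitude(sim$activity)
  expect_equal(ra$RA, circalux:::theoretical_ra(p), tolerance = 1e-9)
})

test_that("placed disturbance bouts are recovered exactly when noiseless", {
  p <- resident_profile("r1", noise_sd = 0,
                        n_disturbances_per_night = 2)
  sim <- simulate_activity_epochs(p, as.Date(c("2023-03-06",
                                               "2023-03-19")), seed = 21)
  nights <- score_nights(sim$activity, theta = 10, min_run = 4)
  truth <- sim$nights
  got <- merge(nights[, .(night_of, n_disturbances)],
               truth[, .(night_of, truth_n = n_disturbances)],
               by = "night_of")
  expect_equal(got$n_disturbances, got$truth_n)
  # bout lengths match too
  m <- merge(nights[, .(night_of, bl = bout_lengths)],
             truth[, .(night_of, tl = bout_minutes)], by = "night_of")
  for (i in seq_len(nrow(m)))
    expect_equal(sort(m$bl[[i]]), sort(m$tl[[i]]))
})

test_that("recovered disturbance medians sit inside the generator's
           Monte-Carlo interval", {
  p <- resident_profile("r1", n_disturbances_per_night = 2)
  sim <- simulate_activity_epochs(p, as.Date(c("2023-03-06",
                                               "2023-04-02")), seed = 31)
  nights <- score_nights(sim$activity, theta = 10, min_run = 4)
  med <- median(nights$n_disturbances)
  # brute-force the generating count distribution: median of 28 nightly
  # Poisson(2) counts, 10,000 replicates
  set.seed(99)
  meds <- replicate(10000, median(rpois(28, 2)))
  expect_gte(med, quantile(meds, 0.025))
  expect_lte(med, quantile(meds, 0.975))
})

test_that("date ranges shorter than one day are rejected", {
  p <- resident_profile("r1")
  expect_error(simulate_activity_epochs(
    p, as.Date(c("2023-03-06", "2023-03-05")), seed = 1), "date_range")
})

test_that("cohort simulation wires up residents, phases and truth", {
  profs <- default_cohort_profiles(11)
  co <- simulate_cohort(profs, seed = 3)
  expect_length(unique(co$activity$resident_id), 11)
  expect_identical(sort(unique(co$truth$parameters$phase)),
                   sort(c("baseline", "weeks5_10", "weeks10_16")))
  # spans exactly the configured 16 weeks
  days <- unique(as.Date(format(co$activity$epoch_start, "%Y-%m-%d")))
  expect_equal(length(days), 16 * 7)
  expect_error(simulate_cohort(list()), "at least one")
  expect_error(simulate_cohort(list(resident_profile("a"),
                                    resident_profile("a"))),
               "duplicate")
})

test_that("QUALIDEM panel: zero noise repeats weekly scores and effects
           stay isolated to their subscale", {
  profs <- default_cohort_profiles(3)
  pan0 <- simulate_qualidem_panel(profs, n_weeks = 6, seed = 7,
                                  latent_week_sd = 0, item_sd = 0)
  sc0 <- score_qualidem_panel(pan0)
  per <- sc0[, .(n_distinct = length(unique(score))),
             by = .(resident_id, subscale)]
  expect_true(all(per$n_distinct == 1))

  eff <- list(intervention_effect("qualidem_B", "weeks5_10", 3))
  pan1 <- simulate_qualidem_panel(profs, eff, n_weeks = 6, seed = 7,
                                  latent_week_sd = 0.25, item_sd = 0)
  # same seed without the effect: only B may differ
  pan2 <- simulate_qualidem_panel(profs, list(), n_weeks = 6, seed = 7,
                                  latent_week_sd = 0.25, item_sd = 0)
  s1 <- score_qualidem_panel(pan1)
  s2 <- score_qualidem_panel(pan2)
  other <- s1$subscale != "B"
  expect_identical(s1$score[other], s2$score[other])
  b5 <- s1$subscale == "B" & s1$week == 5
  expect_true(all(s1$score[b5] >= s2$score[b5]))
  expect_error(simulate_qualidem_panel(
    profs, list(intervention_effect("qualidem_Z", "weeks5_10", 1)),
    n_weeks = 4, seed = 1), "unknown")
})

test_that("injected RA effects shift the generating amplitude as intended
           and IS falls with noise", {
  p <- resident_profile("r1")
  eff <- list(intervention_effect("RA", "weeks5_10", 0.1))
  p5 <- circalux:::apply_phase_effects(p, eff, "weeks5_10")
  expect_equal(circalux:::theoretical_ra(p5),
               circalux:::theoretical_ra(p) + 0.1, tolerance = 1e-6)
  pb <- circalux:::apply_phase_effects(p, eff, "baseline")
  expect_identical(pb, p)
  # monotone parameter links: more noise -> lower expected IS,
  # more amplitude -> higher expected RA
  p_lo <- resident_profile("r1", noise_sd = 5)
  p_hi <- resident_profile("r1", noise_sd = 20)
  expect_gt(circalux:::expected_is(p_lo), circalux:::expected_is(p_hi))
  p_a1 <- resident_profile("r1", amplitude = 15)
  p_a2 <- resident_profile("r1", amplitude = 28)
  expect_gt(circalux:::theoretical_ra(p_a2),
            circalux:::theoretical_ra(p_a1))
})

test_that("cohort files round-trip through the plain-text writers", {
  p <- resident_profile("r1", noise_sd = 5)
  sim <- simulate_resident(p, as.Date(c("2023-03-06", "2023-03-06")),
                           seed = 2, frame_rate = 1)
  f <- tempfile(fileext = ".jsonl")
  write_frames_jsonl(sim$frames, f)
  back <- read_frames(f, tz = "Europe/London")
  expect_equal(nrow(back), nrow(sim$frames))
  expect_equal(back$x, sim$frames$x, tolerance = 1e-9)
  expect_equal(as.numeric(back$timestamp),
               as.numeric(sim$frames$timestamp), tolerance = 0.01)
})
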