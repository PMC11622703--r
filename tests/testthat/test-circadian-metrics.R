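test_that("IS is 1 for a repeated daily profile and flagged for a
           constant one", {
  prof <- 30 + 20 * cos(2 * pi * (0:23 - 14) / 24)
  x <- rep(prof, 7)
  act <- make_hourly_activity(x)
  expect_equal(interdaily_stability(act, epoch_minutes = 60), 1,
               tolerance = 1e-12)
  flat <- make_hourly_activity(rep(5, 48))
  is_f <- interdaily_stability(flat, epoch_minutes = 60)
  expect_true(is.na(is_f))
  expect_identical(attr(is_f, "flag"), "zero_variance")
  expect_error(interdaily_stability(make_hourly_activity(rep(1, 10)),
                                    epoch_minutes = 60), "2 days")
})

test_that("IS and IV match brute-force formula evaluation on seeded
           noise", {
  set.seed(33)
  x <- runif(14 * 24, 0, 100)
  act <- make_hourly_activity(x)
  hod <- as.POSIXlt(act$epoch_start)$hour
  expect_equal(interdaily_stability(act, epoch_minutes = 60),
               brute_is(x, hod), tolerance = 1e-12)
  expect_equal(intradaily_variability(act, epoch_minutes = 60),
               brute_iv(x), tolerance = 1e-12)
  # pure 24 h cosine sampled hourly
  xc <- 50 + 30 * cos(2 * pi * (0:(48 - 1)) / 24)
  actc <- make_hourly_activity(xc)
  expect_equal(intradaily_variability(actc, epoch_minutes = 60),
               brute_iv(xc), tolerance = 1e-12)
})

test_that("IV hits exactly 4 on the strictly alternating series", {
  x <- rep(c(0, 100), 24)  # length 48, alternating
  act <- make_hourly_activity(x)
  expect_equal(intradaily_variability(act, epoch_minutes = 60), 4,
               tolerance = 1e-12)
  flat <- make_hourly_activity(rep(7, 48))
  expect_true(is.na(intradaily_variability(flat, epoch_minutes = 60)))
})

test_that("RA identities hold on constructed profiles", {
  # 10 consecutive hours at 60, remaining 14 at 20 -> M10 60, L5 20
  prof <- c(rep(60, 10), rep(20, 14))
  act <- make_hourly_activity(rep(prof, 3))
  ra <- relative_amplitude(act, epoch_minutes = 60)
  expect_equal(ra$M10, 60)
  expect_equal(ra$L5, 20)
  expect_equal(ra$RA, 0.5)
  # L5 = 0 -> RA = 1
  prof0 <- c(rep(60, 10), rep(0, 14))
  ra0 <- relative_amplitude(make_hourly_activity(rep(prof0, 2)),
                            epoch_minutes = 60)
  expect_equal(ra0$RA, 1)
  # constant profile -> M10 = L5 -> RA = 0
  rac <- relative_amplitude(make_hourly_activity(rep(42, 48)),
                            epoch_minutes = 60)
  expect_equal(rac$RA, 0)
  expect_error(relative_amplitude(make_hourly_activity(rep(1, 10)),
                                  epoch_minutes = 60), "24 h")
})

test_that("M10/L5 windows wrap midnight", {
  # most active block 20:00-06:00 wraps; least active 5 h inside the day
  prof <- c(rep(80, 6), rep(5, 12), rep(80, 6))
  ra <- relative_amplitude(make_hourly_activity(rep(prof, 2)),
                           epoch_minutes = 60)
  expect_equal(ra$M10, mean(rep(80, 10)))
  expect_equal(ra$L5, 5)
})

test_that("rhythm metrics are scale-invariant", {
  set.seed(77)
  x <- runif(7 * 24, 0, 50)
  a1 <- make_hourly_activity(x)
  a2 <- make_hourly_activity(3.7 * x)
  for (f in list(interdaily_stability, intradaily_variability))
    expect_equal(as.numeric(f(a1, epoch_minutes = 60)),
                 as.numeric(f(a2, epoch_minutes = 60)),
                 tolerance = 1e-12)
  expect_equal(relative_amplitude(a1, epoch_minutes = 60)$RA,
               relative_amplitude(a2, epoch_minutes = 60)$RA,
               tolerance = 1e-12)
})

test_that("hours with insufficient epoch coverage are dropped, not
           zero-filled", {
  p <- resident_profile("r1", noise_sd = 5)
  sim <- simulate_activity_epochs(p, as.Date(c("2023-03-06",
                                               "2023-03-12")), seed = 2)
  act <- sim$activity
  # knock out 3 of 4 epochs of every 10:00 hour
  drop <- format(act$epoch_start, "%H:%M") %in% c("10:15", "10:30",
                                                  "10:45")
  hb <- hourly_bins(act[!drop])
  expect_false(any(hb$hour == 10))
  expect_true(all(table(hb$hour) > 0))
})

test_that("sundowning windows follow the per-phase sunset config", {
  vals <- rep(50, 96 * 2)
  act <- make_epoch_activity(vals)
  s <- sundowning_activity(act, "baseline")
  expect_equal(s$mean_activity_pct, 50)
  expect_equal(s$sunset_time, "20:00")
  # known values inside the 16:00-20:00 baseline window
  act2 <- make_epoch_activity(rep(0, 96))
  h <- clock_hours(act2$epoch_start)
  act2[h >= 16 & h < 20, activity_pct := rep(c(10, 20, 30, 40), 4)]
  s2 <- sundowning_activity(act2, "baseline")
  expect_equal(s2$mean_activity_pct, 25)
  expect_equal(s2$n_epochs, 16)
  # weeks5_10 window ends at 21:00, weeks10_16 at 22:00
  expect_equal(sundowning_activity(act, "weeks5_10")$sunset_time,
               "21:00")
  expect_equal(sundowning_activity(act, "weeks10_16")$sunset_time,
               "22:00")
  expect_error(sundowning_activity(act, "weeks20_24"), "sunset")
})
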