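test_that("the packaged schedule looks up the expected program levels", {
  sch <- lighting_schedule()
  e <- schedule_lookup("10:00", sch)
  expect_equal(c(e$lux, e$cct, e$output_pct), c(550, 6500, 100))
  e2 <- schedule_lookup("07:30", sch)
  expect_equal(c(e2$lux, e2$cct, e2$output_pct), c(300, 3350, 90))
  e3 <- schedule_lookup("17:00", sch)
  expect_equal(c(e3$lux, e3$cct, e3$output_pct), c(300, 2700, 90))
  # hold semantics outside the programmed span
  expect_equal(schedule_lookup("05:00", sch)$lux, sch$lux[1])
  expect_equal(schedule_lookup("21:00", sch)$lux,
               sch$lux[nrow(sch)])
  empty <- sch[0, ]
  expect_error(schedule_lookup("10:00", empty), "empty")
})

test_that("melanopic EDI is the anchored linear conversion", {
  expect_equal(melanopic_edi(100, 1.0), 100)
  expect_equal(melanopic_edi(300, round_lux = TRUE), 382)
  expect_equal(melanopic_edi(550, round_lux = TRUE), 700)
  # exact linearity at fixed ratio
  lux <- c(10, 50, 123.4, 900)
  expect_equal(melanopic_edi(lux), lux * (331 / 260), tolerance = 1e-12)
  expect_error(melanopic_edi(-5), "positive")
  expect_error(melanopic_edi(100, 0), "positive")
})

test_that("circadian stimulus saturates at 0.7 and halves at 355.7", {
  expect_equal(circadian_stimulus(0), 0)
  expect_equal(circadian_stimulus(355.7), 0.35, tolerance = 1e-12)
  grid <- seq(0, 5000, by = 50)
  cs <- circadian_stimulus(grid)
  expect_true(all(diff(cs) > 0))
  expect_true(all(cs < 0.7))
  expect_error(circadian_stimulus(-1), "nonnegative")
})

test_that("invert_cs is the exact inverse of the saturation formula", {
  expect_equal(invert_cs(0.35), 355.7, tolerance = 1e-6)
  grid <- seq(0.01, 0.69, length.out = 100)
  expect_equal(circadian_stimulus(invert_cs(grid)), grid,
               tolerance = 1e-9)
  expect_error(invert_cs(0.7), "strictly inside")
  expect_error(invert_cs(0))
  # numerical root-finding oracle for the 0.404 anchor
  root <- uniroot(function(z) circadian_stimulus(z) - 0.404,
                  c(1, 5000), tol = 1e-10)$root
  expect_equal(invert_cs(0.404), root, tolerance = 1e-6)
})

test_that("the anchored CL_A/lux reproduces the intermediate program
           level", {
  m <- lighting_metrics(c(260, 300, 550))
  expect_equal(m$cs[1], 0.404)
  expect_equal(m$cs[2], 0.431)
  expect_equal(m$m_edi, c(331, 382, 700))
  # the brightest level carries the documented constant-ratio residual
  expect_lt(abs(m$cs[3] - 0.532), 0.005)
})

test_that("exposure accounting matches the phase definitions", {
  t0 <- as.POSIXct("2023-04-03 00:00:00", tz = "UTC")
  occ <- data.table::data.table(
    epoch_start = t0 + 900 * 0:95,
    present_fraction = 1, room_id = "room1")
  sw_on <- data.table::data.table(
    timestamp = t0 - 3600, room_id = "room1", state = "on")
  expect_equal(exposure_summary(occ, sw_on,
                                "baseline")$pct_dynamic_exposure, 0)
  e <- exposure_summary(occ, sw_on, "weeks5_10")
  expect_equal(e$pct_dynamic_exposure, 100)
  expect_equal(e$pct_time_in_rooms, 100)
  expect_equal(e$pct_lights_on_while_present, 100)
  # never present: the common-area assumption makes exposure full
  occ0 <- data.table::copy(occ)[, present_fraction := 0]
  e0 <- exposure_summary(occ0, sw_on, "weeks10_16")
  expect_equal(e0$pct_dynamic_exposure, 100)
  expect_equal(e0$pct_time_in_rooms, 0)
  # half present with lights off -> only the absent half counts
  occh <- data.table::copy(occ)[, present_fraction :=
                                  rep(c(1, 0), 48)]
  sw_off <- data.table::data.table(
    timestamp = t0 - 3600, room_id = "room1", state = "off")
  eh <- exposure_summary(occh, sw_off, "weeks5_10")
  expect_equal(eh$pct_dynamic_exposure, 50)
  expect_equal(eh$pct_lights_on_while_present, 0)
  expect_error(exposure_summary(occ, sw_on, "weeks1_2"), "phase")
  expect_error(exposure_summary(occ, sw_on[0], "weeks5_10"), "cover")
})

test_that("exposure percentages stay within convex bounds on simulated
           residents", {
  p <- resident_profile("r1")
  sim <- simulate_activity_epochs(p, as.Date(c("2023-04-03",
                                               "2023-04-09")), seed = 8)
  e <- exposure_summary(sim$occupancy, sim$switches, "weeks5_10")
  expect_true(all(unlist(e[, -1]) >= 0 & unlist(e[, -1]) <= 100))
  # dynamic exposure >= time absent
  expect_gte(e$pct_dynamic_exposure, 100 - e$pct_time_in_rooms - 1e-9)
})
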