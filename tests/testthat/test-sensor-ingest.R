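frame_dt <- function(ts, x, y, sensor = "s1", resident = "r1",
                     tz = "UTC") {
  data.table::data.table(
    timestamp = as.POSIXct(ts, tz = tz), sensor_id = sensor,
    resident_id = resident, x = x, y = y)
}

test_that("total translation sums Euclidean frame-pair displacements", {
  ep <- as.POSIXct(c("2023-03-06 10:00:00", "2023-03-06 10:15:00"),
                   tz = "UTC")
  still <- frame_dt(seq(ep[1], by = 1, length.out = 20), x = 1, y = 2)
  expect_equal(total_translation(still, ep), 0)
  two <- frame_dt(ep[1] + c(0, 1), x = c(0, 3), y = c(0, 4))
  expect_equal(total_translation(two, ep), 5)
  # ten-frame fixture, hand-summed
  xs <- c(0, 1, 1, 2, 2, 2, 3, 3, 4, 4)
  ys <- c(0, 0, 1, 1, 3, 3, 3, 4, 4, 6)
  # successive displacements: 1,1,1,2,0,1,1,1,2 -> total 10
  ten <- frame_dt(ep[1] + 0:9, x = xs, y = ys)
  expect_equal(total_translation(ten, ep), 10)
})

test_that("running-max normalization follows the stated rule", {
  ep <- as.POSIXct("2023-03-06 00:00:00", tz = "UTC") + 900 * 0:1
  tr <- data.table::data.table(epoch_start = ep,
                               raw_translation = c(10, 5))
  expect_equal(normalize_activity(tr)$activity_pct, c(100, 50))
  tr2 <- data.table::data.table(epoch_start = ep,
                                raw_translation = c(5, 10))
  expect_equal(normalize_activity(tr2)$activity_pct, c(100, 100))
  tr0 <- data.table::data.table(epoch_start = ep,
                                raw_translation = c(0, 0))
  expect_equal(normalize_activity(tr0)$activity_pct, c(0, 0))
  expect_error(normalize_activity(data.table::data.table(
    epoch_start = ep, raw_translation = c(-1, 2))), "negative")
})

test_that("a nonzero series always reaches 100% and global mode rescales", {
  set.seed(4)
  ep <- as.POSIXct("2023-03-06 00:00:00", tz = "UTC") + 900 * 0:49
  tr <- data.table::data.table(epoch_start = ep,
                               raw_translation = runif(50, 0, 30))
  a <- normalize_activity(tr)
  expect_equal(max(a$activity_pct), 100)
  expect_true(all(a$activity_pct >= 0 & a$activity_pct <= 100))
  g <- normalize_activity(tr, mode = "global_max")
  expect_equal(g$activity_pct,
               100 * tr$raw_translation / max(tr$raw_translation))
})

test_that("epoch binning conserves displacement against a naive sum", {
  set.seed(9)
  n <- 1000
  ts <- as.POSIXct("2023-03-06 07:03:00", tz = "UTC") +
    cumsum(runif(n, 1, 10))   # spans ~90 minutes of epochs
  fr <- frame_dt(ts, x = cumsum(rnorm(n, 0, 0.2)),
                 y = cumsum(rnorm(n, 0, 0.2)))
  binned <- bin_translations(fr)
  expect_gte(nrow(binned), 6)
  whole <- sum(sqrt(diff(fr$x)^2 + diff(fr$y)^2))  # naive single pass
  expect_equal(sum(binned$raw_translation), whole, tolerance = 1e-12)
  # per-epoch totals match the single-epoch routine (boundary pair rule)
  for (i in 2:5) {
    e <- binned$epoch_start[i]
    expect_equal(binned$raw_translation[i],
                 total_translation(fr, c(e, e + 900)),
                 tolerance = 1e-12)
  }
})

test_that("epoch flooring is clock-aligned and idempotent", {
  t <- as.POSIXct("2023-03-06 10:07:31", tz = "UTC")
  f1 <- epoch_floor(t)
  expect_equal(format(f1, "%H:%M:%S"), "10:00:00")
  expect_identical(epoch_floor(f1), f1)
})

test_that("occupancy fractions follow presence runs and the gap rule", {
  rm <- c(s1 = "room1")
  t0 <- as.POSIXct("2023-03-06 10:00:00", tz = "UTC")
  full <- frame_dt(seq(t0, t0 + 899, by = 10), x = 0, y = 0)
  occ <- occupancy_fraction(full, rm, gap_seconds = 30,
                            range = c(t0, t0 + 900))
  expect_equal(occ$present_fraction, 1)
  expect_equal(occ$room_id, "room1")
  # frames in the first half only
  half <- frame_dt(seq(t0, t0 + 420, by = 10), x = 0, y = 0)
  occ2 <- occupancy_fraction(half, rm, gap_seconds = 30,
                             range = c(t0, t0 + 900))
  expect_equal(occ2$present_fraction, 0.5, tolerance = 0.05)
  # an epoch with no frames at all
  occ3 <- occupancy_fraction(half, rm, gap_seconds = 30,
                             range = c(t0, t0 + 1800))
  expect_equal(occ3$present_fraction[2], 0)
  expect_true(is.na(occ3$room_id[2]))
  expect_error(occupancy_fraction(full, c(other = "roomX")), "unmapped")
})

test_that("ingesting simulated frames recovers the generating activity
           shape", {
  p <- resident_profile("r1", noise_sd = 0, n_disturbances_per_night = 0,
                        room_occupancy_fraction = 1)
  sim <- simulate_resident(p, as.Date(c("2023-03-06", "2023-03-08")),
                           seed = 6, frame_rate = 2)
  act <- frames_to_activity(sim$frames)
  # after the running-max warm-up day the series is exactly periodic
  d2 <- act[as.Date(format(epoch_start, "%Y-%m-%d")) >=
              as.Date("2023-03-07")]
  expect_equal(interdaily_stability(d2), 1, tolerance = 1e-9)
  # normalized shape matches the generating truth up to scale
  tru <- sim$activity[as.Date(format(epoch_start, "%Y-%m-%d")) >=
                        as.Date("2023-03-07")]
  m <- merge(d2, tru, by = "epoch_start")
  nz <- m$activity_pct.y > 0
  ratio <- m$activity_pct.x[nz] / m$activity_pct.y[nz]
  # the circular path's chord-vs-arc deficit bounds the distortion
  expect_lt(diff(range(ratio)), 1e-4)
})
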