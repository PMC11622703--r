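# In-code fixtures shared across test files.

# activity series with one value per hour (use epoch_minutes = 60)
make_hourly_activity <- function(values, start = "2023-03-06",
                                 tz = "UTC") {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = tz)
  data.table::data.table(
    epoch_start = t0 + 3600 * (seq_along(values) - 1),
    activity_pct = as.numeric(values))
}

# activity series at the native 15-minute epoch spacing
make_epoch_activity <- function(values, start = "2023-03-06 00:00:00",
                                tz = "UTC") {
  t0 <- as.POSIXct(start, tz = tz)
  data.table::data.table(
    epoch_start = t0 + 900 * (seq_along(values) - 1),
    activity_pct = as.numeric(values))
}

# small three-subscale item map used so scoring tests are independent of
# the packaged instrument map
fixture_item_map <- function() {
  data.table::data.table(
    item = sprintf("item_%02d", 1:8),
    subscale = c("A", "A", "A", "B", "B", "C", "C", "C"),
    reverse = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    max_rating = 3L)
}
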