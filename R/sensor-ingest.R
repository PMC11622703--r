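# Frame-stream ingestion: 8 Hz positional frames -> clock-aligned 15-minute
# epoch translation totals -> running-max normalized activity percentages,
# plus per-epoch room occupancy fractions.
#
# Epochs are half-open [start, end): the displacement between the last frame
# of one epoch and the first frame of the next is credited to the later
# epoch, so no displacement is lost at epoch boundaries.

#' Read a frame stream from JSONL or CSV
#'
#' Expects the columns written by [write_frames_jsonl()] /
#' `data.table::fwrite`: `timestamp` (ISO-8601), `sensor_id`,
#' `resident_id`, `x`, `y`.
#'
#' @param path file path; format inferred from the `.jsonl`/`.csv` suffix
#'   unless `format` is given.
#' @param format `"jsonl"` or `"csv"`.
#' @param tz timezone to represent timestamps in.
#' @return data.table with `timestamp` (`POSIXct`), `sensor_id`,
#'   `resident_id`, `x`, `y`.
#' @export
read_frames <- function(path, format = NULL, tz = "Europe/London") {
  if (is.null(format))
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  df <- if (format == "jsonl") jsonlite::stream_in(file(path),
                                                   verbose = FALSE)
        else data.table::fread(path)
  dt <- data.table::as.data.table(df)
  dt[, timestamp := as.POSIXct(sub("([+-][0-9]{2}):?([0-9]{2})$", "\\1\\2",
                                   timestamp),
                               format = "%Y-%m-%dT%H:%M:%OS%z", tz = tz)]
  data.table::setorder(dt, sensor_id, timestamp)
  dt[]
}

#' Total x-y translation of a frame stream within one epoch
#'
#' Sums the Euclidean displacement magnitude over consecutive frame pairs
#' whose *later* frame falls inside the half-open epoch `[start, end)`.
#' Returns 0 when the epoch holds fewer than two contributing frames.
#'
#' @param frames frame data.table (single resident), ordered by time.
#' @param epoch length-2 `POSIXct` `c(start, end)`, clock-aligned.
#' @return metres (numeric scalar).
#' @export
total_translation <- function(frames, epoch) {
  stopifnot(length(epoch) == 2L)
  if (nrow(frames) < 2L) return(0)
  d <- sqrt(diff(frames$x)^2 + diff(frames$y)^2)
  later <- frames$timestamp[-1L]
  sum(d[later >= epoch[1] & later < epoch[2]])
}

#' Bin a frame stream into per-epoch translation totals
#'
#' @param frames frame data.table for one resident.
#' @param epoch_minutes epoch length in minutes (clock-aligned).
#' @return data.table `epoch_start`, `raw_translation` (metres), `n_frames`;
#'   epochs with no frames are absent (gaps are explicit missing epochs,
#'   never zeros).
#' @export
bin_translations <- function(frames, epoch_minutes = 15) {
  stopifnot(nrow(frames) >= 1L)
  frames <- frames[order(timestamp)]
  d <- c(0, sqrt(diff(frames$x)^2 + diff(frames$y)^2))
  ep <- epoch_floor(frames$timestamp, epoch_minutes)
  out <- data.table::data.table(epoch_start = ep, d = d)[
    , .(raw_translation = sum(d), n_frames = .N), by = epoch_start]
  data.table::setorder(out, epoch_start)
  out[]
}

#' Normalize epoch translation totals into activity percentages
#'
#' Activity is the epoch translation total as a percentage of the running
#' maximum epoch total observed so far for this resident (`mode =
#' "running_max"`, the default), or of the maximum over the whole series
#' (`mode = "global_max"`). A zero running maximum yields 0%.
#'
#' @param translations data.table from [bin_translations()] (columns
#'   `epoch_start`, `raw_translation`, optionally `n_frames`).
#' @param mode `"running_max"` or `"global_max"`.
#' @return data.table `epoch_start`, `activity_pct` (0-100),
#'   `raw_translation`, `n_frames`.
#' @export
normalize_activity <- function(translations, mode = c("running_max",
                                                      "global_max")) {
  mode <- match.arg(mode)
  stopifnot(nrow(translations) >= 1L)
  if (any(translations$raw_translation < 0))
    stop("negative raw translation: upstream invariant violated")
  out <- data.table::copy(translations)
  data.table::setorder(out, epoch_start)
  mx <- if (mode == "running_max") cummax(out$raw_translation)
        else rep(max(out$raw_translation), nrow(out))
  out[, activity_pct := ifelse(mx > 0, 100 * raw_translation / mx, 0)]
  if (!"n_frames" %in% names(out)) out[, n_frames := NA_integer_]
  out[, .(epoch_start, activity_pct, raw_translation, n_frames)]
}

#' Per-epoch room occupancy fractions from a frame stream
#'
#' Presence is reconstructed as runs of frames whose inter-frame gap does
#' not exceed `gap_seconds`; each run is closed `gap_seconds` after its last
#' frame (capped at the next run). The fraction of each clock-aligned epoch
#' covered by presence runs is reported.
#'
#' @param frames frame data.table for one resident.
#' @param room_map named character vector `sensor_id -> room_id`.
#' @param epoch_minutes epoch length.
#' @param gap_seconds absence-gap threshold (seconds).
#' @param range optional length-2 `POSIXct` analysis range; defaults to the
#'   epoch span of the frames.
#' @return data.table `epoch_start`, `present_fraction` (0-1), `room_id`
#'   (`NA` where absent the whole epoch).
#' @export
occupancy_fraction <- function(frames, room_map, epoch_minutes = 15,
                               gap_seconds = 60, range = NULL) {
  unmapped <- setdiff(unique(frames$sensor_id), names(room_map))
  if (length(unmapped))
    stop("unmapped sensor_id: ", paste(unmapped, collapse = ", "))
  frames <- frames[order(timestamp)]
  ts <- as.numeric(frames$timestamp)
  rid <- cumsum(c(1, as.integer(diff(ts) > gap_seconds)))
  runs <- data.table::data.table(ts = ts, sensor = frames$sensor_id,
                                 rid = rid)[
    , .(start = min(ts), end = max(ts), sensor = sensor[1]), by = rid]
  starts <- runs$start
  ends <- pmin(runs$end + gap_seconds, c(tail(starts, -1), Inf))
  rooms <- room_map[runs$sensor]

  sec <- epoch_minutes * 60
  tz <- attr(frames$timestamp, "tzone")
  if (is.null(range)) {
    e0 <- floor(min(ts) / sec) * sec
    e1 <- ceiling(max(ends[is.finite(ends)]) / sec) * sec
  } else {
    e0 <- floor(as.numeric(range[1]) / sec) * sec
    e1 <- ceiling(as.numeric(range[2]) / sec) * sec
  }
  ep <- seq(e0, e1 - sec, by = sec)
  frac <- numeric(length(ep))
  room_of <- rep(NA_character_, length(ep))
  for (k in seq_along(starts)) {
    lo <- starts[k]; hi <- min(ends[k], e1)
    cover <- pmax(0, pmin(ep + sec, hi) - pmax(ep, lo))
    frac <- frac + cover / sec
    room_of[cover > 0] <- rooms[k]
  }
  data.table::data.table(
    epoch_start = structure(ep, class = c("POSIXct", "POSIXt"), tzone = tz),
    present_fraction = pmin(1, frac), room_id = room_of)
}

#' Frame stream to normalized activity series
#'
#' Convenience wrapper: [bin_translations()] then [normalize_activity()].
#'
#' @inheritParams bin_translations
#' @inheritParams normalize_activity
#' @return see [normalize_activity()].
#' @export
frames_to_activity <- function(frames, epoch_minutes = 15,
                               mode = "running_max") {
  normalize_activity(bin_translations(frames, epoch_minutes), mode = mode)
}
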