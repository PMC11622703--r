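# Clock/epoch helpers shared across modules. All clock logic is evaluated in
# local civil time (the tz attached to the timestamps), so daylight-saving
# transitions simply yield 23/25-hour days.

#' Floor a timestamp to its clock-aligned epoch start
#'
#' Epochs are aligned to the local clock (`:00`, `:15`, `:30`, `:45` for the
#' default 15-minute epoch).
#'
#' @param t a `POSIXct` vector.
#' @param epoch_minutes epoch length in minutes; must divide 60.
#' @return `POSIXct` vector of epoch starts, same timezone as `t`.
#' @export
epoch_floor <- function(t, epoch_minutes = 15) {
  stopifnot(inherits(t, "POSIXct"), 60 %% epoch_minutes == 0)
  sec <- epoch_minutes * 60
  structure(floor(as.numeric(t) / sec) * sec,
            class = class(t), tzone = attr(t, "tzone"))
}

#' Local clock hour as a fraction
#'
#' @param t a `POSIXct` vector.
#' @return numeric hours from local midnight, in `[0, 24)`.
#' @export
clock_hours <- function(t) {
  lt <- as.POSIXlt(t)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Local calendar date
#' @param t a `POSIXct` vector.
#' @return `Date` vector in the timestamps' own timezone.
#' @export
local_date <- function(t) as.Date(format(t, "%Y-%m-%d"))

parse_clock <- function(s) {
  # "HH:MM" -> fractional hours
  p <- strsplit(s, ":", fixed = TRUE)[[1]]
  as.numeric(p[1]) + as.numeric(p[2]) / 60
}

#' Study phase plan
#'
#' The default plan follows the three-phase baseline-intervention design:
#' a static-lighting baseline over weeks 1-4, then dynamic lighting with a
#' midpoint analysis window over weeks 5-10 and an end-of-intervention window
#' over weeks 10-16. Week 10 is printed in both dynamic ranges in the study
#' protocol; week ranges here are half-open (`[5,10)`, `[10,17)`) so that no
#' week is double-counted: week 10 belongs to the final phase.
#'
#' @param start_date `Date` (or coercible) of the Monday of week 1.
#' @param phases named list of integer week vectors (1-based study weeks).
#' @param tz Olson timezone the study clock runs in.
#' @return an object of class `phase_plan`: list with `start_date`, `phases`,
#'   `tz`, and per-phase `Date` ranges.
#' @export
phase_plan <- function(start_date = as.Date("2023-03-06"),
                       phases = list(baseline   = 1:4,
                                     weeks5_10  = 5:9,
                                     weeks10_16 = 10:16),
                       tz = "Europe/London") {
  start_date <- as.Date(start_date)
  wk <- sort(unlist(phases, use.names = FALSE))
  if (anyDuplicated(wk)) stop("phase week ranges overlap")
  ranges <- lapply(phases, function(w) {
    c(start = start_date + (min(w) - 1) * 7,
      end   = start_date + max(w) * 7)  # half-open [start, end)
  })
  structure(list(start_date = start_date, phases = phases, tz = tz,
                 ranges = ranges),
            class = "phase_plan")
}

#' @export
print.phase_plan <- function(x, ...) {
  cat("Phase plan (week 1 starts", format(x$start_date), "tz", x$tz, ")\n")
  for (p in names(x$phases)) {
    r <- x$ranges[[p]]
    cat(sprintf("  %-11s weeks %2d-%2d  [%s, %s)\n", p,
                min(x$phases[[p]]), max(x$phases[[p]]),
                format(r[1]), format(r[2])))
  }
  invisible(x)
}

#' Label timestamps or dates with their study phase
#'
#' @param t `POSIXct` or `Date` vector.
#' @param plan a [phase_plan()].
#' @return character vector of phase labels (`NA` outside all phases).
#' @export
phase_of <- function(t, plan) {
  d <- if (inherits(t, "POSIXct")) local_date(t) else as.Date(t)
  out <- rep(NA_character_, length(d))
  for (p in names(plan$ranges)) {
    r <- plan$ranges[[p]]
    out[d >= r[1] & d < r[2]] <- p
  }
  out
}

#' Study week number of timestamps or dates
#'
#' @inheritParams phase_of
#' @return integer study week (1-based; `NA` before the study start).
#' @export
week_of <- function(t, plan) {
  d <- if (inherits(t, "POSIXct")) local_date(t) else as.Date(t)
  w <- as.integer(floor(as.numeric(d - plan$start_date) / 7)) + 1L
  w[w < 1L] <- NA_integer_
  w
}

# derive a reproducible 32-bit substream seed from a master seed and counter
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 7919 + 104729 * as.numeric(counter)) %%
               2147483647)
}
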