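# QUALIDEM scoring: weekly proxy-rated item responses -> subscale scores
# A-H (analyzed) plus I and J (reported, excluded from statistics).
#
# The instrument's exact item-to-subscale map is deliberately shipped as an
# editable YAML config: the packaged default follows the 37-item
# instrument's subscale structure (A care relationship 7, B positive affect
# 6, C negative affect 3, D restless tense behaviour 3, E positive
# self-image 3, F social relations 6, G social isolation 3, H feeling at
# home 4, I having something to do 2) with negative-worded subscales
# (C, D, G) reverse-scored, plus a small J "other" block. Correctness of
# the scoring machinery is independent of the published map's details.

#' QUALIDEM item map
#'
#' @param path YAML file with an `items` list (`item`, `subscale`,
#'   `reverse`, `max_rating`); defaults to the packaged map.
#' @return data.table `item`, `subscale`, `reverse` (logical),
#'   `max_rating` (integer; items are rated `0..max_rating`).
#' @export
qualidem_item_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "qualidem_item_map.yaml",
                        package = "circalux", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  dt <- data.table::rbindlist(lapply(raw$items, function(e)
    data.table::data.table(item = e$item, subscale = e$subscale,
                           reverse = isTRUE(e$reverse),
                           max_rating = as.integer(e$max_rating))))
  if (anyDuplicated(dt$item)) stop("duplicate item ids in map")
  dt
}

#' Score one QUALIDEM response row into subscale scores
#'
#' Reverse-scored items contribute `max_rating - r`; each subscale is the
#' sum of its item contributions. If some of a subscale's items are missing
#' (`NA`) but at least `prorate_min` of them are answered, the sum is
#' prorated to the full item count; below that the subscale is flagged
#' missing.
#'
#' @param response named list/vector of integer ratings, names matching the
#'   map's `item` ids; missing or `NA` items count as unanswered.
#' @param item_map see [qualidem_item_map()].
#' @param prorate_min minimum answered fraction for proration.
#' @return data.table `subscale`, `score`, `max_score`, `n_answered`,
#'   `n_items`.
#' @export
score_qualidem <- function(response, item_map = qualidem_item_map(),
                           prorate_min = 2 / 3) {
  r <- unlist(response[item_map$item])
  if (is.null(r)) r <- rep(NA_real_, nrow(item_map))
  r <- as.numeric(r)
  bad <- !is.na(r) & (r < 0 | r > item_map$max_rating)
  if (any(bad))
    stop("rating out of range for item(s): ",
         paste(item_map$item[bad], collapse = ", "))
  contrib <- ifelse(item_map$reverse, item_map$max_rating - r, r)
  dt <- data.table::data.table(subscale = item_map$subscale,
                               contrib = contrib,
                               mx = item_map$max_rating)
  dt[, .(score = {
    n_ans <- sum(!is.na(contrib))
    if (n_ans == 0L || n_ans < prorate_min * .N) NA_real_
    else sum(contrib, na.rm = TRUE) * .N / n_ans
  }, max_score = sum(mx), n_answered = sum(!is.na(contrib)),
  n_items = .N), by = subscale]
}

#' Score a weekly QUALIDEM panel
#'
#' @param panel data.table as from [simulate_qualidem_panel()] (columns
#'   `resident_id`, `week`, `item_*`).
#' @inheritParams score_qualidem
#' @return data.table `resident_id`, `week`, `subscale`, `score`,
#'   `max_score`.
#' @export
score_qualidem_panel <- function(panel, item_map = qualidem_item_map(),
                                 prorate_min = 2 / 3) {
  out <- lapply(seq_len(nrow(panel)), function(i) {
    sc <- score_qualidem(as.list(panel[i]), item_map, prorate_min)
    sc[, `:=`(resident_id = panel$resident_id[i], week = panel$week[i])]
    sc[, .(resident_id, week, subscale, score, max_score)]
  })
  data.table::rbindlist(out)
}

#' Restrict scores to the analyzed subscales
#'
#' Subscales I (occupation) and J (other) are carried in reports but
#' excluded from all statistics.
#'
#' @param scores data.table with a `subscale` column.
#' @param analyzed subscale labels retained for analysis.
#' @return the rows of `scores` belonging to analyzed subscales.
#' @export
select_analysis_subscales <- function(scores,
                                      analyzed = LETTERS[1:8]) {
  scores[subscale %in% analyzed]
}
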