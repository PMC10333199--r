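#' Filter false-positive detections
#'
#' Applies the three quality-control rules to a detection table and
#' attributes every rejection to exactly one rule:
#'
#' * `min_pulses` — fewer pulses than a complete burst
#'   (default 3) mark an incomplete, untrustworthy decode.
#' * `freq_offset` — absolute frequency offset larger than `freq_tol_khz`,
#'   when the offset field is present.
#' * `burst_interval` — within each tag-by-station detection sequence,
#'   consecutive detections whose time gaps match an integer multiple
#'   (1..`k_max_missed_bursts`) of the tag's burst interval to within
#'   `burst_interval_tol_s` form a run; runs shorter than
#'   `min_run_bursts` are rejected as noise that happened to decode as a
#'   known tag.
#'
#' The pulse-count and frequency rules are applied first, then runs are
#' computed on the survivors, so re-filtering an already filtered table
#' changes nothing.
#'
#' @param detections detection data.frame (see [read_detections()]).
#' @param deployments deployment data.frame; every detection's tag must be
#'   present (its burst interval is needed).
#' @param config a [rufa_config()] list.
#' @return list with `detections` (the retained rows, sorted by tag then
#'   time) and `report`, a list with `n_input`, `n_rejected_by_rule`
#'   (named integer vector) and `n_valid`.
#' @export
filter_detections <- function(detections, deployments, config = rufa_config()) {
  unknown <- setdiff(unique(detections$tag_id), deployments$tag_id)
  if (length(unknown)) {
    stop("detections reference tag(s) without deployment record: ",
         paste(unknown, collapse = ", "))
  }
  det <- detections[order(detections$tag_id, detections$time), , drop = FALSE]
  n_input <- nrow(det)
  rule <- rep(NA_character_, n_input)

  rule[det$n_pulses < config$min_pulses] <- "min_pulses"
  has_off <- !is.na(det$freq_offset_khz)
  rule[is.na(rule) & has_off &
         abs(det$freq_offset_khz) > config$freq_tol_khz] <- "freq_offset"

  bi <- deployments$burst_interval_s[match(det$tag_id, deployments$tag_id)]
  surv <- which(is.na(rule))
  if (length(surv)) {
    key <- paste(det$tag_id[surv], det$station_id[surv], sep = "\r")
    for (idx in split(surv, key)) {
      idx <- idx[order(det$time[idx])]
      keep <- run_keep(as.numeric(det$time[idx]), bi[idx[1]],
                       config$burst_interval_tol_s,
                       config$k_max_missed_bursts,
                       config$min_run_bursts)
      rule[idx[!keep]] <- "burst_interval"
    }
  }

  rejected <- table(factor(rule, levels = c("min_pulses", "freq_offset",
                                            "burst_interval")))
  report <- list(
    n_input = n_input,
    n_rejected_by_rule = stats::setNames(as.integer(rejected),
                                         names(rejected)),
    n_valid = sum(is.na(rule))
  )
  list(detections = det[is.na(rule), , drop = FALSE], report = report)
}

# Membership of each detection time in a burst-interval-consistent run of
# length >= min_run. A gap is consistent when it is within tol of k * bi
# for some integer k in 1..k_max.
run_keep <- function(times, bi, tol, k_max, min_run) {
  n <- length(times)
  if (n == 0) return(logical(0))
  gaps <- diff(times)
  k <- round(gaps / bi)
  ok_gap <- k >= 1 & k <= k_max & abs(gaps - k * bi) <= tol
  run_id <- cumsum(c(TRUE, !ok_gap))
  run_len <- ave(run_id, run_id, FUN = length)
  run_len >= min_run
}

#' Group detections into station bouts
#'
#' A bout is a contiguous run of valid detections of one tag at one
#' station; a new bout starts when the station changes or the same-station
#' gap exceeds `bout_max_gap_min`. Bouts are the unit of all downstream
#' inference (departure timing, route classification, stopovers, flights).
#'
#' @param detections QC-passed detection data.frame.
#' @param config a [rufa_config()] list.
#' @return data.frame with `tag_id, station_id, start, end, n_detections`,
#'   sorted by tag then start time.
#' @export
bout_detections <- function(detections, config = rufa_config()) {
  if (!nrow(detections)) {
    return(data.frame(tag_id = character(0), station_id = character(0),
                      start = parse_utc(character(0)),
                      end = parse_utc(character(0)),
                      n_detections = integer(0), stringsAsFactors = FALSE))
  }
  det <- detections[order(detections$tag_id, detections$time), , drop = FALSE]
  max_gap_s <- config$bout_max_gap_min * 60
  new_tag <- c(TRUE, det$tag_id[-1] != det$tag_id[-nrow(det)])
  new_sta <- c(TRUE, det$station_id[-1] != det$station_id[-nrow(det)])
  gap <- c(Inf, diff(as.numeric(det$time)))
  bout_id <- cumsum(new_tag | new_sta | gap > max_gap_s)
  split_idx <- split(seq_len(nrow(det)), bout_id)
  out <- data.frame(
    tag_id = vapply(split_idx, function(i) det$tag_id[i[1]], character(1)),
    station_id = vapply(split_idx, function(i) det$station_id[i[1]],
                        character(1)),
    start = as_utc(as.POSIXct(
      vapply(split_idx, function(i) as.numeric(min(det$time[i])), numeric(1)),
      origin = "1970-01-01", tz = "UTC")),
    end = as_utc(as.POSIXct(
      vapply(split_idx, function(i) as.numeric(max(det$time[i])), numeric(1)),
      origin = "1970-01-01", tz = "UTC")),
    n_detections = vapply(split_idx, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$tag_id, out$start), , drop = FALSE]
}
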