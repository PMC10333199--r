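#' Extract migratory flights from a bird's bouts
#'
#' Consecutive same-station bouts are first collapsed into station
#' passages. Every contiguous passage window is then a candidate flight;
#' a candidate is kept when its great-circle displacement between the
#' first and last station is at least `flight_min_displacement_km`
#' (excluding local movements) and its duration is at most
#' `flight_max_duration_h`. Duration runs from the last detection at the
#' beginning station to the first detection at the ending station. A bird
#' may contribute several flights only when their station sequences share
#' no station: candidates are accepted greedily by decreasing
#' displacement (ties broken by earlier departure).
#'
#' @param bouts bout data.frame for a single bird, time-sorted.
#' @param stations station table.
#' @param config a [rufa_config()] list.
#' @return data.frame with one row per flight: `tag_id`,
#'   `station_sequence` (comma-separated), `depart_time`, `arrive_time`,
#'   `total_length_km`, `displacement_km`, `duration_h`,
#'   `net_ground_speed_ms`, `bearing_deg` (initial bearing first to last
#'   station), and departure coordinates `depart_lat`, `depart_lon`.
#' @export
extract_flights <- function(bouts, stations, config = rufa_config()) {
  empty <- data.frame(tag_id = character(0), station_sequence = character(0),
                      depart_time = parse_utc(character(0)),
                      arrive_time = parse_utc(character(0)),
                      total_length_km = numeric(0),
                      displacement_km = numeric(0), duration_h = numeric(0),
                      net_ground_speed_ms = numeric(0),
                      bearing_deg = numeric(0), depart_lat = numeric(0),
                      depart_lon = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(bouts)) return(empty)
  bouts <- bouts[order(bouts$start), , drop = FALSE]
  # collapse consecutive same-station bouts into passages
  n <- nrow(bouts)
  new_pass <- c(TRUE, bouts$station_id[-1] != bouts$station_id[-n])
  pid <- cumsum(new_pass)
  pass <- do.call(rbind, lapply(split(seq_len(n), pid), function(idx) {
    data.frame(station_id = bouts$station_id[idx[1]],
               first = min(bouts$start[idx]),
               last = max(bouts$end[idx]), stringsAsFactors = FALSE)
  }))
  m <- nrow(pass)
  if (m < 2) return(empty)
  si <- match(pass$station_id, stations$station_id)
  if (anyNA(si)) stop("bout references unknown station")
  plat <- stations$lat[si]; plon <- stations$lon[si]
  legs <- gc_distance(plat[-m], plon[-m], plat[-1], plon[-1])

  cand <- list()
  for (i in seq_len(m - 1)) {
    for (j in seq((i + 1), m)) {
      disp <- gc_distance(plat[i], plon[i], plat[j], plon[j])
      dur_h <- as.numeric(difftime(pass$first[j], pass$last[i],
                                   units = "hours"))
      if (disp >= config$flight_min_displacement_km &&
          dur_h > 0 && dur_h <= config$flight_max_duration_h) {
        cand[[length(cand) + 1]] <- list(i = i, j = j, disp = disp,
                                         dur = dur_h)
      }
    }
  }
  if (!length(cand)) return(empty)
  disp <- vapply(cand, `[[`, numeric(1), "disp")
  dep <- vapply(cand, function(x) as.numeric(pass$last[x$i]), numeric(1))
  ord <- order(-disp, dep)
  used_stations <- character(0)
  rows <- list()
  for (k in ord) {
    c0 <- cand[[k]]
    seq_st <- pass$station_id[c0$i:c0$j]
    if (length(intersect(unique(seq_st), used_stations))) next
    used_stations <- c(used_stations, unique(seq_st))
    total <- sum(legs[c0$i:(c0$j - 1)])
    rows[[length(rows) + 1]] <- data.frame(
      tag_id = bouts$tag_id[1],
      station_sequence = paste(seq_st, collapse = ","),
      depart_time = pass$last[c0$i],
      arrive_time = pass$first[c0$j],
      total_length_km = total,
      displacement_km = c0$disp,
      duration_h = c0$dur,
      net_ground_speed_ms = c0$disp * 1000 / (c0$dur * 3600),
      bearing_deg = initial_bearing(plat[c0$i], plon[c0$i],
                                    plat[c0$j], plon[c0$j]),
      depart_lat = plat[c0$i], depart_lon = plon[c0$i],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$depart_time), , drop = FALSE]
  rownames(out) <- NULL
  out
}
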