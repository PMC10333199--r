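#' Analysis configuration
#'
#' Bundles every numeric rule used by the pipeline into one validated list.
#' Defaults encode the study conventions: stations within 30 km of the
#' Delaware Bay watershed count as "bay" stations, stopovers require
#' detection spans strictly greater than 4 h (single station) or 6 h
#' (stations within 30 km of each other), stopover detections must be more
#' than 50 km from the tagging location, migratory flights require at least
#' 150 km displacement and at most 18 h duration, and northbound migration
#' runs from deployment to 15 June.
#'
#' @param bay_buffer_km buffer (km) around the Delaware Bay watershed within
#'   which a station counts as a bay station.
#' @param likely_buffer_km additional buffer (km) beyond `bay_buffer_km`;
#'   repeated multi-day detections in this annulus score "likely stopped".
#' @param min_stop_days minimum day span of bay detections for a stop, and
#'   the transit-slack threshold (days) separating "skipped" from slower
#'   passages.
#' @param stopover_single_station_h detection span (h, strict) at a single
#'   station that defines a stopover.
#' @param stopover_multi_station_h detection span (h, strict) across a
#'   station cluster that defines a stopover.
#' @param stopover_station_cluster_km maximum pairwise distance (km) between
#'   stations of a multi-station stopover cluster.
#' @param stopover_min_dist_from_capture_km stations closer than this to the
#'   tagging location are excluded from stopover detection, and define
#'   "away from the capture site" for departure estimation.
#' @param flight_min_displacement_km minimum great-circle displacement (km)
#'   between the first and last station of a migratory flight.
#' @param flight_max_duration_h maximum flight duration (h).
#' @param heatmap_buffer_km radius (km) around stopover stations used for
#'   the stopover heat map overlay.
#' @param heatmap_cell_deg heat-map raster cell size in degrees.
#' @param assumed_transit_speed_ms ground speed (m/s) assumed when testing
#'   whether a passage left time for a stopover.
#' @param inland_offset_km distance (km) from the Atlantic coastline beyond
#'   which an intermediate detection counts as "inland".
#' @param bout_max_gap_min gap (min) between same-station detections above
#'   which a new detection bout starts.
#' @param min_pulses minimum pulse count for a valid detection.
#' @param min_run_bursts minimum length of a burst-interval-consistent run;
#'   shorter runs are rejected as noise.
#' @param burst_interval_tol_s tolerance (s) when matching detection gaps to
#'   integer multiples of a tag's burst interval.
#' @param k_max_missed_bursts largest multiple of the burst interval
#'   accepted between consecutive detections of a run.
#' @param freq_tol_khz maximum absolute frequency offset (kHz) for a valid
#'   detection, when the offset field is present.
#' @param migration_season_end month-day string "MM-DD"; detections after
#'   this date (in the deployment year) are outside the northbound season.
#'
#' @return A list of class `rufa_config`.
#' @examples
#' cfg <- rufa_config()
#' cfg$flight_min_displacement_km
#' @export
rufa_config <- function(bay_buffer_km = 30,
                        likely_buffer_km = 60,
                        min_stop_days = 1.0,
                        stopover_single_station_h = 4,
                        stopover_multi_station_h = 6,
                        stopover_station_cluster_km = 30,
                        stopover_min_dist_from_capture_km = 50,
                        flight_min_displacement_km = 150,
                        flight_max_duration_h = 18,
                        heatmap_buffer_km = 50,
                        heatmap_cell_deg = 0.25,
                        assumed_transit_speed_ms = 20,
                        inland_offset_km = 150,
                        bout_max_gap_min = 30,
                        min_pulses = 3,
                        min_run_bursts = 3,
                        burst_interval_tol_s = 0.1,
                        k_max_missed_bursts = 10,
                        freq_tol_khz = 2,
                        migration_season_end = "06-15") {
  cfg <- list(
    bay_buffer_km = bay_buffer_km,
    likely_buffer_km = likely_buffer_km,
    min_stop_days = min_stop_days,
    stopover_single_station_h = stopover_single_station_h,
    stopover_multi_station_h = stopover_multi_station_h,
    stopover_station_cluster_km = stopover_station_cluster_km,
    stopover_min_dist_from_capture_km = stopover_min_dist_from_capture_km,
    flight_min_displacement_km = flight_min_displacement_km,
    flight_max_duration_h = flight_max_duration_h,
    heatmap_buffer_km = heatmap_buffer_km,
    heatmap_cell_deg = heatmap_cell_deg,
    assumed_transit_speed_ms = assumed_transit_speed_ms,
    inland_offset_km = inland_offset_km,
    bout_max_gap_min = bout_max_gap_min,
    min_pulses = min_pulses,
    min_run_bursts = min_run_bursts,
    burst_interval_tol_s = burst_interval_tol_s,
    k_max_missed_bursts = k_max_missed_bursts,
    freq_tol_khz = freq_tol_khz,
    migration_season_end = migration_season_end
  )
  num <- vapply(cfg[setdiff(names(cfg), "migration_season_end")],
                is.numeric, logical(1))
  if (!all(num)) stop("all configuration thresholds must be numeric")
  pos <- vapply(cfg[setdiff(names(cfg), "migration_season_end")],
                function(x) is.finite(x) && x > 0, logical(1))
  if (!all(pos)) {
    stop("configuration thresholds must be strictly positive: ",
         paste(names(pos)[!pos], collapse = ", "))
  }
  if (!grepl("^[0-1][0-9]-[0-3][0-9]$", migration_season_end)) {
    stop("migration_season_end must be an 'MM-DD' string")
  }
  structure(cfg, class = "rufa_config")
}

#' Read a configuration file
#'
#' Reads a JSON or YAML file whose entries override the [rufa_config()]
#' defaults; every field is optional.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A `rufa_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML config files")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(vals), names(formals(rufa_config)))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(rufa_config, vals)
}

#' @export
print.rufa_config <- function(x, ...) {
  cat("rufatrack analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-34s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
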