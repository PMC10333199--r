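# In-code fixtures shared across test files.

utc <- function(x) as.POSIXct(x, tz = "UTC")

mk_stations <- function(ids, lat, lon) {
  data.frame(station_id = ids, lat = lat, lon = lon,
             active_from = utc(rep(NA, length(ids))),
             active_to = utc(rep(NA, length(ids))),
             stringsAsFactors = FALSE)
}

mk_deployment <- function(tag = "T1", time = "2019-05-01 12:00:00",
                          lat = 32.54, lon = -80.18, bi = 5.0,
                          mass = NA_real_) {
  data.frame(tag_id = tag, burst_interval_s = bi, nominal_freq_mhz = 166.38,
             deploy_time = utc(time), deploy_lat = lat, deploy_lon = lon,
             body_mass_g = mass, age_class = "adult", site = "test",
             stringsAsFactors = FALSE)
}

mk_detections <- function(tag, station, times, n_pulses = 3,
                          freq_offset = 0, signal = -60) {
  n <- length(times)
  data.frame(tag_id = rep_len(tag, n), station_id = rep_len(station, n),
             time = if (is.numeric(times))
               as.POSIXct(times, origin = "1970-01-01", tz = "UTC")
               else utc(times),
             n_pulses = as.integer(rep_len(n_pulses, n)),
             freq_offset_khz = rep_len(freq_offset, n),
             signal = rep_len(signal, n), stringsAsFactors = FALSE)
}

mk_bouts <- function(tag, station, start, end, n = 5) {
  k <- max(length(station), length(start))
  data.frame(tag_id = rep_len(tag, k), station_id = rep_len(station, k),
             start = utc(start), end = utc(end),
             n_detections = rep_len(n, k), stringsAsFactors = FALSE)
}

# axis-aligned rectangular region
reg_box <- function(role, lat0, lat1, lon0, lon1, name = role) {
  region(name, role,
         list(cbind(c(lon0, lon1, lon1, lon0, lon0),
                    c(lat0, lat0, lat1, lat1, lat0))))
}

# small constant wind field covering the eastern seaboard test domain
mk_wind <- function(u = 0, v = 0, times = utc("2019-05-01 00:00:00") +
                      (0:8) * 21600) {
  nt <- length(times)
  lats <- seq(24, 58, by = 2)
  lons <- seq(-96, -58, by = 2)
  wind_field(times, lats, lons,
             array(u, c(nt, length(lats), length(lons))),
             array(v, c(nt, length(lats), length(lons))))
}

pooled_class <- function(strategy) {
  unname(c(stopped = "stopped", likely_stopped = "stopped",
           skipped = "skipped", likely_skipped = "skipped",
           unknown = "unknown")[strategy])
}

det_key <- function(d) {
  paste(d$tag_id, d$station_id, format(d$time, "%Y%m%d%H%M%OS4"))
}
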