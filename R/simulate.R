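#' Define a simulation scenario
#'
#' Parameters of the synthetic study: a sparse receiver network spanning
#' the Southeast coast, Delaware Bay, the Great Lakes corridor and
#' James/Hudson Bay; birds deployed on the South Carolina coast (no
#' station within 50 km of the capture site, as in the study system) that
#' migrate north along strategy-specific routes; probabilistic detection;
#' station-level false positives; and a 6-hourly gridded wind field that
#' modulates realized ground speeds.
#'
#' Defaults emulate the study conditions: a 40-bird cohort dominated by
#' bay-skipping birds (21 inland skippers, 8 Atlantic-coast birds that
#' stop outside Delaware Bay, 11 bay stoppers), bay stopovers of 2-17
#' days, detection probability 0.8 per station pass, and a mean
#' south-westerly flow so that most departures enjoy tailwinds. Realized
#' ground speed per flight segment is
#' `airspeed + wind_coupling * tailwind + noise`.
#'
#' @param seed integer seed; fixed seed gives byte-identical outputs.
#' @param n_stopped,n_skipped,n_atlantic birds per true strategy
#'   (bay stopover / inland skip / Atlantic non-bay stopover).
#' @param p_detect detection probability per station pass.
#' @param detection_range_km nominal detection range (km) of a station.
#' @param false_positive_per_station_day expected false positives per
#'   station per day.
#' @param airspeed_mean_ms,airspeed_sd_ms per-bird airspeed distribution.
#' @param wind_coupling multiplier on tailwind in realized ground speed.
#' @param speed_noise_sd_ms per-segment speed noise (m/s).
#' @param mean_u_ms,mean_v_ms mean eastward/northward flow (m/s).
#' @param wind_perturb_ms amplitude of smooth wind perturbations (m/s).
#' @param wind_max_ms wind speed bound at every grid node.
#' @param bay_stop_min_d,bay_stop_max_d Delaware Bay stopover duration
#'   range (days).
#' @param alt_stop_min_d,alt_stop_max_d Atlantic (non-bay) stopover
#'   duration range (days).
#' @param residency_min_d,residency_max_d days spent at the capture site
#'   between deployment and departure.
#' @param year simulation year.
#' @param station_density `"default"` (sparse, as in the study years) or
#'   `"dense"` (additional inland and coastal stations).
#' @return list of class `rufa_scenario`.
#' @export
sim_scenario <- function(seed = 1,
                         n_stopped = 11, n_skipped = 21, n_atlantic = 8,
                         p_detect = 0.8,
                         detection_range_km = 15,
                         false_positive_per_station_day = 0.2,
                         airspeed_mean_ms = 16, airspeed_sd_ms = 1,
                         wind_coupling = 1.0, speed_noise_sd_ms = 2,
                         mean_u_ms = 2, mean_v_ms = 4,
                         wind_perturb_ms = 3, wind_max_ms = 25,
                         bay_stop_min_d = 2, bay_stop_max_d = 17,
                         alt_stop_min_d = 2, alt_stop_max_d = 10,
                         residency_min_d = 1, residency_max_d = 8,
                         year = 2019,
                         station_density = c("default", "dense")) {
  station_density <- match.arg(station_density)
  if (p_detect < 0 || p_detect > 1) stop("p_detect must be in [0, 1]")
  if (false_positive_per_station_day < 0) {
    stop("false_positive_per_station_day must be >= 0")
  }
  structure(as.list(environment()), class = "rufa_scenario")
}

#' Synthetic receiver network
#'
#' @param density `"default"` or `"dense"`.
#' @param year simulation year (sets activity periods).
#' @return station data.frame.
#' @export
sim_stations <- function(density = "default", year = 2019) {
  base <- rbind(
    c("SC-COAST-1", 32.85, -79.75),
    c("SC-INLAND", 34.00, -81.00),
    c("NC-INLAND", 35.20, -80.85),
    c("NC-COAST", 34.20, -77.90),
    c("VA-COAST", 37.10, -75.90),
    c("DE-BAY-1", 39.10, -75.40),
    c("DE-BAY-2", 39.20, -75.10),
    c("DE-BAY-3", 38.90, -75.20),
    c("NJ-COAST", 40.00, -74.10),
    c("NY-BAY", 40.55, -73.95),
    c("MA-CAPE", 41.70, -70.10),
    c("ON-ERIE", 42.20, -80.10),
    c("ON-SIMCOE", 44.40, -79.40),
    c("ON-NORTH", 46.30, -79.50),
    c("JAMES-BAY", 52.20, -80.60),
    c("HUDSON-BAY", 55.20, -82.30)
  )
  if (density == "dense") {
    base <- rbind(base,
      c("SC-COAST-2", 33.00, -79.40),
      c("SC-INLAND-2", 33.60, -80.50),
      c("NC-COAST-2", 35.90, -75.60),
      c("DE-BAY-4", 39.40, -75.30),
      c("PA-INLAND", 40.50, -77.00),
      c("NY-INLAND", 42.50, -76.50),
      c("QC-NORTH", 48.50, -79.00)
    )
  }
  data.frame(
    station_id = base[, 1],
    lat = as.numeric(base[, 2]),
    lon = as.numeric(base[, 3]),
    active_from = parse_utc(rep(sprintf("%d-03-01T00:00:00Z", year),
                                nrow(base))),
    active_to = parse_utc(rep("", nrow(base))),
    stringsAsFactors = FALSE
  )
}

#' Synthetic analysis regions
#'
#' Rectangular stand-ins for the Delaware Bay watershed, the Great Lakes
#' Basin, the inland Carolinas, the capture zone, plus a thin
#' Atlantic-coastline strip used for the inland-route test.
#'
#' @return region list.
#' @export
sim_regions <- function() {
  box <- function(lat0, lat1, lon0, lon1) {
    list(cbind(c(lon0, lon1, lon1, lon0, lon0),
               c(lat0, lat0, lat1, lat1, lat0)))
  }
  coast_path <- cbind(
    c(-80.50, -79.30, -77.90, -75.50, -75.90, -74.90, -74.00, -72.00,
      -70.30, -68.50, -67.00),
    c(32.00, 33.00, 33.90, 35.20, 36.90, 38.90, 40.50, 41.00, 41.70,
      43.50, 44.50)
  )
  coast_ring <- rbind(coast_path,
                      cbind(rev(coast_path[, 1]) + 0.02,
                            rev(coast_path[, 2])),
                      coast_path[1, , drop = FALSE])
  list(
    region("Delaware Bay watershed (synthetic)", "delaware_bay",
           box(38.80, 39.70, -75.60, -74.80)),
    region("Great Lakes Basin (synthetic)", "great_lakes",
           box(41.30, 47.00, -84.50, -76.50)),
    region("Inland Carolinas (synthetic)", "inland_carolinas",
           box(33.50, 36.60, -83.50, -79.60)),
    region("Capture zone (synthetic)", "capture_zone",
           box(32.20, 32.90, -80.60, -79.80)),
    region("Atlantic coastline (synthetic)", "atlantic_coast",
           list(coast_ring))
  )
}

#' Simulate a 6-hourly gridded wind field
#'
#' Mean flow plus smooth correlated perturbations built from a few
#' low-order spatial harmonics with random phases drifting in time;
#' node-wise wind speed is capped at `max_ms`.
#'
#' @param times POSIXct time axis (6-hourly in normal use).
#' @param lats,lons increasing grid axes (degrees).
#' @param mean_u,mean_v mean flow components (m/s).
#' @param perturb_ms perturbation amplitude (m/s); 0 gives a constant
#'   field.
#' @param max_ms wind-speed bound.
#' @param seed integer seed.
#' @return a `rufa_wind` object.
#' @export
simulate_wind <- function(times, lats, lons, mean_u = 2, mean_v = 4,
                          perturb_ms = 3, max_ms = 25, seed = 1) {
  set.seed(seed %% .Machine$integer.max)
  nt <- length(times); ny <- length(lats); nx <- length(lons)
  latn <- (lats - min(lats)) / max(1e-9, diff(range(lats)))
  lonn <- (lons - min(lons)) / max(1e-9, diff(range(lons)))
  u <- array(mean_u, c(nt, ny, nx))
  v <- array(mean_v, c(nt, ny, nx))
  if (perturb_ms > 0) {
    n_harm <- 3
    for (comp in c("u", "v")) {
      acc <- array(0, c(nt, ny, nx))
      for (k in seq_len(n_harm)) {
        ph <- stats::runif(1, 0, 2 * pi)
        om <- stats::runif(1, 0.2, 1.0)      # cycles over the whole window
        ky <- sample.int(3, 1); kx <- sample.int(3, 1)
        spat <- outer(latn * ky, lonn * kx, `+`)
        for (t in seq_len(nt)) {
          acc[t, , ] <- acc[t, , ] +
            sin(2 * pi * spat + ph + 2 * pi * om * (t - 1) / max(1, nt - 1)) / k
        }
      }
      amp <- perturb_ms / 1.2  # harmonic sum has ~unit rms
      if (comp == "u") u <- u + amp * acc else v <- v + amp * acc
    }
    spd <- sqrt(u^2 + v^2)
    f <- pmin(1, max_ms / pmax(spd, 1e-12))
    u <- u * f; v <- v * f
  }
  wind_field(times, lats, lons, u, v)
}

#' Simulate a complete synthetic study
#'
#' Generates stations, deployments, regions, wind, detection records and
#' a ground-truth record for every bird. Birds move along piecewise
#' great-circle routes between stations at constant per-segment speed;
#' each station pass emits a short burst-interval-periodic detection bout
#' with probability `p_detect`; stopovers emit repeated bouts across
#' their span; false positives are injected per station-day with real
#' tag ids, random times and non-periodic structure.
#'
#' @param scenario a [sim_scenario()] list.
#' @return list of class `rufa_sim` with elements `stations`,
#'   `deployments`, `detections` (includes a logical `is_true` column),
#'   `regions`, `wind`, `truth` (per-bird list) and `scenario`.
#' @export
simulate_scenario <- function(scenario = sim_scenario()) {
  sc <- scenario
  stations <- sim_stations(sc$station_density, sc$year)
  regions <- sim_regions()
  capture <- c(lat = 32.54, lon = -80.18)
  t0 <- parse_utc(sprintf("%d-04-15T00:00:00Z", sc$year))
  t1 <- parse_utc(sprintf("%d-06-15T00:00:00Z", sc$year))
  wind_times <- seq(t0, t1, by = 6 * 3600)
  wind <- simulate_wind(wind_times,
                        lats = seq(24, 58, by = 2),
                        lons = seq(-96, -58, by = 2),
                        mean_u = sc$mean_u_ms, mean_v = sc$mean_v_ms,
                        perturb_ms = sc$wind_perturb_ms,
                        max_ms = sc$wind_max_ms,
                        seed = sc$seed + 513)

  strategies <- rep(c("stopped", "skipped", "atlantic"),
                    c(sc$n_stopped, sc$n_skipped, sc$n_atlantic))
  n_birds <- length(strategies)
  set.seed(sc$seed %% .Machine$integer.max)
  bird_seeds <- sample.int(.Machine$integer.max - 1, max(1, n_birds))
  deploy_days <- if (n_birds) sample(0:15, n_birds, replace = TRUE) else integer(0)
  bis <- if (n_birds) round(stats::runif(n_birds, 4.7, 11.3), 1) else numeric(0)
  mass <- numeric(n_birds)

  deployments <- data.frame(
    tag_id = sprintf("RUFA-%03d", seq_len(n_birds)),
    burst_interval_s = bis,
    nominal_freq_mhz = rep(166.38, n_birds),
    deploy_time = parse_utc(sprintf("%d-04-20T12:00:00Z", sc$year)) +
      deploy_days * 86400,
    deploy_lat = rep(capture["lat"], n_birds),
    deploy_lon = rep(capture["lon"], n_birds),
    body_mass_g = rep(NA_real_, n_birds),
    age_class = rep("adult", n_birds),
    site = rep("Deveaux Bank (synthetic)", n_birds),
    stringsAsFactors = FALSE
  )

  det_rows <- list()
  truth <- vector("list", n_birds)
  sta_idx <- function(id) match(id, stations$station_id)

  for (b in seq_len(n_birds)) {
    set.seed(bird_seeds[b])
    strat <- strategies[b]
    mass[b] <- round(stats::rnorm(1,
      mean = if (strat == "stopped") 131 else 140, sd = 13), 1)
    mass[b] <- max(mass[b], 95)
    airspeed <- stats::rnorm(1, sc$airspeed_mean_ms, sc$airspeed_sd_ms)
    residency <- stats::runif(1, sc$residency_min_d, sc$residency_max_d)
    dep_date <- utc_date(deployments$deploy_time[b]) + floor(residency)
    depart <- parse_utc(format(dep_date)) +
      round(stats::runif(1, 10, 16) * 3600)
    route <- switch(strat,
      stopped = {
        bay_station <- sample(c("DE-BAY-1", "DE-BAY-2", "DE-BAY-3"), 1)
        list(
          list(id = "SC-COAST-1", stop_d = 0),
          list(id = "NC-COAST", stop_d = 0),
          list(id = "VA-COAST", stop_d = 0),
          list(id = bay_station,
               stop_d = stats::runif(1, sc$bay_stop_min_d, sc$bay_stop_max_d),
               alt_station = if (stats::runif(1) < 0.3 &&
                                   bay_station != "DE-BAY-3") {
                 setdiff(c("DE-BAY-1", "DE-BAY-2"), bay_station)[1]
               } else NULL,
               region = "delaware_bay"),
          list(id = "NJ-COAST", stop_d = 0),
          list(id = "MA-CAPE", stop_d = 0)
        )
      },
      skipped = list(
        list(id = "SC-INLAND", stop_d = 0),
        list(id = "NC-INLAND", stop_d = 0),
        list(id = "ON-ERIE", stop_d = 0),
        list(id = "ON-SIMCOE", stop_d = 0),
        list(id = "ON-NORTH", stop_d = 0),
        list(id = "JAMES-BAY", stop_d = 0)
      ),
      atlantic = list(
        list(id = "SC-COAST-1", stop_d = 0),
        list(id = "NC-COAST", stop_d = 0),
        list(id = "VA-COAST", stop_d = 0),
        list(id = "NY-BAY",
             stop_d = stats::runif(1, sc$alt_stop_min_d, sc$alt_stop_max_d),
             region = "new_york_bay"),
        list(id = "MA-CAPE", stop_d = 0),
        list(id = "JAMES-BAY", stop_d = 0)
      )
    )

    tag <- deployments$tag_id[b]
    bi <- deployments$burst_interval_s[b]
    now <- as.numeric(depart)
    pos <- c(capture["lat"], capture["lon"])
    stopovers <- list()
    segments <- list()
    emit <- function(t_start, station_id, n_bursts) {
      tt <- t_start + (seq_len(n_bursts) - 1) * bi +
        stats::runif(n_bursts, -0.02, 0.02)
      det_rows[[length(det_rows) + 1]] <<- data.frame(
        tag_id = tag, station_id = station_id,
        time = as_utc(as.POSIXct(tt, origin = "1970-01-01", tz = "UTC")),
        n_pulses = 3L,
        freq_offset_khz = round(stats::rnorm(n_bursts, 0, 0.4), 3),
        signal = round(-60 + stats::rnorm(n_bursts, 0, 5), 1),
        is_true = TRUE, stringsAsFactors = FALSE
      )
    }

    for (wp in route) {
      i <- sta_idx(wp$id)
      d_km <- gc_distance(pos[1], pos[2], stations$lat[i], stations$lon[i])
      brg <- initial_bearing(pos[1], pos[2], stations$lat[i], stations$lon[i])
      uv <- sample_wind(wind,
                        as.POSIXct(now, origin = "1970-01-01", tz = "UTC"),
                        pos[1], pos[2])
      tw <- tailwind_support(uv["u"], uv["v"], brg)
      spd <- max(5, airspeed + sc$wind_coupling * tw +
                   stats::rnorm(1, 0, sc$speed_noise_sd_ms))
      arr <- now + d_km * 1000 / spd
      segments[[length(segments) + 1]] <- data.frame(
        from_lat = pos[1], from_lon = pos[2], to_station = wp$id,
        start = format_utc(as.POSIXct(now, origin = "1970-01-01",
                                      tz = "UTC")),
        end = format_utc(as.POSIXct(arr, origin = "1970-01-01",
                                    tz = "UTC")),
        ground_speed_ms = spd, tailwind_ms = unname(tw),
        stringsAsFactors = FALSE
      )
      now <- arr
      pos <- c(stations$lat[i], stations$lon[i])
      if (wp$stop_d > 0) {
        stop_end <- now + wp$stop_d * 86400
        t <- now
        alt <- wp$alt_station
        k <- 0
        while (t < stop_end) {
          st_id <- if (!is.null(alt) && k %% 2 == 1) alt else wp$id
          if (stats::runif(1) < sc$p_detect) {
            emit(t, st_id, 4 + stats::rpois(1, 3))
          }
          t <- t + stats::runif(1, 1, 4) * 3600
          k <- k + 1
        }
        stopovers[[length(stopovers) + 1]] <- list(
          region = wp$region %||% "other", station = wp$id,
          start = format_utc(as.POSIXct(now, origin = "1970-01-01",
                                        tz = "UTC")),
          end = format_utc(as.POSIXct(stop_end, origin = "1970-01-01",
                                      tz = "UTC")))
        now <- stop_end
      } else {
        if (stats::runif(1) < sc$p_detect) {
          emit(now, wp$id, 4 + stats::rpois(1, 3))
        }
      }
    }

    truth[[b]] <- list(
      tag_id = tag, true_strategy = strat,
      pooled_strategy = if (strat == "stopped") "stopped" else "skipped",
      true_departure_date = format(utc_date(depart)),
      stopovers = stopovers,
      segments = do.call(rbind, segments)
    )
  }
  deployments$body_mass_g <- mass

  # false positives: real tag ids, random times, non-periodic
  if (sc$false_positive_per_station_day > 0 && n_birds > 0) {
    set.seed((sc$seed + 777) %% .Machine$integer.max)
    n_days <- as.numeric(difftime(t1, t0, units = "days"))
    for (s in seq_len(nrow(stations))) {
      n_fp <- stats::rpois(1, sc$false_positive_per_station_day * n_days)
      if (!n_fp) next
      tt <- as.numeric(t0) + sort(stats::runif(n_fp, 0, n_days * 86400))
      det_rows[[length(det_rows) + 1]] <- data.frame(
        tag_id = sample(deployments$tag_id, n_fp, replace = TRUE),
        station_id = stations$station_id[s],
        time = as_utc(as.POSIXct(tt, origin = "1970-01-01", tz = "UTC")),
        n_pulses = sample(1:3, n_fp, replace = TRUE,
                          prob = c(0.4, 0.3, 0.3)),
        freq_offset_khz = round(stats::rnorm(n_fp, 0, 4), 3),
        signal = round(-75 + stats::rnorm(n_fp, 0, 8), 1),
        is_true = FALSE, stringsAsFactors = FALSE
      )
    }
  }

  detections <- if (length(det_rows)) do.call(rbind, det_rows) else
    data.frame(tag_id = character(0), station_id = character(0),
               time = parse_utc(character(0)), n_pulses = integer(0),
               freq_offset_khz = numeric(0), signal = numeric(0),
               is_true = logical(0), stringsAsFactors = FALSE)
  detections <- detections[order(detections$tag_id, detections$time,
                                 detections$station_id), , drop = FALSE]
  rownames(detections) <- NULL

  structure(list(stations = stations, deployments = deployments,
                 detections = detections, regions = regions, wind = wind,
                 truth = truth, scenario = sc),
            class = "rufa_sim")
}

#' Write a simulated scenario to disk
#'
#' Emits `stations.csv`, `deployments.csv`, `detections.csv`,
#' `regions.geojson`, `wind.csv` (long format) and `truth.json` in the
#' exact input schemas expected by [load_dataset()].
#'
#' @param sim a `rufa_sim` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    stations = file.path(dir, "stations.csv"),
    deployments = file.path(dir, "deployments.csv"),
    detections = file.path(dir, "detections.csv"),
    regions = file.path(dir, "regions.geojson"),
    wind = file.path(dir, "wind.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_table_utc(sim$stations, paths["stations"])
  dep <- sim$deployments
  names(dep)[names(dep) == "deploy_time"] <- "deploy_time_utc"
  write_table_utc(dep, paths["deployments"])
  det <- sim$detections
  det <- det[, c("tag_id", "station_id", "time", "n_pulses",
                 "freq_offset_khz", "signal")]
  names(det)[names(det) == "time"] <- "time_utc"
  write_table_utc(det, paths["detections"])
  write_regions(sim$regions, paths["regions"])
  write_wind(sim$wind, paths["wind"])
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paths)
}

#' Write regions as GeoJSON
#'
#' @param regions region list.
#' @param path output path.
#' @export
write_regions <- function(regions, path) {
  features <- lapply(regions, function(r) {
    coords <- lapply(r$rings, function(ring) {
      lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
    })
    geom <- if (length(coords) == 1) {
      list(type = "Polygon", coordinates = coords)
    } else {
      list(type = "MultiPolygon",
           coordinates = lapply(coords, function(cc) list(cc)))
    }
    list(type = "Feature",
         properties = list(name = r$name, role = r$role),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
}
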