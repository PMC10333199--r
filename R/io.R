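#' Read a station table
#'
#' Expects columns `station_id, lat, lon, active_from, active_to`; activity
#' timestamps may be blank (open-ended). Longitudes are normalized to
#' `[-180, 180)`.
#'
#' @param path CSV file path.
#' @return data.frame with `station_id` (character), `lat`/`lon` (numeric)
#'   and `active_from`/`active_to` (POSIXct UTC, possibly `NA`).
#' @export
read_stations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  stopifnot_cols(df, c("station_id", "lat", "lon", "active_from", "active_to"),
                 "stations")
  data.frame(
    station_id = df$station_id,
    lat = as.numeric(df$lat),
    lon = normalize_lon(as.numeric(df$lon)),
    active_from = parse_utc(df$active_from),
    active_to = parse_utc(df$active_to),
    stringsAsFactors = FALSE
  )
}

#' Read a tag deployment table
#'
#' Expects columns `tag_id, burst_interval_s, nominal_freq_mhz,
#' deploy_time_utc, deploy_lat, deploy_lon, body_mass_g, age_class, site`.
#' Body mass may be blank; `age_class` must be one of
#' `adult`, `second_year`, `unknown` (blank maps to `unknown`).
#'
#' @param path CSV file path.
#' @return data.frame of deployments with POSIXct UTC deploy times.
#' @export
read_deployments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  stopifnot_cols(df, c("tag_id", "burst_interval_s", "nominal_freq_mhz",
                       "deploy_time_utc", "deploy_lat", "deploy_lon",
                       "body_mass_g", "age_class", "site"),
                 "deployments")
  age <- df$age_class
  age[!nzchar(trimws(age))] <- "unknown"
  bad_age <- !age %in% c("adult", "second_year", "unknown")
  if (any(bad_age)) {
    stop("deployments: invalid age_class value(s): ",
         paste(unique(age[bad_age]), collapse = ", "))
  }
  out <- data.frame(
    tag_id = df$tag_id,
    burst_interval_s = as.numeric(df$burst_interval_s),
    nominal_freq_mhz = as.numeric(df$nominal_freq_mhz),
    deploy_time = parse_utc(df$deploy_time_utc),
    deploy_lat = as.numeric(df$deploy_lat),
    deploy_lon = normalize_lon(as.numeric(df$deploy_lon)),
    body_mass_g = suppressWarnings(as.numeric(df$body_mass_g)),
    age_class = age,
    site = df$site,
    stringsAsFactors = FALSE
  )
  if (any(!is.na(out$burst_interval_s) & out$burst_interval_s <= 0)) {
    stop("deployments: burst_interval_s must be > 0")
  }
  if (any(!is.na(out$body_mass_g) & out$body_mass_g <= 0)) {
    stop("deployments: body_mass_g must be > 0 when present")
  }
  out
}

#' Read a detection table
#'
#' Expects columns `tag_id, station_id, time_utc, n_pulses,
#' freq_offset_khz, signal`; the last two may be blank.
#'
#' @param path CSV file path.
#' @return data.frame of detections sorted by `tag_id` then `time`.
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  stopifnot_cols(df, c("tag_id", "station_id", "time_utc", "n_pulses",
                       "freq_offset_khz", "signal"),
                 "detections")
  out <- data.frame(
    tag_id = df$tag_id,
    station_id = df$station_id,
    time = parse_utc(df$time_utc),
    n_pulses = as.integer(df$n_pulses),
    freq_offset_khz = suppressWarnings(as.numeric(df$freq_offset_khz)),
    signal = suppressWarnings(as.numeric(df$signal)),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$time))) {
    stop("detections: ", sum(is.na(out$time)),
         " row(s) with unparseable time_utc")
  }
  if (any(is.na(out$n_pulses) | out$n_pulses < 1)) {
    stop("detections: n_pulses must be >= 1 on every row")
  }
  out[order(out$tag_id, out$time), , drop = FALSE]
}

#' Read analysis regions from GeoJSON
#'
#' Reads a `FeatureCollection` of Polygon / MultiPolygon features carrying
#' `properties.name` and `properties.role`. Recognized roles are
#' `delaware_bay`, `great_lakes`, `inland_carolinas`, `capture_zone`,
#' `atlantic_coast` and `other`. Only exterior rings are used; holes are
#' not supported.
#'
#' @param path GeoJSON file path.
#' @return list of regions, each a list with `name`, `role` and `rings`
#'   (list of closed two-column lon/lat matrices).
#' @export
read_regions <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("regions: expected a GeoJSON FeatureCollection")
  }
  lapply(gj$features, function(f) {
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = list(ring_matrix(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates,
                            function(p) ring_matrix(p[[1]])),
      stop("regions: unsupported geometry type: ", geom$type)
    )
    region(name = f$properties$name %||% "",
           role = f$properties$role %||% "other",
           rings = rings)
  })
}

#' Construct a region
#'
#' @param name region name.
#' @param role one of the recognized region roles.
#' @param rings list of two-column (lon, lat) matrices; each ring is closed
#'   (first vertex repeated last) — it is closed automatically if not.
#' @return a region list as used by [region_membership()].
#' @export
region <- function(name, role, rings) {
  roles <- c("delaware_bay", "great_lakes", "inland_carolinas",
             "capture_zone", "atlantic_coast", "other")
  if (!role %in% roles) {
    stop("region role must be one of: ", paste(roles, collapse = ", "))
  }
  if (!length(rings)) stop("region needs at least one ring")
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2 || nrow(r) < 3) stop("region ring needs >= 3 vertices")
    r[, 1] <- normalize_lon(r[, 1])
    if (any(abs(r[, 2]) > 90)) stop("region ring latitude out of range")
    if (r[1, 1] != r[nrow(r), 1] || r[1, 2] != r[nrow(r), 2]) {
      r <- rbind(r, r[1, ])
    }
    unname(r)
  })
  list(name = name, role = role, rings = rings)
}

ring_matrix <- function(coords) {
  m <- t(vapply(coords, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]])),
                numeric(2)))
  m
}

#' Construct a gridded wind field
#'
#' @param times sorted POSIXct UTC time axis.
#' @param lats,lons strictly monotone grid axes in degrees.
#' @param u,v eastward / northward wind components (m/s), arrays of shape
#'   `[time, lat, lon]`.
#' @param pressure_level pressure level in hPa (near-surface by default).
#' @return an object of class `rufa_wind`.
#' @export
wind_field <- function(times, lats, lons, u, v, pressure_level = 1000) {
  times <- parse_utc(times)
  if (is.unsorted(times, strictly = TRUE)) stop("wind times must be strictly increasing")
  if (length(lats) > 1 && any(diff(lats) <= 0) && any(diff(lats) >= 0)) {
    stop("wind lat axis must be strictly monotone")
  }
  if (length(lons) > 1 && any(diff(lons) <= 0) && any(diff(lons) >= 0)) {
    stop("wind lon axis must be strictly monotone")
  }
  dims <- c(length(times), length(lats), length(lons))
  if (!identical(dim(u), as.integer(dims)) || !identical(dim(v), as.integer(dims))) {
    stop("wind u/v arrays must have shape [time, lat, lon]")
  }
  # store axes increasing so interpolation can assume sorted grids
  if (length(lats) > 1 && lats[1] > lats[2]) {
    lats <- rev(lats)
    u <- u[, rev(seq_along(lats)), , drop = FALSE]
    v <- v[, rev(seq_along(lats)), , drop = FALSE]
  }
  if (length(lons) > 1 && lons[1] > lons[2]) {
    lons <- rev(lons)
    u <- u[, , rev(seq_along(lons)), drop = FALSE]
    v <- v[, , rev(seq_along(lons)), drop = FALSE]
  }
  structure(list(times = times, lats = as.numeric(lats),
                 lons = normalize_lon(as.numeric(lons)),
                 u = u, v = v, pressure_level = pressure_level),
            class = "rufa_wind")
}

#' @export
print.rufa_wind <- function(x, ...) {
  cat(sprintf("rufa_wind: %d times x %d lats x %d lons at %g hPa\n",
              length(x$times), length(x$lats), length(x$lons),
              x$pressure_level))
  cat(sprintf("  time  %s .. %s\n", format_utc(x$times[1]),
              format_utc(x$times[length(x$times)])))
  cat(sprintf("  lat   %g .. %g   lon %g .. %g\n",
              min(x$lats), max(x$lats), min(x$lons), max(x$lons)))
  invisible(x)
}

#' Read a wind field from long-format CSV
#'
#' Long format has columns `time, lat, lon, u, v` with one row per grid
#' node per time step; the cross product of the unique axes must be fully
#' present.
#'
#' @param path CSV file path.
#' @param pressure_level pressure level to record (hPa).
#' @return a `rufa_wind` object.
#' @export
read_wind <- function(path, pressure_level = 1000) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("time", "lat", "lon", "u", "v"), "wind")
  times <- sort(unique(parse_utc(df$time)))
  lats <- sort(unique(as.numeric(df$lat)))
  lons <- sort(unique(as.numeric(df$lon)))
  dims <- c(length(times), length(lats), length(lons))
  if (nrow(df) != prod(dims)) {
    stop("wind: long CSV does not cover the full time x lat x lon grid")
  }
  ti <- match(as.numeric(parse_utc(df$time)), as.numeric(times))
  yi <- match(as.numeric(df$lat), lats)
  xi <- match(as.numeric(df$lon), lons)
  u <- array(NA_real_, dims); v <- array(NA_real_, dims)
  idx <- cbind(ti, yi, xi)
  u[idx] <- as.numeric(df$u)
  v[idx] <- as.numeric(df$v)
  wind_field(times, lats, lons, u, v, pressure_level)
}

#' Write a wind field to long-format CSV
#'
#' @param wind a `rufa_wind` object.
#' @param path output CSV path.
#' @export
write_wind <- function(wind, path) {
  grid <- expand.grid(lon = seq_along(wind$lons), lat = seq_along(wind$lats),
                      time = seq_along(wind$times))
  idx <- cbind(grid$time, grid$lat, grid$lon)
  df <- data.frame(
    time = format_utc(wind$times[grid$time]),
    lat = wind$lats[grid$lat],
    lon = wind$lons[grid$lon],
    u = wind$u[idx],
    v = wind$v[idx]
  )
  df <- df[order(df$time, df$lat, df$lon), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Load and cross-check a complete dataset
#'
#' Reads all inputs and enforces referential integrity: every detection's
#' station must exist in the station table and every detection's tag must
#' have a deployment record.
#'
#' @param detections,stations,deployments,regions paths to the respective
#'   files.
#' @param wind optional path to a long-format wind CSV.
#' @param config a [rufa_config()] list.
#' @return a list of class `rufa_dataset`.
#' @export
load_dataset <- function(detections, stations, deployments, regions,
                         wind = NULL, config = rufa_config()) {
  for (p in c(detections, stations, deployments, regions, wind)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  det <- read_detections(detections)
  sta <- read_stations(stations)
  dep <- read_deployments(deployments)
  reg <- read_regions(regions)
  wnd <- if (!is.null(wind)) read_wind(wind) else NULL
  orphan_sta <- setdiff(unique(det$station_id), sta$station_id)
  if (length(orphan_sta)) {
    stop("referential integrity: detections reference unknown station(s): ",
         paste(orphan_sta, collapse = ", "))
  }
  orphan_tag <- setdiff(unique(det$tag_id), dep$tag_id)
  if (length(orphan_tag)) {
    stop("referential integrity: detections reference undeployed tag(s): ",
         paste(orphan_tag, collapse = ", "))
  }
  structure(list(detections = det, stations = sta, deployments = dep,
                 regions = reg, wind = wnd, config = config),
            class = "rufa_dataset")
}

#' @export
print.rufa_dataset <- function(x, ...) {
  cat(sprintf("rufa_dataset: %d detections, %d tags, %d stations, %d regions%s\n",
              nrow(x$detections), nrow(x$deployments), nrow(x$stations),
              length(x$regions),
              if (is.null(x$wind)) "" else ", wind grid attached"))
  invisible(x)
}

#' Consistency checks on a loaded dataset
#'
#' Produces a report (not an error) flagging coordinates out of range,
#' detections before a tag's deployment, and detections outside a station's
#' activity period. Activity-period mismatches are warnings only; they are
#' never filtered automatically.
#'
#' @param dataset a `rufa_dataset`.
#' @return data.frame with columns `level` (`error`/`warning`), `code`,
#'   `message`, `ref`; zero rows when fully consistent.
#' @export
validate_dataset <- function(dataset) {
  out <- list()
  add <- function(level, code, message, ref) {
    out[[length(out) + 1]] <<- data.frame(level = level, code = code,
                                          message = message, ref = ref,
                                          stringsAsFactors = FALSE)
  }
  sta <- dataset$stations
  bad_lat <- which(abs(sta$lat) > 90)
  for (i in bad_lat) {
    add("error", "lat_out_of_range",
        sprintf("station %s latitude %g outside [-90, 90]",
                sta$station_id[i], sta$lat[i]),
        sta$station_id[i])
  }
  rev_act <- which(!is.na(sta$active_from) & !is.na(sta$active_to) &
                     sta$active_from > sta$active_to)
  for (i in rev_act) {
    add("error", "activity_reversed",
        sprintf("station %s active_from after active_to", sta$station_id[i]),
        sta$station_id[i])
  }
  det <- dataset$detections
  dep <- dataset$deployments
  dtime <- dep$deploy_time[match(det$tag_id, dep$tag_id)]
  pre <- which(!is.na(dtime) & det$time < dtime)
  for (i in pre) {
    add("warning", "pre_deployment_detection",
        sprintf("tag %s detected at %s before deployment (%s)",
                det$tag_id[i], format_utc(det$time[i]),
                format_utc(dtime[i])),
        sprintf("%s@%s", det$tag_id[i], format_utc(det$time[i])))
  }
  si <- match(det$station_id, sta$station_id)
  a0 <- sta$active_from[si]; a1 <- sta$active_to[si]
  off <- which((!is.na(a0) & det$time < a0) | (!is.na(a1) & det$time > a1))
  for (i in off) {
    add("warning", "outside_station_activity",
        sprintf("tag %s detected at station %s outside its activity period",
                det$tag_id[i], det$station_id[i]),
        sprintf("%s@%s", det$tag_id[i], det$station_id[i]))
  }
  if (!length(out)) {
    return(data.frame(level = character(0), code = character(0),
                      message = character(0), ref = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

# Deterministic CSV writer: POSIXct columns serialized as ISO-8601 UTC,
# NA as empty string, stable row order left to the caller.
write_table_utc <- function(df, path) {
  for (nm in names(df)) {
    if (inherits(df[[nm]], "POSIXct")) df[[nm]] <- format_utc(df[[nm]])
    if (inherits(df[[nm]], "Date")) {
      d <- format(df[[nm]], "%Y-%m-%d")
      d[is.na(df[[nm]])] <- ""
      df[[nm]] <- d
    }
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
}
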