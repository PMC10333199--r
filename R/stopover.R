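#' Detect stopovers from detection bouts
#'
#' A stopover is a detection span at migratory distance from the tagging
#' site: only bouts at stations more than
#' `stopover_min_dist_from_capture_km` (50 km) from the deployment
#' coordinates are considered. Two rules then apply to the time-ordered
#' bout sequence, both with strict time thresholds:
#'
#' * single station — a maximal run of bouts at one station with no
#'   intervening bout elsewhere, spanning more than
#'   `stopover_single_station_h` (4 h);
#' * station cluster — a maximal run of bouts whose stations are all
#'   within `stopover_station_cluster_km` (30 km) of each other
#'   (pairwise), spanning more than `stopover_multi_station_h` (6 h).
#'
#' Overlapping qualifying runs are merged, so each bout belongs to at most
#' one stopover. A span of exactly 4.0 h (or 6.0 h) is not a stopover.
#'
#' @param bouts bout data.frame for a single bird, time-sorted.
#' @param stations station table.
#' @param deployment single-row deployment data.frame (for the tagging
#'   location).
#' @param config a [rufa_config()] list.
#' @return data.frame with one row per stopover: `tag_id`, `stations`
#'   (comma-separated ids), `start`, `end`, `duration_h`,
#'   `centroid_lat`, `centroid_lon`.
#' @export
detect_stopovers <- function(bouts, stations, deployment,
                             config = rufa_config()) {
  stopifnot(nrow(deployment) == 1)
  empty <- data.frame(tag_id = character(0), stations = character(0),
                      start = parse_utc(character(0)),
                      end = parse_utc(character(0)),
                      duration_h = numeric(0), centroid_lat = numeric(0),
                      centroid_lon = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(bouts)) return(empty)
  bouts <- bouts[order(bouts$start), , drop = FALSE]
  si <- match(bouts$station_id, stations$station_id)
  if (anyNA(si)) stop("bout references unknown station")
  far <- gc_distance(deployment$deploy_lat, deployment$deploy_lon,
                     stations$lat[si], stations$lon[si]) >
    config$stopover_min_dist_from_capture_km
  bouts <- bouts[far, , drop = FALSE]; si <- si[far]
  n <- nrow(bouts)
  if (!n) return(empty)
  slat <- stations$lat[si]; slon <- stations$lon[si]

  span_h <- function(i, j) {
    as.numeric(difftime(max(bouts$end[i:j]), min(bouts$start[i:j]),
                        units = "hours"))
  }

  runs <- list()
  # single-station maximal runs
  same <- c(FALSE, bouts$station_id[-1] == bouts$station_id[-n])
  run_id <- cumsum(!same)
  for (idx in split(seq_len(n), run_id)) {
    i <- idx[1]; j <- idx[length(idx)]
    if (span_h(i, j) > config$stopover_single_station_h) {
      runs[[length(runs) + 1]] <- c(i, j)
    }
  }
  # multi-station cluster maximal runs: extend each start while all pairwise
  # station distances stay within the cluster radius
  if (n >= 2) {
    dmat <- outer(seq_len(n), seq_len(n),
                  function(a, b) gc_distance(slat[a], slon[a],
                                             slat[b], slon[b]))
    prev_j <- 0
    for (i in seq_len(n)) {
      j <- i
      while (j < n &&
             all(dmat[(i:j), j + 1] <= config$stopover_station_cluster_km)) {
        j <- j + 1
      }
      if (j > i && j > prev_j &&
          span_h(i, j) > config$stopover_multi_station_h) {
        runs[[length(runs) + 1]] <- c(i, j)
        prev_j <- j
      }
    }
  }
  if (!length(runs)) return(empty)
  # merge overlapping candidate runs
  covered <- rep(FALSE, n)
  for (r in runs) covered[r[1]:r[2]] <- TRUE
  grp <- cumsum(c(TRUE, diff(which(covered)) > 1))
  out <- lapply(split(which(covered), grp), function(idx) {
    st <- sort(unique(bouts$station_id[idx]))
    coord <- unique(cbind(slat[idx], slon[idx]))
    data.frame(
      tag_id = bouts$tag_id[idx[1]],
      stations = paste(st, collapse = ","),
      start = min(bouts$start[idx]),
      end = max(bouts$end[idx]),
      duration_h = as.numeric(difftime(max(bouts$end[idx]),
                                       min(bouts$start[idx]),
                                       units = "hours")),
      centroid_lat = mean(coord[, 1]),
      centroid_lon = mean(coord[, 2]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Delaware Bay stopover durations
#'
#' Duration of bay use per bird, measured as the time elapsed between the
#' first and last detection within the (buffered) Delaware Bay region, in
#' days. Birds with fewer than two bay detections are excluded.
#'
#' @param detections QC-passed detection data.frame (all birds).
#' @param stations station table.
#' @param regions region list containing a `delaware_bay` region.
#' @param config a [rufa_config()] list.
#' @return data.frame with `tag_id`, `first_bay`, `last_bay`,
#'   `duration_d`, `n_bay_detections`; one row per bird with two or more
#'   bay detections.
#' @export
delaware_stopover_durations <- function(detections, stations, regions,
                                        config = rufa_config()) {
  bay <- region_by_role(regions, "delaware_bay")
  if (is.null(bay)) stop("regions must include a delaware_bay region")
  si <- match(detections$station_id, stations$station_id)
  if (anyNA(si)) stop("detection references unknown station")
  u <- !duplicated(si)
  in_bay_u <- region_membership(stations$lat[si[u]], stations$lon[si[u]],
                                bay, buffer_km = config$bay_buffer_km)
  in_bay <- in_bay_u[match(si, si[u])]
  det <- detections[in_bay, , drop = FALSE]
  if (!nrow(det)) {
    return(data.frame(tag_id = character(0),
                      first_bay = parse_utc(character(0)),
                      last_bay = parse_utc(character(0)),
                      duration_d = numeric(0),
                      n_bay_detections = integer(0),
                      stringsAsFactors = FALSE))
  }
  by_tag <- split(seq_len(nrow(det)), det$tag_id)
  by_tag <- by_tag[vapply(by_tag, length, integer(1)) >= 2]
  out <- lapply(by_tag, function(idx) {
    data.frame(
      tag_id = det$tag_id[idx[1]],
      first_bay = min(det$time[idx]),
      last_bay = max(det$time[idx]),
      duration_d = as.numeric(difftime(max(det$time[idx]),
                                       min(det$time[idx]),
                                       units = "days")),
      n_bay_detections = length(idx),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(tag_id = character(0), first_bay = parse_utc(character(0)),
               last_bay = parse_utc(character(0)), duration_d = numeric(0),
               n_bay_detections = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$tag_id), , drop = FALSE]
}

#' Stopover heat-map grid
#'
#' Rasterized version of the buffered-station overlay: each grid cell
#' counts the number of distinct individuals with at least one stopover
#' station within `buffer_km` of the cell center. An individual counts at
#' most once per cell however many stopovers it had there.
#'
#' @param stopovers stopover data.frame (multiple birds; see
#'   [detect_stopovers()]).
#' @param stations station table (stopover station coordinates).
#' @param lat_range,lon_range numeric length-2 grid extents in degrees.
#' @param cell_deg cell size in degrees.
#' @param buffer_km buffer radius around stopover stations.
#' @return data.frame with `cell_lat`, `cell_lon` (cell centers) and
#'   `count`; zero-count cells included.
#' @export
stopover_heatmap <- function(stopovers, stations, lat_range, lon_range,
                             cell_deg = 0.25, buffer_km = 50) {
  if (diff(range(lat_range)) < cell_deg / 2 ||
      diff(range(lon_range)) < cell_deg / 2) {
    stop("degenerate heat-map grid")
  }
  lat_c <- seq(min(lat_range) + cell_deg / 2, max(lat_range), by = cell_deg)
  lon_c <- seq(min(lon_range) + cell_deg / 2, max(lon_range), by = cell_deg)
  grid <- expand.grid(cell_lat = lat_c, cell_lon = lon_c)
  grid$count <- 0L
  if (nrow(stopovers)) {
    pairs <- unique(do.call(rbind, lapply(seq_len(nrow(stopovers)),
      function(i) {
        data.frame(tag_id = stopovers$tag_id[i],
                   station_id = strsplit(stopovers$stations[i], ",")[[1]],
                   stringsAsFactors = FALSE)
      })))
    si <- match(pairs$station_id, stations$station_id)
    if (anyNA(si)) stop("stopover references unknown station")
    for (tag in unique(pairs$tag_id)) {
      rows <- which(pairs$tag_id == tag)
      hit <- rep(FALSE, nrow(grid))
      for (r in rows) {
        d <- gc_distance(grid$cell_lat, grid$cell_lon,
                         stations$lat[si[r]], stations$lon[si[r]])
        hit <- hit | d <= buffer_km
      }
      grid$count <- grid$count + as.integer(hit)
    }
  }
  grid
}

#' Write a heat-map grid as GeoJSON
#'
#' Each nonzero cell becomes a square polygon feature with a `count`
#' property.
#'
#' @param heatmap data.frame from [stopover_heatmap()].
#' @param cell_deg cell size used to build the grid.
#' @param path output GeoJSON path.
#' @export
write_heatmap_geojson <- function(heatmap, cell_deg, path) {
  nz <- heatmap[heatmap$count > 0, , drop = FALSE]
  h <- cell_deg / 2
  features <- lapply(seq_len(nrow(nz)), function(i) {
    la <- nz$cell_lat[i]; lo <- nz$cell_lon[i]
    ring <- list(c(lo - h, la - h), c(lo + h, la - h), c(lo + h, la + h),
                 c(lo - h, la + h), c(lo - h, la - h))
    list(type = "Feature",
         properties = list(count = nz$count[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
}
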