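#' Simple least-squares regression
#'
#' Closed-form ordinary least squares of `y` on `x` with the slope
#' t-statistic on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return list with `slope`, `intercept`, `t`, `df`, `p`, `r_squared`.
#' @export
simple_ols <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least three observations")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("x is constant; slope undefined")
  slope <- sum(xc * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  se <- sqrt(sse / (n - 2) / sxx)
  # degenerate exact fits: zero residual SE gives t = +/-Inf for a nonzero
  # slope; a constant response has slope 0 and explains nothing (R^2 = 0)
  tval <- if (se > 0) slope / se else if (slope == 0) 0 else
    sign(slope) * Inf
  list(slope = slope, intercept = intercept, t = tval, df = n - 2,
       p = 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE),
       r_squared = if (sst > 0) 1 - sse / sst else 0)
}

#' Run the full migration analysis pipeline
#'
#' Chains detection QC, bout construction, per-bird departure estimation,
#' Delaware Bay strategy classification, stopover detection, flight
#' extraction and (when a wind field is supplied) tailwind support, then
#' assembles the study summary.
#'
#' @param detections raw detection data.frame.
#' @param stations station table.
#' @param deployments deployment table.
#' @param regions region list (must include `delaware_bay`).
#' @param wind optional `rufa_wind` object.
#' @param config a [rufa_config()] list.
#' @return object of class `rufa_report`; see [build_report()].
#' @export
run_pipeline <- function(detections, stations, deployments, regions,
                         wind = NULL, config = rufa_config()) {
  qc <- filter_detections(detections, deployments, config)
  bouts <- bout_detections(qc$detections, config)

  departures <- list(); strategies <- list()
  stopovers <- list(); flights <- list()
  for (b in seq_len(nrow(deployments))) {
    dep <- deployments[b, , drop = FALSE]
    bb <- bouts[bouts$tag_id == dep$tag_id, , drop = FALSE]
    if (!nrow(bb)) next
    departures[[dep$tag_id]] <-
      estimate_departure(bb, dep, stations, regions, config)
    strategies[[dep$tag_id]] <-
      classify_delaware_strategy(bb, stations, dep, regions, config)
    so <- detect_stopovers(bb, stations, dep, config)
    if (nrow(so)) stopovers[[dep$tag_id]] <- so
    fl <- extract_flights(bb, stations, config)
    if (nrow(fl)) flights[[dep$tag_id]] <- fl
  }
  stopovers <- if (length(stopovers)) do.call(rbind, c(stopovers,
                                                       make.row.names = FALSE))
    else detect_stopovers(bouts[0, ], stations, deployments[1, , drop = FALSE],
                          config)
  flights <- if (length(flights)) do.call(rbind, c(flights,
                                                   make.row.names = FALSE))
    else extract_flights(bouts[0, ], stations, config)
  if (!is.null(wind) && nrow(flights)) {
    flights <- flight_wind_support(flights, wind)
  }
  durations <- delaware_stopover_durations(qc$detections, stations,
                                           regions, config)
  build_report(qc = qc, bouts = bouts, departures = departures,
               strategies = strategies, stopovers = stopovers,
               flights = flights, delaware_durations = durations,
               stations = stations, deployments = deployments,
               config = config)
}

#' Assemble the study report
#'
#' Aggregates upstream module outputs into one deterministic summary:
#' the uncertainty-weighted departure timeline with its weighted median,
#' strategy counts and pooled proportions, body-mass ANOVA, Delaware Bay
#' stopover duration statistics and the duration-versus-arrival
#' regression, flight length/speed statistics, the ground-speed /
#' tailwind correlation, and the stopover heat map. Sections whose inputs
#' are too small are marked `"insufficient data"` rather than failing.
#'
#' @param qc output of [filter_detections()].
#' @param bouts output of [bout_detections()].
#' @param departures named list of `rufa_departure` (or `NULL`) per bird.
#' @param strategies named list of `rufa_strategy` per bird.
#' @param stopovers stopover data.frame (all birds).
#' @param flights flight data.frame, with wind columns when available.
#' @param delaware_durations output of [delaware_stopover_durations()].
#' @param stations station table.
#' @param deployments deployment table (for body mass).
#' @param config a [rufa_config()] list.
#' @return list of class `rufa_report`.
#' @export
build_report <- function(qc, bouts, departures, strategies, stopovers,
                         flights, delaware_durations, stations,
                         deployments = NULL, config = rufa_config()) {
  for (arg in c("qc", "bouts", "departures", "strategies", "stopovers",
                "flights", "delaware_durations")) {
    if (is.null(get(arg))) stop("missing upstream stage: ", arg)
  }
  est <- Filter(Negate(is.null), departures)
  dep_section <- if (length(est)) {
    tl <- departure_timeline(est)
    list(timeline = tl, weighted_median = weighted_median_date(tl),
         n_known = sum(vapply(est, `[[`, character(1), "kind") == "known"),
         n_window = sum(vapply(est, `[[`, character(1), "kind") == "window"),
         n_birds = length(est))
  } else "insufficient data"

  strat_df <- data.frame(
    tag_id = vapply(strategies, `[[`, character(1), "tag_id"),
    strategy = vapply(strategies, `[[`, character(1), "strategy"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  strat_section <- if (nrow(strat_df)) summarize_strategies(strat_df)
    else "insufficient data"

  dd <- delaware_durations
  dur_section <- if (nrow(dd) >= 1) {
    ols <- if (nrow(dd) >= 3) {
      x <- as.numeric(dd$first_bay) / 86400
      tryCatch(simple_ols(x, dd$duration_d), error = function(e) NULL)
    } else NULL
    list(n = nrow(dd), mean_d = mean(dd$duration_d),
         sd_d = stats::sd(dd$duration_d),
         median_d = stats::median(dd$duration_d),
         range_d = range(dd$duration_d),
         duration_vs_arrival = ols %||% "insufficient data")
  } else "insufficient data"

  flight_section <- if (nrow(flights)) {
    assoc <- if ("tailwind_ms" %in% names(flights) &&
                 sum(is.finite(flights$tailwind_ms)) >= 3) {
      speed_wind_association(flights$net_ground_speed_ms,
                             flights$tailwind_ms)
    } else "insufficient data"
    list(n_flights = nrow(flights),
         n_birds = length(unique(flights$tag_id)),
         median_total_km = stats::median(flights$total_length_km),
         range_total_km = range(flights$total_length_km),
         median_displacement_km = stats::median(flights$displacement_km),
         range_displacement_km = range(flights$displacement_km),
         mean_speed_ms = mean(flights$net_ground_speed_ms),
         speed_wind = assoc)
  } else "insufficient data"

  mass_section <- if (is.null(deployments)) "insufficient data" else
    tryCatch(mass_by_strategy(deployments, strat_df),
             error = function(e) "insufficient data")

  heat <- if (nrow(stopovers)) {
    st_ids <- unique(unlist(strsplit(stopovers$stations, ",")))
    si <- match(st_ids, stations$station_id)
    stopover_heatmap(stopovers, stations,
                     lat_range = range(stations$lat[si]) + c(-1, 1),
                     lon_range = range(stations$lon[si]) + c(-1, 1),
                     cell_deg = config$heatmap_cell_deg,
                     buffer_km = config$heatmap_buffer_km)
  } else "insufficient data"

  structure(list(
    qc = qc$report, bouts = bouts,
    departures = departures, departure_summary = dep_section,
    strategies = strat_df, strategy_summary = strat_section,
    mass_anova = mass_section,
    stopovers = stopovers, delaware_durations = dd,
    stopover_duration_summary = dur_section,
    flights = flights, flight_summary = flight_section,
    heatmap = heat, config = config
  ), class = "rufa_report")
}

#' @export
print.rufa_report <- function(x, ...) {
  cat("rufatrack study report\n")
  cat(sprintf("  QC: %d detections in, %d valid (%s)\n",
              x$qc$n_input, x$qc$n_valid,
              paste(sprintf("%s %d", names(x$qc$n_rejected_by_rule),
                            x$qc$n_rejected_by_rule), collapse = ", ")))
  if (is.list(x$departure_summary)) {
    ds <- x$departure_summary
    cat(sprintf("  departures: %d birds (%d known, %d window); weighted median %s\n",
                ds$n_birds, ds$n_known, ds$n_window,
                format(ds$weighted_median)))
  }
  if (is.list(x$strategy_summary)) {
    ss <- x$strategy_summary
    cat(sprintf("  strategy: %s; skipped-pooled %.0f%% of %d classifiable\n",
                paste(sprintf("%s %d", names(ss$counts), ss$counts),
                      collapse = ", "),
                100 * ss$prop_skipped_pooled, ss$n_classifiable))
  }
  if (is.list(x$stopover_duration_summary)) {
    d <- x$stopover_duration_summary
    cat(sprintf("  Delaware Bay duration: %.1f +/- %.1f d (median %.1f, range %.1f-%.1f, n = %d)\n",
                d$mean_d, d$sd_d, d$median_d, d$range_d[1], d$range_d[2],
                d$n))
  }
  if (is.list(x$flight_summary)) {
    f <- x$flight_summary
    cat(sprintf("  flights: %d (%d birds); median displacement %.0f km; mean speed %.1f m/s\n",
                f$n_flights, f$n_birds, f$median_displacement_km,
                f$mean_speed_ms))
    if (is.list(f$speed_wind)) {
      cat(sprintf("  speed~tailwind: r = %.2f (P = %.3g, n = %d); tailwind departures %.0f%%\n",
                  f$speed_wind$r, f$speed_wind$p, f$speed_wind$n,
                  100 * f$speed_wind$tailwind_fraction))
    }
  }
  invisible(x)
}

#' Write report tables to disk
#'
#' Writes the per-figure tables (`departures.csv`, `timeline.csv`,
#' `strategies.csv`, `stopovers.csv`, `delaware_durations.csv`,
#' `flights.csv`), the heat map (`heatmap.geojson`) and a JSON summary
#' (`summary.json`). Output is deterministic: identical reports produce
#' identical bytes, with rows ordered by tag then time.
#'
#' @param report a `rufa_report`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_results <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  est <- Filter(Negate(is.null), report$departures)
  dep_df <- if (length(est)) {
    do.call(rbind, lapply(est, function(e) data.frame(
      tag_id = e$tag_id, kind = e$kind,
      window_start = format(e$window_start),
      window_end = format(e$window_end), stringsAsFactors = FALSE)))
  } else {
    data.frame(tag_id = character(0), kind = character(0),
               window_start = character(0), window_end = character(0))
  }
  dep_df <- dep_df[order(dep_df$tag_id), , drop = FALSE]
  write_table_utc(dep_df, file.path(out_dir, "departures.csv"))

  tl <- if (is.list(report$departure_summary))
    report$departure_summary$timeline
    else data.frame(date = as.Date(character(0)), weight = numeric(0))
  write_table_utc(tl, file.path(out_dir, "timeline.csv"))

  sdf <- report$strategies[order(report$strategies$tag_id), , drop = FALSE]
  write_table_utc(sdf, file.path(out_dir, "strategies.csv"))
  so <- report$stopovers[order(report$stopovers$tag_id,
                               report$stopovers$start), , drop = FALSE]
  write_table_utc(so, file.path(out_dir, "stopovers.csv"))
  write_table_utc(report$delaware_durations,
                  file.path(out_dir, "delaware_durations.csv"))
  fl <- report$flights[order(report$flights$tag_id,
                             report$flights$depart_time), , drop = FALSE]
  write_table_utc(fl, file.path(out_dir, "flights.csv"))
  if (is.data.frame(report$heatmap)) {
    write_heatmap_geojson(report$heatmap, report$config$heatmap_cell_deg,
                          file.path(out_dir, "heatmap.geojson"))
  }
  summary <- list(
    qc = report$qc,
    departure = summarize_for_json(report$departure_summary),
    strategy = report$strategy_summary,
    mass_anova = summarize_for_json(report$mass_anova),
    stopover_duration = summarize_for_json(report$stopover_duration_summary),
    flights = summarize_for_json(report$flight_summary)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", Date = "ISO8601")
  invisible(list.files(out_dir, full.names = TRUE))
}

summarize_for_json <- function(x) {
  if (!is.list(x)) return(x)
  x[["timeline"]] <- NULL
  lapply(x, function(el) {
    if (inherits(el, "Date")) format(el) else
      if (is.table(el) || (is.numeric(el) && !is.null(names(el))))
        as.list(stats::setNames(as.numeric(el), names(el))) else el
  })
}
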