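#' Estimate a bird's departure date from the capture region
#'
#' Departure is resolved at one-day resolution. When the bird's first
#' detection away from the capture site (a station more than
#' `stopover_min_dist_from_capture_km` from the tagging location) comes
#' from a station inside the inland Carolinas region, that date is taken
#' as a known migration-initiation date with weight 1. Otherwise the bird
#' receives an inclusive day window from the deployment date to the date
#' of first detection away from the capture site, with uniform per-day
#' weights `1/n` over the `n` days of the window (a 5-day window
#' contributes 0.2 to each of its days). Both endpoints count as candidate
#' departure days.
#'
#' @param bouts bout data.frame for a single bird, time-sorted.
#' @param deployment single-row deployment data.frame for the bird.
#' @param stations station table.
#' @param regions region list containing an `inland_carolinas` region
#'   (optional; without it no departure can be scored "known").
#' @param config a [rufa_config()] list.
#' @return an object of class `rufa_departure` (fields `tag_id`, `kind`
#'   (`"known"` or `"window"`), `known_date`, `window_start`,
#'   `window_end`, `weights`), or `NULL` when the bird was never detected
#'   away from the capture site.
#' @export
estimate_departure <- function(bouts, deployment, stations, regions,
                               config = rufa_config()) {
  stopifnot(nrow(deployment) == 1)
  if (nrow(bouts) && is.unsorted(as.numeric(bouts$start))) {
    stop("bouts must be sorted by start time")
  }
  if (!nrow(bouts)) return(NULL)
  si <- match(bouts$station_id, stations$station_id)
  if (anyNA(si)) stop("bout references unknown station")
  post <- bouts$end >= deployment$deploy_time
  bouts <- bouts[post, , drop = FALSE]; si <- si[post]
  if (!nrow(bouts)) return(NULL)
  d_km <- gc_distance(deployment$deploy_lat, deployment$deploy_lon,
                      stations$lat[si], stations$lon[si])
  away <- d_km > config$stopover_min_dist_from_capture_km
  if (!any(away)) return(NULL)
  first_away <- which(away)[1]
  away_date <- utc_date(bouts$start[first_away])
  inland <- region_by_role(regions, "inland_carolinas")
  is_inland <- !is.null(inland) &&
    region_membership(stations$lat[si[first_away]],
                      stations$lon[si[first_away]], inland)
  if (is_inland) {
    est <- list(tag_id = deployment$tag_id, kind = "known",
                known_date = away_date,
                window_start = away_date, window_end = away_date,
                weights = stats::setNames(1, format(away_date)))
  } else {
    w0 <- utc_date(deployment$deploy_time)
    w1 <- away_date
    if (w1 < w0) stop("first away detection precedes deployment date")
    days <- seq(w0, w1, by = "day")
    est <- list(tag_id = deployment$tag_id, kind = "window",
                known_date = as.Date(NA),
                window_start = w0, window_end = w1,
                weights = stats::setNames(rep(1 / length(days),
                                              length(days)),
                                          format(days)))
  }
  structure(est, class = "rufa_departure")
}

#' @export
print.rufa_departure <- function(x, ...) {
  if (x$kind == "known") {
    cat(sprintf("tag %s: known departure %s\n", x$tag_id,
                format(x$known_date)))
  } else {
    cat(sprintf("tag %s: departure window %s .. %s (%d days, weight %.4g/day)\n",
                x$tag_id, format(x$window_start), format(x$window_end),
                length(x$weights), x$weights[[1]]))
  }
  invisible(x)
}

#' Uncertainty-weighted departure timeline
#'
#' Sums per-day departure weights across birds. Each bird contributes
#' total mass 1 (a known date contributes 1 to that day; an n-day window
#' contributes 1/n to each day), so the timeline's total mass equals the
#' number of contributing birds.
#'
#' @param estimates list of `rufa_departure` objects (`NULL` entries are
#'   dropped).
#' @return data.frame with `date` and `weight`, covering every day from
#'   the earliest to the latest candidate day (zero-filled in gaps).
#' @export
departure_timeline <- function(estimates) {
  estimates <- Filter(Negate(is.null), estimates)
  if (!length(estimates)) stop("no departure estimates supplied")
  wl <- lapply(estimates, `[[`, "weights")
  dates <- as.Date(unlist(lapply(wl, names), use.names = FALSE))
  vals <- unlist(wl, use.names = FALSE)
  days <- seq(min(dates), max(dates), by = "day")
  w <- vapply(split(vals, match(dates, days)), sum, numeric(1))
  weight <- numeric(length(days))
  weight[as.integer(names(w))] <- w
  data.frame(date = days, weight = weight)
}

#' Weighted median date of a departure timeline
#'
#' The smallest date at which the cumulative normalized timeline mass
#' reaches one half.
#'
#' @param timeline data.frame from [departure_timeline()].
#' @return a `Date`.
#' @export
weighted_median_date <- function(timeline) {
  total <- sum(timeline$weight)
  if (total <= 0) stop("timeline has no mass")
  cum <- cumsum(timeline$weight) / total
  timeline$date[which(cum >= 0.5 - 1e-12)[1]]
}
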