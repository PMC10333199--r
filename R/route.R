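#' Classify a bird's use of Delaware Bay
#'
#' Scores one bird on the stopped / skipped spectrum from its
#' quality-controlled detection bouts, using a fixed decision tree
#' evaluated in order:
#'
#' 1. **stopped** — at least two bay bouts (stations within
#'    `bay_buffer_km` of the Delaware Bay watershed) whose detections span
#'    more than `min_stop_days`.
#' 2. **likely_stopped** — at least two bouts in the annulus within
#'    `likely_buffer_km` beyond the bay buffer, touching two or more
#'    calendar days (repeated presence just outside the watershed).
#' 3. **skipped** — the bird was detected north of the bay and the time
#'    between its last detection at or below the bay's latitude and its
#'    first detection above left less than `min_stop_days` of slack beyond
#'    a direct great-circle flight at `assumed_transit_speed_ms`, with any
#'    bay detections being brief fly-throughs.
#' 4. **likely_skipped** — northern detection with slack of at least
#'    `min_stop_days`, but every intermediate detection was inland
#'    (inside the Great Lakes Basin or more than `inland_offset_km` from
#'    the Atlantic coastline), inconsistent with use of the mid-Atlantic
#'    coast.
#' 5. **unknown** — anything else.
#'
#' Only bouts between deployment and `migration_season_end` are used.
#'
#' @param bouts bout data.frame for a single bird, time-sorted.
#' @param stations station table.
#' @param deployment single-row deployment data.frame.
#' @param regions region list; must contain a `delaware_bay` region; the
#'   `great_lakes` and `atlantic_coast` regions sharpen rule 4 when
#'   present.
#' @param config a [rufa_config()] list.
#' @return list of class `rufa_strategy` with `tag_id`, `strategy` and an
#'   `evidence` list (bay bout count and day span, annulus evidence,
#'   transit slack in hours, inland-route flag).
#' @export
classify_delaware_strategy <- function(bouts, stations, deployment, regions,
                                       config = rufa_config()) {
  stopifnot(nrow(deployment) == 1)
  bay <- region_by_role(regions, "delaware_bay")
  if (is.null(bay)) stop("regions must include a delaware_bay region")
  season_end <- season_end_date(config$migration_season_end,
                                deployment$deploy_time)
  keep <- bouts$end >= deployment$deploy_time &
    utc_date(bouts$start) <= season_end
  bouts <- bouts[keep, , drop = FALSE]
  if (!nrow(bouts)) {
    stop("no bouts between deployment and season end for tag ",
         deployment$tag_id)
  }
  bouts <- bouts[order(bouts$start), , drop = FALSE]
  si <- match(bouts$station_id, stations$station_id)
  if (anyNA(si)) stop("bout references unknown station")
  slat <- stations$lat[si]; slon <- stations$lon[si]

  usi <- !duplicated(bouts$station_id)
  in_bay_u <- region_membership(slat[usi], slon[usi], bay,
                                buffer_km = config$bay_buffer_km)
  in_wide_u <- region_membership(slat[usi], slon[usi], bay,
                                 buffer_km = config$bay_buffer_km +
                                   config$likely_buffer_km)
  lookup <- function(v) v[match(bouts$station_id, bouts$station_id[usi])]
  in_bay <- lookup(in_bay_u)
  in_annulus <- lookup(in_wide_u) & !in_bay

  bay_span_d <- if (any(in_bay)) {
    as.numeric(difftime(max(bouts$end[in_bay]), min(bouts$start[in_bay]),
                        units = "days"))
  } else 0
  ann_days <- if (any(in_annulus)) {
    length(unique(c(utc_date(bouts$start[in_annulus]),
                    utc_date(bouts$end[in_annulus]))))
  } else 0L

  evidence <- list(
    n_bay_bouts = sum(in_bay), bay_span_days = bay_span_d,
    n_annulus_bouts = sum(in_annulus), annulus_calendar_days = ann_days,
    north_detected = FALSE, slack_h = NA_real_, inland_route = NA
  )
  result <- function(strategy) {
    structure(list(tag_id = deployment$tag_id, strategy = strategy,
                   evidence = evidence), class = "rufa_strategy")
  }

  if (sum(in_bay) >= 2 && bay_span_d > config$min_stop_days) {
    return(result("stopped"))
  }
  if (sum(in_annulus) >= 2 && ann_days >= 2) {
    return(result("likely_stopped"))
  }

  bay_lat <- region_max_lat(bay)
  above <- slat > bay_lat
  flythrough_only <- !any(in_bay) || bay_span_d <= config$min_stop_days
  if (any(above)) {
    evidence$north_detected <- TRUE
    first_above <- which(above)[which.min(as.numeric(bouts$start[above]))]
    below_ok <- !above & bouts$end <= bouts$start[first_above]
    if (any(below_ok)) {
      last_below <- which(below_ok)[which.max(as.numeric(bouts$end[below_ok]))]
      elapsed_h <- as.numeric(difftime(bouts$start[first_above],
                                       bouts$end[last_below],
                                       units = "hours"))
      d_km <- gc_distance(slat[last_below], slon[last_below],
                          slat[first_above], slon[first_above])
      min_flight_h <- d_km * 1000 / config$assumed_transit_speed_ms / 3600
      slack_h <- elapsed_h - min_flight_h
      evidence$slack_h <- slack_h
      if (flythrough_only && slack_h < config$min_stop_days * 24) {
        return(result("skipped"))
      }
      if (flythrough_only && slack_h >= config$min_stop_days * 24) {
        inter <- which(!above & !in_bay &
                         bouts$start < bouts$start[first_above])
        if (length(inter)) {
          far <- gc_distance(deployment$deploy_lat, deployment$deploy_lon,
                             slat[inter], slon[inter]) >
            config$stopover_min_dist_from_capture_km
          inter <- inter[far]
        }
        if (length(inter)) {
          inland <- is_inland_point(slat[inter], slon[inter], regions,
                                    config$inland_offset_km)
          evidence$inland_route <- all(inland)
          if (all(inland)) return(result("likely_skipped"))
        }
      }
    }
  }
  result("unknown")
}

# Inland = inside the Great Lakes Basin, or farther than offset_km from the
# Atlantic coastline when a coastline region is available.
is_inland_point <- function(lat, lon, regions, offset_km) {
  lakes <- region_by_role(regions, "great_lakes")
  coast <- region_by_role(regions, "atlantic_coast")
  out <- rep(FALSE, length(lat))
  if (!is.null(lakes)) out <- out | region_membership(lat, lon, lakes)
  if (!is.null(coast)) {
    out <- out | dist_to_boundary_km(lat, lon, coast) > offset_km
  }
  out
}

#' @export
print.rufa_strategy <- function(x, ...) {
  cat(sprintf("tag %s: %s (bay bouts %d spanning %.2f d; slack %s h)\n",
              x$tag_id, x$strategy, x$evidence$n_bay_bouts,
              x$evidence$bay_span_days,
              ifelse(is.na(x$evidence$slack_h), "NA",
                     sprintf("%.1f", x$evidence$slack_h))))
  invisible(x)
}

#' Tabulate strategy calls
#'
#' Counts all five classes and pools them into stopped
#' (stopped + likely_stopped) versus skipped (skipped + likely_skipped).
#' Proportions are computed over classifiable birds only (unknowns are
#' excluded from the denominator).
#'
#' @param calls list of `rufa_strategy` objects, or a data.frame with a
#'   `strategy` column.
#' @return list with `counts` (all five classes), `n_classifiable`,
#'   `prop_stopped_pooled`, `prop_skipped_pooled` (both `NA` when no bird
#'   is classifiable).
#' @export
summarize_strategies <- function(calls) {
  strategy <- if (is.data.frame(calls)) calls$strategy else
    vapply(calls, `[[`, character(1), "strategy")
  if (!length(strategy)) stop("no strategy calls supplied")
  lev <- c("stopped", "likely_stopped", "skipped", "likely_skipped",
           "unknown")
  counts <- table(factor(strategy, levels = lev))
  pooled_stop <- sum(counts[c("stopped", "likely_stopped")])
  pooled_skip <- sum(counts[c("skipped", "likely_skipped")])
  n_class <- pooled_stop + pooled_skip
  list(
    counts = stats::setNames(as.integer(counts), lev),
    n_classifiable = as.integer(n_class),
    prop_stopped_pooled = if (n_class > 0) pooled_stop / n_class else NA_real_,
    prop_skipped_pooled = if (n_class > 0) pooled_skip / n_class else NA_real_
  )
}

#' Body mass by migration strategy (one-way ANOVA)
#'
#' Compares capture body mass across pooled strategy groups (stopped,
#' skipped, unknown) with a classical one-way analysis of variance
#' computed from between- and within-group sums of squares.
#'
#' @param deployments deployment table with `body_mass_g`.
#' @param calls list of `rufa_strategy` objects or data.frame with
#'   `tag_id` and `strategy`.
#' @return list of class `rufa_anova`: `group_means`, `group_n`, `F`,
#'   `df` (numerator, denominator), `p`, `r_squared`.
#' @export
mass_by_strategy <- function(deployments, calls) {
  df <- if (is.data.frame(calls)) calls else
    data.frame(tag_id = vapply(calls, `[[`, character(1), "tag_id"),
               strategy = vapply(calls, `[[`, character(1), "strategy"),
               stringsAsFactors = FALSE)
  pooled <- c(stopped = "stopped", likely_stopped = "stopped",
              skipped = "skipped", likely_skipped = "skipped",
              unknown = "unknown")
  df$group <- unname(pooled[df$strategy])
  df$mass <- deployments$body_mass_g[match(df$tag_id, deployments$tag_id)]
  df <- df[!is.na(df$mass), , drop = FALSE]
  tab <- table(df$group)
  tab <- tab[tab > 0]
  if (length(tab) < 2 || sum(tab >= 2) < 2) {
    stop("need at least two strategy groups with two or more birds each")
  }
  res <- oneway_anova(df$mass, df$group)
  structure(res, class = "rufa_anova")
}

# Classical one-way ANOVA from sums of squares.
oneway_anova <- function(y, g) {
  g <- as.character(g)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  grand <- mean(y)
  ssb <- sum(ns * (means - grand)^2)
  sst <- sum((y - grand)^2)
  ssw <- sst - ssb
  dfb <- length(means) - 1
  dfw <- length(y) - length(means)
  if (ssw <= 0 && ssb <= 0) stop("all observations identical; F undefined")
  if (ssw <= 0) stop("zero within-group variance; F undefined")
  Fval <- (ssb / dfb) / (ssw / dfw)
  list(group_means = means, group_n = ns, F = Fval, df = c(dfb, dfw),
       p = stats::pf(Fval, dfb, dfw, lower.tail = FALSE),
       r_squared = if (sst > 0) ssb / sst else NA_real_)
}

#' @export
print.rufa_anova <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F_%d,%d = %.3g, P = %.3g, R^2 = %.3g\n",
              x$df[1], x$df[2], x$F, x$p, x$r_squared))
  means <- sprintf("%s: %.1f g (n = %d)", names(x$group_means),
                   x$group_means, x$group_n)
  cat(" ", paste(means, collapse = "; "), "\n")
  invisible(x)
}
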