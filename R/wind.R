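#' Sample a wind field at a time and place
#'
#' Selects the grid time slice closest to the query time (ties go to the
#' earlier slice) and interpolates the u and v components at the query
#' point, bilinearly by default or by nearest grid node.
#'
#' @param wind a `rufa_wind` object.
#' @param time POSIXct UTC query time; must lie within the grid's time
#'   range extended by one step on either side.
#' @param lat,lon query point, degrees; must be inside the grid extent.
#' @param mode `"bilinear"` or `"nearest"`.
#' @return named numeric vector `c(u =, v =)` in m/s.
#' @export
sample_wind <- function(wind, time, lat, lon, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  time <- parse_utc(time)
  lat <- unname(lat); lon <- unname(lon)
  tnum <- as.numeric(wind$times)
  step <- if (length(tnum) > 1) min(diff(tnum)) else 21600
  if (as.numeric(time) < tnum[1] - step ||
      as.numeric(time) > tnum[length(tnum)] + step) {
    stop("query time outside wind-field time range")
  }
  dt <- abs(tnum - as.numeric(time))
  ti <- which(dt == min(dt))[1]  # tie -> earlier slice

  lats <- wind$lats; lons <- wind$lons
  if (lat < min(lats) || lat > max(lats) ||
      lon < min(lons) || lon > max(lons)) {
    stop("query point outside wind-field grid extent")
  }
  if (mode == "nearest") {
    yi <- which.min(abs(lats - lat))
    xi <- which.min(abs(lons - lon))
    return(c(u = wind$u[ti, yi, xi], v = wind$v[ti, yi, xi]))
  }
  interp1 <- function(axis, val) {
    if (length(axis) == 1) return(list(i0 = 1, i1 = 1, w = 0))
    i1 <- findInterval(val, axis, rightmost.closed = TRUE)
    i1 <- min(max(i1, 1), length(axis) - 1)
    w <- (val - axis[i1]) / (axis[i1 + 1] - axis[i1])
    list(i0 = i1, i1 = i1 + 1, w = w)
  }
  ay <- interp1(lats, lat); ax <- interp1(lons, lon)
  bl <- function(arr) {
    (1 - ay$w) * (1 - ax$w) * arr[ti, ay$i0, ax$i0] +
      (1 - ay$w) * ax$w * arr[ti, ay$i0, ax$i1] +
      ay$w * (1 - ax$w) * arr[ti, ay$i1, ax$i0] +
      ay$w * ax$w * arr[ti, ay$i1, ax$i1]
  }
  c(u = bl(wind$u), v = bl(wind$v))
}

#' Tailwind support along a preferred bearing
#'
#' Projects the wind vector onto the preferred direction of movement:
#' `tailwind = u * sin(beta) + v * cos(beta)` with `beta` the bearing in
#' degrees clockwise from north, `u` the eastward and `v` the northward
#' wind component. Positive values support the flight; any wind within
#' 90 degrees of the direction of movement is a tailwind (for a due-north
#' flight, winds from just south of east through just south of west all
#' qualify).
#'
#' @param u,v wind components, m/s; vectorized.
#' @param bearing_deg preferred bearing, degrees clockwise from north.
#' @return signed tailwind speed(s), m/s.
#' @export
tailwind_support <- function(u, v, bearing_deg) {
  b <- bearing_deg * pi / 180
  u * sin(b) + v * cos(b)
}

#' Wind support for a set of flights
#'
#' Samples the wind field at each flight's departure station at the
#' measurement time closest to departure and projects it onto the
#' flight's great-circle bearing toward the ending station.
#'
#' @param flights flight data.frame from [extract_flights()].
#' @param wind a `rufa_wind` object.
#' @param mode interpolation mode passed to [sample_wind()].
#' @return `flights` with added columns `u`, `v`, `tailwind_ms`,
#'   `is_tailwind`.
#' @export
flight_wind_support <- function(flights, wind, mode = "bilinear") {
  if (!nrow(flights)) {
    flights$u <- numeric(0); flights$v <- numeric(0)
    flights$tailwind_ms <- numeric(0); flights$is_tailwind <- logical(0)
    return(flights)
  }
  uv <- t(vapply(seq_len(nrow(flights)), function(i) {
    sample_wind(wind, flights$depart_time[i], flights$depart_lat[i],
                flights$depart_lon[i], mode = mode)
  }, numeric(2)))
  flights$u <- uv[, 1]
  flights$v <- uv[, 2]
  flights$tailwind_ms <- tailwind_support(uv[, 1], uv[, 2],
                                          flights$bearing_deg)
  flights$is_tailwind <- flights$tailwind_ms > 0
  flights
}

#' Ground speed vs tailwind association
#'
#' Pearson correlation between net ground speed and tailwind support,
#' computed from centered cross-moments, with a two-sided p-value from
#' the t transform on n - 2 degrees of freedom, plus the fraction of
#' flights departing with a tailwind.
#'
#' @param speed_ms net ground speeds, m/s.
#' @param tailwind_ms signed tailwind support, m/s.
#' @return list with `r`, `p`, `n`, `tailwind_fraction`.
#' @export
speed_wind_association <- function(speed_ms, tailwind_ms) {
  ok <- is.finite(speed_ms) & is.finite(tailwind_ms)
  x <- tailwind_ms[ok]; y <- speed_ms[ok]
  n <- length(x)
  if (n < 3) stop("need at least three flights with finite speed and tailwind")
  r <- pearson_r(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r,
       p = 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE),
       n = n,
       tailwind_fraction = mean(x > 0))
}

# Pearson correlation from centered cross-moments.
pearson_r <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sum(xc^2); sy <- sum(yc^2)
  if (sx == 0 || sy == 0) stop("zero variance; correlation undefined")
  sum(xc * yc) / sqrt(sx * sy)
}
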