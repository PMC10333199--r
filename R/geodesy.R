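#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0 km. Sub-half-percent
#' deviations from an ellipsoid are irrelevant at the 150-km scales used by
#' the flight filters, and the spherical form is deterministic and
#' dependency-light.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS84);
#'   vectorized with recycling.
#' @return distance(s) in km.
#' @examples
#' gc_distance(0, 0, 90, 0)   # quarter meridian, pi/2 * 6371
#' @export
gc_distance <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000
}

EARTH_RADIUS_KM <- 6371.0

#' Initial great-circle bearing
#'
#' Bearing, in degrees clockwise from true north in `[0, 360)`, of the
#' great-circle route from the first point toward the second.
#'
#' @inheritParams gc_distance
#' @return bearing(s) in degrees in `[0, 360)`.
#' @examples
#' initial_bearing(0, 0, 0, 10)  # due east on the equator: 90
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  if (any(p1[, 1] == p2[, 1] & p1[, 2] == p2[, 2])) {
    stop("initial_bearing undefined for coincident points")
  }
  # spherical great-circle formula, consistent with the 6371-km sphere used
  # by gc_distance (geosphere::bearing is ellipsoidal)
  f1 <- p1[, 2] * pi / 180; f2 <- p2[, 2] * pi / 180
  dl <- (p2[, 1] - p1[, 1]) * pi / 180
  th <- atan2(sin(dl) * cos(f2),
              cos(f1) * sin(f2) - sin(f1) * cos(f2) * cos(dl))
  (th * 180 / pi + 360) %% 360
}

#' Test point membership in a buffered region
#'
#' A point belongs to a region when it lies inside the region polygon or
#' within `buffer_km` (geodesic) of its boundary. This realizes rules such
#' as "stations within 30 km of the Delaware Bay watershed".
#'
#' @param lat,lon point coordinates, decimal degrees; vectorized.
#' @param region a region as returned by [read_regions()]: a list with at
#'   least `rings`, a list of two-column (lon, lat) matrices.
#' @param buffer_km buffer distance in km (0 means strict containment).
#' @return logical vector.
#' @export
region_membership <- function(lat, lon, region, buffer_km = 0) {
  rings <- region$rings
  if (is.null(rings) || !length(rings)) stop("region has an empty polygon")
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  pts <- cbind(lon, lat)
  inside <- rep(FALSE, n)
  for (ring in rings) {
    inside <- inside | mgcv::in.out(ring, pts)
  }
  if (buffer_km > 0 && !all(inside)) {
    todo <- which(!inside)
    d <- dist_to_boundary_km(lat[todo], lon[todo], region)
    inside[todo] <- d <= buffer_km
  }
  inside
}

#' Geodesic distance from points to a region boundary
#'
#' Minimum great-circle distance (km) from each point to the polygon
#' boundary of a region; exact cross-track distance per edge, not a
#' densified approximation. Points inside the polygon still get their
#' distance to the boundary (use [region_membership()] for containment).
#'
#' @inheritParams region_membership
#' @return numeric vector of distances in km.
#' @export
dist_to_boundary_km <- function(lat, lon, region) {
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  best <- rep(Inf, n)
  for (ring in region$rings) {
    m <- nrow(ring)
    for (i in seq_len(m - 1)) {
      d <- dist_point_segment_km(lat, lon,
                                 ring[i, 2], ring[i, 1],
                                 ring[i + 1, 2], ring[i + 1, 1])
      best <- pmin(best, d)
    }
  }
  best
}

# Great-circle distance from point P to the segment A-B using the
# cross-track formula; falls back to endpoint distance when the foot of the
# perpendicular lies off the segment.
dist_point_segment_km <- function(latp, lonp, lata, lona, latb, lonb) {
  dPA <- gc_distance(latp, lonp, lata, lona)
  dPB <- gc_distance(latp, lonp, latb, lonb)
  if (lata == latb && lona == lonb) return(dPA)
  dAB <- gc_distance(lata, lona, latb, lonb)
  b12 <- initial_bearing(lata, lona, latb, lonb) * pi / 180
  # angular distances
  a13 <- dPA / EARTH_RADIUS_KM
  ok <- dPA > 0
  out <- dPA
  if (any(ok)) {
    b13 <- rep(0, length(dPA))
    b13[ok] <- initial_bearing(rep(lata, sum(ok)), rep(lona, sum(ok)),
                               latp[seq_along(dPA)][ok],
                               lonp[seq_along(dPA)][ok]) * pi / 180
    dxt <- asin(pmin(1, pmax(-1, sin(a13) * sin(b13 - b12))))
    cos_dxt <- cos(dxt)
    along <- ifelse(abs(cos_dxt) < 1e-12, 0,
                    acos(pmin(1, pmax(-1, cos(a13) / cos_dxt))))
    # sign of the along-track position: behind A when the bearing difference
    # exceeds 90 degrees
    behind <- cos(b13 - b12) < 0
    on_seg <- ok & !behind & along <= dAB / EARTH_RADIUS_KM
    out[on_seg] <- abs(dxt[on_seg]) * EARTH_RADIUS_KM
    out[!on_seg] <- pmin(dPA, dPB)[!on_seg]
  } else {
    out <- pmin(dPA, dPB)
  }
  out
}

# Largest latitude attained by a region's boundary (used to decide whether a
# detection lies "north of the bay").
region_max_lat <- function(region) {
  max(vapply(region$rings, function(r) max(r[, 2]), numeric(1)))
}

# Pull one region by role from a region list; NULL if absent.
region_by_role <- function(regions, role) {
  hit <- Filter(function(r) identical(r$role, role), regions)
  if (!length(hit)) return(NULL)
  hit[[1]]
}
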