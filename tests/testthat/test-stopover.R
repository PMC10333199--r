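so_stations <- mk_stations(
  c("FAR1", "FAR2", "FAR3", "NEAR40"),
  c(39.10, 39.20, 40.50, 32.80),
  c(-75.40, -75.10, -74.00, -80.50))
so_dep <- mk_deployment("T1", time = "2019-05-01 00:00:00",
                        lat = 32.54, lon = -80.18)
so_cfg <- rufa_config()

test_that("single-station spans obey the strict 4-h rule", {
  b_450 <- mk_bouts("T1", "FAR1", "2019-05-10 06:00:00",
                    "2019-05-10 10:30:00")
  s1 <- detect_stopovers(b_450, so_stations, so_dep, so_cfg)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$duration_h, 4.5)
  expect_equal(s1$stations, "FAR1")

  b_400 <- mk_bouts("T1", "FAR1", "2019-05-10 06:00:00",
                    "2019-05-10 10:00:00")
  expect_equal(nrow(detect_stopovers(b_400, so_stations, so_dep, so_cfg)),
               0L)
})

test_that("nearby-station clusters obey the strict 6-h rule", {
  expect_lt(gc_distance(39.10, -75.40, 39.20, -75.10), 30)
  b <- mk_bouts("T1", c("FAR1", "FAR2"),
                c("2019-05-10 06:00:00", "2019-05-10 09:00:00"),
                c("2019-05-10 08:00:00", "2019-05-10 12:30:00"))
  s <- detect_stopovers(b, so_stations, so_dep, so_cfg)
  expect_equal(nrow(s), 1L)
  expect_equal(s$stations, "FAR1,FAR2")
  expect_equal(s$duration_h, 6.5)

  b6 <- mk_bouts("T1", c("FAR1", "FAR2"),
                 c("2019-05-10 06:00:00", "2019-05-10 09:00:00"),
                 c("2019-05-10 08:00:00", "2019-05-10 12:00:00"))
  expect_equal(nrow(detect_stopovers(b6, so_stations, so_dep, so_cfg)), 0L)

  # stations beyond the 30-km cluster radius never pool
  expect_gt(gc_distance(39.20, -75.10, 40.50, -74.00), 30)
  bfar <- mk_bouts("T1", c("FAR2", "FAR3"),
                   c("2019-05-10 06:00:00", "2019-05-10 09:00:00"),
                   c("2019-05-10 08:00:00", "2019-05-10 12:30:00"))
  expect_equal(nrow(detect_stopovers(bfar, so_stations, so_dep, so_cfg)), 0L)
})

test_that("stations within 50 km of the tagging site are excluded", {
  expect_lt(gc_distance(32.54, -80.18, 32.80, -80.50), 50)
  b <- mk_bouts("T1", "NEAR40", "2019-05-10 06:00:00",
                "2019-05-10 16:00:00")
  expect_equal(nrow(detect_stopovers(b, so_stations, so_dep, so_cfg)), 0L)
})

test_that("stopovers match a brute-force enumeration on small inputs", {
  oracle <- function(bouts, stations, dep, cfg) {
    si <- match(bouts$station_id, stations$station_id)
    far <- gc_distance(dep$deploy_lat, dep$deploy_lon,
                       stations$lat[si], stations$lon[si]) >
      cfg$stopover_min_dist_from_capture_km
    bouts <- bouts[far, , drop = FALSE]; si <- si[far]
    n <- nrow(bouts)
    if (!n) return(integer(0))
    covered <- rep(FALSE, n)
    for (i in seq_len(n)) for (j in i:n) {
      idx <- i:j
      span <- as.numeric(difftime(max(bouts$end[idx]), min(bouts$start[idx]),
                                  units = "hours"))
      same <- length(unique(bouts$station_id[idx])) == 1
      dmax <- max(outer(idx, idx, function(a, b)
        gc_distance(stations$lat[si[a]], stations$lon[si[a]],
                    stations$lat[si[b]], stations$lon[si[b]])))
      if ((same && span > cfg$stopover_single_station_h) ||
          (dmax <= cfg$stopover_station_cluster_km &&
             span > cfg$stopover_multi_station_h)) {
        covered[idx] <- TRUE
      }
    }
    which(covered)
  }
  set.seed(77)
  for (rep in 1:40) {
    k <- sample(1:10, 1)
    ids <- sample(so_stations$station_id, k, replace = TRUE)
    st <- utc("2019-05-10 00:00:00") + sort(runif(k, 0, 3 * 86400))
    bouts <- data.frame(tag_id = "T1", station_id = ids, start = st,
                        end = st + runif(k, 600, 5 * 3600),
                        n_detections = 5L, stringsAsFactors = FALSE)
    got <- detect_stopovers(bouts, so_stations, so_dep, so_cfg)
    ref_idx <- oracle(bouts, so_stations, so_dep, so_cfg)
    # compare total covered span and stopover count against the oracle
    if (!length(ref_idx)) {
      expect_equal(nrow(got), 0L)
    } else {
      si <- match(bouts$station_id, so_stations$station_id)
      far <- gc_distance(so_dep$deploy_lat, so_dep$deploy_lon,
                         so_stations$lat[si], so_stations$lon[si]) >
        so_cfg$stopover_min_dist_from_capture_km
      bb <- bouts[far, , drop = FALSE]
      grp <- cumsum(c(TRUE, diff(ref_idx) > 1))
      ref_spans <- vapply(split(ref_idx, grp), function(ii)
        c(min(as.numeric(bb$start[ii])), max(as.numeric(bb$end[ii]))),
        numeric(2))
      expect_equal(nrow(got), ncol(ref_spans))
      expect_equal(as.numeric(got$start), unname(sort(ref_spans[1, ])))
      expect_equal(as.numeric(got$end),
                   unname(ref_spans[2, order(ref_spans[1, ])]))
    }
  }
})

test_that("lengthening a span never removes a stopover", {
  b <- mk_bouts("T1", "FAR1", "2019-05-10 06:00:00", "2019-05-10 10:30:00")
  base <- detect_stopovers(b, so_stations, so_dep, so_cfg)
  b2 <- b; b2$end <- b2$end + 3600
  longer <- detect_stopovers(b2, so_stations, so_dep, so_cfg)
  expect_gte(nrow(longer), nrow(base))
  # raising thresholds never creates one
  strict <- rufa_config(stopover_single_station_h = 6,
                        stopover_multi_station_h = 8)
  expect_lte(nrow(detect_stopovers(b, so_stations, so_dep, strict)),
             nrow(base))
})

test_that("bay durations use first-to-last detection time", {
  regions <- list(reg_box("delaware_bay", 38.80, 39.70, -75.60, -74.80))
  det <- rbind(
    mk_detections("T1", "FAR1", c("2019-05-10 06:00:00",
                                  "2019-05-15 20:24:00")),
    mk_detections("T2", "FAR1", "2019-05-11 00:00:00"),
    mk_detections("T3", "NEAR40", c("2019-05-11 00:00:00",
                                    "2019-05-12 00:00:00")))
  d <- delaware_stopover_durations(det, so_stations, regions, so_cfg)
  expect_equal(d$tag_id, "T1")
  expect_equal(d$duration_d, 5.6)
  # a single bay detection is excluded; zero span is a valid zero
  det0 <- mk_detections("T4", "FAR1", rep("2019-05-11 00:00:00", 2))
  d0 <- delaware_stopover_durations(det0, so_stations, regions, so_cfg)
  expect_equal(d0$duration_d, 0)
})

test_that("heat map counts individuals once per cell", {
  so1 <- data.frame(tag_id = "A", stations = "FAR1",
                    start = utc("2019-05-10 00:00:00"),
                    end = utc("2019-05-11 00:00:00"), duration_h = 24,
                    centroid_lat = 39.1, centroid_lon = -75.4,
                    stringsAsFactors = FALSE)
  grid <- stopover_heatmap(so1, so_stations, c(38, 40.5), c(-77, -73),
                           cell_deg = 0.25, buffer_km = 50)
  near <- gc_distance(grid$cell_lat, grid$cell_lon, 39.1, -75.4) <= 50
  expect_true(all(grid$count[near] == 1))
  expect_true(all(grid$count[!near] == 0))

  # same individual twice: still 1; two individuals: 2
  so2 <- rbind(so1, so1)
  g2 <- stopover_heatmap(so2, so_stations, c(38, 40.5), c(-77, -73))
  expect_equal(max(g2$count), 1L)
  so3 <- rbind(so1, within(so1, tag_id <- "B"))
  g3 <- stopover_heatmap(so3, so_stations, c(38, 40.5), c(-77, -73))
  expect_equal(max(g3$count), 2L)
  expect_lte(max(g3$count), length(unique(so3$tag_id)))
  expect_error(stopover_heatmap(so1, so_stations, c(38, 38), c(-77, -77)),
               "degenerate")
})
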