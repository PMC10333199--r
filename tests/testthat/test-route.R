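route_stations <- mk_stations(
  c("SC", "SCI", "BAY1", "BAY2", "NORTH", "LAKES", "COASTN", "VAC"),
  c(33.00, 34.50, 39.10, 39.20, 41.09, 43.00, 40.00, 37.10),
  c(-79.00, -81.50, -75.40, -75.10, -79.00, -79.50, -74.10, -75.90))
coast_ring <- local({
  path <- cbind(c(-80.5, -79.3, -77.9, -75.5, -75.9, -74.9, -74.0),
                c(32.0, 33.0, 33.9, 35.2, 36.9, 38.9, 40.5))
  rbind(path, cbind(rev(path[, 1]) + 0.02, rev(path[, 2])),
        path[1, , drop = FALSE])
})
route_regions <- list(
  reg_box("delaware_bay", 38.80, 39.70, -75.60, -74.80),
  reg_box("great_lakes", 41.30, 47.00, -84.50, -76.50),
  reg_box("inland_carolinas", 33.50, 36.60, -83.50, -79.60),
  region("coast", "atlantic_coast", list(coast_ring)))
route_dep <- mk_deployment("T1", time = "2019-05-01 00:00:00",
                           lat = 32.54, lon = -80.18)

test_that("multi-day bay presence scores stopped", {
  bouts <- mk_bouts("T1", c("SC", "BAY1", "BAY2", "NORTH"),
                    c("2019-05-09 12:00:00", "2019-05-10 02:00:00",
                      "2019-05-12 09:00:00", "2019-05-14 10:00:00"),
                    c("2019-05-09 12:10:00", "2019-05-10 02:30:00",
                      "2019-05-12 09:30:00", "2019-05-14 10:10:00"))
  call <- classify_delaware_strategy(bouts, route_stations, route_dep,
                                     route_regions)
  expect_equal(call$strategy, "stopped")
  expect_equal(call$evidence$n_bay_bouts, 2L)
  expect_gt(call$evidence$bay_span_days, 1)
})

test_that("bay bouts spanning no more than one day do not make a stop", {
  bouts <- mk_bouts("T1", c("BAY1", "BAY2"),
                    c("2019-05-10 02:00:00", "2019-05-11 01:00:00"),
                    c("2019-05-10 02:30:00", "2019-05-11 01:30:00"))
  call <- classify_delaware_strategy(bouts, route_stations, route_dep,
                                     route_regions)
  expect_false(call$strategy == "stopped")
})

test_that("a fast northward transit with no slack scores skipped", {
  # last sub-bay detection May 15 18:00; first detection at a station about
  # 900 km north at May 16 10:00: 16 h elapsed vs 12.5 h minimum flight
  d <- gc_distance(33, -79, 41.09, -79)
  expect_equal(d, 900, tolerance = 0.01)
  bouts <- mk_bouts("T1", c("SC", "NORTH"),
                    c("2019-05-15 17:00:00", "2019-05-16 10:00:00"),
                    c("2019-05-15 18:00:00", "2019-05-16 10:10:00"))
  call <- classify_delaware_strategy(bouts, route_stations, route_dep,
                                     route_regions)
  expect_equal(call$strategy, "skipped")
  expect_equal(call$evidence$slack_h, 16 - d * 1000 / 20 / 3600,
               tolerance = 1e-6)
})

test_that("slow inland transits score likely_skipped, coastal ones unknown", {
  # 3 days inland-SC -> LAKES (plenty of slack), intermediate detections
  # all far from the coastline
  bouts_inland <- mk_bouts("T1", c("SCI", "LAKES"),
                           c("2019-05-10 00:00:00", "2019-05-13 00:00:00"),
                           c("2019-05-10 01:00:00", "2019-05-13 01:00:00"))
  call1 <- classify_delaware_strategy(bouts_inland, route_stations,
                                      route_dep, route_regions)
  expect_equal(call1$strategy, "likely_skipped")
  expect_true(call1$evidence$inland_route)

  # same slack but the intermediate evidence includes a coastal station
  bouts_coast <- mk_bouts("T1", c("SCI", "VAC", "LAKES"),
                          c("2019-05-10 00:00:00", "2019-05-11 00:00:00",
                            "2019-05-13 00:00:00"),
                          c("2019-05-10 01:00:00", "2019-05-11 01:00:00",
                            "2019-05-13 01:00:00"))
  call2 <- classify_delaware_strategy(bouts_coast, route_stations,
                                      route_dep, route_regions)
  expect_equal(call2$strategy, "unknown")
})

test_that("insufficient evidence scores unknown", {
  bouts <- mk_bouts("T1", "SC", "2019-05-10 02:00:00",
                    "2019-05-10 02:05:00")
  call <- classify_delaware_strategy(bouts, route_stations, route_dep,
                                     route_regions)
  expect_equal(call$strategy, "unknown")
  expect_error(classify_delaware_strategy(bouts[0, ], route_stations,
                                          route_dep, route_regions),
               "no bouts")
})

test_that("adding qualifying bay bouts moves a skipped bird to stopped", {
  fast <- mk_bouts("T1", c("SC", "NORTH"),
                   c("2019-05-15 17:00:00", "2019-05-16 10:00:00"),
                   c("2019-05-15 18:00:00", "2019-05-16 10:10:00"))
  expect_equal(classify_delaware_strategy(fast, route_stations, route_dep,
                                          route_regions)$strategy, "skipped")
  with_bay <- rbind(fast[1, ],
                    mk_bouts("T1", c("BAY1", "BAY1"),
                             c("2019-05-16 02:00:00", "2019-05-18 04:00:00"),
                             c("2019-05-16 02:10:00", "2019-05-18 04:10:00")),
                    fast[2, ])
  with_bay <- with_bay[order(with_bay$start), ]
  call <- classify_delaware_strategy(with_bay, route_stations, route_dep,
                                     route_regions)
  expect_equal(call$strategy, "stopped")
})

test_that("the decision tree is total on random bout histories", {
  set.seed(99)
  for (i in 1:40) {
    k <- sample(1:6, 1)
    ids <- sample(route_stations$station_id, k, replace = TRUE)
    st <- utc("2019-05-05 00:00:00") + sort(runif(k, 0, 30 * 86400))
    bouts <- data.frame(tag_id = "T1", station_id = ids, start = st,
                        end = st + runif(k, 60, 3600),
                        n_detections = 5L, stringsAsFactors = FALSE)
    call <- classify_delaware_strategy(bouts, route_stations, route_dep,
                                       route_regions)
    expect_true(call$strategy %in% c("stopped", "likely_stopped", "skipped",
                                     "likely_skipped", "unknown"))
  }
})

test_that("strategy summaries pool classes and exclude unknowns", {
  calls <- data.frame(
    tag_id = sprintf("B%02d", 1:42),
    strategy = rep(c("skipped", "likely_skipped", "stopped",
                     "likely_stopped", "unknown"),
                   c(20, 4, 8, 1, 9)), stringsAsFactors = FALSE)
  s <- summarize_strategies(calls)
  expect_equal(s$n_classifiable, 33L)
  expect_equal(s$prop_skipped_pooled, 24 / 33)
  expect_equal(round(100 * s$prop_skipped_pooled), 73)
  expect_equal(sum(s$counts), 42L)

  s2 <- summarize_strategies(data.frame(strategy = c("stopped", "skipped")))
  expect_equal(s2$prop_skipped_pooled, 0.5)
  s3 <- summarize_strategies(data.frame(strategy = rep("unknown", 3)))
  expect_true(is.na(s3$prop_skipped_pooled))
})

test_that("one-way ANOVA matches hand computation and stats::lm", {
  y <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  res <- rufatrack:::oneway_anova(y, g)
  expect_equal(res$F, 13.5)
  expect_equal(res$df, c(1, 4))
  expect_equal(res$r_squared, 13.5 / 17.5)

  # identical groups: F = 0
  res0 <- rufatrack:::oneway_anova(c(1, 2, 3, 1, 2, 3), g)
  expect_equal(res0$F, 0)

  # cross-check against the standard linear-model ANOVA
  set.seed(4)
  y2 <- rnorm(30); g2 <- sample(c("a", "b", "c"), 30, TRUE)
  res2 <- rufatrack:::oneway_anova(y2, g2)
  ref <- anova(lm(y2 ~ g2))
  expect_equal(res2$F, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(res2$p, ref$`Pr(>F)`[1], tolerance = 1e-12)

  expect_error(rufatrack:::oneway_anova(c(1, 1, 1, 1), c("a", "a", "b", "b")),
               "F undefined")
})

test_that("mass_by_strategy groups by pooled class", {
  dep <- do.call(rbind, lapply(1:6, function(i)
    mk_deployment(paste0("B", i), mass = c(130, 132, 131, 140, 142, 141)[i])))
  calls <- data.frame(tag_id = paste0("B", 1:6),
                      strategy = rep(c("stopped", "skipped"), each = 3),
                      stringsAsFactors = FALSE)
  res <- mass_by_strategy(dep, calls)
  expect_s3_class(res, "rufa_anova")
  expect_equal(sort(names(res$group_means)), c("skipped", "stopped"))
  expect_equal(unname(res$group_means["skipped"] -
                        res$group_means["stopped"]), 10)
  expect_error(mass_by_strategy(dep[1:3, ], calls[1:3, ]), "two strategy")
})
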