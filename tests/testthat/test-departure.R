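# toy coastal geometry: capture site plus one far coastal station (away,
# not inland) and one far inland-Carolinas station
dep_stations <- mk_stations(c("NEAR", "COASTAL", "INLAND"),
                            c(32.6, 33.3, 34.0),
                            c(-80.2, -79.3, -81.0))
dep_regions <- list(reg_box("inland_carolinas", 33.5, 36.6, -83.5, -79.6),
                    reg_box("capture_zone", 32.2, 32.9, -80.6, -79.8))

test_that("first away detection at an inland station gives a known date", {
  dep <- mk_deployment("T1", time = "2019-05-08 12:00:00")
  bouts <- mk_bouts("T1", "INLAND", "2019-05-12 14:00:00",
                    "2019-05-12 14:10:00")
  est <- estimate_departure(bouts, dep, dep_stations, dep_regions)
  expect_equal(est$kind, "known")
  expect_equal(est$known_date, as.Date("2019-05-12"))
  expect_equal(unname(est$weights), 1)
  expect_equal(names(est$weights), "2019-05-12")
})

test_that("a coastal first detection yields a uniform inclusive window", {
  dep <- mk_deployment("T1", time = "2019-05-01 09:00:00")
  bouts <- mk_bouts("T1", "COASTAL", "2019-05-05 22:00:00",
                    "2019-05-05 22:05:00")
  est <- estimate_departure(bouts, dep, dep_stations, dep_regions)
  expect_equal(est$kind, "window")
  expect_equal(est$window_start, as.Date("2019-05-01"))
  expect_equal(est$window_end, as.Date("2019-05-05"))
  expect_equal(unname(est$weights), rep(0.2, 5))
  expect_equal(sum(est$weights), 1, tolerance = 1e-12)

  # 2-day window: deploy May 3, away May 4
  dep2 <- mk_deployment("T2", time = "2019-05-03 09:00:00")
  bouts2 <- mk_bouts("T2", "COASTAL", "2019-05-04 02:00:00",
                     "2019-05-04 02:05:00")
  est2 <- estimate_departure(bouts2, dep2, dep_stations, dep_regions)
  expect_equal(unname(est2$weights), c(0.5, 0.5))
})

test_that("stations within 50 km never count as away", {
  dep <- mk_deployment("T1", time = "2019-05-01 09:00:00")
  expect_lt(gc_distance(32.54, -80.18, 32.6, -80.2), 50)
  bouts <- mk_bouts("T1", "NEAR", "2019-05-04 02:00:00",
                    "2019-05-04 02:05:00")
  expect_null(estimate_departure(bouts, dep, dep_stations, dep_regions))
})

test_that("timeline sums weights and conserves total mass", {
  dep1 <- mk_deployment("K1", time = "2019-05-10 09:00:00")
  b1 <- mk_bouts("K1", "INLAND", "2019-05-10 15:00:00",
                 "2019-05-10 15:05:00")
  e1 <- estimate_departure(b1, dep1, dep_stations, dep_regions)
  dep2 <- mk_deployment("W1", time = "2019-05-08 09:00:00")
  b2 <- mk_bouts("W1", "COASTAL", "2019-05-12 15:00:00",
                 "2019-05-12 15:05:00")
  e2 <- estimate_departure(b2, dep2, dep_stations, dep_regions)

  tl <- departure_timeline(list(e1, e2))
  expect_equal(tl$weight[tl$date == as.Date("2019-05-10")], 1.2)
  expect_equal(tl$weight[tl$date == as.Date("2019-05-09")], 0.2)
  expect_equal(sum(tl$weight), 2, tolerance = 1e-12)
  expect_equal(tl$date, seq(as.Date("2019-05-08"), as.Date("2019-05-12"),
                            by = "day"))
})

test_that("per-bird weights always sum to one over random windows", {
  set.seed(23)
  ests <- lapply(1:30, function(i) {
    d0 <- as.Date("2019-04-20") + sample(0:15, 1)
    span <- sample(0:26, 1)
    dep <- mk_deployment(paste0("B", i),
                         time = paste(format(d0), "09:00:00"))
    bouts <- mk_bouts(paste0("B", i), "COASTAL",
                      paste(format(d0 + span), "18:00:00"),
                      paste(format(d0 + span), "18:05:00"))
    estimate_departure(bouts, dep, dep_stations, dep_regions)
  })
  for (e in ests) expect_equal(sum(e$weights), 1, tolerance = 1e-9)
  tl <- departure_timeline(ests)
  expect_equal(sum(tl$weight), 30, tolerance = 1e-9)
})

test_that("shrinking a window keeps mass inside the original window", {
  dep <- mk_deployment("T1", time = "2019-05-01 09:00:00")
  wide <- estimate_departure(
    mk_bouts("T1", "COASTAL", "2019-05-09 01:00:00", "2019-05-09 01:05:00"),
    dep, dep_stations, dep_regions)
  narrow <- estimate_departure(
    mk_bouts("T1", "COASTAL", "2019-05-05 01:00:00", "2019-05-05 01:05:00"),
    dep, dep_stations, dep_regions)
  expect_true(all(names(narrow$weights) %in% names(wide$weights)))
})

test_that("weighted median is the smallest date reaching half mass", {
  tl <- data.frame(date = as.Date("2019-05-01") + 0:4,
                   weight = c(1, 1, 1, 1, 6))
  expect_equal(weighted_median_date(tl), as.Date("2019-05-05"))
  tl2 <- data.frame(date = as.Date("2019-05-01") + 0:2,
                    weight = c(1, 1, 2))
  expect_equal(weighted_median_date(tl2), as.Date("2019-05-02"))
})
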