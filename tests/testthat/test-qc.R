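cfg <- rufa_config()

test_that("incomplete bursts are rejected by the pulse-count rule", {
  dep <- mk_deployment(bi = 5)
  t0 <- as.numeric(utc("2019-05-02 08:00:00"))
  det <- mk_detections("T1", "A", t0 + c(0, 5, 10, 15, 20),
                       n_pulses = c(3, 3, 2, 3, 3))
  res <- filter_detections(det, dep, cfg)
  expect_equal(res$report$n_rejected_by_rule[["min_pulses"]], 1L)
  expect_equal(res$report$n_valid, 4L)
  expect_false(2 %in% res$detections$n_pulses)
})

test_that("perfectly periodic detections are all retained", {
  dep <- mk_deployment(bi = 7.1)
  t0 <- as.numeric(utc("2019-05-02 08:00:00"))
  det <- mk_detections("T1", "A", t0 + (0:4) * 7.1)
  res <- filter_detections(det, dep, cfg)
  expect_equal(res$report$n_valid, 5L)
  expect_equal(sum(res$report$n_rejected_by_rule), 0L)
})

test_that("gaps matching no burst-interval multiple reject the run", {
  # gaps 7.3 s and 13.1 s for a 5.0 s tag: brute-force check that no
  # multiple k in 1..10 is within 0.1 s
  gaps <- c(7.3, 13.1)
  for (g in gaps) {
    expect_false(any(abs(g - (1:10) * 5.0) <= 0.1))
  }
  dep <- mk_deployment(bi = 5)
  t0 <- as.numeric(utc("2019-05-02 08:00:00"))
  det <- mk_detections("T1", "A", t0 + cumsum(c(0, gaps)))
  res <- filter_detections(det, dep, cfg)
  expect_equal(res$report$n_rejected_by_rule[["burst_interval"]], 3L)
  expect_equal(res$report$n_valid, 0L)
})

test_that("missed bursts within k_max keep a run intact", {
  dep <- mk_deployment(bi = 5)
  t0 <- as.numeric(utc("2019-05-02 08:00:00"))
  det <- mk_detections("T1", "A", t0 + c(0, 5, 20, 25, 75))  # k = 1,3,1,10
  res <- filter_detections(det, dep, cfg)
  expect_equal(res$report$n_valid, 5L)
  # a gap of 11 * bi breaks the run
  det2 <- mk_detections("T1", "A", t0 + c(0, 5, 10, 65, 70))
  res2 <- filter_detections(det2, dep, cfg)
  expect_equal(res2$report$n_valid, 3L)
  expect_equal(res2$report$n_rejected_by_rule[["burst_interval"]], 2L)
})

test_that("large frequency offsets are rejected when present", {
  dep <- mk_deployment(bi = 5)
  t0 <- as.numeric(utc("2019-05-02 08:00:00"))
  det <- mk_detections("T1", "A", t0 + (0:4) * 5,
                       freq_offset = c(0, 0.5, 3.5, NA, -0.2))
  res <- filter_detections(det, dep, cfg)
  expect_equal(res$report$n_rejected_by_rule[["freq_offset"]], 1L)
})

test_that("every detection is counted exactly once (conservation)", {
  set.seed(31)
  dep <- rbind(mk_deployment("T1", bi = 5), mk_deployment("T2", bi = 8.3))
  t0 <- as.numeric(utc("2019-05-02 08:00:00"))
  det <- rbind(
    mk_detections("T1", "A", t0 + cumsum(runif(20, 1, 30))),
    mk_detections("T1", "A", t0 + (0:9) * 5),
    mk_detections("T2", "B", t0 + (0:7) * 8.3,
                  n_pulses = sample(1:3, 8, TRUE)),
    mk_detections("T2", "A", t0 + cumsum(runif(5, 1, 200)),
                  freq_offset = rnorm(5, 0, 4))
  )
  res <- filter_detections(det, dep, cfg)
  expect_equal(res$report$n_input,
               res$report$n_valid + sum(res$report$n_rejected_by_rule))
  expect_equal(res$report$n_input, nrow(det))
})

test_that("filtering is idempotent", {
  set.seed(12)
  dep <- mk_deployment(bi = 6.2)
  t0 <- as.numeric(utc("2019-05-02 08:00:00"))
  det <- rbind(
    mk_detections("T1", "A", t0 + (0:6) * 6.2),
    mk_detections("T1", "A", t0 + 4000 + cumsum(runif(4, 1, 20))),
    mk_detections("T1", "B", t0 + 9000 + (0:3) * 6.2,
                  n_pulses = c(3, 2, 3, 3))
  )
  pass1 <- filter_detections(det, dep, cfg)
  pass2 <- filter_detections(pass1$detections, dep, cfg)
  expect_equal(pass2$report$n_valid, pass1$report$n_valid)
  expect_equal(sum(pass2$report$n_rejected_by_rule), 0L)
  expect_equal(det_key(pass2$detections), det_key(pass1$detections))
})

test_that("unknown tags are refused", {
  det <- mk_detections("GHOST", "A", as.numeric(utc("2019-05-02 08:00:00")))
  expect_error(filter_detections(det, mk_deployment("T1"), cfg), "GHOST")
})

test_that("bout construction splits on station change and long gaps", {
  t0 <- as.numeric(utc("2019-05-02 08:00:00"))
  det <- mk_detections("T1", "A", t0 + (0:9) * 240)  # 4-min gaps
  b <- bout_detections(det, cfg)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_detections, 10L)
  expect_equal(as.numeric(b$end - b$start, units = "secs"), 9 * 240)

  det2 <- rbind(mk_detections("T1", "A", t0),
                mk_detections("T1", "B", t0 + 300),
                mk_detections("T1", "A", t0 + 600))
  expect_equal(nrow(bout_detections(det2, cfg)), 3L)

  det3 <- mk_detections("T1", "A", c(t0, t0 + 60, t0 + 7200, t0 + 7260))
  b3 <- bout_detections(det3, cfg)
  expect_equal(nrow(b3), 2L)
  expect_equal(b3$n_detections, c(2L, 2L))
})

test_that("bout membership conserves detections across tags", {
  set.seed(5)
  t0 <- as.numeric(utc("2019-05-02 08:00:00"))
  det <- do.call(rbind, lapply(c("T1", "T2", "T3"), function(tg) {
    mk_detections(tg, sample(c("A", "B"), 30, TRUE),
                  t0 + sort(runif(30, 0, 86400)))
  }))
  b <- bout_detections(det, cfg)
  expect_equal(sum(b$n_detections), nrow(det))
})
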