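test_that("ZOC removes constant offsets and leaves clean records alone", {
  surface <- synthetic_dive_trace(rep(0.5, 600))
  z <- zero_offset_correct(surface)
  expect_lt(max(abs(z$depth_m)), 1e-9)
  clean <- synthetic_dive_trace(c(rep(0, 200), 0:20, rep(20, 50), 20:0,
                                  rep(0, 200)))
  z2 <- zero_offset_correct(clean)
  expect_lt(max(abs(z2$depth_m - clean$depth_m)), 1e-9)
})

test_that("ZOC tracks a linear drift against a rolling-quantile oracle", {
  set.seed(9)
  n <- 1800
  drift <- seq(0, 1, length.out = n)
  # ~50% surface time: alternating 60 s dives / 60 s surface
  cyc <- rep(c(rep(0, 60), rep(15, 60)), length.out = n)
  depth <- synthetic_dive_trace(cyc + drift)
  z <- zero_offset_correct(depth)
  surf <- which(cyc == 0)
  expect_lt(max(abs(z$depth_m[surf])), 0.1)
  # brute-force centred rolling 10th percentile oracle
  w <- 300; h <- w %/% 2
  oracle <- vapply(seq_len(n), function(i)
    quantile(depth$depth_m[max(1, i - h):min(n, i + h)], 0.1, names = FALSE),
    numeric(1))
  expect_equal(attr(z, "zoc_baseline"), oracle, tolerance = 1e-12)
})

test_that("ZOC window longer than record falls back to a global offset", {
  short <- synthetic_dive_trace(rep(0.3, 60))
  expect_warning(z <- zero_offset_correct(short), "global offset")
  expect_lt(max(abs(z$depth_m)), 1e-9)
})

test_that("segmentation finds forced square-wave dives exactly", {
  flat <- synthetic_dive_trace(runif(300, 0, 1.2))
  expect_equal(nrow(segment_dives(flat)), 0)
  sq <- synthetic_dive_trace(c(rep(0, 30), rep(10, 60), rep(0, 30)))
  d <- segment_dives(sq)
  expect_equal(nrow(d), 1)
  expect_equal(d$max_depth_m, 10)
  expect_equal(d$duration_s, 60)
  # sub-threshold and too-short runs are dropped
  blip <- synthetic_dive_trace(c(rep(0, 30), rep(10, 3), rep(0, 30)))
  expect_equal(nrow(segment_dives(blip)), 0)
})

test_that("segmentation recovers planted dives within 2 s", {
  td <- test_dives(1)
  truth <- td$sim$truth$dives
  dives <- td$dives
  expect_equal(nrow(dives), nrow(truth))
  expect_true(all(abs(as.numeric(dives$start) - as.numeric(truth$start))
                  <= 2))
  expect_true(all(abs(as.numeric(dives$end) - as.numeric(truth$end)) <= 2))
  expect_true(all(abs(dives$max_depth_m - truth$max_depth_m) < 0.25))
  # segmentation is a partition: disjoint ordered intervals
  expect_true(all(diff(as.numeric(dives$start)) > 0))
  expect_true(all(as.numeric(dives$start)[-1] >=
                    as.numeric(dives$end)[-nrow(dives)]))
  # post-dive interval is the gap to the next dive
  expect_equal(dives$post_dive_interval_s[-nrow(dives)],
               as.numeric(dives$start[-1]) -
                 as.numeric(dives$end[-nrow(dives)]))
})

test_that("dive phases match an exhaustive scan oracle", {
  # symmetric V-dive (steep flanks): bottom at most 2 samples
  v <- synthetic_dive_trace(c(rep(0, 10), seq(0, 12, 3), seq(9, 0, -3),
                              rep(0, 10)))
  dv <- dive_phases(segment_dives(v), v)
  expect_lte(dv$bottom_s, 2)
  # trapezoid with a 20 s flat bottom at max depth
  tz <- synthetic_dive_trace(c(rep(0, 10), seq(0, 15, 5), rep(20, 20),
                               seq(15, 0, -5), rep(0, 10)))
  dt <- dive_phases(segment_dives(tz), tz)
  expect_lte(abs(dt$bottom_s - 20), 1)
  # random profiles vs brute-force index search
  set.seed(21)
  for (rep in 1:5) {
    prof <- c(rep(0, 5), 2 + cumsum(runif(40, -2, 2.5)), rep(0, 5))
    prof <- pmax(prof, 0)
    tr <- synthetic_dive_trace(prof)
    d <- segment_dives(tr, min_duration_s = 3)
    if (nrow(d) == 0) next
    dp <- dive_phases(d, tr)
    for (i in seq_len(nrow(d))) {
      idx <- which(as.numeric(tr$time) >= as.numeric(d$start[i]) &
                     as.numeric(tr$time) < as.numeric(d$end[i]))
      dd <- tr$depth_m[idx]
      at_b <- which(dd >= 0.8 * max(dd))
      expect_equal(dp$descent_s[i], at_b[1] - 1)
      expect_equal(dp$bottom_s[i], at_b[length(at_b)] - at_b[1] + 1)
      expect_equal(dp$descent_s[i] + dp$bottom_s[i] + dp$ascent_s[i],
                   dp$duration_s[i])
    }
  }
})

test_that("trip dive statistics follow their definitions", {
  one <- synthetic_dive_trace(c(rep(0, 10), rep(30, 20), rep(0, 10)))
  d <- segment_dives(one)
  s <- trip_dive_stats(d, 2)
  expect_equal(s$vertical_distance_km, 60 / 1000)
  expect_equal(s$dive_rate_per_h, 0.5)
  empty <- segment_dives(synthetic_dive_trace(rep(0, 100)))
  expect_equal(unlist(trip_dive_stats(empty, 4)),
               c(vertical_distance_km = 0, dive_rate_per_h = 0,
                 time_diving_h = 0))
  expect_error(trip_dive_stats(d, 0), "positive")
})
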