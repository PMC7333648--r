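t0 <- as.POSIXct("2020-01-01", tz = "UTC")

fake_dives <- function(n, type = "benthic", vedba = 400, dur = 100) {
  data.frame(index = seq_len(n), start = t0 + (seq_len(n) - 1) * 200,
             end = t0 + (seq_len(n) - 1) * 200 + dur,
             duration_s = dur, max_depth_m = 30, bottom_s = 20,
             total_vedba = vedba, mean_vedba = vedba / (dur * 25),
             missing_effort = FALSE, type = type)
}

fake_events <- function(dive_idx, depth = 25) {
  data.frame(time = t0 + dive_idx * 200, depth_m = depth,
             dive_idx = dive_idx, n_windows = 3)
}

test_that("per-dive scoring follows the FEI/DE definitions", {
  dives <- fake_dives(3)
  m <- score_dives(dives, fake_events(c(1, 1)))   # 2 captures in dive 1
  expect_equal(m$n_captures, c(2, 0, 0))
  expect_equal(m$success, c(1, 0, 0))
  expect_equal(m$fei[1], 2 / 400)
  expect_equal(m$de[1], 2 / 100)
  expect_equal(m$log_fei[1], log(0.005))
  # zero-capture dives: success 0, fei 0, log transforms undefined
  expect_equal(m$fei[2], 0)
  expect_true(is.na(m$log_fei[2]))
  expect_true(is.na(m$log_de[3]))
  # capture conservation
  expect_equal(sum(m$n_captures), 2)
  # missing effort propagates to FEI but the dive is retained
  dv <- fake_dives(1); dv$total_vedba <- NA; dv$missing_effort <- TRUE
  m2 <- score_dives(dv, fake_events(1))
  expect_true(is.na(m2$fei))
  expect_equal(m2$n_captures, 1)
})

test_that("capture rates aggregate per animal then across animals", {
  m1 <- score_dives(fake_dives(4), fake_events(c(1, 2, 3, 4)),
                    animal_id = "a1")
  m2 <- score_dives(fake_dives(4), fake_events(c(1, 1, 2, 3)),
                    animal_id = "a2")
  r <- capture_rates(rbind(m1, m2))
  expect_equal(r$n_animals, 2)
  expect_equal(r$n_dives, 8)
  # two-stage oracle: mean of per-animal means
  expect_equal(r$capture_rate, mean(c(1, 1)))
  expect_equal(r$pct_successful, mean(c(100, 75)))
  expect_equal(r$pct_successful_se,
               100 * sd(c(1, 0.75)) / sqrt(2))
  # one animal, all rates equal -> SE 0
  r1 <- capture_rates(m1)
  expect_equal(r1$capture_rate_se, 0)
})

test_that("capture-depth correlation behaves at analytic extremes", {
  dives <- fake_dives(10)
  dives$max_depth_m <- seq(20, 65, 5)
  # captures exactly at max depth -> r = 1
  ev <- fake_events(1:10, depth = dives$max_depth_m)
  expect_equal(capture_depth_correlation(ev, dives), 1)
  # captures at a constant depth across varying dives -> r = 0 (sd zero in
  # one margin gives NA; use a hair of noise and check |r| small)
  set.seed(1)
  ev2 <- fake_events(1:10, depth = 15 + rnorm(10, 0, 1e-6))
  expect_lt(abs(capture_depth_correlation(ev2, dives)), 0.5)
  expect_error(capture_depth_correlation(fake_events(1), dives),
               "insufficient")
  # type restriction: pelagic events ignored
  dives$type[6:10] <- "pelagic"
  ev3 <- fake_events(1:10, depth = dives$max_depth_m)
  expect_equal(capture_depth_correlation(ev3, dives, "benthic"), 1)
})

test_that("summary table conserves totals and mirrors group-by oracle", {
  m1 <- score_dives(fake_dives(3), fake_events(c(1, 2)),
                    animal_id = "a1", colony = "SC", sex = "F")
  m2 <- score_dives(fake_dives(3, type = "pelagic"), fake_events(1),
                    animal_id = "a2", colony = "SC", sex = "M")
  met <- rbind(m1, m2)
  ev <- rbind(cbind(fake_events(c(1, 2)), animal_id = "a1"),
              cbind(fake_events(1), animal_id = "a2"))
  s <- summary_table(met, ev)
  expect_equal(sum(s$total_prey), sum(met$n_captures))
  expect_equal(sum(s$n_dives), nrow(met))
  row_b <- s[s$type == "benthic", ]
  expect_equal(row_b$pct_successful, 100 * 2 / 3)
  expect_equal(row_b$mean_capture_depth_m, 25)
})

test_that("model table export keeps schema and drops excluded dives", {
  m <- score_dives(fake_dives(4), fake_events(1))
  m$type[4] <- "excluded"
  out <- export_model_table(m)
  expect_equal(nrow(out), 3)
  expect_named(out, c("animal_id", "colony", "sex", "type", "max_depth_m",
                      "duration_s", "predator_context", "success",
                      "n_captures", "fei", "de", "log_fei", "log_de"))
  # FEI/DE invariant to time translation of the record
  dv2 <- fake_dives(4); dv2$start <- dv2$start + 86400
  dv2$end <- dv2$end + 86400
  ev2 <- fake_events(1); ev2$time <- ev2$time + 86400
  m2 <- score_dives(dv2, ev2)
  expect_equal(m2$fei, m$fei)
  expect_equal(m2$de, m$de)
})
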