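fake_derived <- function(dyn, hz = 25) {
  structure(list(time = as.POSIXct("2020-01-01", tz = "UTC") +
                   (0:(nrow(dyn) - 1)) / hz,
                 static = matrix(0, nrow(dyn), 3), dynamic = dyn,
                 vedba = sqrt(rowSums(dyn^2)), sample_hz = hz),
            class = "accel_derived")
}

test_that("window features match a direct per-window oracle", {
  set.seed(2)
  dyn <- matrix(rnorm(80 * 3), 80, 3)
  der <- fake_derived(dyn)
  fw <- extract_features(der, window = 8, stride = 8)
  expect_equal(nrow(fw$features), 10)  # 80 samples, stride 8
  chan <- cbind(dyn, der$vedba)
  for (w in c(1, 4, 10)) {
    seg <- chan[((w - 1) * 8 + 1):(w * 8), ]
    for (c in 1:4) {
      x <- seg[, c]
      m2 <- mean((x - mean(x))^2)
      expect_equal(unname(fw$features[w, (c - 1) * 6 + 1:6]),
                   c(mean(x), sd(x), min(x), max(x),
                     mean((x - mean(x))^3) / m2^1.5,
                     mean((x - mean(x))^4) / m2^2 - 3),
                   tolerance = 1e-10)
    }
  }
  # constant window: sd 0, min = max = mean, shape stats 0 by convention
  cw <- extract_features(fake_derived(matrix(1, 20, 3)))
  expect_equal(unname(cw$features[1, 1:6]), c(1, 0, 1, 1, 0, 0))
  # record shorter than the window
  expect_length(extract_features(fake_derived(matrix(0, 5, 3)))$start_index,
                0)
})

test_that("window labelling equals an interval-overlap oracle", {
  der <- fake_derived(matrix(0, 250, 3))
  fw <- extract_features(der)
  # no truth -> all swim
  expect_false(any(label_windows(fw, numeric(0))$label_capture))
  # one event mid-record: exactly the overlapping windows are positive
  ev <- der$time[125]
  lab <- label_windows(fw, ev, tolerance_s = 0.5)
  oracle <- fw$time_start - 0.5 <= as.numeric(ev) &
    fw$time_end + 0.5 >= as.numeric(ev)
  expect_equal(lab$label_capture, oracle)
  expect_gt(sum(oracle), 0)
  # several random events
  set.seed(6)
  evs <- sort(as.numeric(der$time[1]) + runif(5, 0, 9.9))
  lab2 <- label_windows(fw, evs, tolerance_s = 0.5)
  oracle2 <- vapply(seq_along(fw$start_index), function(i)
    any(evs >= fw$time_start[i] - 0.5 & evs <= fw$time_end[i] + 0.5),
    logical(1))
  expect_equal(lab2$label_capture, oracle2)
})

test_that("training-set downsampling keeps the 5:1 contract", {
  set.seed(4)
  fw <- extract_features(fake_derived(matrix(rnorm(3000), 1000, 3)))
  fw$label_capture <- seq_along(fw$start_index) <= 100
  ts <- build_training_set(fw, ratio = 5, seed = 9)
  expect_equal(sum(ts$y), 100)
  expect_equal(sum(!ts$y), 500)
  # determinism
  ts2 <- build_training_set(fw, ratio = 5, seed = 9)
  expect_identical(ts, ts2)
  # too few swim windows: all kept, with warning
  fw$label_capture <- seq_along(fw$start_index) <= 900
  expect_warning(ts3 <- build_training_set(fw, 5, 1), "keeping all")
  expect_equal(sum(!ts3$y), length(fw$start_index) - 900)
  fw$label_capture <- rep(FALSE, length(fw$label_capture))
  expect_error(build_training_set(fw, 5, 1), "no capture windows")
})

test_that("detector is near-perfect on separable features", {
  set.seed(10)
  n <- 120
  x <- rbind(matrix(rnorm(n * 4, 0, 1), n, 4),
             matrix(rnorm(n / 2 * 4, 8, 1), n / 2, 4))
  y <- c(rep(FALSE, n), rep(TRUE, n / 2))
  det <- train_detector(x, y, folds = 5, cost_grid = c(1, 10),
                        gamma_grid = c(0.01, 0.1), seed = 2)
  acc <- det$cv_metrics$mean[det$cv_metrics$metric == "accuracy"]
  expect_gte(acc, 0.98)
})

test_that("permuted labels fall to the majority baseline", {
  # at 5:1 class ratio a majority-predicting fit gives ~5/6 accuracy and
  # ~zero recall; permuting labels destroys all signal
  set.seed(20)
  n_cap <- 40
  x <- matrix(rnorm((n_cap * 6) * 4), ncol = 4)
  y <- sample(c(rep(TRUE, n_cap), rep(FALSE, 5 * n_cap)))
  det <- train_detector(x, y, folds = 5, cost_grid = c(0.1, 1),
                        gamma_grid = c(0.01, 0.1), seed = 3)
  acc <- det$cv_metrics$mean[det$cv_metrics$metric == "accuracy"]
  rec <- det$cv_metrics$mean[det$cv_metrics$metric == "recall"]
  expect_lt(abs(acc - 5 / 6), 0.07)
  expect_lt(rec, 0.25)
})

test_that("prediction is deterministic and checks feature arity", {
  set.seed(30)
  x <- rbind(matrix(rnorm(400), 100, 4), matrix(rnorm(200, 5), 50, 4))
  y <- c(rep(FALSE, 100), rep(TRUE, 50))
  det <- train_detector(x, y, folds = 3, cost_grid = 1, gamma_grid = 0.1,
                        seed = 1)
  dyn <- matrix(rnorm(600), 200, 3)
  der <- fake_derived(dyn)
  expect_error(predict_captures(det, der), "model mismatch")
  # matching arity: build a detector on real 24-dim features
  fw <- extract_features(der)
  fw$label_capture <- fw$features[, "vedba_max"] >
    quantile(fw$features[, "vedba_max"], 0.9)
  ts <- build_training_set(fw, 5, 1)
  det24 <- train_detector(ts$x, ts$y, folds = 3, cost_grid = 10,
                          gamma_grid = 0.1, seed = 1)
  p1 <- predict_captures(det24, der)
  p2 <- predict_captures(det24, der)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), nrow(fw$features))
  # empty record -> empty predictions
  p0 <- predict_captures(det24, fake_derived(matrix(0, 4, 3)))
  expect_equal(nrow(p0), 0)
})

test_that("event consolidation merges runs and assigns dives", {
  t0 <- as.POSIXct("2020-01-01", tz = "UTC")
  mkpred <- function(idx) {
    data.frame(start_index = idx,
               time_start = as.numeric(t0) + (idx - 1) / 25,
               time_end = as.numeric(t0) + (idx + 6) / 25,
               decision = 1, capture = TRUE)
  }
  dives <- data.frame(index = 1L, start = t0, end = t0 + 60)
  depth <- synthetic_dive_trace(rep(10, 120), t0 = t0)
  # one 6-window run -> one event (explicit permissive min_run)
  ev <- consolidate_events(mkpred(10:15), dives, depth, min_run = 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_windows, 6)
  expect_equal(ev$dive_idx, 1L)
  # two runs separated by 50 samples -> two events
  ev2 <- consolidate_events(mkpred(c(10:15, 70:76)), dives, depth,
                            min_run = 2)
  expect_equal(nrow(ev2), 2)
  # runs separated by <= max_gap merge
  ev3 <- consolidate_events(mkpred(c(10:12, 18:20)), dives, depth,
                            min_run = 2)
  expect_equal(nrow(ev3), 1)
  # single-window flicker dropped
  ev4 <- consolidate_events(mkpred(c(10, 40)), dives, depth, min_run = 2)
  expect_equal(nrow(ev4), 0)
  # default min_run drops any run a single hot sample could explain
  ev4b <- consolidate_events(mkpred(10:17), dives, depth)
  expect_equal(nrow(ev4b), 0)
  ev4c <- consolidate_events(mkpred(10:25), dives, depth)
  expect_equal(nrow(ev4c), 1)
  # event outside any dive discarded and counted
  far <- mkpred(25 * 80 + (0:5))
  ev5 <- consolidate_events(far, dives, depth, min_run = 2)
  expect_equal(nrow(ev5), 0)
  expect_equal(attr(ev5, "n_outside_dives"), 1L)
})

test_that("event evaluation matches an exhaustive matching oracle", {
  t0 <- as.POSIXct("2020-01-01", tz = "UTC")
  truth <- t0 + c(10, 20, 30)
  ev <- evaluate_events(truth, truth, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  none <- evaluate_events(as.POSIXct(character(0)), truth, 1)
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 0)
  expect_true(none$undefined_precision)
  # small random cases vs brute-force optimal assignment
  set.seed(40)
  for (rep in 1:10) {
    p <- runif(4, 0, 20); tr <- runif(4, 0, 20)
    got <- evaluate_events(p, tr, 1)
    # brute force: maximum one-to-one matching within tolerance
    best <- 0
    perms <- expand.grid(rep(list(1:4), 4))
    for (r in seq_len(nrow(perms))) {
      pe <- unlist(perms[r, ])
      if (anyDuplicated(pe)) next
      best <- max(best, sum(abs(p - tr[pe]) <= 1))
    }
    expect_equal(got$tp, best)
  }
})
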