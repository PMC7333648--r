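test_that("bathymetry generation is deterministic, bounded and shaped", {
  b1 <- generate_bathymetry(seed = 3, depth_range = c(0, 90),
                            n_cells = c(50, 50))
  b2 <- generate_bathymetry(seed = 3, depth_range = c(0, 90),
                            n_cells = c(50, 50))
  expect_identical(b1, b2)
  expect_equal(dim(b1$seafloor_depth), c(50, 50))
  expect_length(b1$lon_axis, 50)
  expect_true(all(b1$seafloor_depth <= 90))
  expect_gt(sum(b1$seafloor_depth > 15), 0)
  # colony cell is land
  expect_error(lookup_seafloor(b1, 25.80, -33.79), "land")
  expect_error(generate_bathymetry(extent = c(1, 1, 0, 1)), "degenerate")
  expect_error(generate_bathymetry(depth_range = c(0, 10)), ">= 20")
})

test_that("simulation is reproducible and respects stream invariants", {
  s1 <- simulate_trip(test_sim_config(5), test_bathy())
  s2 <- simulate_trip(test_sim_config(5), test_bathy())
  expect_identical(s1, s2)
  trip <- s1$trip
  for (stream in list(trip$gps, trip$depth, trip$accel))
    expect_true(all(diff(as.numeric(stream$time)) > 0))
  expect_true(all(trip$depth$depth_m >= -0.5))
  # every capture lies inside exactly one truth dive window
  tr <- s1$truth
  for (i in seq_len(nrow(tr$captures))) {
    inside <- sum(tr$captures$time[i] >= tr$dives$start &
                    tr$captures$time[i] <= tr$dives$end)
    expect_equal(inside, 1)
  }
  # benthic windows respect the configured seafloor ratio range (seafloor
  # as seen by the generator at the dive position)
  ben <- tr$dives[tr$dives$type == "benthic", ]
  ratio <- ben$max_depth_m / ben$seafloor_m
  expect_true(all(ratio > 0.8 & ratio <= 1))
})

test_that("zero dive rate yields a flat surface trace", {
  sim <- simulate_trip(test_sim_config(2, dive_rate_per_h = 0), test_bathy())
  expect_equal(nrow(sim$truth$dives), 0)
  expect_true(all(sim$trip$depth$depth_m < 1.5))
})

test_that("planted capture counts follow the configured rates (LLN)", {
  # pool several trips; compare per-type mean captures/dive to the
  # configured intensity within 3 standard errors
  nc_b <- nc_p <- c()
  for (seed in 1:4) {
    tr <- test_trip(seed)$truth
    nc <- tabulate(factor(tr$captures$dive_idx,
                          levels = seq_len(nrow(tr$dives))),
                   nbins = nrow(tr$dives))
    nc_b <- c(nc_b, nc[tr$dives$type == "benthic"])
    nc_p <- c(nc_p, nc[tr$dives$type == "pelagic"])
  }
  se <- function(v) sd(v) / sqrt(length(v))
  expect_lt(abs(mean(nc_b) - 1.2), 3 * se(nc_b))
  expect_lt(abs(mean(nc_p) - 0.4), 3 * se(nc_p))
  # success fractions match the hurdle probabilities
  expect_lt(abs(mean(nc_b > 0) - 0.60), 3 * se(nc_b > 0))
  expect_lt(abs(mean(nc_p > 0) - 0.23), 3 * se(nc_p > 0))
})

test_that("planted benthic dives satisfy the typing rule by construction", {
  # ratio > 0.8 and within 10% of an adjacent dive, >= 99% of cases
  ok <- total <- 0
  for (seed in 1:4) {
    sim <- test_trip(seed)
    tr <- sim$truth$dives
    sf <- tr$seafloor_m
    n <- nrow(tr)
    prev <- c(NA, tr$max_depth_m[-n]); nxt <- c(tr$max_depth_m[-1], NA)
    for (i in which(tr$type == "benthic")) {
      tol <- 0.1 * tr$max_depth_m[i]
      sim_ok <- (!is.na(prev[i]) && abs(tr$max_depth_m[i] - prev[i]) <= tol) ||
        (!is.na(nxt[i]) && abs(tr$max_depth_m[i] - nxt[i]) <= tol)
      ok <- ok + (tr$max_depth_m[i] / sf[i] > 0.8 && sim_ok)
      total <- total + 1
    }
  }
  expect_gte(ok / total, 0.99)
})

test_that("fixtures round-trip losslessly through the io module", {
  sim <- test_trip(1)
  dir <- withr::local_tempdir()
  write_fixture(sim$trip, sim$truth, test_bathy(), dir)
  trip2 <- read_sensors(dir)
  expect_equal(trip2$animal_id, sim$trip$animal_id)
  for (stream in c("gps", "depth", "accel")) {
    expect_equal(as.numeric(trip2[[stream]]$time),
                 as.numeric(sim$trip[[stream]]$time), tolerance = 1e-3)
    num <- setdiff(names(sim$trip[[stream]]), "time")
    expect_equal(as.data.frame(trip2[[stream]])[num],
                 as.data.frame(sim$trip[[stream]])[num], tolerance = 1e-7)
  }
  truth2 <- read_truth(dir)
  expect_equal(nrow(truth2$captures), nrow(sim$truth$captures))
  bathy2 <- read_bathymetry(file.path(dir, "bathymetry.asc"))
  expect_equal(bathy2$seafloor_depth, test_bathy()$seafloor_depth,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(bathy2$lon_axis, test_bathy()$lon_axis, tolerance = 1e-9)
})

test_that("empty truth writes a header-only captures file", {
  sim <- simulate_trip(test_sim_config(2, dive_rate_per_h = 0), test_bathy())
  dir <- withr::local_tempdir()
  write_fixture(sim$trip, sim$truth, NULL, dir)
  lines <- readLines(file.path(dir, "truth_captures.csv"))
  expect_length(lines, 1)
  truth2 <- read_truth(dir)
  expect_equal(nrow(truth2$captures), 0)
})
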