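# Shared fixtures. Built once per test run and cached; everything is
# generated in code (no stored binary data) and kept small so the whole
# suite stays fast: a steep near-colony shelf lets a short trip reach
# diveable water in minutes.

.fixture_cache <- new.env(parent = emptyenv())

test_bathy <- function(seed = 7) {
  key <- paste0("bathy", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_bathymetry(
      seed = seed,
      extent = c(25.70, 25.90, -33.95, -33.77),
      depth_range = c(0, 60),
      n_cells = c(80, 80),
      colony_lonlat = c(25.80, -33.79),
      offshore_km = 2.5)
  .fixture_cache[[key]]
}

# short trip over the steep test shelf; ~25-40 dives in ~45 min
test_sim_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, trip_duration_h = 0.75, dive_rate_per_h = 45,
         colony_exclusion_km = 0.4, transit_speed_kmh = 6),
    list(...))
  do.call(sim_config, args)
}

test_trip <- function(seed = 1) {
  key <- paste0("trip", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_trip(test_sim_config(seed),
                                           test_bathy())
  .fixture_cache[[key]]
}

test_typing_config <- function(...) {
  typing_config(colony_exclusion_km = 0.4,
                colony_lonlat = c(25.80, -33.79), ...)
}

test_pipeline_config <- function(...) {
  pipeline_config(
    typing = list(colony_exclusion_km = 0.4,
                  colony_lonlat = c(25.80, -33.79)),
    ...)
}

# dive table + corrected depth for one cached trip
test_dives <- function(seed = 1) {
  key <- paste0("dives", seed)
  if (is.null(.fixture_cache[[key]])) {
    sim <- test_trip(seed)
    depth <- zero_offset_correct(sim$trip$depth)
    dives <- dive_phases(segment_dives(depth), depth)
    .fixture_cache[[key]] <- list(depth = depth, dives = dives, sim = sim)
  }
  .fixture_cache[[key]]
}

# accel derived (static/dynamic/vedba) for one cached trip
test_derived <- function(seed = 1) {
  key <- paste0("derived", seed)
  if (is.null(.fixture_cache[[key]])) {
    sim <- test_trip(seed)
    .fixture_cache[[key]] <- compute_vedba(split_static_dynamic(sim$trip$accel))
  }
  .fixture_cache[[key]]
}

# hand-built V or trapezoid depth profile at 1 Hz
synthetic_dive_trace <- function(depths, t0 = as.POSIXct("2020-01-01",
                                                         tz = "UTC")) {
  data.frame(time = t0 + seq_along(depths) - 1, depth_m = depths)
}
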