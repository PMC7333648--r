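#' Simulation configuration
#'
#' Defaults describe a guard-stage foraging trip of an African penguin in
#' a south-facing bay: ~23 h at sea, ~25 dives per hour, a quarter of
#' dives benthic, planted prey-capture intensities of 1.2 (benthic) and
#' 0.4 (pelagic) captures per dive with per-dive success probabilities of
#' 0.60 and 0.23, swim noise of 0.2 g and capture bursts of 1.5 g, depth
#' sampled at 1 Hz and acceleration at 25 Hz.
#'
#' Capture counts follow a hurdle model: a dive is successful with the
#' type-specific probability, and a successful dive receives
#' `1 + Poisson(rate/p - 1)` captures, so the per-dive mean equals the
#' configured rate while the success fraction equals `p`.
#'
#' @param seed Integer RNG seed; every stream is reproducible from it.
#' @param colony_lonlat Colony position `c(lon, lat)`.
#' @param trip_duration_h Trip duration, hours.
#' @param dive_rate_per_h Nominal dives per hour of trip.
#' @param frac_benthic Long-run fraction of dives that are benthic.
#' @param capture_rate_benthic,capture_rate_pelagic Mean planted captures
#'   per dive by type.
#' @param success_prob_benthic,success_prob_pelagic Probability a dive of
#'   each type has at least one capture. Must satisfy `rate/p >= 1`.
#' @param capture_burst_amplitude_g Peak amplitude of the capture burst.
#' @param swim_noise_sd_g SD of Gaussian swim noise per dynamic axis.
#' @param depth_sample_hz,accel_sample_hz Sampling rates; acceleration
#'   must be sampled faster than depth.
#' @param benthic_ratio_range Range the benthic max-depth/seafloor ratio
#'   is drawn from; must lie in (0.8, 1].
#' @param colony_exclusion_km No dives are planted within this radius.
#' @param transit_speed_kmh,forage_speed_kmh Horizontal swim speeds.
#' @param descent_rate_ms Vertical descent/ascent rate, m/s.
#' @param gps_interval_s,gps_noise_m GPS sampling interval and position
#'   noise.
#' @param depth_drift_m Linear pressure-sensor drift over the trip
#'   (removed downstream by zero-offset correction).
#' @param animal_id,colony,sex Metadata labels.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       colony_lonlat = c(25.80, -33.79),
                       trip_duration_h = 23.09,
                       dive_rate_per_h = 25,
                       frac_benthic = 0.25,
                       capture_rate_benthic = 1.2,
                       capture_rate_pelagic = 0.4,
                       success_prob_benthic = 0.60,
                       success_prob_pelagic = 0.23,
                       capture_burst_amplitude_g = 1.5,
                       swim_noise_sd_g = 0.2,
                       depth_sample_hz = 1,
                       accel_sample_hz = 25,
                       benthic_ratio_range = c(0.85, 0.98),
                       colony_exclusion_km = 2,
                       transit_speed_kmh = 5,
                       forage_speed_kmh = 1.5,
                       descent_rate_ms = 1.2,
                       gps_interval_s = 60,
                       gps_noise_m = 10,
                       depth_drift_m = 0.3,
                       animal_id = "sim01",
                       colony = "SC",
                       sex = "F") {
  cfg <- as.list(environment())
  stopifnot(cfg$dive_rate_per_h >= 0, cfg$capture_rate_benthic >= 0,
            cfg$capture_rate_pelagic >= 0,
            cfg$frac_benthic >= 0, cfg$frac_benthic <= 1,
            cfg$accel_sample_hz > cfg$depth_sample_hz,
            cfg$benthic_ratio_range[1] > 0.8,
            cfg$benthic_ratio_range[2] <= 1,
            diff(cfg$benthic_ratio_range) >= 0)
  for (ty in c("benthic", "pelagic")) {
    r <- cfg[[paste0("capture_rate_", ty)]]
    p <- cfg[[paste0("success_prob_", ty)]]
    if (r > 0 && (p <= 0 || p > 1 || r / p < 1))
      stop("capture_rate_", ty, " / success_prob_", ty,
           " must be >= 1 for the hurdle count model")
  }
  structure(cfg, class = "sim_config")
}

.sf_at <- function(bathy, lon, lat) {
  # unchecked nearest-cell lookup (simulator hot path)
  dlon <- bathy$lon_axis[2] - bathy$lon_axis[1]
  dlat <- bathy$lat_axis[2] - bathy$lat_axis[1]
  i <- min(max(round((lat - bathy$lat_axis[1]) / dlat) + 1, 1),
           length(bathy$lat_axis))
  j <- min(max(round((lon - bathy$lon_axis[1]) / dlon) + 1, 1),
           length(bathy$lon_axis))
  bathy$seafloor_depth[i, j]
}

# n points in [lo, hi] at least `gap` apart (separate prey chases produce
# distinct bursts; keeps planted events from merging during consolidation)
.draw_spaced <- function(n, lo, hi, gap = 3) {
  if (n == 1) return(runif(1, lo, hi))
  if (hi - lo <= gap * (n - 1))
    return(seq(lo, hi, length.out = n))
  for (try in 1:100) {
    x <- sort(runif(n, lo, hi))
    if (all(diff(x) >= gap)) return(x)
  }
  seq(lo, hi, length.out = n)
}

#' Simulate one complete foraging trip with ground truth
#'
#' Generates a continuous swim path (colony -> offshore -> meandering
#' foraging -> colony), plants dives along the foraging section, and
#' renders synchronized GPS, 1 Hz depth and 25 Hz tri-axial acceleration
#' streams. Benthic dives track the seafloor (max depth a fraction of the
#' local seafloor drawn from `benthic_ratio_range`) and occur in runs of
#' at least two consecutive similar-depth dives; pelagic dive depths are
#' drawn independently. Each planted capture adds a 0.5-2 s band-limited
#' burst of the configured amplitude on all three dynamic axes; benthic
#' captures sit in the bottom phase. The recorded depth carries a linear
#' sensor drift so zero-offset correction has work to do. Byte-identical
#' output for a fixed seed.
#'
#' @param cfg A [sim_config].
#' @param bathy A [bathymetry_grid] containing the colony.
#' @return List with `trip` (class `trip_record`: `animal_id`, `colony`,
#'   `sex`, `gps`, `depth`, `accel`) and `truth` (class `synthetic_truth`:
#'   `dives` with start/end/type/max_depth_m, `captures` with
#'   time/depth_m/dive_idx).
#' @export
simulate_trip <- function(cfg, bathy) {
  stopifnot(inherits(cfg, "sim_config"), inherits(bathy, "bathymetry_grid"))
  .df_local_seed(cfg$seed, .simulate_trip_impl(cfg, bathy))
}

.simulate_trip_impl <- function(cfg, bathy) {
  t0 <- as.POSIXct("2017-05-01 04:00:00", tz = "UTC")
  n1 <- round(cfg$trip_duration_h * 3600)
  if (n1 < 60) stop("simulation failure: trip shorter than one minute")

  # offshore attractor: the nearest comfortably diveable cell (the bird
  # needs water deep enough to forage in, not the deepest water around)
  colony <- cfg$colony_lonlat
  want <- min(0.5 * max(bathy$seafloor_depth), 28)
  deep <- which(bathy$seafloor_depth >= want, arr.ind = TRUE)
  if (nrow(deep) == 0)
    stop("simulation failure: bathymetry has no cell deeper than ", want,
         " m")
  dd <- gc_distance_km(bathy$lon_axis[deep[, 2]], bathy$lat_axis[deep[, 1]],
                       colony[1], colony[2])
  dp <- deep[which.min(dd), ]
  target <- c(bathy$lon_axis[dp[2]], bathy$lat_axis[dp[1]])

  lon <- numeric(n1); lat <- numeric(n1)
  lon[1] <- colony[1]; lat[1] <- colony[2]
  phase <- integer(n1)  # 1 outbound, 2 forage, 3 return, 4 done
  ph <- 1L
  brg <- atan2(target[1] - colony[1], target[2] - colony[2])
  v_tr <- cfg$transit_speed_kmh / 3600
  v_fo <- cfg$forage_speed_kmh / 3600
  min_sf <- 18
  for (i in 2:n1) {
    here_sf <- .sf_at(bathy, lon[i - 1], lat[i - 1])
    d_col <- gc_distance_km(lon[i - 1], lat[i - 1], colony[1], colony[2])
    t_left <- n1 - i
    if (ph < 3L && t_left <= (d_col / v_tr) * 1.2 + 120) ph <- 3L
    if (ph == 1L && d_col >= cfg$colony_exclusion_km + 0.3 &&
        here_sf >= min_sf + 2) ph <- 2L
    if (ph == 1L) {
      brg <- 0.9 * brg + 0.1 * atan2(target[1] - lon[i - 1],
                                     target[2] - lat[i - 1]) +
        rnorm(1, 0, 0.05)
      v <- v_tr
    } else if (ph == 2L) {
      pull <- if (here_sf < min_sf + 4)
        atan2(target[1] - lon[i - 1], target[2] - lat[i - 1])
      else if (here_sf > 0.85 * max(bathy$seafloor_depth))
        atan2(colony[1] - lon[i - 1], colony[2] - lat[i - 1])
      else brg
      brg <- 0.98 * brg + 0.02 * pull + rnorm(1, 0, 0.08)
      v <- v_fo
    } else {
      brg <- atan2(colony[1] - lon[i - 1], colony[2] - lat[i - 1])
      v <- v_tr
      if (d_col < 0.05) ph <- 4L
    }
    if (ph == 4L) {
      lon[i] <- colony[1]; lat[i] <- colony[2]; phase[i] <- 4L
      next
    }
    step <- v  # km per second times dt = 1 s
    nlat <- lat[i - 1] + step * cos(brg) / 111.32
    nlon <- lon[i - 1] + step * sin(brg) / (111.32 * cos(nlat * pi / 180))
    # stay inside the grid
    nlon <- min(max(nlon, bathy$lon_axis[1]), tail(bathy$lon_axis, 1))
    nlat <- min(max(nlat, bathy$lat_axis[1]), tail(bathy$lat_axis, 1))
    lon[i] <- nlon; lat[i] <- nlat; phase[i] <- ph
  }
  if (!any(phase == 2L) && cfg$dive_rate_per_h > 0)
    stop("simulation failure: trip never reached water deep enough to dive",
         " (seafloor >= ", min_sf, " m beyond the colony exclusion)")

  # ---- plant dives along the foraging section --------------------------
  depth_true <- pmax(-0.4, pmin(0.45, rnorm(n1, 0, 0.12)))  # surface wobble
  vd <- cfg$descent_rate_ms
  dives <- list(); caps <- list()
  n_target <- round(cfg$dive_rate_per_h * cfg$trip_duration_h)
  if (n_target > 0 && any(phase == 2L)) {
    i_f0 <- which(phase == 2L)[1]
    i_f1 <- max(which(phase == 2L))
    cycle <- (i_f1 - i_f0) / n_target
    mb <- 4; mp <- 3  # mean benthic / pelagic block lengths
    f <- cfg$frac_benthic
    q_benthic <- if (f >= 1) 1 else f * mp / (mb - f * mb + f * mp)
    block_type <- NULL; block_left <- 0L; run_ratio <- NA
    prev_benthic_D <- NA
    t <- i_f0 + round(runif(1, 5, 20))
    k <- 0L
    while (t < i_f1) {
      sf <- .sf_at(bathy, lon[t], lat[t])
      if (sf < min_sf) { t <- t + 30; next }
      if (block_left <= 0L) {
        est_dur <- 2 * 0.9 * sf / vd + 25
        benthic_ok <- (i_f1 - t) > 2 * (est_dur + 8)
        if (runif(1) < q_benthic && benthic_ok) {
          block_type <- "benthic"; block_left <- 2L + rpois(1, 2)
          run_ratio <- runif(1, cfg$benthic_ratio_range[1],
                             cfg$benthic_ratio_range[2])
          prev_benthic_D <- NA
        } else {
          block_type <- "pelagic"; block_left <- 1L + rpois(1, 2)
        }
      }
      if (block_type == "benthic") {
        ratio <- min(cfg$benthic_ratio_range[2],
                     max(cfg$benthic_ratio_range[1],
                         run_ratio * (1 + runif(1, -0.02, 0.02))))
        D <- ratio * sf
        # hold consecutive run depths within 8%: over a steep shelf the
        # seafloor itself can drift several percent between dives, and the
        # classification rule requires adjacent similarity within 10%
        if (!is.na(prev_benthic_D) && block_left > 0L) {
          D <- min(max(D, 0.92 * prev_benthic_D), 1.08 * prev_benthic_D)
          D <- min(max(D, 0.81 * sf), 0.99 * sf)
        }
        prev_benthic_D <- D
        tb <- runif(1, 15, 35)
      } else {
        # min depth 5.5 m: a shallower V-dive spends < 5 samples above
        # the 1.5 m threshold and would be invisible to the segmenter
        D <- min(max(5.5, rlnorm(1, log(9), 0.45)), 0.7 * sf - 1)
        tb <- if (runif(1) < 0.5) runif(1, 0, 3) else runif(1, 3, 10)
      }
      td <- D / vd; ta <- D / vd
      dur <- ceiling(td + tb + ta)
      if (t + dur >= i_f1) break
      u <- 0:(dur - 1)
      prof <- pmin(u * vd, D, (dur - 1 - u) * vd)
      plateau <- which(prof >= D - 1e-9)
      if (length(plateau) > 0) {
        prof[plateau] <- D * (1 - runif(length(plateau), 0, 0.02))
        prof[plateau[ceiling(length(plateau) / 2)]] <- D
      }
      depth_true[t + u] <- prof
      k <- k + 1L
      rate <- if (block_type == "benthic") cfg$capture_rate_benthic
        else cfg$capture_rate_pelagic
      p <- if (block_type == "benthic") cfg$success_prob_benthic
        else cfg$success_prob_pelagic
      nc <- 0L
      if (rate > 0 && runif(1) < p) nc <- 1L + rpois(1, rate / p - 1)
      cap_t <- numeric(0)
      if (nc > 0) {
        if (block_type == "benthic" && length(plateau) >= 2) {
          # seconds from dive start; sample j covers [j-1, j)
          w0 <- min(plateau) - 1 + 0.3; w1 <- max(plateau) - 0.3
        } else {
          # keep captures below ~2.5 m: a capture planted while the bird
          # is still above the 1.5 m segmentation threshold lies outside
          # every detectable dive window and could never be assigned
          w0 <- 3; w1 <- dur - 4
        }
        if (w1 <= w0) { w0 <- dur / 2 - 0.5; w1 <- dur / 2 + 0.5 }
        cap_t <- .draw_spaced(nc, w0, w1)
      }
      dives[[k]] <- data.frame(
        start_s = t - 1, dur_s = dur, type = block_type,
        max_depth_m = max(prof), seafloor_m = sf,
        lon = lon[t], lat = lat[t])
      if (nc > 0)
        caps[[length(caps) + 1]] <- data.frame(
          offset_s = t - 1 + cap_t,
          depth_m = depth_true[t + pmin(dur - 1, floor(cap_t))],
          dive_idx = k)
      block_left <- block_left - 1L
      gap <- max(8, rgamma(1, shape = 4, scale = max(2, cycle - dur) / 4))
      t <- t + dur + round(gap)
    }
    if (k == 0L)
      stop("simulation failure: no dives could be planted over water; ",
           "foraging window too short for the local bathymetry")
  }
  truth_dives <- if (length(dives)) do.call(rbind, dives) else
    data.frame(start_s = numeric(0), dur_s = numeric(0),
               type = character(0), max_depth_m = numeric(0),
               seafloor_m = numeric(0), lon = numeric(0), lat = numeric(0))
  truth_caps <- if (length(caps)) do.call(rbind, caps) else
    data.frame(offset_s = numeric(0), depth_m = numeric(0),
               dive_idx = integer(0))

  # ---- render sensor streams ------------------------------------------
  sec <- 0:(n1 - 1)
  depth_rec <- depth_true + 0.1 + cfg$depth_drift_m * sec / n1
  depth_df <- data.frame(time = t0 + sec, depth_m = depth_rec)

  hz <- cfg$accel_sample_hz
  n25 <- n1 * hz
  t25 <- sec[1] + (0:(n25 - 1)) / hz
  dyn <- matrix(rnorm(3 * n25, 0, cfg$swim_noise_sd_g), n25, 3)
  # swim strokes while submerged
  in_dive <- rep(depth_true >= 1, each = hz)
  dyn[in_dive, 2] <- dyn[in_dive, 2] +
    0.12 * sin(2 * pi * 2.5 * t25[in_dive])
  if (nrow(truth_caps) > 0) {
    for (ci in seq_len(nrow(truth_caps))) {
      bd <- runif(1, 0.5, 2)
      ctr <- truth_caps$offset_s[ci]
      i0 <- max(1, round((ctr - bd / 2) * hz) + 1)
      i1 <- min(n25, round((ctr + bd / 2) * hz) + 1)
      m <- i1 - i0 + 1
      env <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = m))
      for (ax in 1:3) {
        fr <- runif(1, 3, 8); phi <- runif(1, 0, 2 * pi)
        dyn[i0:i1, ax] <- dyn[i0:i1, ax] +
          cfg$capture_burst_amplitude_g * env *
          sin(2 * pi * fr * t25[i0:i1] + phi)
      }
    }
  }
  # gravity rides on the heave axis for an upright swimming bird
  accel_df <- data.frame(time = t0 + t25,
                         ax_g = dyn[, 1], ay_g = 1 + dyn[, 2],
                         az_g = dyn[, 3])

  gi <- seq(1, n1, by = cfg$gps_interval_s)
  sd_deg <- cfg$gps_noise_m / 111320
  gps_df <- data.frame(
    time = t0 + sec[gi],
    lon = lon[gi] + rnorm(length(gi), 0, sd_deg / cos(lat[gi] * pi / 180)),
    lat = lat[gi] + rnorm(length(gi), 0, sd_deg))

  trip <- structure(list(animal_id = cfg$animal_id, colony = cfg$colony,
                         sex = cfg$sex, gps = gps_df, depth = depth_df,
                         accel = accel_df),
                    class = "trip_record")
  truth <- structure(list(
    dives = data.frame(start = t0 + truth_dives$start_s,
                       end = t0 + truth_dives$start_s + truth_dives$dur_s,
                       type = truth_dives$type,
                       max_depth_m = truth_dives$max_depth_m,
                       seafloor_m = truth_dives$seafloor_m,
                       lon = truth_dives$lon, lat = truth_dives$lat),
    captures = data.frame(time = t0 + truth_caps$offset_s,
                          depth_m = truth_caps$depth_m,
                          dive_idx = truth_caps$dive_idx)),
    class = "synthetic_truth")
  list(trip = trip, truth = truth)
}

#' @export
print.trip_record <- function(x, ...) {
  cat(sprintf("<trip_record> %s (%s, %s): %d GPS fixes, %d depth samples, %d accel samples\n",
              x$animal_id, x$colony, x$sex,
              nrow(x$gps), nrow(x$depth), nrow(x$accel)))
  invisible(x)
}
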