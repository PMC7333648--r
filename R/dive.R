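#' @title Dive segmentation and phase analysis
#' @name dive_analysis
#' @description
#' Depth series are data frames with columns `time` (POSIXct) and
#' `depth_m` (metres, positive down), sampled at a regular interval of at
#' most 2 s. Dives are maximal contiguous runs of samples at or below the
#' surface threshold (1.5 m by default, the threshold used to strip
#' surface and transiting periods from penguin depth records).
NULL

.depth_dt <- function(depth) {
  stopifnot(is.data.frame(depth),
            all(c("time", "depth_m") %in% names(depth)))
  dt <- median(diff(as.numeric(depth$time)))
  if (!is.finite(dt) || dt <= 0)
    stop("depth series must have increasing times")
  dt
}

#' Zero-offset correction of a depth record
#'
#' Pressure sensors drift, so raw depth does not read zero at the surface.
#' The surface baseline is estimated as a centred rolling quantile
#' (default: 10th percentile over 300 s) and subtracted, the approach used
#' by time-depth-recorder packages such as diveMove.
#'
#' @param depth Depth data frame (`time`, `depth_m`); sampling interval
#'   must be 2 s or finer.
#' @param window_s Rolling window length in seconds.
#' @param quantile Quantile taken as the surface baseline.
#' @return The depth data frame with `depth_m` corrected and the baseline
#'   in attribute `zoc_baseline`.
#' @export
zero_offset_correct <- function(depth, window_s = 300, quantile = 0.1) {
  dt <- .depth_dt(depth)
  if (dt > 2)
    stop("zero-offset correction requires a sampling interval <= 2 s")
  n <- nrow(depth)
  w <- max(1L, as.integer(round(window_s / dt)))
  if (w >= n) {
    warning("ZOC window longer than record; applying a single global offset")
    base <- rep(stats::quantile(depth$depth_m, quantile, names = FALSE), n)
  } else {
    base <- roll_quantile_c(depth$depth_m, w, quantile)
  }
  out <- depth
  out$depth_m <- depth$depth_m - base
  attr(out, "zoc_baseline") <- base
  out
}

#' Segment a depth record into dives
#'
#' A dive is a maximal contiguous run of samples with depth at or above
#' the threshold. Runs shorter than `min_duration_s` are discarded as wave
#' splash. Duration is `n_samples * dt` so a square-wave excursion of 60
#' one-second samples has a duration of 60 s.
#'
#' @param depth Zero-offset-corrected depth data frame.
#' @param threshold_m Surface threshold in metres (default 1.5).
#' @param min_duration_s Minimum dive duration in seconds (default 5).
#' @return A `dive_table` data frame with one row per dive: `index`,
#'   `start`, `end`, `duration_s`, `max_depth_m`, `n_samples`,
#'   `post_dive_interval_s` (NA for the last dive).
#' @export
segment_dives <- function(depth, threshold_m = 1.5, min_duration_s = 5) {
  dt <- .depth_dt(depth)
  below <- depth$depth_m >= threshold_m
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths * dt >= min_duration_s
  starts <- starts[keep]; ends <- ends[keep]
  tt <- as.numeric(depth$time)
  k <- length(starts)
  out <- data.frame(
    index = seq_len(k),
    start = as.POSIXct(tt[starts], origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(tt[starts] + (ends - starts + 1) * dt,
                     origin = "1970-01-01", tz = "UTC"),
    duration_s = (ends - starts + 1) * dt,
    max_depth_m = vapply(seq_len(k), function(i)
      max(depth$depth_m[starts[i]:ends[i]]), numeric(1)),
    n_samples = ends - starts + 1)
  out$post_dive_interval_s <-
    c(as.numeric(out$start[-1]) - as.numeric(out$end[-k]), NA)[seq_len(k)]
  attr(out, "sample_interval_s") <- dt
  attr(out, "first_sample_index") <- starts
  class(out) <- c("dive_table", "data.frame")
  out
}

#' Compute descent / bottom / ascent phases for each dive
#'
#' The bottom phase spans the first to the last sample with depth at or
#' above `bottom_fraction` of the dive's maximum depth (80% by default, the
#' standard convention). Descent is everything before it, ascent everything
#' after; the three phase durations sum to the dive duration.
#'
#' @param dives A `dive_table` from [segment_dives()].
#' @param depth The depth data frame the dives were segmented from.
#' @param bottom_fraction Proportion of max depth defining the bottom
#'   phase.
#' @return The dive table with `descent_s`, `bottom_s`, `ascent_s` added.
#' @export
dive_phases <- function(dives, depth, bottom_fraction = 0.8) {
  dt <- .depth_dt(depth)
  tt <- as.numeric(depth$time)
  n <- nrow(dives)
  desc <- bot <- asc <- numeric(n)
  for (i in seq_len(n)) {
    idx <- which(tt >= as.numeric(dives$start[i]) &
                   tt < as.numeric(dives$end[i]))
    d <- depth$depth_m[idx]
    at_bottom <- which(d >= bottom_fraction * max(d))
    b0 <- at_bottom[1]; b1 <- at_bottom[length(at_bottom)]
    desc[i] <- (b0 - 1) * dt
    bot[i] <- (b1 - b0 + 1) * dt
    asc[i] <- (length(d) - b1) * dt
  }
  dives$descent_s <- desc
  dives$bottom_s <- bot
  dives$ascent_s <- asc
  dives
}

#' Trip-level dive statistics
#'
#' @param dives A `dive_table`.
#' @param trip_duration_h Foraging trip duration in hours (> 0).
#' @return data.frame with `vertical_distance_km` (sum of twice the
#'   maximum depth of every dive), `dive_rate_per_h` (dives / duration) and
#'   `time_diving_h`.
#' @export
trip_dive_stats <- function(dives, trip_duration_h) {
  if (!is.numeric(trip_duration_h) || trip_duration_h <= 0)
    stop("trip_duration_h must be a positive number")
  data.frame(
    vertical_distance_km = sum(2 * dives$max_depth_m) / 1000,
    dive_rate_per_h = nrow(dives) / trip_duration_h,
    time_diving_h = sum(dives$duration_s) / 3600)
}
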