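#' @title GPS track conditioning
#' @name track_processing
#' @description
#' A track is a data frame with columns `time` (POSIXct, strictly
#' increasing), `lon` and `lat` (WGS84 decimal degrees). Conditioning
#' removes fixes on land, removes fixes implying unrealistic swim speeds,
#' and resamples to a regular time grid.
NULL

.check_track <- function(track, min_fixes = 2) {
  stopifnot(is.data.frame(track),
            all(c("time", "lon", "lat") %in% names(track)))
  if (nrow(track) < min_fixes)
    stop(sprintf("track has %d fix(es); need at least %d",
                 nrow(track), min_fixes))
  tt <- as.numeric(track$time)
  if (any(diff(tt) <= 0))
    stop("track times must be strictly increasing (no duplicate timestamps)")
  invisible(track)
}

#' Remove fixes exceeding a maximum sustainable speed
#'
#' Forward-sequential single-pass filter: the first fix is always retained;
#' each subsequent fix is dropped if the great-circle speed from the
#' previously *retained* fix exceeds `vmax_kmh`. After filtering, every
#' consecutive-pair speed is `<= vmax_kmh`. The default 12.4 km/h is the
#' mean maximum sustainable swim speed reported for African penguins.
#'
#' @param track Track data frame (see [track_processing]).
#' @param vmax_kmh Speed threshold in km/h.
#' @return The filtered track.
#' @export
filter_speed <- function(track, vmax_kmh = 12.4) {
  .check_track(track)
  tt <- as.numeric(track$time)
  keep <- logical(nrow(track))
  keep[1] <- TRUE
  last <- 1
  for (i in 2:nrow(track)) {
    d_km <- gc_distance_km(track$lon[last], track$lat[last],
                           track$lon[i], track$lat[i])
    v <- d_km / ((tt[i] - tt[last]) / 3600)
    if (v <= vmax_kmh) {
      keep[i] <- TRUE
      last <- i
    }
  }
  if (sum(keep) == 1)
    warning("speed filter removed all but one fix")
  track[keep, , drop = FALSE]
}

#' Remove fixes located on land
#'
#' A fix is on land if its nearest bathymetry cell has
#' `seafloor_depth <= 0`.
#'
#' @param track Track data frame.
#' @param bathy A [bathymetry_grid]; all fixes must fall inside its extent.
#' @return The filtered track.
#' @export
filter_on_land <- function(track, bathy) {
  .check_track(track, min_fixes = 1)
  sf <- lookup_seafloor(bathy, track$lon, track$lat, on_land = "value")
  track[sf > 0, , drop = FALSE]
}

#' Interpolate a track to regular time intervals
#'
#' Linear interpolation of lon and lat on a regular grid from the first to
#' the last fix time.
#'
#' @param track Track data frame with at least 2 fixes.
#' @param interval_s Output interval in seconds (default 60).
#' @return Interpolated track with attributes `interpolated = TRUE` and
#'   `interval_s`.
#' @export
interpolate_track <- function(track, interval_s = 60) {
  if (nrow(track) < 2)
    stop("cannot interpolate a track with fewer than 2 fixes")
  .check_track(track)
  tt <- as.numeric(track$time)
  grid <- seq(tt[1], tt[length(tt)], by = interval_s)
  out <- data.frame(
    time = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
    lon = approx(tt, track$lon, xout = grid)$y,
    lat = approx(tt, track$lat, xout = grid)$y)
  attr(out, "interpolated") <- TRUE
  attr(out, "interval_s") <- interval_s
  out
}

#' Track position at given times
#'
#' Linear interpolation of an (already conditioned) track at arbitrary
#' times; times outside the track span are clamped to the ends.
#'
#' @param track Track data frame.
#' @param times POSIXct (or numeric seconds) vector.
#' @return data.frame with columns lon, lat.
#' @export
track_position_at <- function(track, times) {
  tt <- as.numeric(track$time)
  xt <- pmin(pmax(as.numeric(times), tt[1]), tt[length(tt)])
  data.frame(lon = approx(tt, track$lon, xout = xt)$y,
             lat = approx(tt, track$lat, xout = xt)$y)
}

#' Trip-level track summary
#'
#' @param track Interpolated track data frame.
#' @return data.frame with `horizontal_distance_km` (sum of great-circle
#'   segment lengths), `mean_speed_kmh` (distance / duration) and
#'   `duration_h` (last minus first fix time).
#' @export
trip_summary <- function(track) {
  .check_track(track, min_fixes = 1)
  n <- nrow(track)
  dist <- if (n < 2) 0 else
    sum(gc_distance_km(track$lon[-n], track$lat[-n],
                       track$lon[-1], track$lat[-1]))
  dur_h <- as.numeric(difftime(track$time[n], track$time[1], units = "hours"))
  data.frame(horizontal_distance_km = dist,
             mean_speed_kmh = if (dur_h > 0) dist / dur_h else 0,
             duration_h = dur_h)
}
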