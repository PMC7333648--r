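#' Configuration for benthic/pelagic dive typing
#'
#' The two-step criterion: a dive is benthic when its bathymetric depth
#' ratio (max dive depth / seafloor depth at the dive location) exceeds
#' `ratio_threshold` AND its maximum depth is within
#' `similarity_fraction` of either the previous or the following dive's
#' maximum depth (the similarity denominator is the focal dive's max
#' depth). All other dives are pelagic. Dives over shallow seafloor
#' (< `min_seafloor_m`, where open bathymetry products are unreliable) or
#' within `colony_exclusion_km` of the colony are excluded.
#'
#' @param ratio_threshold Bathymetric depth ratio threshold (default 0.8).
#' @param similarity_fraction Adjacent-depth similarity (default 0.10).
#' @param min_seafloor_m Minimum reliable seafloor depth (default 15 m).
#' @param colony_exclusion_km Radius around the colony to exclude
#'   (default 2 km).
#' @param colony_lonlat Colony position, `c(lon, lat)`.
#' @return A `typing_config` list.
#' @export
typing_config <- function(ratio_threshold = 0.8,
                          similarity_fraction = 0.10,
                          min_seafloor_m = 15,
                          colony_exclusion_km = 2,
                          colony_lonlat = c(25.80, -33.79)) {
  stopifnot(ratio_threshold > 0, ratio_threshold <= 1,
            similarity_fraction > 0, similarity_fraction <= 1,
            min_seafloor_m >= 0, colony_exclusion_km >= 0)
  structure(list(ratio_threshold = ratio_threshold,
                 similarity_fraction = similarity_fraction,
                 min_seafloor_m = min_seafloor_m,
                 colony_exclusion_km = colony_exclusion_km,
                 colony_lonlat = colony_lonlat),
            class = "typing_config")
}

#' Classify a single dive as benthic, pelagic or excluded
#'
#' @param max_depth_m Maximum dive depth (m).
#' @param prev_depth,next_depth Maximum depths of the adjacent dives, or
#'   NA when absent.
#' @param seafloor_m Seafloor depth at the dive location (m, > 0).
#' @param dist_colony_km Distance from the colony (km); NA skips the
#'   colony exclusion.
#' @param cfg A [typing_config].
#' @return Character scalar: `"benthic"`, `"pelagic"` or `"excluded"`,
#'   with an `exclusion_reason` attribute when excluded.
#' @export
classify_dive <- function(max_depth_m, prev_depth, next_depth, seafloor_m,
                          dist_colony_km = NA, cfg = typing_config()) {
  if (!is.na(seafloor_m) && seafloor_m <= 0)
    stop("seafloor depth must be positive at a dive location")
  if (is.na(seafloor_m))
    return(structure("excluded", exclusion_reason = "lookup_failed"))
  if (seafloor_m < cfg$min_seafloor_m)
    return(structure("excluded", exclusion_reason = "shallow_seafloor"))
  if (!is.na(dist_colony_km) && dist_colony_km < cfg$colony_exclusion_km)
    return(structure("excluded", exclusion_reason = "near_colony"))
  if (is.na(prev_depth) && is.na(next_depth))
    warning("dive has no neighbouring dives; similarity test fails, ",
            "classifying as pelagic")
  tol <- cfg$similarity_fraction * max_depth_m
  similar <- (!is.na(prev_depth) && abs(max_depth_m - prev_depth) <= tol) ||
    (!is.na(next_depth) && abs(max_depth_m - next_depth) <= tol)
  ratio <- max_depth_m / seafloor_m
  if (ratio > cfg$ratio_threshold && similar) "benthic" else "pelagic"
}

#' Classify every dive in a trip
#'
#' Looks up the seafloor depth at each dive's location (the interpolated
#' track position at dive start), applies [classify_dive()] with
#' neighbouring dive depths taken from adjacent dives regardless of their
#' own type, and conserves counts:
#' `n_benthic + n_pelagic + n_excluded = n_dives`. Lookup failures (outside
#' extent or land cell) downgrade the dive to `excluded`.
#'
#' @param dives A time-ordered `dive_table`.
#' @param track Conditioned (interpolated) track.
#' @param bathy A [bathymetry_grid].
#' @param cfg A [typing_config].
#' @return List with `dives` (the table with `lon`, `lat`, `seafloor_m`,
#'   `depth_ratio`, `type`, `exclusion_reason` columns added) and `counts`
#'   (named vector benthic/pelagic/excluded).
#' @export
classify_all <- function(dives, track, bathy, cfg = typing_config()) {
  n <- nrow(dives)
  if (n == 0) {
    dives$type <- character(0)
    dives$exclusion_reason <- character(0)
    return(list(dives = dives,
                counts = c(benthic = 0L, pelagic = 0L, excluded = 0L)))
  }
  pos <- track_position_at(track, dives$start)
  sf <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sf[i] <- tryCatch(
      lookup_seafloor(bathy, pos$lon[i], pos$lat[i], on_land = "value"),
      error = function(e) NA_real_)
  }
  sf[!is.na(sf) & sf <= 0] <- NA_real_   # land lookup -> excluded
  dist_col <- gc_distance_km(pos$lon, pos$lat,
                             cfg$colony_lonlat[1], cfg$colony_lonlat[2])
  prev_d <- c(NA, dives$max_depth_m[-n])
  next_d <- c(dives$max_depth_m[-1], NA)
  type <- character(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cl <- suppressWarnings(
      classify_dive(dives$max_depth_m[i], prev_d[i], next_d[i], sf[i],
                    dist_col[i], cfg))
    type[i] <- as.character(cl)
    if (type[i] == "excluded") reason[i] <- attr(cl, "exclusion_reason")
  }
  dives$lon <- pos$lon
  dives$lat <- pos$lat
  dives$seafloor_m <- sf
  dives$depth_ratio <- ifelse(is.na(sf), NA, dives$max_depth_m / sf)
  dives$type <- type
  dives$exclusion_reason <- reason
  counts <- c(benthic = sum(type == "benthic"),
              pelagic = sum(type == "pelagic"),
              excluded = sum(type == "excluded"))
  list(dives = dives, counts = counts)
}
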