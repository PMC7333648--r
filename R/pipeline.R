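#' Pipeline configuration
#'
#' Nested configuration for the full processing chain. Every key has a
#' documented default; unknown keys are rejected before any computation.
#' Serialises round-trip through JSON ([read_pipeline_config()]).
#'
#' @param ... Named overrides for nested blocks, e.g.
#'   `dive = list(threshold_m = 3)`.
#' @return A `pipeline_config` list with blocks `seed`, `track`, `dive`,
#'   `accel`, `typing`, `svm`, `metrics`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    track = list(vmax_kmh = 12.4, interval_s = 60),
    dive = list(threshold_m = 1.5, bottom_fraction = 0.8,
                zoc_window_s = 300, zoc_quantile = 0.1, min_duration_s = 5),
    accel = list(window_s = 1, sample_hz = NULL),
    typing = list(ratio_threshold = 0.8, similarity_fraction = 0.10,
                  min_seafloor_m = 15, colony_exclusion_km = 2,
                  colony_lonlat = c(25.80, -33.79)),
    svm = list(window = 8, stride = 1, label_tolerance_s = 0.5,
               swim_ratio = 5, folds = 10, train_frac = 0.7,
               cost_grid = c(0.1, 1, 10, 100),
               gamma_grid = c(0.001, 0.01, 0.1, 1),
               max_gap_samples = 8, min_run = 10),
    metrics = list(event_match_tol_s = 1))
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (blk in names(over)) {
    if (is.list(defaults[[blk]])) {
      bad <- setdiff(names(over[[blk]]), names(defaults[[blk]]))
      if (length(bad))
        stop("unknown config key(s) in '", blk, "': ",
             paste(bad, collapse = ", "))
      defaults[[blk]][names(over[[blk]])] <- over[[blk]]
    } else {
      defaults[[blk]] <- over[[blk]]
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with (a subset of) the blocks of
#'   [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(raw)
}

#' Process one trip through the full analysis chain
#'
#' Stage order: land filter -> speed filter -> interpolation (track);
#' zero-offset correction -> segmentation -> phases (dive); static/dynamic
#' split -> VeDBA -> per-dive effort (acceleration); benthic/pelagic
#' typing; capture detection (training on truth labels unless a trained
#' detector is supplied); event consolidation; per-dive metrics.
#'
#' @param trip A `trip_record`.
#' @param bathy A [bathymetry_grid].
#' @param cfg A [pipeline_config()].
#' @param truth Optional `synthetic_truth` for detector training and
#'   evaluation.
#' @param detector Optional pre-trained `capture_detector`; when NULL one
#'   is trained from `truth` capture times.
#' @return List: `track`, `dives` (typed, with phases and effort),
#'   `type_counts`, `detector`, `events`, `metrics`, `log` (parameter and
#'   exclusion record).
#' @export
process_trip <- function(trip, bathy, cfg = pipeline_config(),
                         truth = NULL, detector = NULL) {
  stopifnot(inherits(trip, "trip_record"))
  log <- list(config = unclass(cfg), n_gps_raw = nrow(trip$gps))

  track <- filter_on_land(trip$gps, bathy)
  log$n_removed_land <- nrow(trip$gps) - nrow(track)
  n0 <- nrow(track)
  track <- filter_speed(track, cfg$track$vmax_kmh)
  log$n_removed_speed <- n0 - nrow(track)
  track <- interpolate_track(track, cfg$track$interval_s)

  depth <- zero_offset_correct(trip$depth, cfg$dive$zoc_window_s,
                               cfg$dive$zoc_quantile)
  dives <- segment_dives(depth, cfg$dive$threshold_m,
                         cfg$dive$min_duration_s)
  log$n_dives <- nrow(dives)
  if (nrow(dives) > 0)
    dives <- dive_phases(dives, depth, cfg$dive$bottom_fraction)

  derived <- split_static_dynamic(trip$accel, cfg$accel$window_s,
                                  cfg$accel$sample_hz)
  derived <- compute_vedba(derived)
  dives <- per_dive_vedba(dives, derived)

  tcfg <- typing_config(cfg$typing$ratio_threshold,
                        cfg$typing$similarity_fraction,
                        cfg$typing$min_seafloor_m,
                        cfg$typing$colony_exclusion_km,
                        cfg$typing$colony_lonlat)
  typed <- classify_all(dives, track, bathy, tcfg)
  dives <- typed$dives
  log$type_counts <- typed$counts

  if (is.null(detector)) {
    if (is.null(truth))
      stop("need either a trained detector or truth labels to detect ",
           "captures")
    fw <- extract_features(derived, cfg$svm$window, cfg$svm$stride)
    fw <- label_windows(fw, truth$captures$time, cfg$svm$label_tolerance_s)
    ts <- build_training_set(fw, cfg$svm$swim_ratio, seed = cfg$seed)
    detector <- train_detector(ts$x, ts$y, folds = cfg$svm$folds,
                               train_frac = cfg$svm$train_frac,
                               cost_grid = cfg$svm$cost_grid,
                               gamma_grid = cfg$svm$gamma_grid,
                               seed = cfg$seed)
    pred <- predict_captures(detector, fw)
  } else {
    pred <- predict_captures(detector, derived)
  }
  events <- consolidate_events(pred, dives, depth,
                               cfg$svm$max_gap_samples, cfg$svm$min_run)
  log$n_events <- nrow(events)
  log$n_events_outside_dives <- attr(events, "n_outside_dives")

  metrics <- score_dives(dives, events, animal_id = trip$animal_id,
                         colony = trip$colony, sex = trip$sex)
  list(track = track, dives = dives, type_counts = typed$counts,
       detector = detector, events = events, metrics = metrics, log = log)
}

#' Run the pipeline on a fixture directory and write artefacts
#'
#' Reads sensors (and truth, if present) from `input_dir`, runs
#' [process_trip()], and writes `dives.csv`, `events.csv`, `metrics.csv`,
#' `summary.csv`, `model_table.csv`, `detector.json` and `run_log.json`
#' to `out_dir`. Deterministic for a fixed `cfg$seed`.
#'
#' @param input_dir Fixture directory (see [io_formats]).
#' @param out_dir Output directory.
#' @param cfg A [pipeline_config()].
#' @return The [process_trip()] result, invisibly.
#' @export
run_pipeline <- function(input_dir, out_dir, cfg = pipeline_config()) {
  trip <- read_sensors(input_dir)
  bathy <- read_bathymetry(file.path(input_dir, "bathymetry.asc"))
  truth <- if (file.exists(file.path(input_dir, "truth_captures.csv")))
    read_truth(input_dir) else NULL
  res <- process_trip(trip, bathy, cfg, truth = truth)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, name, tcols = intersect(c("time", "start", "end"),
                                            names(d))) {
    d <- as.data.frame(d)
    for (tc in tcols) d[[tc]] <- .fmt_time(d[[tc]])
    data.table::fwrite(d, file.path(out_dir, name))
  }
  wt(res$dives, "dives.csv")
  wt(res$events, "events.csv")
  wt(res$metrics, "metrics.csv")
  wt(summary_table(res$metrics, res$events), "summary.csv")
  export_model_table(res$metrics, file.path(out_dir, "model_table.csv"))
  jsonlite::write_json(detector_to_list(res$detector),
                       file.path(out_dir, "detector.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(res)
}

#' Serialise / restore a trained detector
#'
#' The archive is self-describing JSON: support vectors, coefficients,
#' intercept, hyperparameters, standardisation parameters and the
#' grid-search record.
#'
#' @param detector A `capture_detector`.
#' @return A plain list (for `detector_to_list`); a `capture_detector`
#'   (for `detector_from_list`).
#' @export
detector_to_list <- function(detector) {
  out <- unclass(detector)
  out$sv <- as.data.frame(out$sv)
  out
}

#' @rdname detector_to_list
#' @param x A list produced by `detector_to_list` (e.g. parsed from
#'   JSON).
#' @export
detector_from_list <- function(x) {
  x$sv <- as.matrix(as.data.frame(x$sv))
  x$coef <- as.numeric(x$coef)
  x$center <- setNames(as.numeric(x$center), x$feature_names)
  x$scale <- setNames(as.numeric(x$scale), x$feature_names)
  x$cv_metrics <- as.data.frame(x$cv_metrics)
  structure(x, class = "capture_detector")
}
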