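#' @title File formats and fixtures
#' @name io_formats
#' @description
#' CSV dialects (all times ISO-8601 UTC with millisecond precision):
#' `gps.csv` (time, lon, lat); `depth.csv` (time, depth_m); `accel.csv`
#' (time, ax_g, ay_g, az_g); `truth_captures.csv` (time, depth_m,
#' dive_idx); `truth_dives.csv` (start, end, type, max_depth_m).
#' Bathymetry is an ESRI ASCII grid (`bathymetry.asc`).
NULL

.fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")

.parse_time <- function(s, file = "") {
  t <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (anyNA(t)) {
    bad <- which(is.na(t))[1]
    stop(sprintf("unparseable timestamp at data line %d of %s: '%s'",
                 bad, file, s[bad]))
  }
  t
}

.read_stream <- function(path, time_col = "time") {
  if (!file.exists(path)) stop("missing sensor file: ", path)
  d <- tryCatch(
    data.table::fread(path, colClasses = list(character = time_col)),
    error = function(e) stop("cannot read ", path, ": ",
                             conditionMessage(e)))
  d <- as.data.frame(d)
  d[[time_col]] <- .parse_time(d[[time_col]], basename(path))
  tt <- as.numeric(d[[time_col]])
  if (is.unsorted(tt)) {
    warning("rows of ", basename(path), " are not time-sorted; sorting")
    d <- d[order(tt), , drop = FALSE]
    tt <- sort(tt)
  }
  if (anyDuplicated(tt))
    stop("non-monotone time in ", basename(path),
         ": duplicate timestamp at row ", which(duplicated(tt))[1])
  rownames(d) <- NULL
  d
}

#' Write a simulated trip (plus truth and bathymetry) as a fixture
#'
#' Writes the CSV file set and ESRI ASCII bathymetry documented in
#' [io_formats]; the set round-trips losslessly through [read_sensors()]
#' and [read_bathymetry()] at millisecond time precision.
#'
#' @param trip A `trip_record`.
#' @param truth A `synthetic_truth` (or NULL to skip truth files).
#' @param bathy A [bathymetry_grid] (or NULL to skip).
#' @param directory Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(trip, truth = NULL, bathy = NULL, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop("cannot create fixture directory: ", directory)
  w <- function(d, name, tcols = "time") {
    for (tc in intersect(tcols, names(d))) d[[tc]] <- .fmt_time(d[[tc]])
    data.table::fwrite(d, file.path(directory, name))
  }
  w(trip$gps, "gps.csv")
  w(trip$depth, "depth.csv")
  w(trip$accel, "accel.csv")
  if (!is.null(truth)) {
    w(truth$captures, "truth_captures.csv")
    w(truth$dives, "truth_dives.csv", tcols = c("start", "end"))
  }
  if (!is.null(bathy))
    write_bathymetry(bathy, file.path(directory, "bathymetry.asc"))
  meta <- list(animal_id = trip$animal_id, colony = trip$colony,
               sex = trip$sex)
  jsonlite::write_json(meta, file.path(directory, "metadata.json"),
                       auto_unbox = TRUE)
  invisible(directory)
}

#' Read a sensor file set into a trip record
#'
#' @param directory Directory holding `gps.csv`, `depth.csv`, `accel.csv`
#'   (and optionally `metadata.json`).
#' @return A `trip_record`.
#' @export
read_sensors <- function(directory) {
  gps <- .read_stream(file.path(directory, "gps.csv"))
  depth <- .read_stream(file.path(directory, "depth.csv"))
  accel <- .read_stream(file.path(directory, "accel.csv"))
  meta <- list(animal_id = "unknown", colony = NA, sex = NA)
  mp <- file.path(directory, "metadata.json")
  if (file.exists(mp)) meta <- jsonlite::read_json(mp)
  structure(list(animal_id = meta$animal_id, colony = meta$colony,
                 sex = meta$sex, gps = gps, depth = depth, accel = accel),
            class = "trip_record")
}

#' Read ground-truth files written by [write_fixture()]
#'
#' @param directory Fixture directory.
#' @return A `synthetic_truth`.
#' @export
read_truth <- function(directory) {
  caps <- .read_stream(file.path(directory, "truth_captures.csv"))
  dv <- data.table::fread(file.path(directory, "truth_dives.csv"),
                          colClasses = list(character = c("start", "end")))
  dv <- as.data.frame(dv)
  dv$start <- .parse_time(dv$start, "truth_dives.csv")
  dv$end <- .parse_time(dv$end, "truth_dives.csv")
  structure(list(dives = dv, captures = caps), class = "synthetic_truth")
}
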