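#' Bathymetry grid container
#'
#' A regular lon/lat raster of seafloor depth in metres, positive down.
#' Cells with `seafloor_depth <= 0` encode land. The matrix is stored with
#' one row per latitude (ascending) and one column per longitude
#' (ascending).
#'
#' @param lon_axis Strictly monotone vector of cell-centre longitudes
#'   (degrees east).
#' @param lat_axis Strictly monotone vector of cell-centre latitudes
#'   (degrees north).
#' @param seafloor_depth Numeric matrix, `length(lat_axis)` rows by
#'   `length(lon_axis)` columns, metres positive down.
#' @return An object of class `bathymetry_grid`.
#' @export
bathymetry_grid <- function(lon_axis, lat_axis, seafloor_depth) {
  mono <- function(a) length(a) >= 2 &&
    (all(diff(a) > 0) || all(diff(a) < 0))
  if (!mono(lon_axis)) stop("lon_axis must be strictly monotone")
  if (!mono(lat_axis)) stop("lat_axis must be strictly monotone")
  if (diff(lon_axis[1:2]) < 0) {
    lon_axis <- rev(lon_axis)
    seafloor_depth <- seafloor_depth[, rev(seq_along(lon_axis)), drop = FALSE]
  }
  if (diff(lat_axis[1:2]) < 0) {
    lat_axis <- rev(lat_axis)
    seafloor_depth <- seafloor_depth[rev(seq_along(lat_axis)), , drop = FALSE]
  }
  if (!identical(dim(seafloor_depth),
                 c(length(lat_axis), length(lon_axis))))
    stop("seafloor_depth dimensions must match lat (rows) x lon (cols) axes")
  structure(list(lon_axis = as.numeric(lon_axis),
                 lat_axis = as.numeric(lat_axis),
                 seafloor_depth = seafloor_depth),
            class = "bathymetry_grid")
}

#' @export
print.bathymetry_grid <- function(x, ...) {
  cat(sprintf(
    "<bathymetry_grid> %d x %d cells, lon [%.4f, %.4f], lat [%.4f, %.4f]\n",
    length(x$lat_axis), length(x$lon_axis),
    min(x$lon_axis), max(x$lon_axis), min(x$lat_axis), max(x$lat_axis)))
  cat(sprintf("  depth range %.1f to %.1f m (land cells: %d)\n",
              min(x$seafloor_depth), max(x$seafloor_depth),
              sum(x$seafloor_depth <= 0)))
  invisible(x)
}

#' Generate a synthetic coastal bathymetry
#'
#' Builds a smooth, offshore-deepening seafloor surface over a lon/lat box
#' with a wavy coastline along the northern edge (the geometry of a
#' south-facing bay). The colony cell and a coastal strip are land
#' (`depth <= 0`). Deterministic for a fixed seed.
#'
#' @param seed Integer RNG seed.
#' @param extent Numeric length-4: `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param depth_range Length-2 metres: offshore depth limits; max must be
#'   at least 20 m.
#' @param n_cells Length-2 integer: number of columns (lon) and rows (lat).
#' @param colony_lonlat Colony position; forced to be a land cell.
#' @param offshore_km Distance from the coast at which the seafloor reaches
#'   `depth_range[2]`; controls the slope of the shelf.
#' @return A [bathymetry_grid].
#' @export
generate_bathymetry <- function(seed = 1,
                                extent = c(25.55, 26.05, -34.15, -33.77),
                                depth_range = c(0, 90),
                                n_cells = c(60, 60),
                                colony_lonlat = c(25.80, -33.79),
                                offshore_km = 12) {
  if (length(extent) != 4 || extent[1] >= extent[2] || extent[3] >= extent[4])
    stop("degenerate extent: need lon_min < lon_max and lat_min < lat_max")
  if (depth_range[2] < 20)
    stop("depth_range maximum must be >= 20 m")
  .df_local_seed(seed, {
    nlon <- n_cells[1]; nlat <- n_cells[2]
    lon <- seq(extent[1], extent[2], length.out = nlon)
    lat <- seq(extent[3], extent[4], length.out = nlat)

    # coastline along the northern edge, gently wavy
    coast_amp <- 0.15 * (extent[4] - extent[3])
    phs <- runif(2, 0, 2 * pi)
    coast_lat <- extent[4] - 0.05 * (extent[4] - extent[3]) -
      coast_amp * (0.5 + 0.5 * sin(2 * pi * (lon - extent[1]) /
                                     (extent[2] - extent[1]) * 1.3 + phs[1]))
    # anchor the coastline at the colony: the colony sits on the shore
    # (just inland) whatever the phase of the coastline wave
    ic <- which.min(abs(lon - colony_lonlat[1]))
    coast_lat <- coast_lat - (coast_lat[ic] - colony_lonlat[2]) - 1e-4

    latm <- matrix(lat, nlat, nlon)
    coastm <- matrix(coast_lat, nlat, nlon, byrow = TRUE)
    off_km <- (coastm - latm) * 111.32          # offshore distance, km
    depth <- depth_range[2] * pmin(pmax(off_km / offshore_km, 0), 1)^1.1

    # smooth low-order random relief, ~6% of the depth range
    a <- runif(3, -1, 1)
    lonn <- matrix((lon - extent[1]) / (extent[2] - extent[1]),
                   nlat, nlon, byrow = TRUE)
    latn <- (latm - extent[3]) / (extent[4] - extent[3])
    relief <- a[1] * sin(2 * pi * lonn + phs[2]) * cos(2 * pi * latn) +
      a[2] * cos(3 * pi * lonn) * sin(2 * pi * latn) +
      a[3] * sin(4 * pi * (lonn + latn))
    depth <- depth + 0.06 * depth_range[2] * relief * pmin(off_km / 2, 1)
    depth <- pmin(pmax(depth, off_km * 0.5), depth_range[2])

    depth[latm >= coastm] <- -2               # land strip
    # colony cell (and immediate neighbourhood) is land
    jc <- which.min(abs(lat - colony_lonlat[2]))
    depth[max(1, jc - 1):min(nlat, jc + 1),
          max(1, ic - 1):min(nlon, ic + 1)] <- -2

    bathymetry_grid(lon, lat, depth)
  })
}

#' Nearest-cell seafloor lookup
#'
#' Returns the seafloor depth (m, positive down) of the grid cell whose
#' centre is nearest to each query point. No interpolation is performed:
#' at the coarse resolution typical of open bathymetry products,
#' interpolating would imply false precision.
#'
#' @param bathy A [bathymetry_grid].
#' @param lon,lat Query coordinates (vectorised).
#' @param on_land `"error"` (default) to fail on a land cell, `"value"` to
#'   return the stored (non-positive) value.
#' @return Numeric vector of seafloor depths.
#' @export
lookup_seafloor <- function(bathy, lon, lat, on_land = c("error", "value")) {
  on_land <- match.arg(on_land)
  dlon <- median(diff(bathy$lon_axis))
  dlat <- median(diff(bathy$lat_axis))
  out_lon <- lon < min(bathy$lon_axis) - dlon / 2 |
    lon > max(bathy$lon_axis) + dlon / 2
  out_lat <- lat < min(bathy$lat_axis) - dlat / 2 |
    lat > max(bathy$lat_axis) + dlat / 2
  if (any(out_lon | out_lat)) {
    bad <- which(out_lon | out_lat)[1]
    stop(sprintf(
      "point %d (lon %.5f, lat %.5f) is outside the bathymetry extent",
      bad, lon[bad], lat[bad]))
  }
  i <- pmin(pmax(round((lat - bathy$lat_axis[1]) / dlat) + 1, 1),
            length(bathy$lat_axis))
  j <- pmin(pmax(round((lon - bathy$lon_axis[1]) / dlon) + 1, 1),
            length(bathy$lon_axis))
  v <- bathy$seafloor_depth[cbind(i, j)]
  if (on_land == "error" && any(v <= 0)) {
    bad <- which(v <= 0)[1]
    stop(sprintf("point %d (lon %.5f, lat %.5f) falls on a land cell",
                 bad, lon[bad], lat[bad]))
  }
  v
}

#' Read an ESRI ASCII grid as a bathymetry raster
#'
#' Supports the standard `cellsize` header and the GDAL `dx`/`dy` variant
#' for non-square cells. `NODATA` cells are mapped to land (-9999, which is
#' `<= 0` and therefore land under the package convention).
#'
#' @param path Path to a `.asc` file.
#' @return A [bathymetry_grid].
#' @export
read_bathymetry <- function(path) {
  if (!file.exists(path)) stop("bathymetry file not found: ", path)
  lines <- readLines(path, n = 7)
  hdr <- list()
  n_hdr <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path)
  if (!is.null(hdr$cellsize)) {
    dx <- hdr$cellsize; dy <- hdr$cellsize
  } else if (!is.null(hdr$dx) && !is.null(hdr$dy)) {
    dx <- hdr$dx; dy <- hdr$dy
  } else stop("ESRI ASCII header must contain cellsize or dx/dy: ", path)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value

  m <- tryCatch(
    as.matrix(data.table::fread(path, skip = n_hdr, header = FALSE)),
    error = function(e) stop("cannot parse grid body of ", path, ": ",
                             conditionMessage(e)))
  if (nrow(m) != hdr$nrows || ncol(m) != hdr$ncols)
    stop(sprintf("grid body is %d x %d but header says %d x %d in %s",
                 nrow(m), ncol(m), hdr$nrows, hdr$ncols, path))
  m[m == nodata] <- -9999
  lon <- hdr$xllcorner + dx * (seq_len(hdr$ncols) - 0.5)
  lat <- hdr$yllcorner + dy * (seq_len(hdr$nrows) - 0.5)
  # rows in the file run north -> south
  bathymetry_grid(lon, lat, m[rev(seq_len(nrow(m))), , drop = FALSE])
}

#' Write a bathymetry grid as ESRI ASCII
#'
#' Land cells keep their stored (non-positive) values so write/read
#' round-trips are lossless. Non-square cells are written with the GDAL
#' `dx`/`dy` header variant.
#'
#' @param bathy A [bathymetry_grid].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bathymetry <- function(bathy, path) {
  dlon <- median(diff(bathy$lon_axis))
  dlat <- median(diff(bathy$lat_axis))
  hdr <- c(sprintf("ncols %d", length(bathy$lon_axis)),
           sprintf("nrows %d", length(bathy$lat_axis)),
           sprintf("xllcorner %.10g", bathy$lon_axis[1] - dlon / 2),
           sprintf("yllcorner %.10g", bathy$lat_axis[1] - dlat / 2))
  hdr <- if (abs(dlon - dlat) < 1e-9)
    c(hdr, sprintf("cellsize %.10g", dlon))
  else
    c(hdr, sprintf("dx %.10g", dlon), sprintf("dy %.10g", dlat))
  hdr <- c(hdr, "NODATA_value -9999")
  body <- apply(bathy$seafloor_depth[rev(seq_along(bathy$lat_axis)), ,
                                     drop = FALSE],
                1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                     collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
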