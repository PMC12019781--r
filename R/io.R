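#' Write a climate grid to a plain-text file
#'
#' Grids are stored in a simple lossless text format: a one-line JSON header
#' with the full metadata (variable, units, coordinates, time axis) followed
#' by one line of `%.17g`-formatted values per time step. `%.17g` guarantees
#' bit-exact double round-trips.
#'
#' @param x a [climate_grid()] or [monthly_climatology()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(x, path) {
  is_clim <- inherits(x, "monthly_climatology")
  if (!is_clim && !inherits(x, "climate_grid")) stopf("not a grid object")
  meta <- list(type = if (is_clim) "monthly_climatology" else "climate_grid",
               variable = x$variable,
               units = if (is.null(x$units)) NULL else x$units,
               lon = x$lon, lat = x$lat)
  if (!is_clim) { meta$year <- x$year; meta$month <- x$month }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null"), con)
  nt <- dim(x$values)[3]
  for (t in seq_len(nt)) {
    v <- as.vector(x$values[, , t])
    writeLines(paste(ifelse(is.na(v), "NA", sprintf("%.17g", v)), collapse = " "), con)
  }
  invisible(path)
}

#' Read a climate grid written by [write_grid()]
#'
#' @param path file path.
#' @return a `climate_grid` or `monthly_climatology`, matching what was written.
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stopf("not a grid file: %s", path)
  meta <- jsonlite::fromJSON(lines[1])
  if (is.null(meta$type) || !meta$type %in% c("climate_grid", "monthly_climatology")) {
    stopf("unknown grid type in %s", path)
  }
  ny <- length(meta$lat); nx <- length(meta$lon); nt <- length(lines) - 1L
  vals <- array(NA_real_, c(ny, nx, nt))
  for (t in seq_len(nt)) {
    v <- scan(text = lines[t + 1L], what = numeric(), quiet = TRUE, na.strings = "NA")
    if (length(v) != ny * nx) stopf("layer %d has %d values, expected %d", t, length(v), ny * nx)
    vals[, , t] <- v
  }
  if (meta$type == "monthly_climatology") {
    monthly_climatology(vals, meta$variable, meta$lon, meta$lat)
  } else {
    climate_grid(vals, meta$variable, meta$lon, meta$lat, meta$year, meta$month)
  }
}

#' Read species occurrence records from CSV
#'
#' Validates the required columns (`species`, `lon`, `lat`), rejects
#' malformed coordinates with the offending row number, and optionally
#' checks records against a grid extent.
#'
#' @param path CSV file with columns `species`, `lon`, `lat`.
#' @param lon_range,lat_range optional length-2 extents; records outside are
#'   rejected.
#' @return a `data.frame` of occurrence records.
#' @export
read_occurrences <- function(path, lon_range = NULL, lat_range = NULL) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(occ))) {
    stopf("occurrence CSV must have columns %s", paste(need, collapse = ", "))
  }
  for (col in c("lon", "lat")) {
    v <- suppressWarnings(as.numeric(occ[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) stopf("malformed %s in occurrence CSV at row %d", col, bad[1])
    occ[[col]] <- v
  }
  bad <- which(occ$lat < -90 | occ$lat > 90)
  if (length(bad)) stopf("latitude out of range [-90, 90] at row %d", bad[1])
  bad <- which(occ$lon < -180 | occ$lon > 360)
  if (length(bad)) stopf("longitude out of range at row %d", bad[1])
  if (!is.null(lon_range)) {
    bad <- which(occ$lon < min(lon_range) | occ$lon > max(lon_range))
    if (length(bad)) stopf("longitude outside grid extent at row %d", bad[1])
  }
  if (!is.null(lat_range)) {
    bad <- which(occ$lat < min(lat_range) | occ$lat > max(lat_range))
    if (length(bad)) stopf("latitude outside grid extent at row %d", bad[1])
  }
  occ[c("species", "lon", "lat")]
}

#' Write occurrence records to CSV
#'
#' @param occ a data.frame with columns `species`, `lon`, `lat`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ[c("species", "lon", "lat")], path, row.names = FALSE)
  invisible(path)
}
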