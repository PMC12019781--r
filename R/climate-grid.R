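#' Monthly climate grid
#'
#' The central container of the pipeline: one climate variable (monthly mean
#' temperature in degC or monthly precipitation sum in mm) on a regular
#' lon/lat grid over a run of consecutive calendar months. Values are stored
#' as an array `[lat, lon, time]`, rows running north to south; missing cells
#' are `NA` and the mask must be identical across time steps.
#'
#' @param values numeric array `[length(lat), length(lon), n_months]`.
#' @param variable `"temperature"` or `"precipitation"`.
#' @param lon,lat numeric vectors of cell-center coordinates (degrees);
#'   `lon` increasing, `lat` decreasing (north first).
#' @param year,month integer vectors (one entry per time step) giving the
#'   calendar position of each layer; must advance by exactly one month.
#' @return an object of class `climate_grid`.
#' @export
climate_grid <- function(values, variable = c("temperature", "precipitation",
                                              "pet", "cwb"),
                         lon, lat, year, month) {
  variable <- match.arg(variable)
  values <- as.array(values)
  if (length(dim(values)) != 3L) stopf("values must be a 3-d array [lat, lon, time]")
  if (dim(values)[1] != length(lat) || dim(values)[2] != length(lon)) {
    stopf("values dimensions do not match lon/lat lengths")
  }
  nt <- dim(values)[3]
  if (length(year) != nt || length(month) != nt) {
    stopf("year/month must have one entry per time step")
  }
  if (nt > 1L) {
    idx <- year * 12L + (month - 1L)
    if (any(diff(idx) != 1L)) stopf("time axis must advance by exactly one month")
  }
  if (length(lat) > 1L && any(diff(lat) >= 0)) stopf("lat must be strictly decreasing (north first)")
  if (length(lon) > 1L && any(diff(lon) <= 0)) stopf("lon must be strictly increasing")
  if (variable %in% c("precipitation", "pet") && any(values < 0, na.rm = TRUE)) {
    stopf("%s must be non-negative where not masked", variable)
  }
  mask <- is.na(values)
  if (nt > 1L && !all(mask == mask[, , rep(1L, nt)])) {
    stopf("missing-value mask must be identical across time steps")
  }
  structure(
    list(values = values, variable = variable,
         units = if (variable == "temperature") "degC" else "mm",  # pet/cwb: mm/month
         lon = as.numeric(lon), lat = as.numeric(lat),
         year = as.integer(year), month = as.integer(month)),
    class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %s [%s], %d x %d cells, %d months (%d-%02d .. %d-%02d)\n",
              x$variable, x$units, length(x$lat), length(x$lon), length(x$year),
              x$year[1], x$month[1], x$year[length(x$year)], x$month[length(x$month)]))
  invisible(x)
}

#' @export
dim.climate_grid <- function(x) dim(x$values)

#' Subset a climate grid to a span of calendar years
#'
#' @param x a [climate_grid()].
#' @param years integer vector of calendar years to keep (contiguous).
#' @param lead_december also keep December of the year preceding `years`
#'   when present (used for DJF aggregation).
#' @return a `climate_grid` restricted to the requested months.
#' @export
subset_years <- function(x, years, lead_december = FALSE) {
  keep <- x$year %in% years
  if (lead_december) keep <- keep | (x$year == (min(years) - 1L) & x$month == 12L)
  if (!any(keep)) stopf("requested years not present in the series")
  climate_grid(x$values[, , keep, drop = FALSE], x$variable,
               x$lon, x$lat, x$year[keep], x$month[keep])
}

#' 12-month climatology
#'
#' Per-cell mean over all occurrences of each calendar month.
#'
#' @param x a [climate_grid()].
#' @param years optional calendar years to average over (default: all).
#' @return a `monthly_climatology`: array `[lat, lon, 12]` plus grid metadata.
#' @export
climatology <- function(x, years = NULL) {
  if (!is.null(years)) x <- subset_years(x, years)
  ny <- length(x$lat); nx <- length(x$lon)
  out <- array(NA_real_, c(ny, nx, 12L))
  for (m in 1:12) {
    sel <- x$month == m
    if (!any(sel)) stopf("month %d missing from the series", m)
    out[, , m] <- rowMeans(matrix(x$values[, , sel, drop = FALSE], ny * nx, sum(sel)))
  }
  monthly_climatology(out, x$variable, x$lon, x$lat)
}

#' Construct a 12-month climatology object
#'
#' @param values array `[lat, lon, 12]`.
#' @param variable,lon,lat as for [climate_grid()].
#' @return an object of class `monthly_climatology`.
#' @export
monthly_climatology <- function(values, variable, lon, lat) {
  values <- as.array(values)
  if (length(dim(values)) != 3L || dim(values)[3] != 12L) {
    stopf("a climatology must hold exactly 12 monthly fields")
  }
  if (dim(values)[1] != length(lat) || dim(values)[2] != length(lon)) {
    stopf("climatology dimensions do not match lon/lat lengths")
  }
  structure(list(values = values, variable = variable,
                 lon = as.numeric(lon), lat = as.numeric(lat)),
            class = "monthly_climatology")
}

# index of the enclosing/nearest source cell for each target coordinate
nearest_index <- function(target, source) {
  vapply(target, function(t) which.min(abs(source - t)), integer(1))
}

#' Regrid a field stack by nearest-neighbour lookup
#'
#' @param values array `[lat, lon, k]` on the source grid.
#' @param lon,lat source coordinates.
#' @param lon_out,lat_out target coordinates.
#' @return array `[lat_out, lon_out, k]`.
#' @export
regrid_nearest <- function(values, lon, lat, lon_out, lat_out) {
  ii <- nearest_index(lat_out, lat)
  jj <- nearest_index(lon_out, lon)
  values[ii, jj, , drop = FALSE]
}

#' Regrid a field stack by bilinear interpolation
#'
#' Coordinates outside the source hull are clamped to the edge (constant
#' extrapolation), appropriate for smooth anomaly fields.
#'
#' @inheritParams regrid_nearest
#' @return array `[lat_out, lon_out, k]`.
#' @export
regrid_bilinear <- function(values, lon, lat, lon_out, lat_out) {
  # work on increasing axes
  lat_inc <- rev(lat)
  interp_axis <- function(src, tgt) {
    tgt <- pmin(pmax(tgt, min(src)), max(src))
    j1 <- pmax(findInterval(tgt, src), 1L)
    j1 <- pmin(j1, length(src) - 1L)
    if (length(src) == 1L) return(list(i0 = rep(1L, length(tgt)), i1 = rep(1L, length(tgt)), w = rep(0, length(tgt))))
    w <- (tgt - src[j1]) / (src[j1 + 1L] - src[j1])
    list(i0 = j1, i1 = j1 + 1L, w = w)
  }
  ax_x <- interp_axis(lon, lon_out)
  ax_y <- interp_axis(lat_inc, rev(lat_out))
  k <- dim(values)[3]
  vflip <- values[rev(seq_along(lat)), , , drop = FALSE]
  out <- array(NA_real_, c(length(lat_out), length(lon_out), k))
  for (b in seq_len(k)) {
    f <- vflip[, , b]
    v00 <- f[ax_y$i0, ax_x$i0, drop = FALSE]; v01 <- f[ax_y$i0, ax_x$i1, drop = FALSE]
    v10 <- f[ax_y$i1, ax_x$i0, drop = FALSE]; v11 <- f[ax_y$i1, ax_x$i1, drop = FALSE]
    wy <- matrix(ax_y$w, nrow = length(ax_y$w), ncol = length(ax_x$w))
    wx <- matrix(ax_x$w, nrow = length(ax_y$w), ncol = length(ax_x$w), byrow = TRUE)
    g <- (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11)
    out[, , b] <- g[rev(seq_len(nrow(g))), , drop = FALSE]
  }
  out
}
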