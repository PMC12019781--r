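#' AMOC-collapse anomaly maps
#'
#' Twelve monthly additive surface-air-temperature anomaly fields (SAT, degC)
#' and twelve monthly relative precipitation anomaly fields (RPA, fraction;
#' -0.2 means a 20% reduction, so RPA >= -1 always).
#'
#' @param sat array `[lat, lon, 12]` of additive temperature anomalies (degC).
#' @param rpa array `[lat, lon, 12]` of relative precipitation anomalies.
#' @param lon,lat cell-center coordinates.
#' @return an `anomaly_maps` object.
#' @export
anomaly_maps <- function(sat, rpa, lon, lat) {
  sat <- as.array(sat); rpa <- as.array(rpa)
  if (length(dim(sat)) != 3L || dim(sat)[3] != 12L ||
      length(dim(rpa)) != 3L || dim(rpa)[3] != 12L) {
    stopf("SAT and RPA must each hold exactly 12 monthly fields")
  }
  if (!all(is.finite(sat)) || !all(is.finite(rpa))) stopf("anomaly fields must be finite")
  if (any(rpa < -1)) stopf("RPA below -1: cannot remove more than all precipitation")
  structure(list(sat = sat, rpa = rpa, lon = as.numeric(lon), lat = as.numeric(lat)),
            class = "anomaly_maps")
}

#' Regrid anomaly maps to a target grid
#'
#' @param anomalies an [anomaly_maps()].
#' @param lon_out,lat_out target cell centers.
#' @param method `"bilinear"` (default; the source maps are coarse and
#'   smooth) or `"nearest"`.
#' @return an `anomaly_maps` on the target grid.
#' @export
regrid_anomalies <- function(anomalies, lon_out, lat_out,
                             method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  f <- if (method == "bilinear") regrid_bilinear else regrid_nearest
  anomaly_maps(f(anomalies$sat, anomalies$lon, anomalies$lat, lon_out, lat_out),
               pmax(f(anomalies$rpa, anomalies$lon, anomalies$lat, lon_out, lat_out), -1),
               lon_out, lat_out)
}

#' Superimpose AMOC-collapse anomalies on a projection
#'
#' Within the stated period (default 2071-2100, the last climate normal of
#' the century), temperature receives the matching calendar month's SAT
#' additively and precipitation is scaled by `1 + RPA`; months outside the
#' period pass through untouched. Applied after quantile mapping. Note that
#' the multiplicative RPA composes as a product, so a repeated overlay is
#' not the same as a single one.
#'
#' @param temperature,precipitation [climate_grid()]s on one grid.
#' @param anomalies an [anomaly_maps()] already on the series grid (use
#'   [regrid_anomalies()] first if needed).
#' @param period integer years over which the anomalies act
#'   (default `2071:2100`).
#' @return a list with the modified `temperature` and `precipitation` grids.
#' @export
superimpose_anomalies <- function(temperature, precipitation, anomalies,
                                  period = 2071:2100) {
  for (g in list(temperature, precipitation)) {
    if (!isTRUE(all.equal(g$lon, anomalies$lon)) ||
        !isTRUE(all.equal(g$lat, anomalies$lat))) {
      stopf("anomaly maps must be on the series grid (regrid first)")
    }
  }
  tv <- temperature$values; pv <- precipitation$values
  sel <- which(temperature$year %in% period)
  for (t in sel) {
    m <- temperature$month[t]
    tv[, , t] <- tv[, , t] + anomalies$sat[, , m]
    pv[, , t] <- pmax(pv[, , t] * (1 + anomalies$rpa[, , m]), 0)
  }
  list(temperature = climate_grid(tv, "temperature", temperature$lon,
                                  temperature$lat, temperature$year, temperature$month),
       precipitation = climate_grid(pv, "precipitation", precipitation$lon,
                                    precipitation$lat, precipitation$year,
                                    precipitation$month))
}
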