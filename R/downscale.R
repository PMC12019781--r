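#' Change-factor downscaling of a coarse monthly series
#'
#' Transfers a coarse monthly series to a high-resolution grid using a pair
#' of 12-month climatologies. Temperature uses additive anomalies
#' (fine = fine climatology + coarse anomaly of the enclosing coarse cell);
#' precipitation uses multiplicative anomalies
#' (fine = fine climatology x coarse ratio), with the ratio capped at 5 and
#' forced to 1 where the coarse climatology is below 1 mm to keep arid
#' months from blowing up.
#'
#' @param coarse a [climate_grid()] on the source grid.
#' @param fine_climatology a [monthly_climatology()] on the target grid.
#' @param coarse_climatology a [monthly_climatology()] on the source grid.
#' @param ratio_cap cap on the precipitation ratio (default 5).
#' @param dry_threshold coarse-climatology value (mm) below which the ratio
#'   is forced to 1 (default 1).
#' @return a `climate_grid` on the target grid.
#' @export
change_factor_downscale <- function(coarse, fine_climatology, coarse_climatology,
                                    ratio_cap = 5, dry_threshold = 1) {
  if (!identical(coarse$variable, fine_climatology$variable) ||
      !identical(coarse$variable, coarse_climatology$variable)) {
    stopf("variable mismatch between series and climatologies")
  }
  if (!isTRUE(all.equal(coarse$lon, coarse_climatology$lon)) ||
      !isTRUE(all.equal(coarse$lat, coarse_climatology$lat))) {
    stopf("coarse climatology must live on the series grid")
  }
  lon_f <- fine_climatology$lon; lat_f <- fine_climatology$lat
  if (min(lon_f) > max(coarse$lon) + diff(range(coarse$lon)) ||
      max(lon_f) < min(coarse$lon) - diff(range(coarse$lon))) {
    stopf("no spatial overlap between coarse and target grids")
  }
  ii <- nearest_index(lat_f, coarse$lat)
  jj <- nearest_index(lon_f, coarse$lon)
  nt <- dim(coarse$values)[3]
  out <- array(NA_real_, c(length(lat_f), length(lon_f), nt))
  for (t in seq_len(nt)) {
    m <- coarse$month[t]
    cc <- coarse_climatology$values[, , m]
    cv <- coarse$values[, , t]
    fc <- fine_climatology$values[, , m]
    if (coarse$variable == "temperature") {
      out[, , t] <- fc + (cv - cc)[ii, jj, drop = FALSE]
    } else {
      ratio <- cv / cc
      ratio[cc < dry_threshold] <- 1
      ratio <- pmin(ratio, ratio_cap)
      out[, , t] <- pmax(fc * ratio[ii, jj, drop = FALSE], 0)
    }
  }
  climate_grid(out, coarse$variable, lon_f, lat_f, coarse$year, coarse$month)
}
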