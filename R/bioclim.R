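#' Canonical bioclimatic variable names
#'
#' The default 17-variable catalogue: nine temperature aggregates (annual
#' and meteorological-season means, warmest- and coldest-month means, and
#' two continentality measures — the SD and the range of the 12 monthly
#' means) and eight climatic-water-balance aggregates (annual and seasonal
#' sums, the driest-month CWB, and the same two continentality measures).
#'
#' @return character vector of 17 names.
#' @export
bioclim_variable_names <- function() {
  c("t_ann", "t_djf", "t_mam", "t_jja", "t_son", "t_warm", "t_cold", "t_sd", "t_rng",
    "cwb_ann", "cwb_djf", "cwb_mam", "cwb_jja", "cwb_son", "cwb_min", "cwb_sd", "cwb_rng")
}

#' Bioclim stack container
#'
#' @param values array `[lat, lon, variable]` with variable dimnames.
#' @param lon,lat cell centers.
#' @param period period label.
#' @param model model label (`"observed"` for the historic periods).
#' @param provenance free-form input provenance string.
#' @return a `bioclim_stack`.
#' @export
bioclim_stack <- function(values, lon, lat, period = NA_character_,
                          model = NA_character_, provenance = NA_character_) {
  values <- as.array(values)
  vars <- dimnames(values)[[3]]
  if (is.null(vars)) stopf("bioclim values need variable dimnames")
  structure(list(values = values, lon = as.numeric(lon), lat = as.numeric(lat),
                 variables = vars, period = period, model = model,
                 provenance = provenance),
            class = "bioclim_stack")
}

#' Thornthwaite potential evapotranspiration
#'
#' Monthly PET (mm) from monthly mean temperature: heat index
#' `I = sum((T_clim/5)^1.514)` over the 12 climatological months with
#' positive mean temperature; exponent
#' `a = 6.75e-7 I^3 - 7.71e-5 I^2 + 1.792e-2 I + 0.49239`; unadjusted
#' `PET = 16 (10 T / I)^a` for `T > 0`, 0 for `T <= 0`; multiplied by the
#' standard day-length/month-length correction from solar geometry at the
#' cell latitude. The heat index is computed from the whole series'
#' climatology (stable across years), the standard usage.
#'
#' @param temperature a temperature [climate_grid()] in degC.
#' @param correction `"daylength"` (default) or `"none"` (correction factor
#'   forced to 1).
#' @return a PET `climate_grid` (mm/month).
#' @export
thornthwaite_pet <- function(temperature, correction = c("daylength", "none")) {
  correction <- match.arg(correction)
  if (temperature$variable != "temperature") stopf("PET needs a temperature grid")
  if (is.null(temperature$lat)) stopf("PET needs per-cell latitudes")
  clim <- climatology(temperature)$values
  tpos <- pmax(clim, 0)
  ncell <- dim(clim)[1] * dim(clim)[2]
  heat <- matrix(rowSums(matrix((tpos / 5)^1.514, ncell, 12L)),
                 dim(clim)[1], dim(clim)[2])
  a <- 6.75e-7 * heat^3 - 7.71e-5 * heat^2 + 1.792e-2 * heat + 0.49239

  mdays <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  midday <- cumsum(mdays) - mdays / 2
  k_fac <- matrix(1, length(temperature$lat), 12L)
  if (correction == "daylength") {
    phi <- temperature$lat * pi / 180
    for (m in 1:12) {
      delta <- 0.409 * sin(2 * pi * midday[m] / 365 - 1.39)
      x <- pmin(pmax(-tan(phi) * tan(delta), -1), 1)
      daylen <- 24 / pi * acos(x)
      k_fac[, m] <- daylen / 12 * mdays[m] / 30
    }
  }

  ny <- length(temperature$lat); nx <- length(temperature$lon)
  out <- array(0, dim(temperature$values))
  for (t in seq_len(dim(out)[3])) {
    tv <- matrix(temperature$values[, , t], ny, nx)
    pet <- matrix(0, ny, nx)
    pos <- which(tv > 0 & heat > 0)
    if (length(pos)) {
      pet[pos] <- 16 * (10 * tv[pos] / heat[pos])^(a[pos])
    }
    pet <- pet * k_fac[, temperature$month[t]]
    pet[is.na(tv)] <- NA_real_
    out[, , t] <- pet
  }
  climate_grid(out, "pet", temperature$lon, temperature$lat,
               temperature$year, temperature$month)
}

#' Monthly climatic water balance
#'
#' `CWB = precipitation - PET`, elementwise on aligned grids/time axes.
#'
#' @param precipitation a precipitation [climate_grid()].
#' @param pet a PET [climate_grid()], e.g. from [thornthwaite_pet()].
#' @return a CWB `climate_grid` (mm/month, signed).
#' @export
monthly_cwb <- function(precipitation, pet) {
  if (!identical(precipitation$year, pet$year) ||
      !identical(precipitation$month, pet$month) ||
      !isTRUE(all.equal(precipitation$lon, pet$lon)) ||
      !isTRUE(all.equal(precipitation$lat, pet$lat))) {
    stopf("precipitation and PET must share grid and time axis")
  }
  climate_grid(precipitation$values - pet$values, "cwb",
               precipitation$lon, precipitation$lat,
               precipitation$year, precipitation$month)
}

#' Catalogue of the 14 projection periods
#'
#' Two historic climate normals (1951-1980, 1991-2020), three scenarios
#' crossed with three 30-year future normals (2021-2050, 2046-2075,
#' 2071-2100), and three AMOC-collapse variants of the very last normal
#' (2071-2100).
#'
#' @param scenarios scenario labels (default `ssp126`, `ssp245`, `ssp585`).
#' @return a data.frame with columns `label`, `start`, `end`, `scenario`,
#'   `amoc` (`"on"`/`"off"`; `"off"` marks the collapse variants).
#' @export
period_catalogue <- function(scenarios = c("ssp126", "ssp245", "ssp585")) {
  rows <- list(
    data.frame(label = "hist_1951_1980", start = 1951L, end = 1980L,
               scenario = "historic", amoc = "on"),
    data.frame(label = "hist_1991_2020", start = 1991L, end = 2020L,
               scenario = "historic", amoc = "on"))
  spans <- list(c(2021L, 2050L), c(2046L, 2075L), c(2071L, 2100L))
  for (sc in scenarios) for (sp in spans) {
    rows[[length(rows) + 1L]] <-
      data.frame(label = sprintf("%s_%d_%d", sc, sp[1], sp[2]),
                 start = sp[1], end = sp[2], scenario = sc, amoc = "on")
  }
  for (sc in scenarios) {
    rows[[length(rows) + 1L]] <-
      data.frame(label = sprintf("%s_amoc_2071_2100", sc),
                 start = 2071L, end = 2100L, scenario = sc, amoc = "off")
  }
  do.call(rbind, rows)
}

# per-year aggregation over a [ny, nx, 12] block (+ previous December);
# vectorised across cells: columns of M are calendar months
year_stats <- function(tm, cm, t_dec_prev, c_dec_prev) {
  ny <- dim(tm)[1]; nx <- dim(tm)[2]
  Mt <- matrix(tm, ny * nx, 12L); Mc <- matrix(cm, ny * nx, 12L)
  shape <- function(v) matrix(v, ny, nx)
  col_list <- function(M) lapply(seq_len(ncol(M)), function(j) M[, j])
  row_max <- function(M) do.call(pmax, col_list(M))
  row_min <- function(M) do.call(pmin, col_list(M))
  row_sd <- function(M) {
    mu <- rowMeans(M)
    sqrt(pmax(rowSums(M * M) - ncol(M) * mu * mu, 0) / (ncol(M) - 1L))
  }
  djf_t <- if (is.null(t_dec_prev)) NULL else (t_dec_prev + tm[, , 1] + tm[, , 2]) / 3
  djf_c <- if (is.null(c_dec_prev)) NULL else (c_dec_prev + cm[, , 1] + cm[, , 2])
  list(
    t_ann = shape(rowMeans(Mt)), t_djf = djf_t,
    t_mam = shape(rowMeans(Mt[, 3:5, drop = FALSE])),
    t_jja = shape(rowMeans(Mt[, 6:8, drop = FALSE])),
    t_son = shape(rowMeans(Mt[, 9:11, drop = FALSE])),
    t_warm = shape(row_max(Mt)), t_cold = shape(row_min(Mt)),
    t_sd = shape(row_sd(Mt)), t_rng = shape(row_max(Mt) - row_min(Mt)),
    cwb_ann = shape(rowSums(Mc)), cwb_djf = djf_c,
    cwb_mam = shape(rowSums(Mc[, 3:5, drop = FALSE])),
    cwb_jja = shape(rowSums(Mc[, 6:8, drop = FALSE])),
    cwb_son = shape(rowSums(Mc[, 9:11, drop = FALSE])),
    cwb_min = shape(row_min(Mc)),
    cwb_sd = shape(row_sd(Mc)), cwb_rng = shape(row_max(Mc) - row_min(Mc)))
}

#' Derive bioclimatic variables over a 30-year climate normal
#'
#' Computes monthly PET (Thornthwaite) and CWB, derives the catalogue
#' variables per calendar year, and averages over the period's years.
#' Meteorological seasons are used; DJF takes December from the preceding
#' calendar year — the period's first year borrows its December from the
#' last pre-period month when the series provides it and otherwise drops
#' that year's DJF from the average. The driest month (minimal CWB) is
#' located per year, then averaged.
#'
#' @param temperature,precipitation [climate_grid()]s covering the period.
#' @param years calendar years of the period (e.g. `1951:1980`).
#' @param variables variable catalogue (default the canonical 17,
#'   [bioclim_variable_names()]); a subset may be requested.
#' @param period,model labels stored on the result.
#' @return a [bioclim_stack()].
#' @export
compute_bioclim <- function(temperature, precipitation, years,
                            variables = bioclim_variable_names(),
                            period = NA_character_, model = NA_character_) {
  if (!all(variables %in% bioclim_variable_names())) {
    stopf("unknown bioclim variables requested")
  }
  tt <- subset_years(temperature, years, lead_december = TRUE)
  pp <- subset_years(precipitation, years, lead_december = TRUE)
  for (y in years) {
    if (sum(tt$year == y) != 12L) stopf("incomplete year %d in temperature series", y)
    if (sum(pp$year == y) != 12L) stopf("incomplete year %d in precipitation series", y)
  }
  pet <- thornthwaite_pet(tt)
  cwb <- monthly_cwb(pp, pet)
  ny <- length(tt$lat); nx <- length(tt$lon)
  acc <- lapply(bioclim_variable_names(), function(v) matrix(0, ny, nx))
  names(acc) <- bioclim_variable_names()
  cnt <- stats::setNames(numeric(17), bioclim_variable_names())
  for (y in years) {
    sel <- which(tt$year == y)
    tm <- tt$values[, , sel, drop = FALSE]
    cm <- cwb$values[, , sel, drop = FALSE]
    prev <- which(tt$year == y - 1L & tt$month == 12L)
    t_prev <- if (length(prev)) tt$values[, , prev[1]] else NULL
    c_prev <- if (length(prev)) cwb$values[, , prev[1]] else NULL
    st <- year_stats(tm, cm, t_prev, c_prev)
    for (v in names(st)) {
      if (is.null(st[[v]])) next
      acc[[v]] <- acc[[v]] + st[[v]]
      cnt[v] <- cnt[v] + 1
    }
  }
  vals <- array(NA_real_, c(ny, nx, length(variables)),
                dimnames = list(NULL, NULL, variables))
  for (v in variables) vals[, , v] <- acc[[v]] / cnt[v]
  bioclim_stack(vals, tt$lon, tt$lat, period = period, model = model,
                provenance = sprintf("computed over %d-%d", min(years), max(years)))
}
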