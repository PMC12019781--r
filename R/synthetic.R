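#' Configuration of a synthetic climate world
#'
#' Defines a small, fully seeded world used to exercise the whole pipeline:
#' a coarse "observed" grid (CRU-like), a finer target grid reached through a
#' fixed integer refinement factor (CHELSA-like climatology), a set of
#' pseudo-climate-models with known additive temperature and multiplicative
#' precipitation biases, per-scenario warming/drying trends, and an
#' AMOC-collapse anomaly specification with a north-south gradient.
#'
#' Temperature follows a latitude + elevation gradient with a seasonal
#' sinusoid whose amplitude grows eastward (a continentality axis), plus iid
#' noise; precipitation is a smooth positive field modulated seasonally with
#' multiplicative lognormal noise. Elevation is a fixed smooth surface built
#' from low-order harmonics so the fine grid carries genuine sub-coarse-cell
#' structure.
#'
#' @param nx,ny coarse-grid cell counts (lon, lat).
#' @param downscale_factor integer refinement factor of the fine grid.
#' @param lon_range,lat_range extents in degrees.
#' @param years_observed calendar years the observed series covers (the
#'   historic reference runs past the model-overlap window, like a gridded
#'   observational product updated beyond the model baseline).
#' @param years_historic,years_future calendar year vectors; the historic
#'   range is the observed/model overlap used for quantile-map calibration.
#' @param n_models number of pseudo-climate models (>= 2).
#' @param scenarios character vector of scenario labels.
#' @param bias_temperature additive degC offset per model.
#' @param bias_precipitation multiplicative precipitation factor per model.
#' @param variance_inflation per-model noise-scale factor.
#' @param trend_warming degC per decade per scenario (applied from the first
#'   future year).
#' @param trend_precip percent precipitation change per decade per scenario.
#' @param amoc_max_cooling most negative surface-air-temperature anomaly
#'   (degC, at the northern edge in the coldest month).
#' @param amoc_precip_reduction most negative relative precipitation anomaly
#'   (fraction, >= -1).
#' @param amoc_gradient_power exponent of the north-south anomaly gradient.
#' @param noise_temperature iid noise SD (degC) of monthly temperature.
#' @param noise_precipitation lognormal sigma of monthly precipitation noise.
#' @param elevation_seed,climate_seed,species_seed integer seeds; all
#'   randomness flows through these, never through global state.
#' @return a `synthetic_world_config` list.
#' @export
synthetic_world_config <- function(nx = 12L, ny = 10L, downscale_factor = 5L,
                                   lon_range = c(5, 17), lat_range = c(44, 54),
                                   years_observed = 1951:2020,
                                   years_historic = 1951:2014,
                                   years_future = 2015:2100,
                                   n_models = 3L,
                                   scenarios = c("ssp126", "ssp245", "ssp585"),
                                   bias_temperature = NULL,
                                   bias_precipitation = NULL,
                                   variance_inflation = NULL,
                                   trend_warming = c(ssp126 = 0.15, ssp245 = 0.3, ssp585 = 0.55),
                                   trend_precip = c(ssp126 = 0, ssp245 = -1, ssp585 = -2),
                                   amoc_max_cooling = -8,
                                   amoc_precip_reduction = -0.3,
                                   amoc_gradient_power = 2,
                                   noise_temperature = 1.0,
                                   noise_precipitation = 0.25,
                                   elevation_seed = 101L, climate_seed = 202L,
                                   species_seed = 303L) {
  if (diff(range(lon_range)) <= 0 || diff(range(lat_range)) <= 0) {
    stopf("degenerate lon/lat extent")
  }
  if (n_models < 2L) stopf("n_models must be >= 2")
  if (max(years_historic) >= min(years_future)) stopf("historic and future years must not overlap")
  if (!all(years_historic %in% years_observed)) {
    stopf("the calibration window must lie inside the observed years")
  }
  if (is.null(bias_temperature)) bias_temperature <- seq(-1.5, 1.5, length.out = n_models)
  if (is.null(bias_precipitation)) bias_precipitation <- seq(0.85, 1.2, length.out = n_models)
  if (is.null(variance_inflation)) variance_inflation <- rep(1, n_models)
  stopifnot(length(bias_temperature) == n_models,
            length(bias_precipitation) == n_models,
            length(variance_inflation) == n_models)
  if (!all(scenarios %in% names(trend_warming)) || !all(scenarios %in% names(trend_precip))) {
    stopf("trend_warming/trend_precip must be named by scenario")
  }
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny),
    downscale_factor = as.integer(downscale_factor),
    lon_range = lon_range, lat_range = lat_range,
    years_observed = as.integer(years_observed),
    years_historic = as.integer(years_historic),
    years_future = as.integer(years_future),
    n_models = as.integer(n_models), scenarios = scenarios,
    models = sprintf("model%02d", seq_len(n_models)),
    bias_temperature = bias_temperature,
    bias_precipitation = bias_precipitation,
    variance_inflation = variance_inflation,
    trend_warming = trend_warming, trend_precip = trend_precip,
    amoc_max_cooling = amoc_max_cooling,
    amoc_precip_reduction = amoc_precip_reduction,
    amoc_gradient_power = amoc_gradient_power,
    noise_temperature = noise_temperature,
    noise_precipitation = noise_precipitation,
    elevation_seed = as.integer(elevation_seed),
    climate_seed = as.integer(climate_seed),
    species_seed = as.integer(species_seed)
  ), class = "synthetic_world_config")
}

world_axes <- function(config, fine = FALSE) {
  f <- if (fine) config$downscale_factor else 1L
  nx <- config$nx * f; ny <- config$ny * f
  dx <- diff(config$lon_range) / nx
  dy <- diff(config$lat_range) / ny
  list(lon = config$lon_range[1] + (seq_len(nx) - 0.5) * dx,
       lat = config$lat_range[2] - (seq_len(ny) - 0.5) * dy)
}

#' Elevation surface of the synthetic world (km)
#'
#' A fixed, smooth ridge system from low-order 2-d harmonics, rescaled to
#' 0-1.5 km; evaluating it on the fine grid yields real sub-coarse-cell
#' relief for the downscaling stage.
#'
#' @param config a [synthetic_world_config()].
#' @param fine evaluate on the fine grid?
#' @return matrix `[lat, lon]` of elevations in km.
#' @export
world_elevation <- function(config, fine = FALSE) {
  co <- with_seed(config$elevation_seed, {
    k <- 4L
    list(a = stats::runif(k, 0.4, 1), fx = sample(1:3, k, replace = TRUE),
         fy = sample(1:3, k, replace = TRUE), ph = stats::runif(k, 0, 2 * pi))
  })
  ax <- world_axes(config, fine)
  u <- (ax$lon - config$lon_range[1]) / diff(config$lon_range)
  v <- (ax$lat - config$lat_range[1]) / diff(config$lat_range)
  e <- matrix(0, length(ax$lat), length(ax$lon))
  for (k in seq_along(co$a)) {
    e <- e + co$a[k] * outer(sin(2 * pi * co$fy[k] * v + co$ph[k]),
                             sin(2 * pi * co$fx[k] * u + co$ph[k] / 2))
  }
  lo <- min(e); hi <- max(e)
  1.5 * (e - lo) / (hi - lo)
}

# deterministic monthly means of the synthetic climate (no noise)
# month effect: coldest near January, warmest near July
season_shape <- function(month) -cos(2 * pi * (month - 0.5) / 12)

# fixed smooth spatial pattern of one calendar month (unit variance-ish),
# evaluated analytically so coarse and fine grids see the same surface;
# gives every monthly/seasonal aggregate its own spatial signal instead of
# making all of them linear combinations of two latent gradients
monthly_pattern <- function(config, lon, lat, m, kind) {
  off <- if (kind == "temperature") 7000L else 8000L
  co <- with_seed(config$elevation_seed + off + m, {
    k <- 3L
    list(a = stats::runif(k, 0.5, 1), fx = sample(1:4, k, replace = TRUE),
         fy = sample(1:4, k, replace = TRUE), ph = stats::runif(k, 0, 2 * pi))
  })
  u <- (lon - config$lon_range[1]) / diff(config$lon_range)
  v <- (lat - config$lat_range[1]) / diff(config$lat_range)
  g <- matrix(0, length(lat), length(lon))
  for (k in seq_along(co$a)) {
    g <- g + co$a[k] * outer(sin(2 * pi * co$fy[k] * v + co$ph[k]),
                             sin(2 * pi * co$fx[k] * u + co$ph[k] / 3))
  }
  g / sqrt(sum(co$a^2) / 2)
}

world_deterministic <- function(config, lon, lat, elev, year, month) {
  nt <- length(year)
  amp <- 4 + 8 * (lon - config$lon_range[1]) / diff(config$lon_range)
  t_base <- outer(-0.6 * (lat - config$lat_range[1]), rep(1, length(lon))) +
    14 - 6.5 * elev
  p_base <- 45 + 45 * elev +
    matrix(20 * sin(pi * (lon - config$lon_range[1]) / diff(config$lon_range)),
           nrow = length(lat), ncol = length(lon), byrow = TRUE)
  trend <- 0.01 * (year - config$years_historic[1])
  tv <- array(NA_real_, c(length(lat), length(lon), nt))
  pv <- array(NA_real_, c(length(lat), length(lon), nt))
  s <- season_shape(month)
  amp_m <- matrix(amp, nrow = length(lat), ncol = length(lon), byrow = TRUE)
  gt <- lapply(1:12, function(m) monthly_pattern(config, lon, lat, m, "temperature"))
  gp <- lapply(1:12, function(m) monthly_pattern(config, lon, lat, m, "precipitation"))
  for (t in seq_len(nt)) {
    m <- month[t]
    tv[, , t] <- t_base + amp_m * s[t] + 1.5 * gt[[m]] + trend[t]
    pv[, , t] <- p_base * (1 + 0.35 * s[t]) * exp(0.15 * gp[[m]])
  }
  list(temperature = tv, precipitation = pv)
}

month_axis <- function(years) {
  list(year = rep(as.integer(years), each = 12L), month = rep(1:12, length(years)))
}

apply_scenario_trend <- function(values, variable, config, scenario, year_axis) {
  y0 <- config$years_future[1]
  extra <- pmax(year_axis - y0, 0)
  if (variable == "temperature") {
    shift <- config$trend_warming[[scenario]] / 10 * extra
    sweep(values, 3, shift, `+`)
  } else {
    # trend_precip is % per decade: factor = 1 + pct/100 * (years elapsed)/10
    fac <- pmax(1 + config$trend_precip[[scenario]] / 100 * extra / 10, 0)
    sweep(values, 3, fac, `*`)
  }
}

#' Generate the synthetic climate inputs
#'
#' Produces everything the preparation stages consume: an observed
#' temperature/precipitation pair on the coarse grid over the historic years,
#' one series pair per model x scenario spanning historic + future years with
#' the configured biases and trends, and deterministic 12-month climatologies
#' on both the coarse and the fine grid (the fine one carrying the
#' high-resolution relief signal).
#'
#' @param config a [synthetic_world_config()].
#' @return a list with elements `observed`, `models` (nested
#'   `[[model]][[scenario]]`), `coarse_climatology`, `fine_climatology`,
#'   `elevation` (`coarse`, `fine` matrices) and `grid` metadata.
#' @export
generate_climate <- function(config) {
  axc <- world_axes(config, fine = FALSE)
  axf <- world_axes(config, fine = TRUE)
  elev_c <- world_elevation(config, fine = FALSE)
  elev_f <- world_elevation(config, fine = TRUE)

  ax_hist <- month_axis(config$years_observed)
  det_hist <- world_deterministic(config, axc$lon, axc$lat, elev_c,
                                  ax_hist$year, ax_hist$month)
  nt_h <- length(ax_hist$year); ncell <- length(axc$lat) * length(axc$lon)

  noise_pair <- function(seed, nt, infl = 1) {
    with_seed(seed, list(
      t = array(stats::rnorm(ncell * nt, sd = config$noise_temperature * infl),
                c(length(axc$lat), length(axc$lon), nt)),
      p = array(stats::rnorm(ncell * nt, sd = 1), c(length(axc$lat), length(axc$lon), nt))))
  }
  lognoise <- function(z, infl = 1) {
    s <- config$noise_precipitation * infl
    if (s == 0) array(1, dim(z)) else exp(s * z - s^2 / 2)
  }

  nz <- noise_pair(config$climate_seed, nt_h)
  obs_t <- climate_grid(det_hist$temperature + nz$t, "temperature",
                        axc$lon, axc$lat, ax_hist$year, ax_hist$month)
  obs_p <- climate_grid(det_hist$precipitation * lognoise(nz$p), "precipitation",
                        axc$lon, axc$lat, ax_hist$year, ax_hist$month)

  years_all <- c(config$years_historic, config$years_future)
  ax_all <- month_axis(years_all)
  det_all <- world_deterministic(config, axc$lon, axc$lat, elev_c,
                                 ax_all$year, ax_all$month)
  nt_a <- length(ax_all$year)

  models <- list()
  for (mi in seq_len(config$n_models)) {
    mname <- config$models[mi]
    models[[mname]] <- list()
    for (si in seq_along(config$scenarios)) {
      sc <- config$scenarios[si]
      seed <- config$climate_seed + 1000L * mi + si
      nzm <- noise_pair(seed, nt_a, config$variance_inflation[mi])
      tv <- det_all$temperature + config$bias_temperature[mi] + nzm$t
      tv <- apply_scenario_trend(tv, "temperature", config, sc, ax_all$year)
      pv <- det_all$precipitation * config$bias_precipitation[mi] *
        lognoise(nzm$p, config$variance_inflation[mi])
      pv <- apply_scenario_trend(pv, "precipitation", config, sc, ax_all$year)
      models[[mname]][[sc]] <- list(
        temperature = climate_grid(tv, "temperature", axc$lon, axc$lat,
                                   ax_all$year, ax_all$month),
        precipitation = climate_grid(pv, "precipitation", axc$lon, axc$lat,
                                     ax_all$year, ax_all$month))
    }
  }

  clim_of <- function(lon, lat, elev) {
    mid_year <- round(mean(config$years_historic))
    det <- world_deterministic(config, lon, lat, elev, rep(mid_year, 12L), 1:12)
    list(temperature = monthly_climatology(det$temperature, "temperature", lon, lat),
         precipitation = monthly_climatology(det$precipitation, "precipitation", lon, lat))
  }

  list(observed = list(temperature = obs_t, precipitation = obs_p),
       models = models,
       coarse_climatology = clim_of(axc$lon, axc$lat, elev_c),
       fine_climatology = clim_of(axf$lon, axf$lat, elev_f),
       elevation = list(coarse = elev_c, fine = elev_f),
       grid = list(coarse = axc, fine = axf))
}

#' Generate AMOC-collapse anomaly maps
#'
#' Twelve monthly surface-air-temperature anomaly fields (degC, additive,
#' non-positive, strongest in the north and in winter) and twelve relative
#' precipitation anomaly fields (fraction, mostly negative, same gradient),
#' smooth in space, on the coarse grid.
#'
#' @param config a [synthetic_world_config()].
#' @return an [anomaly_maps()] object.
#' @export
generate_anomalies <- function(config) {
  ax <- world_axes(config, fine = FALSE)
  w <- ((ax$lat - config$lat_range[1]) / diff(config$lat_range))^config$amoc_gradient_power
  w <- w / max(w)  # anchor the configured maximum cooling at the northern cell row
  sat <- array(0, c(length(ax$lat), length(ax$lon), 12L))
  rpa <- array(0, c(length(ax$lat), length(ax$lon), 12L))
  for (m in 1:12) {
    sm <- 0.7 + 0.3 * cos(2 * pi * (m - 1) / 12)   # max 1 in January
    rm <- 0.85 + 0.15 * cos(2 * pi * (m - 1) / 12)
    sat[, , m] <- config$amoc_max_cooling * sm * matrix(w, length(ax$lat), length(ax$lon))
    rpa[, , m] <- pmax(config$amoc_precip_reduction * rm *
                         matrix(w, length(ax$lat), length(ax$lon)), -1)
  }
  anomaly_maps(sat, rpa, ax$lon, ax$lat)
}

#' Specification of a synthetic species
#'
#' A species whose occurrence probability is, by construction, a product of
#' independent Gaussian suitabilities over 2-3 named bioclimatic variables —
#' the same conflated-independent structure the envelope model assumes, so
#' parameter recovery is well-posed.
#'
#' @param species species name.
#' @param variables 2-3 names from [bioclim_variable_names()].
#' @param optima per-variable suitability center (variable units).
#' @param tolerances per-variable Gaussian SD (> 0, variable units).
#' @param n_records number of occurrence records to draw.
#' @return a `synthetic_species_spec`.
#' @export
synthetic_species_spec <- function(species, variables, optima, tolerances, n_records) {
  if (length(variables) < 2L || length(variables) > 3L) {
    stopf("a synthetic species needs 2-3 generating variables")
  }
  if (!all(variables %in% bioclim_variable_names())) {
    stopf("generating variables must come from the canonical 17-variable list")
  }
  if (length(optima) != length(variables) || length(tolerances) != length(variables)) {
    stopf("optima/tolerances must match the generating variables")
  }
  if (any(tolerances <= 0)) stopf("tolerances must be > 0")
  structure(list(species = species, variables = variables,
                 optima = as.numeric(optima), tolerances = as.numeric(tolerances),
                 n_records = as.integer(n_records)),
            class = "synthetic_species_spec")
}

#' True suitability of a synthetic species on a bioclim stack
#'
#' @param spec a [synthetic_species_spec()].
#' @param bioclim a [bioclim_stack()].
#' @return matrix `[lat, lon]` of suitabilities in (0, 1].
#' @export
true_suitability <- function(spec, bioclim) {
  s <- matrix(1, length(bioclim$lat), length(bioclim$lon))
  for (k in seq_along(spec$variables)) {
    v <- bioclim$values[, , spec$variables[k]]
    s <- s * exp(-0.5 * ((v - spec$optima[k]) / spec$tolerances[k])^2)
  }
  s
}

#' True suitable region of a synthetic species
#'
#' Cells where every generating variable lies within `z` tolerances of its
#' optimum — the reference region for overlap (Jaccard) checks.
#'
#' @inheritParams true_suitability
#' @param z half-width of the region in tolerance units (default 2).
#' @return logical matrix `[lat, lon]`.
#' @export
true_suitable_region <- function(spec, bioclim, z = 2) {
  ok <- matrix(TRUE, length(bioclim$lat), length(bioclim$lon))
  for (k in seq_along(spec$variables)) {
    v <- bioclim$values[, , spec$variables[k]]
    ok <- ok & abs(v - spec$optima[k]) <= z * spec$tolerances[k]
  }
  ok & !is.na(bioclim$values[, , 1])
}

#' Sample occurrence records for synthetic species
#'
#' Cells are drawn without replacement with probability proportional to the
#' product-Gaussian suitability, so every species occupies distinct cells
#' (unique coordinate pairs by construction) around its configured optima.
#'
#' @param specs a list of [synthetic_species_spec()].
#' @param bioclim a [bioclim_stack()] covering the grid.
#' @param seed integer seed (per-species streams are derived from it).
#' @return a data.frame with columns `species`, `lon`, `lat`.
#' @export
generate_occurrences <- function(specs, bioclim, seed) {
  if (inherits(specs, "synthetic_species_spec")) specs <- list(specs)
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (sp$n_records == 0L) {
      out[[i]] <- data.frame(species = character(), lon = numeric(), lat = numeric())
      next
    }
    s <- true_suitability(sp, bioclim)
    s[is.na(bioclim$values[, , 1])] <- 0
    eligible <- which(s > 1e-12)
    if (sp$n_records > length(eligible)) {
      stopf("species '%s': %d records requested but only %d distinct suitable cells",
            sp$species, sp$n_records, length(eligible))
    }
    cells <- with_seed(seed + i, sample(eligible, sp$n_records, prob = s[eligible]))
    rr <- arrayInd(cells, dim(s))
    out[[i]] <- data.frame(species = sp$species,
                           lon = bioclim$lon[rr[, 2]], lat = bioclim$lat[rr[, 1]])
  }
  do.call(rbind, out)
}

#' Default synthetic species set
#'
#' Builds `n` species whose generating pairs cycle through three weakly
#' related climate axes of the synthetic world (annual temperature, annual
#' temperature range, annual water balance), with optima placed at interior
#' quantiles of the realised fields so each envelope sits inside the gradient.
#'
#' @param bioclim the calibration-period [bioclim_stack()].
#' @param n number of species.
#' @param n_records records per species.
#' @param seed integer seed for optimum placement.
#' @return a list of [synthetic_species_spec()].
#' @export
default_species_specs <- function(bioclim, n = 20L, n_records = 350L, seed = 7L) {
  pairs <- list(c("t_ann", "cwb_ann"), c("t_ann", "t_rng"), c("t_rng", "cwb_ann"))
  qs <- with_seed(seed, stats::runif(2L * n, 0.2, 0.8))
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    vars <- pairs[[(i - 1L) %% length(pairs) + 1L]]
    opt <- tol <- numeric(2)
    for (k in 1:2) {
      v <- bioclim$values[, , vars[k]]
      v <- v[!is.na(v)]
      opt[k] <- stats::quantile(v, qs[2 * (i - 1) + k], names = FALSE)
      tol[k] <- 0.22 * stats::sd(v)
    }
    specs[[i]] <- synthetic_species_spec(sprintf("species_%02d", i), vars,
                                         opt, tol, n_records)
  }
  specs
}
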