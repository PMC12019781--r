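# deterministic toy series on one grid: values = climatology + anomaly
toy_series <- function(variable, clim_monthly, anomaly, years = 1951:1960,
                       lon = c(10, 11), lat = c(51, 50)) {
  nt <- 12L * length(years)
  base <- rep(clim_monthly, length(years))
  vals <- array(rep(base + anomaly, each = length(lon) * length(lat)),
                c(length(lat), length(lon), nt))
  climate_grid(aperm(vals, c(1, 2, 3)), variable, lon, lat,
               rep(years, each = 12L), rep(1:12, length(years)))
}

test_that("downscaling with identical grids and climatologies is the identity", {
  clim <- monthly_climatology(array(rep(5 + 1:12, each = 4), c(2, 2, 12)),
                              "temperature", c(10, 11), c(51, 50))
  ser <- toy_series("temperature", 5 + 1:12, anomaly = 0.7)
  out <- change_factor_downscale(ser, clim, clim)
  expect_equal(out$values, ser$values, tolerance = 1e-13)
})

test_that("temperature downscaling adds the coarse anomaly to the fine climatology", {
  cl <- small_climate()
  obs <- cl$observed$temperature
  # constant +1.5 anomaly over the coarse climatology
  vals <- array(NA_real_, dim(obs$values))
  for (t in seq_len(dim(vals)[3])) {
    vals[, , t] <- cl$coarse_climatology$temperature$values[, , obs$month[t]] + 1.5
  }
  ser <- climate_grid(vals, "temperature", obs$lon, obs$lat, obs$year, obs$month)
  out <- change_factor_downscale(ser, cl$fine_climatology$temperature,
                                 cl$coarse_climatology$temperature)
  for (t in c(1L, 7L)) {
    expect_equal(out$values[, , t] - cl$fine_climatology$temperature$values[, , out$month[t]],
                 matrix(1.5, length(out$lat), length(out$lon)), tolerance = 1e-12)
  }
})

test_that("precipitation downscaling scales the fine climatology by the coarse ratio", {
  cl <- small_climate()
  obs <- cl$observed$precipitation
  vals <- array(NA_real_, dim(obs$values))
  for (t in seq_len(dim(vals)[3])) {
    vals[, , t] <- cl$coarse_climatology$precipitation$values[, , obs$month[t]] * 2
  }
  ser <- climate_grid(vals, "precipitation", obs$lon, obs$lat, obs$year, obs$month)
  out <- change_factor_downscale(ser, cl$fine_climatology$precipitation,
                                 cl$coarse_climatology$precipitation)
  for (t in c(3L, 8L)) {
    expect_equal(out$values[, , t],
                 cl$fine_climatology$precipitation$values[, , out$month[t]] * 2,
                 tolerance = 1e-12)
  }
})

test_that("quantile mapping a series onto itself is the identity", {
  fo <- small_fine_obs()
  obs <- fo$temperature
  qm <- fit_quantile_map(obs, obs, 1951:1980)
  out <- apply_quantile_map(subset_years(obs, 1951:1980), qm)
  expect_lt(max(abs(out$values - subset_years(obs, 1951:1980)$values)), 1e-9)
})

test_that("a constant +2 temperature offset is removed at interior quantiles", {
  fo <- small_fine_obs()
  obs <- subset_years(fo$temperature, 1951:1980)
  shifted <- climate_grid(obs$values + 2, "temperature", obs$lon, obs$lat,
                          obs$year, obs$month)
  qm <- fit_quantile_map(obs, shifted, 1951:1980)
  out <- apply_quantile_map(shifted, qm)
  expect_lt(max(abs(out$values - obs$values)), 0.2)
  expect_lt(stats::median(abs(out$values - obs$values)), 1e-6)
})

test_that("stored quantile tables are monotone non-decreasing", {
  fo <- small_fine_obs()
  qm <- fit_quantile_map(fo$temperature, fo$temperature, 1951:1980)
  dif <- apply(qm$q_obs, c(1, 2, 3), function(v) min(diff(v)))
  expect_true(all(dif >= -1e-12, na.rm = TRUE))
})

test_that("the fitted transfer function is non-decreasing in its input", {
  fo <- small_fine_obs()
  obs <- fo$temperature
  noisy <- climate_grid(obs$values * 1.1 + 0.5, "temperature", obs$lon,
                        obs$lat, obs$year, obs$month)
  qm <- fit_quantile_map(obs, noisy, 1951:1980)
  xs <- seq(min(noisy$values), max(noisy$values), length.out = 60)
  ys <- envelopeshift:::qmap_cell(xs, qm$q_mod[2, 3, 6, ], qm$q_obs[2, 3, 6, ],
                                  qm$probs, "temperature")
  expect_true(all(diff(ys) >= -1e-12))
})

test_that("values at stored model quantiles map exactly to paired observed quantiles", {
  fo <- small_fine_obs()
  obs <- fo$temperature
  shifted <- climate_grid(obs$values + 2, "temperature", obs$lon, obs$lat,
                          obs$year, obs$month)
  qm <- fit_quantile_map(obs, shifted, 1951:1980)
  ks <- c(1L, 25L, 50L, 75L, 99L)
  got <- envelopeshift:::qmap_cell(qm$q_mod[1, 1, 3, ks], qm$q_mod[1, 1, 3, ],
                                   qm$q_obs[1, 1, 3, ], qm$probs, "temperature")
  expect_equal(got, qm$q_obs[1, 1, 3, ks], tolerance = 1e-12)
})

test_that("an always-dry month stays dry after correction", {
  clim <- c(0, 0, rep(40, 10))
  ser <- toy_series("precipitation", clim, anomaly = 0)
  qm <- fit_quantile_map(ser, ser, 1951:1960)
  out <- apply_quantile_map(ser, qm)
  expect_true(all(out$values[, , out$month %in% 1:2] == 0))
})

test_that("short calibration windows are rejected", {
  fo <- small_fine_obs()
  expect_error(fit_quantile_map(fo$temperature, fo$temperature, 1951:1955),
               "at least 10 years")
})

test_that("corrected calibration series reproduces observed per-cell monthly ECDFs", {
  cfg <- synthetic_world_config(
    nx = 10L, ny = 10L, downscale_factor = 1L,
    years_observed = 1981:2010, years_historic = 1981:2010,
    years_future = 2011:2012, n_models = 2L,
    bias_temperature = c(1.5, 0), bias_precipitation = c(1.25, 1))
  cl <- generate_climate(cfg)
  for (v in c("temperature", "precipitation")) {
    obs <- cl$observed[[v]]
    mod <- subset_years(cl$models$model01$ssp126[[v]], 1981:2010)
    qm <- fit_quantile_map(obs, mod, 1981:2010)
    corr <- apply_quantile_map(mod, qm)
    expect_lt(max_ecdf_distance(corr, obs, 1981:2010), 0.05)
  }
})

test_that("constant-offset tail extrapolation preserves projected temperature trends", {
  cfg <- synthetic_world_config(
    nx = 6L, ny = 5L, downscale_factor = 1L,
    years_observed = 1951:2014, years_historic = 1951:2014,
    years_future = 2015:2100, n_models = 2L,
    bias_temperature = c(1.8, 0), bias_precipitation = c(1.2, 1))
  cl <- generate_climate(cfg)
  obs <- cl$observed$temperature
  mod <- cl$models$model01$ssp585$temperature
  qm <- fit_quantile_map(obs, mod, 1951:2014)
  corr <- apply_quantile_map(mod, qm)
  mean_over <- function(g, yrs) mean(subset_years(g, yrs)$values)
  raw_delta <- mean_over(mod, 2071:2100) - mean_over(mod, 1985:2014)
  corr_delta <- mean_over(corr, 2071:2100) - mean_over(corr, 1985:2014)
  expect_lt(abs(raw_delta - corr_delta), 0.2)
})
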