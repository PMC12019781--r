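# Shared fixtures, built once per test run and memoised. The "small world"
# is big enough for envelope fitting (432 fine cells) but cheap to simulate.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

small_world <- function() memo("world", synthetic_world_config(
  nx = 8L, ny = 6L, downscale_factor = 3L,
  years_observed = 1951:1990, years_historic = 1951:1984,
  years_future = 1985:2000, n_models = 2L))

small_climate <- function() memo("climate", generate_climate(small_world()))

small_fine_obs <- function() memo("fine_obs", {
  cl <- small_climate()
  list(temperature = change_factor_downscale(cl$observed$temperature,
                                             cl$fine_climatology$temperature,
                                             cl$coarse_climatology$temperature),
       precipitation = change_factor_downscale(cl$observed$precipitation,
                                               cl$fine_climatology$precipitation,
                                               cl$coarse_climatology$precipitation))
})

small_stack <- function() memo("stack", {
  fo <- small_fine_obs()
  compute_bioclim(fo$temperature, fo$precipitation, 1951:1980,
                  period = "hist_1951_1980", model = "observed")
})

small_specs <- function(n = 3L, n_records = 60L) memo("specs",
  default_species_specs(small_stack(), n = n, n_records = n_records, seed = 7L))

small_occurrences <- function() memo("occ",
  generate_occurrences(small_specs(), small_stack(), small_world()$species_seed))

# flat single-cell series builder for closed-form checks
series_1cell <- function(monthly, years, variable = "temperature") {
  nt <- 12L * length(years)
  vals <- array(rep(monthly, length(years)), c(1, 1, nt))
  climate_grid(vals, variable, lon = 10, lat = 50,
               year = rep(years, each = 12L), month = rep(1:12, length(years)))
}
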