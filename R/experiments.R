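#' Envelope parameter-recovery experiment
#'
#' The package's core validation experiment: build a synthetic world, derive
#' the calibration-period bioclim stack, sample species with known
#' 2-variable product-Gaussian envelopes, refit each with the exhaustive
#' subset search, and measure (a) whether the generating pair is recovered,
#' (b) the verification TSS and (c) the Jaccard overlap between the
#' projected suitable region (`p >= threshold`) and the true region (every
#' generating variable within 2 tolerances of its optimum).
#'
#' The default world refines a 12 x 10 coarse grid twelvefold (144 x 120
#' cells) so 300 records per species leave the suitability core unsaturated;
#' sampling without replacement over a saturated core would widen the
#' fitted envelopes artificially.
#'
#' @param n_species number of synthetic species (default 20).
#' @param n_records occurrence records per species (default 300).
#' @param world world configuration; seeds in it drive everything.
#' @param calibration_years years of the calibration normal.
#' @param species_seed seed for optimum placement and record sampling
#'   (default: the world's `species_seed`).
#' @return a data.frame (one row per species) with columns `species`,
#'   `true_vars`, `selected_vars`, `recovered`, `tss`, `threshold`,
#'   `jaccard`.
#' @export
recovery_experiment <- function(n_species = 20L, n_records = 300L,
                                world = synthetic_world_config(downscale_factor = 12L),
                                calibration_years = 1951:1980,
                                species_seed = NULL) {
  if (is.null(species_seed)) species_seed <- world$species_seed
  cl <- generate_climate(world)
  ft <- change_factor_downscale(cl$observed$temperature,
                                cl$fine_climatology$temperature,
                                cl$coarse_climatology$temperature)
  fp <- change_factor_downscale(cl$observed$precipitation,
                                cl$fine_climatology$precipitation,
                                cl$coarse_climatology$precipitation)
  st <- compute_bioclim(ft, fp, calibration_years)
  specs <- default_species_specs(st, n = n_species, n_records = n_records,
                                 seed = species_seed)
  occ <- generate_occurrences(specs, st, species_seed)
  rows <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    sp <- specs[[i]]
    env <- calibrate_envelope(occ[occ$species == sp$species, , drop = FALSE], st,
                              background_seed = species_seed + 100L + i)
    p <- project_occurrence(env, st)
    pred <- !is.na(p) & p >= env$threshold
    truth <- true_suitable_region(sp, st)
    rows[[i]] <- data.frame(
      species = sp$species,
      true_vars = paste(sort(sp$variables), collapse = "+"),
      selected_vars = paste(sort(env$variables), collapse = "+"),
      recovered = setequal(env$variables, sp$variables),
      tss = env$tss, threshold = env$threshold,
      jaccard = sum(pred & truth) / sum(pred | truth))
  }
  do.call(rbind, rows)
}

#' Quantile-mapping calibration-match experiment
#'
#' Builds a synthetic observed series and a model series carrying an
#' additive temperature bias and a multiplicative precipitation bias, fits
#' the empirical quantile map over the calibration window, applies it back
#' to the calibration series, and returns the largest per-cell per-month
#' ECDF (Kolmogorov-Smirnov) distance between the corrected and the
#' observed series for each variable. A successful correction reproduces
#' the observed distributions almost perfectly, so the distances sit near
#' the 1/n granularity of the empirical CDFs.
#'
#' @param nx,ny grid size (default 40 x 40).
#' @param years calibration years (default 60 years, 1955-2014).
#' @param bias_temperature additive model bias in degC (default +2).
#' @param bias_precipitation multiplicative model bias (default 1.3).
#' @param climate_seed seed of the climate noise.
#' @return named numeric: max KS distance for `temperature` and
#'   `precipitation`.
#' @export
qmap_match_experiment <- function(nx = 40L, ny = 40L, years = 1955:2014,
                                  bias_temperature = 2, bias_precipitation = 1.3,
                                  climate_seed = 202L) {
  world <- synthetic_world_config(
    nx = nx, ny = ny, downscale_factor = 1L,
    years_observed = years, years_historic = years,
    years_future = (max(years) + 1L):(max(years) + 2L),
    n_models = 2L,
    bias_temperature = c(bias_temperature, 0),
    bias_precipitation = c(bias_precipitation, 1),
    climate_seed = climate_seed)
  cl <- generate_climate(world)
  out <- c(temperature = NA_real_, precipitation = NA_real_)
  for (v in c("temperature", "precipitation")) {
    obs <- cl$observed[[v]]
    mod <- subset_years(cl$models$model01[[world$scenarios[1]]][[v]], years)
    qm <- fit_quantile_map(obs, mod, years)
    corrected <- apply_quantile_map(mod, qm)
    out[v] <- max_ecdf_distance(corrected, obs, years)
  }
  out
}
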