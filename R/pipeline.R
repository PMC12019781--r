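#' Pipeline configuration
#'
#' Bundles the synthetic world, the species set and every tunable the
#' stages need. All randomness is derived from the seeds stored here.
#'
#' @param out_dir output directory (created if missing).
#' @param world a [synthetic_world_config()].
#' @param n_species number of synthetic species.
#' @param n_records occurrence records per species.
#' @param share_threshold species-filter share (default 0.01, the 1% rule).
#' @param zero_eps probability treated as zero in the evaluation stage.
#' @param min_count replacement-tally suppression count (default 5; scales
#'   with grid size, the continental analysis used 20,000 cells).
#' @param calibration_period period label the envelopes are calibrated on.
#' @param focal_period,amoc_period scenario-period labels emphasised in the
#'   evaluation: by default the middle-of-the-road scenario at the end of
#'   the century, with and without an AMOC collapse.
#' @param n_focal_species number of focal species in the evaluation.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            world = synthetic_world_config(),
                            n_species = 6L, n_records = 350L,
                            share_threshold = 0.01, zero_eps = 1e-3,
                            min_count = 5L,
                            calibration_period = "hist_1951_1980",
                            focal_period = "ssp245_2071_2100",
                            amoc_period = "ssp245_amoc_2071_2100",
                            n_focal_species = 4L) {
  structure(list(out_dir = out_dir, world = world,
                 n_species = as.integer(n_species),
                 n_records = as.integer(n_records),
                 share_threshold = share_threshold, zero_eps = zero_eps,
                 min_count = as.integer(min_count),
                 calibration_period = calibration_period,
                 focal_period = focal_period, amoc_period = amoc_period,
                 n_focal_species = as.integer(n_focal_species)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()] arguments; a `world` mapping
#' is passed to [synthetic_world_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path, eval.expr = TRUE)
  world <- do.call(synthetic_world_config, if (is.null(y$world)) list() else y$world)
  y$world <- world
  do.call(pipeline_config, y)
}

hash_obj <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE, version = 2)
  unname(tools::md5sum(f))
}

save_stage <- function(obj, path) {
  saveRDS(obj, path, compress = FALSE, version = 2)
  unname(tools::md5sum(path))
}

#' Run the full projection pipeline
#'
#' Executes simulate, downscale, quantile-map, AMOC overlay, bioclim,
#' envelope fitting, projection and evaluation in order on the configured
#' synthetic world, writing one artifact per stage under `out_dir` plus a
#' `manifest.json` recording the config hash and per-stage output checksums.
#' A stage whose artifact already exists with a matching checksum under an
#' unchanged config is skipped and marked `cached`; a corrupted artifact
#' forces that stage and all downstream stages to re-run.
#'
#' @param config a [pipeline_config()] (or path to its YAML form).
#' @param quiet suppress progress messages.
#' @return the run manifest (invisibly contains per-stage paths, checksums
#'   and cached flags); stage results live in the written `.rds` artifacts.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  cfg_hash <- hash_obj(config[setdiff(names(config), "out_dir")])
  man_path <- file.path(config$out_dir, "manifest.json")
  old_man <- if (file.exists(man_path)) {
    tryCatch(jsonlite::fromJSON(man_path, simplifyVector = FALSE), error = function(e) NULL)
  } else NULL
  reuse <- !is.null(old_man) && identical(old_man$config_hash, cfg_hash)

  stages <- list()
  dirty <- FALSE
  run_stage <- function(name, fun) {
    path <- file.path(config$out_dir, paste0(name, ".rds"))
    if (reuse && !dirty && !is.null(old_man$stages[[name]]) && file.exists(path) &&
        identical(unname(tools::md5sum(path)), old_man$stages[[name]]$md5)) {
      say("stage %s: cached", name)
      stages[[name]] <<- list(path = path, md5 = old_man$stages[[name]]$md5,
                              cached = TRUE)
      return(readRDS(path))
    }
    dirty <<- TRUE
    say("stage %s: running", name)
    obj <- tryCatch(fun(), error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    md5 <- save_stage(obj, path)
    stages[[name]] <<- list(path = path, md5 = md5, cached = FALSE)
    obj
  }

  world <- config$world
  catalogue <- period_catalogue(world$scenarios)

  sim <- run_stage("simulate", function() {
    list(climate = generate_climate(world), anomalies = generate_anomalies(world))
  })

  fine_obs <- run_stage("downscale", function() {
    cl <- sim$climate
    list(temperature = change_factor_downscale(cl$observed$temperature,
                                               cl$fine_climatology$temperature,
                                               cl$coarse_climatology$temperature),
         precipitation = change_factor_downscale(cl$observed$precipitation,
                                                 cl$fine_climatology$precipitation,
                                                 cl$coarse_climatology$precipitation))
  })

  qmapped <- run_stage("qmap", function() {
    cl <- sim$climate
    fg <- cl$grid$fine
    out <- list()
    for (mo in world$models) {
      out[[mo]] <- list()
      for (sc in world$scenarios) {
        ser <- cl$models[[mo]][[sc]]
        res <- list()
        for (v in c("temperature", "precipitation")) {
          g <- ser[[v]]
          fine_model <- climate_grid(
            regrid_nearest(g$values, g$lon, g$lat, fg$lon, fg$lat),
            v, fg$lon, fg$lat, g$year, g$month)
          qm <- fit_quantile_map(fine_obs[[v]], fine_model, world$years_historic)
          res[[v]] <- apply_quantile_map(fine_model, qm)
        }
        out[[mo]][[sc]] <- res
      }
    }
    out
  })

  overlaid <- run_stage("overlay", function() {
    fg <- sim$climate$grid$fine
    anom <- regrid_anomalies(sim$anomalies, fg$lon, fg$lat, method = "bilinear")
    out <- list()
    for (mo in world$models) {
      out[[mo]] <- list()
      for (sc in world$scenarios) {
        s <- qmapped[[mo]][[sc]]
        out[[mo]][[sc]] <- superimpose_anomalies(s$temperature, s$precipitation,
                                                 anom, period = 2071:2100)
      }
    }
    out
  })

  stacks <- run_stage("bioclim", function() {
    out <- list()
    for (r in seq_len(nrow(catalogue))) {
      per <- catalogue[r, ]
      yrs <- per$start:per$end
      if (per$scenario == "historic") {
        out[[per$label]] <- list(observed = compute_bioclim(
          fine_obs$temperature, fine_obs$precipitation, yrs,
          period = per$label, model = "observed"))
      } else {
        src <- if (per$amoc == "off") overlaid else qmapped
        out[[per$label]] <- lapply(stats::setNames(world$models, world$models),
          function(mo) {
            s <- src[[mo]][[per$scenario]]
            compute_bioclim(s$temperature, s$precipitation, yrs,
                            period = per$label, model = mo)
          })
      }
    }
    out
  })

  fitted <- run_stage("fit", function() {
    calib <- stacks[[config$calibration_period]][[1]]
    specs <- default_species_specs(calib, n = config$n_species,
                                   n_records = config$n_records,
                                   seed = world$species_seed)
    occ <- unique_occurrences(generate_occurrences(specs, calib, world$species_seed))
    filt <- filter_species(occ, config$share_threshold)
    envs <- list()
    for (sp in sort(unique(filt$occurrences$species))) {
      envs[[sp]] <- calibrate_envelope(
        filt$occurrences[filt$occurrences$species == sp, ], calib,
        background_seed = world$species_seed + match(sp, sort(unique(occ$species))))
    }
    list(specs = specs, occurrences = occ, filter_report = filt$report,
         envelopes = envs)
  })

  cube <- run_stage("project", function() {
    fields <- list(); ens <- list()
    for (sp in names(fitted$envelopes)) {
      fields[[sp]] <- list(); ens[[sp]] <- list()
      for (lbl in names(stacks)) {
        per_model <- lapply(stacks[[lbl]], function(st)
          project_occurrence(fitted$envelopes[[sp]], st))
        fields[[sp]][[lbl]] <- per_model
        ens[[sp]][[lbl]] <- ensemble_mean(per_model)
      }
    }
    list(fields = fields, ensemble = ens)
  })

  evaluation <- run_stage("evaluate", function() {
    ens <- cube$ensemble
    species <- names(ens)
    hist_lbl <- config$calibration_period
    focal <- species[seq_len(min(config$n_focal_species, length(species)))]
    per_species_fields <- function(lbl) lapply(ens, function(e) e[[lbl]])
    hist_fields <- per_species_fields(hist_lbl)

    dmaps <- list(); centers <- list(); trajectories <- list()
    for (sp in focal) {
      dmaps[[sp]] <- delta_p(ens[[sp]][[hist_lbl]], ens[[sp]][[config$focal_period]],
                             config$zero_eps)
      centers[[sp]] <- lapply(ens[[sp]], function(p) {
        if (all(is.na(p) | p <= config$zero_eps)) NULL else
          distribution_center(p, sim$climate$grid$fine$lon,
                              sim$climate$grid$fine$lat, zero_eps = config$zero_eps)
      })
      trajectories[[sp]] <- vapply(ens[[sp]], mean_occurrence,
                                   numeric(1), zero_eps = config$zero_eps)
    }

    dom <- dominance_change_maps(hist_fields, per_species_fields(config$focal_period),
                                 config$zero_eps)
    dom_amoc <- dominance_change_maps(hist_fields, per_species_fields(config$amoc_period),
                                      config$zero_eps)
    tally <- replacement_tally(hist_fields, per_species_fields(config$focal_period),
                               focal, config$min_count, config$zero_eps)
    tally_amoc <- replacement_tally(hist_fields, per_species_fields(config$amoc_period),
                                    focal, config$min_count, config$zero_eps)
    div <- diversity_change(hist_fields, per_species_fields(config$focal_period))
    div_amoc <- diversity_change(hist_fields, per_species_fields(config$amoc_period))

    sp_maps <- lapply(stats::setNames(species, species), function(sp)
      percentual_sd(cube$fields[[sp]][[config$focal_period]]))

    anova_fields <- list()
    spans <- grep("_2071_2100$", names(stacks), value = TRUE)
    spans <- spans[!grepl("amoc", spans)]
    for (mo in world$models) {
      anova_fields[[mo]] <- list()
      for (lbl in spans) {
        f <- lapply(cube$fields, function(sf) sf[[lbl]][[mo]])
        anova_fields[[mo]][[lbl]] <- Reduce(`+`, f) / length(f)
      }
    }
    unc <- anova_partition_maps(anova_fields)

    utils::write.csv(tally, file.path(config$out_dir, "replacement_tally.csv"),
                     row.names = FALSE)
    list(delta_p = dmaps, centers = centers, trajectories = trajectories,
         dominance = dom, dominance_amoc = dom_amoc,
         replacement = tally, replacement_amoc = tally_amoc,
         diversity = div, diversity_amoc = div_amoc,
         percentual_sd = sp_maps, anova = unc)
  })

  manifest <- list(package = "envelopeshift",
                   version = as.character(utils::packageVersion("envelopeshift")),
                   config_hash = cfg_hash,
                   seeds = list(elevation = world$elevation_seed,
                                climate = world$climate_seed,
                                species = world$species_seed),
                   stages = stages)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE), man_path)
  invisible(manifest)
}
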