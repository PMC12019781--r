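test_that("the species filter applies the ceiling share cutoff and reports shares", {
  toy <- data.frame(species = rep(c("a", "b", "c"), c(50, 30, 20)),
                    lon = runif(100), lat = runif(100))
  res <- filter_species(toy, 0.25)
  expect_identical(res$report$cutoff, 25L)
  expect_identical(sort(res$report$retained$species), c("a", "b"))
  expect_identical(res$report$retained_records, 80L)
  expect_equal(res$report$retained_share, 0.8)

  all_in <- filter_species(toy, 1e-6)
  expect_identical(all_in$report$n_retained, 3L)

  expect_error(filter_species(toy, 0), "share_threshold")
  expect_error(filter_species(toy, 1), "share_threshold")
  expect_error(filter_species(toy[0, ], 0.01), "empty")
})

test_that("envelope probabilities peak at the smoothed median and vanish outside support", {
  set.seed(31)
  x <- rnorm(2000, mean = 12, sd = 3)
  d <- fit_envelope_dist(x)
  expect_equal(envelope_pvalue(d$median, d), 1, tolerance = 1e-8)
  expect_identical(envelope_pvalue(d$support[2] + 5, d), 0)
  expect_identical(envelope_pvalue(d$support[1] - 5, d), 0)
  q10 <- stats::quantile(x, 0.1, names = FALSE)
  expect_lt(abs(envelope_pvalue(q10, d) - 0.2), 0.04)
  expect_error(envelope_pvalue(1, structure(list(), class = "lm")), "unfitted")
  expect_error(fit_envelope_dist(rep(3, 50)), "constant")
})

test_that("Fisher conflation matches the df-4 closed form and handles limits", {
  chi <- -2 * (log(0.5) + log(0.5))
  oracle <- exp(-chi / 2) * (1 + chi / 2)
  expect_lt(abs(fisher_conflate(c(0.5, 0.5)) - oracle), 1e-10)
  expect_identical(fisher_conflate(c(1, 1)), stats::pchisq(0, 4, lower.tail = FALSE))
  expect_equal(fisher_conflate(c(1, 1, 1)), 1)
  expect_identical(fisher_conflate(c(0, 0.7)), 0)
  expect_identical(fisher_conflate(c(0.2, 0.9, 0)), 0)
  expect_error(fisher_conflate(c(0.5, 1.2)), "0, 1")
  # conflation decreases as any component decreases
  expect_gt(fisher_conflate(c(0.6, 0.6)), fisher_conflate(c(0.6, 0.3)))
})

test_that("TSS is sensitivity plus specificity minus one", {
  expect_identical(tss(1, 1), 1)
  expect_identical(tss(0.5, 0.5), 0)
  expect_equal(tss(0.8, 0.7), 0.5, tolerance = 1e-12)
  expect_error(tss(1.2, 0.5), "sensitivity")
  expect_error(tss(0.5, -0.1), "specificity")
})

test_that("calibration recovers a well-separated species' generating pair", {
  st <- small_stack()
  specs <- small_specs()
  occ <- small_occurrences()
  sp <- specs[[1]]
  env <- calibrate_envelope(occ[occ$species == sp$species, ], st,
                            background_seed = 5L)
  # at 60 records the search may add a correlated third variable, but the
  # generating pair must be part of the selection (exact recovery at scale
  # is exercised by recovery_experiment())
  expect_true(all(sp$variables %in% env$variables))
  expect_gte(env$tss, 0.7)
  expect_true(env$threshold > 0 && env$threshold < 1)
  expect_identical(env$tss, env$sensitivity + env$specificity - 1)

  p <- project_occurrence(env, st)
  ii <- vapply(occ$lat[occ$species == sp$species],
               function(y) which.min(abs(st$lat - y)), 1L)
  jj <- vapply(occ$lon[occ$species == sp$species],
               function(x) which.min(abs(st$lon - x)), 1L)
  pres <- unique(cbind(ii, jj))
  expect_gt(mean(p[pres]), mean(p, na.rm = TRUE))
})

test_that("presences indistinguishable from background give near-zero TSS", {
  st <- small_stack()
  ncell <- length(st$lon) * length(st$lat)
  cells <- withr::with_seed(99, sample.int(ncell, 250))
  occ <- data.frame(
    species = "null",
    lon = st$lon[(cells - 1L) %/% length(st$lat) + 1L],
    lat = st$lat[(cells - 1L) %% length(st$lat) + 1L])
  env <- calibrate_envelope(occ, st, candidates = c("t_ann", "cwb_ann"),
                            background_seed = 3L)
  expect_lt(abs(env$tss), 0.15)
})

test_that("too few presences and constant variables are handled explicitly", {
  st <- small_stack()
  occ <- data.frame(species = "rare", lon = st$lon[1:5], lat = st$lat[1:5])
  expect_error(calibrate_envelope(occ, st), "presence")

  st2 <- st
  st2$values[, , "t_ann"] <- 5
  occ2 <- small_occurrences()
  sp <- small_specs()[[2]]
  expect_warning(
    calibrate_envelope(occ2[occ2$species == sp$species, ], st2,
                       candidates = c("t_ann", "t_rng", "cwb_ann"),
                       background_seed = 4L),
    "constant")
})

test_that("a stack shifted beyond every support projects to exactly zero", {
  st <- small_stack()
  specs <- small_specs()
  occ <- small_occurrences()
  shifted <- st
  shifted$values <- st$values + 1e4
  for (sp in specs) {
    env <- calibrate_envelope(occ[occ$species == sp$species, ], st,
                              background_seed = 6L)
    p <- project_occurrence(env, shifted)
    expect_true(all(p == 0))
  }
})

test_that("projection is deterministic and bounded in [0, 1]", {
  st <- small_stack()
  occ <- small_occurrences()
  sp <- small_specs()[[1]]
  env <- calibrate_envelope(occ[occ$species == sp$species, ], st,
                            background_seed = 7L)
  p1 <- project_occurrence(env, st)
  p2 <- project_occurrence(env, st)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1, na.rm = TRUE))
})

test_that("conflated probability falls along rays away from the medians", {
  st <- small_stack()
  occ <- small_occurrences()
  sp <- small_specs()[[1]]
  env <- calibrate_envelope(occ[occ$species == sp$species, ], st,
                            background_seed = 8L)
  meds <- vapply(env$dists, `[[`, numeric(1), "median")
  spans <- vapply(env$dists, function(d) diff(d$support), numeric(1))
  steps <- seq(0, 1.2, length.out = 25)
  dirs <- list(c(1, 1), c(1, -1), c(-1, 0.5))
  for (dir in dirs) {
    pv <- vapply(steps, function(s) {
      x <- meds + s * dir[seq_along(meds)] * spans / 2
      fisher_conflate(vapply(seq_along(meds), function(k)
        envelope_pvalue(x[k], env$dists[[k]]), numeric(1)))
    }, numeric(1))
    expect_true(all(diff(pv) <= 1e-9))
  }
})

test_that("ensemble means average model fields cellwise and stay convex", {
  a <- matrix(c(0.2, 0.5, 0, 1), 2)
  b <- matrix(c(0.4, 0.1, 0.3, 1), 2)
  m <- ensemble_mean(list(a, b))
  expect_equal(m[1, 1], 0.3)
  expect_true(all(m >= pmin(a, b) - 1e-12 & m <= pmax(a, b) + 1e-12))
  expect_equal(ensemble_mean(list(a, a, a)), a, tolerance = 1e-15)
  expect_error(ensemble_mean(list()), "at least one")
})

test_that("envelopes survive a JSON round trip", {
  st <- small_stack()
  occ <- small_occurrences()
  sp <- small_specs()[[1]]
  env <- calibrate_envelope(occ[occ$species == sp$species, ], st,
                            background_seed = 9L)
  path <- withr::local_tempfile(fileext = ".json")
  write_envelope_json(env, path)
  back <- read_envelope_json(path)
  expect_identical(back$variables, env$variables)
  expect_equal(back$threshold, env$threshold)
  expect_equal(project_occurrence(back, st), project_occurrence(env, st),
               tolerance = 1e-12)
})
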