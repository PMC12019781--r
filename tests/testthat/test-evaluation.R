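test_that("delta_p follows the relative-change formula and the class partition", {
  ph <- matrix(c(0.4, 0.4, 0.3, 0, 0, 0.5), 2)
  pf <- matrix(c(0.4, 0.2, 0, 0.25, 0, 1.0), 2)
  dp <- delta_p(ph, pf)
  expect_equal(dp$delta[1, 1], 0)
  expect_equal(dp$delta[2, 1], -50)
  expect_identical(dp$class[1, 2], "extinct")
  expect_equal(dp$delta[1, 2], -100)
  expect_identical(dp$class[2, 2], "expanded")
  expect_identical(dp$class[1, 3], "absent")
  expect_equal(dp$delta[2, 3], 100)
  # every cell belongs to exactly one class
  expect_true(all(dp$class %in% c("changed", "extinct", "expanded", "absent")))
  expect_error(delta_p(-ph, pf), "negative")
})

test_that("class counts match a brute-force recount on a constructed grid", {
  set.seed(11)
  ph <- matrix(sample(c(0, 0.2, 0.6), 100, replace = TRUE), 10)
  pf <- matrix(sample(c(0, 0.3, 0.9), 100, replace = TRUE), 10)
  dp <- delta_p(ph, pf, zero_eps = 1e-3)
  brute <- c(changed = sum(ph > 1e-3 & pf > 1e-3),
             extinct = sum(ph > 1e-3 & pf <= 1e-3),
             expanded = sum(ph <= 1e-3 & pf > 1e-3),
             absent = sum(ph <= 1e-3 & pf <= 1e-3))
  got <- table(factor(dp$class, levels = names(brute)))
  expect_equal(as.integer(got), unname(brute))
})

test_that("distribution centers respect symmetry, scale invariance and exclusion of zeros", {
  p <- matrix(0, 3, 3)
  p[1, 2] <- 0.6
  one <- distribution_center(p, lon = c(8, 9, 10), lat = c(52, 51, 50))
  expect_equal(one$lon, 9); expect_equal(one$lat, 52)
  one_a <- distribution_center(p, c(8, 9, 10), c(52, 51, 50), method = "arithmetic")
  expect_equal(one_a$lon, 9); expect_equal(one_a$lat, 52)

  p2 <- matrix(0, 3, 1)
  p2[c(1, 3), 1] <- 0.4
  cen <- distribution_center(p2, lon = 10, lat = c(60, 55, 50), method = "arithmetic")
  expect_equal(cen$lat, 55)

  p3 <- matrix(runif(9), 3)
  c1 <- distribution_center(p3, c(8, 9, 10), c(52, 51, 50))
  c2 <- distribution_center(p3 / 2, c(8, 9, 10), c(52, 51, 50))
  expect_equal(c1$lon, c2$lon, tolerance = 1e-12)
  expect_equal(c1$lat, c2$lat, tolerance = 1e-12)
  expect_identical(c1$n_cells, 9L)

  expect_error(distribution_center(matrix(0, 2, 2), c(1, 2), c(2, 1)), "all-zero")
})

test_that("mean occurrence averages only occupied cells and scales linearly", {
  p <- matrix(c(0.2, 0.4, 0, 0.5), 2)
  expect_equal(mean_occurrence(matrix(c(0.5, 0.5, 0, 0), 2)), 0.5)
  expect_equal(mean_occurrence(matrix(c(0.2, 0.4, 0, 0), 2)), 0.3)
  expect_equal(mean_occurrence(p / 2), mean_occurrence(p) / 2)
  expect_warning(m0 <- mean_occurrence(matrix(0, 2, 2)), "no occupied")
  expect_identical(m0, 0)
})

test_that("dominance assigns the argmax species with alphabetical tie-breaks", {
  a <- matrix(c(0.8, 0.1, 0, 0.4), 2)
  b <- matrix(c(0.2, 0.6, 0, 0.4), 2)
  dom <- dominant_species(list(beta = b, alpha = a))
  expect_identical(dom$species[1, 1], "alpha")
  expect_identical(dom$species[2, 1], "beta")
  expect_true(is.na(dom$species[1, 2]))
  expect_identical(dom$species[2, 2], "alpha")  # exact tie -> alphabetical
  # scaling every species by one constant leaves the map unchanged
  dom2 <- dominant_species(list(beta = b * 0.5, alpha = a * 0.5))
  expect_identical(dom$species, dom2$species)
})

test_that("dominance change maps flag extinctions and new colonisations", {
  hist_f <- list(a = matrix(c(0.8, 0, 0.5, 0), 2),
                 b = matrix(c(0.1, 0, 0.2, 0), 2))
  fut_f <- list(a = matrix(c(0, 0, 0.5, 0), 2),
                b = matrix(c(0.3, 0.4, 0.2, 0), 2))
  m <- dominance_change_maps(hist_f, fut_f)
  expect_identical(m$map_a$species[1, 1], "a")
  expect_identical(m$map_a$class[1, 1], "extinct")
  expect_identical(m$map_b$species[2, 1], "b")
  expect_identical(m$map_b$class[2, 1], "newly_colonized")
  expect_identical(m$map_a$class[2, 2], "none")
  expect_equal(m$map_a$delta[1, 2], 0)
  expect_equal(m$map_b$delta[1, 2], 0)

  same <- dominance_change_maps(hist_f, hist_f)
  occupied <- !is.na(same$map_a$delta)
  expect_true(all(same$map_a$delta[occupied] == 0))
})

test_that("replacement tallies match a brute-force recount", {
  set.seed(21)
  ny <- 8; nx <- 8
  sp <- c("a", "b", "c")
  hist_f <- lapply(setNames(sp, sp), function(s) matrix(runif(ny * nx), ny))
  fut_f <- lapply(setNames(sp, sp), function(s) matrix(runif(ny * nx) *
                                                         (runif(ny * nx) > 0.4), ny))
  tal <- replacement_tally(hist_f, fut_f, focal = sp, zero_eps = 1e-3)

  dom_h <- dominant_species(hist_f, 1e-3)$species
  dom_f <- dominant_species(fut_f, 1e-3)$species
  for (f in sp) {
    ext <- which(dom_h == f & fut_f[[f]] <= 1e-3)
    expect_identical(sum(tal$cells[tal$focal == f]), length(ext))
    repl <- dom_f[ext]; repl[is.na(repl)] <- "none"
    want <- table(repl)
    for (r in names(want)) {
      expect_identical(tal$cells[tal$focal == f & tal$replacement == r],
                       as.integer(want[[r]]))
    }
  }

  none <- replacement_tally(hist_f, hist_f, focal = sp)
  expect_identical(nrow(none), 0L)
  expect_true(all(replacement_tally(hist_f, fut_f, sp, min_count = 5L)$cells >= 5L))
})

test_that("Shannon H' follows equal-share closed forms and rescaling invariance", {
  f2 <- list(a = matrix(0.3), b = matrix(0.3))
  expect_equal(shannon_h(f2)$h[1, 1], log(2), tolerance = 1e-12)
  f3 <- list(a = matrix(0.2), b = matrix(0.2), c = matrix(0.2))
  expect_equal(shannon_h(f3)$h[1, 1], log(3), tolerance = 1e-12)
  f3s <- lapply(f3, function(m) m * 3.7)
  expect_equal(shannon_h(f3s)$h, shannon_h(f3)$h, tolerance = 1e-12)
  expect_equal(shannon_h(list(a = matrix(0.9)))$h[1, 1], 0)
  expect_equal(shannon_h(list(a = matrix(0)))$h[1, 1], 0)
  expect_error(shannon_h(list(a = matrix(-0.1))), "negative")
})

test_that("H' is bounded by log(k) and delta H' is antisymmetric", {
  set.seed(5)
  fields <- lapply(setNames(letters[1:4], letters[1:4]),
                   function(s) matrix(runif(25), 5))
  sh <- shannon_h(fields)
  expect_true(all(sh$h <= log(pmax(sh$k, 1)) + 1e-12))
  expect_true(all(sh$h >= 0))
  fut <- lapply(fields, function(m) m * matrix(runif(25) > 0.3, 5))
  d1 <- diversity_change(fields, fut)
  d2 <- diversity_change(fut, fields)
  expect_equal(d1$delta, -d2$delta, tolerance = 1e-12)
  expect_identical(d1$class[d2$class == "colonized"],
                   rep("disappeared", sum(d2$class == "colonized")))
})

test_that("percentual SD matches the hand-computed example and scale invariance", {
  expect_equal(percentual_sd(c(0.2, 0.4)), 47.14045, tolerance = 1e-5)
  expect_equal(percentual_sd(c(0.3, 0.3, 0.3)), 0)
  expect_equal(percentual_sd(c(0.2, 0.4) * 3), percentual_sd(c(0.2, 0.4)),
               tolerance = 1e-12)
  expect_true(is.na(percentual_sd(c(0, 0))))
  expect_error(percentual_sd(c(0.4)), "at least 2")
  f <- list(matrix(c(0.2, 0.1), 1), matrix(c(0.4, 0.1), 1))
  m <- percentual_sd(f)
  expect_equal(m[1, 1], 47.14045, tolerance = 1e-5)
  expect_equal(m[1, 2], 0)
})

test_that("ANOVA shares match the hand-worked 2x2 table and sum to one", {
  tab <- matrix(c(0.1, 0.3, 0.2, 0.4), 2)  # rows models, cols scenarios
  a <- anova_partition(tab)
  expect_equal(a$model, 0.8, tolerance = 1e-12)
  expect_equal(a$scenario, 0.2, tolerance = 1e-12)
  expect_equal(a$residual, 0, tolerance = 1e-12)

  only_model <- matrix(c(0.1, 0.5, 0.1, 0.5), 2)
  b <- anova_partition(only_model)
  expect_equal(b$model, 1); expect_equal(b$scenario, 0); expect_equal(b$residual, 0)

  set.seed(9)
  for (i in 1:5) {
    tab <- matrix(runif(12), 3, 4)
    sh <- anova_partition(tab)
    expect_equal(sh$model + sh$scenario + sh$residual, 1, tolerance = 1e-12)
    # permutation of factor levels leaves shares unchanged
    sh2 <- anova_partition(tab[sample(3), sample(4)])
    expect_equal(sh2$model, sh$model, tolerance = 1e-12)
    expect_equal(sh2$scenario, sh$scenario, tolerance = 1e-12)
  }

  const <- anova_partition(matrix(0.4, 2, 3))
  expect_true(const$no_variance)
  expect_equal(const$model + const$scenario + const$residual, 0)
  expect_error(anova_partition(matrix(c(1, NA, 2, 3), 2)), "unbalanced")
})

test_that("closed-form ANOVA shares agree with aov() on random tables", {
  set.seed(33)
  for (i in 1:4) {
    tab <- matrix(runif(9), 3, 3)
    mine <- anova_partition(tab)
    df <- expand.grid(model = factor(1:3), scenario = factor(1:3))
    df$p <- as.vector(tab)
    ss <- summary(stats::aov(p ~ model + scenario, data = df))[[1]][["Sum Sq"]]
    expect_equal(mine$model, ss[1] / sum(ss), tolerance = 1e-9)
    expect_equal(mine$scenario, ss[2] / sum(ss), tolerance = 1e-9)
    expect_equal(mine$residual, ss[3] / sum(ss), tolerance = 1e-9)
  }
})

test_that("per-cell ANOVA maps partition every unmasked cell", {
  set.seed(44)
  fields <- list()
  for (mo in c("m1", "m2")) {
    fields[[mo]] <- list()
    for (sc in c("s1", "s2", "s3")) fields[[mo]][[sc]] <- matrix(runif(6), 2)
  }
  maps <- anova_partition_maps(fields)
  expect_equal(maps$model + maps$scenario + maps$residual,
               matrix(1, 2, 3), tolerance = 1e-9)
  expect_true(all(maps$model >= 0 & maps$scenario >= 0 & maps$residual >= 0))
})
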