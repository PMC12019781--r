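#' Filter species by their share of all occurrence records
#'
#' Retains species whose record count reaches
#' `ceiling(share_threshold x total records)` — with a 1% share of 589,937
#' records the inclusion cutoff is 5900 records — and reports the retained
#' species, their counts, and the retained share of the whole table.
#'
#' @param occ occurrence data.frame with a `species` column.
#' @param share_threshold minimum share of all records, in (0, 1)
#'   (default 0.01).
#' @return a list: `occurrences` (the filtered table) and `report`
#'   (`total_records`, `cutoff`, per-species `retained` table,
#'   `retained_records`, `retained_share`).
#' @export
filter_species <- function(occ, share_threshold = 0.01) {
  assert_fraction(share_threshold, "share_threshold")
  if (nrow(occ) == 0L) stopf("empty occurrence table")
  total <- nrow(occ)
  cutoff <- ceiling(share_threshold * total)
  counts <- sort(table(occ$species), decreasing = TRUE)
  keep <- names(counts)[counts >= cutoff]
  retained <- data.frame(species = keep,
                         count = as.integer(counts[keep]),
                         share = as.numeric(counts[keep]) / total)
  kept <- occ[occ$species %in% keep, , drop = FALSE]
  list(occurrences = kept,
       report = list(total_records = total, cutoff = as.integer(cutoff),
                     retained = retained,
                     n_retained = length(keep),
                     retained_records = nrow(kept),
                     retained_share = nrow(kept) / total))
}

#' Drop duplicate coordinate pairs per species
#'
#' @param occ occurrence data.frame (`species`, `lon`, `lat`).
#' @return the table with unique (species, lon, lat) triples.
#' @export
unique_occurrences <- function(occ) {
  unique(occ[c("species", "lon", "lat")])
}

# Gaussian-kernel-smoothed empirical CDF, evaluated in chunks
ksmooth_cdf <- function(q, x, bw) {
  out <- numeric(length(q))
  step <- max(1L, floor(2e6 / length(x)))
  for (s in seq(1L, length(q), by = step)) {
    idx <- s:min(s + step - 1L, length(q))
    out[idx] <- colMeans(stats::pnorm(outer(x, q[idx], function(xi, qq) (qq - xi) / bw)))
  }
  out
}

#' Fit a per-variable envelope distribution
#'
#' Represents the presence-value distribution of one bioclimatic variable
#' by a Gaussian-kernel-smoothed CDF (bandwidth by Silverman's rule). The
#' support is the presence range extended by one bandwidth on each side;
#' outside it the envelope probability is zero.
#'
#' @param x presence values of the variable.
#' @return an `envelope_dist` (sorted values, bandwidth, support bounds and
#'   the smoothed-CDF median, where the two-sided probability peaks at 1).
#' @export
fit_envelope_dist <- function(x) {
  x <- sort(x[is.finite(x)])
  if (length(x) < 5L) stopf("need at least 5 presence values to fit a distribution")
  if (stats::sd(x) == 0) stopf("constant variable: no distribution to fit")
  bw <- stats::bw.nrd0(x)
  med <- stats::uniroot(function(q) ksmooth_cdf(q, x, bw) - 0.5,
                        interval = range(x), extendInt = "upX", tol = 1e-10)$root
  structure(list(values = x, bw = bw,
                 support = c(x[1] - bw, x[length(x)] + bw), median = med),
            class = "envelope_dist")
}

#' Two-sided envelope probability of a variable value
#'
#' `p = 2 min(F(x), 1 - F(x))` with `F` the smoothed presence CDF: 1 at the
#' presence median, falling towards 0 in the tails, and exactly 0 outside
#' the extended support.
#'
#' @param x numeric values (vectorised; `NA` passes through).
#' @param dist an [fit_envelope_dist()] object.
#' @return probabilities in `[0, 1]`.
#' @export
envelope_pvalue <- function(x, dist) {
  if (!inherits(dist, "envelope_dist")) stopf("unfitted distribution")
  out <- rep(NA_real_, length(x))
  ok <- which(is.finite(x))
  if (length(ok)) {
    f <- ksmooth_cdf(x[ok], dist$values, dist$bw)
    p <- pmin(pmax(2 * pmin(f, 1 - f), 0), 1)
    p[x[ok] < dist$support[1] | x[ok] > dist$support[2]] <- 0
    out[ok] <- p
  }
  out
}

#' Conflate component probabilities with Fisher's combined test
#'
#' `chi^2 = -2 sum(log p_i)` on `2k` degrees of freedom; the conflated value
#' is the upper-tail chi-square probability. A zero component forces the
#' conflated value to zero (the limit of the statistic).
#'
#' @param p numeric vector of probabilities in `[0, 1]` (typically 2-3).
#' @return the conflated probability.
#' @export
fisher_conflate <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stopf("probabilities must lie in [0, 1]")
  if (any(p == 0)) return(0)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

# rowwise Fisher conflation of a probability matrix (NA rows propagate)
conflate_rows <- function(P) {
  out <- rep(NA_real_, nrow(P))
  ok <- rowSums(is.na(P)) == 0L
  zero <- ok & rowSums(P == 0, na.rm = TRUE) > 0L
  pos <- ok & !zero
  out[zero] <- 0
  if (any(pos)) {
    chi <- -2 * rowSums(log(P[pos, , drop = FALSE]))
    out[pos] <- stats::pchisq(chi, df = 2 * ncol(P), lower.tail = FALSE)
  }
  out
}

#' True Skill Statistic
#'
#' `TSS = sensitivity + specificity - 1`, in `[-1, 1]`.
#'
#' @param sensitivity,specificity fractions in `[0, 1]`.
#' @return the TSS score.
#' @export
tss <- function(sensitivity, specificity) {
  assert_fraction(sensitivity, "sensitivity", open = FALSE)
  assert_fraction(specificity, "specificity", open = FALSE)
  sensitivity + specificity - 1
}

# TSS over a threshold ladder; returns the best threshold (lowest on ties)
tss_scan <- function(conf_pres, conf_bg, thresholds) {
  sp <- sort(conf_pres); sb <- sort(conf_bg)
  sens <- 1 - findInterval(thresholds, sp, left.open = TRUE) / length(sp)
  spec <- findInterval(thresholds, sb, left.open = TRUE) / length(sb)
  tssv <- sens + spec - 1
  k <- which.max(tssv)
  list(threshold = thresholds[k], tss = tssv[k], sensitivity = sens[k],
       specificity = spec[k])
}

# map record coordinates to unique cell indices of a stack's grid
occurrence_cells <- function(occ, bioclim) {
  ii <- nearest_index(occ$lat, bioclim$lat)
  jj <- nearest_index(occ$lon, bioclim$lon)
  unique((jj - 1L) * length(bioclim$lat) + ii)
}

#' Calibrate a species' climate envelope
#'
#' Draws balanced pseudo-absences (a uniform seeded sample of non-presence
#' cells), fits per-variable smoothed-CDF distributions on the presence
#' values, and searches every 2- and 3-variable subset of the candidate
#' pool exhaustively: each subset's per-variable probabilities are conflated
#' with Fisher's test and the presence/absence threshold maximising the TSS
#' against the background sample is found on a 99-point ladder. The subset
#' with maximal TSS wins; subsets whose TSS falls within `tss_tolerance` of
#' the maximum are ties (the statistic is estimated on finitely many points,
#' so sub-quantum differences carry no skill), resolved to fewer variables,
#' then to lexicographic variable order. Constant variables are excluded
#' with a warning.
#'
#' @param occurrences occurrence records of one species (`lon`, `lat`;
#'   a `species` column, if present, must be single-valued).
#' @param bioclim calibration-period [bioclim_stack()].
#' @param candidates candidate variable names (default: all 17).
#' @param background_seed seed of the pseudo-absence draw.
#' @param max_vars largest subset size (2 or 3; default 3).
#' @param thresholds threshold ladder (default `seq(0.01, 0.99, 0.01)`).
#' @param min_presence minimum presence cells required (default 30).
#' @param tss_tolerance TSS band within which subsets count as tied
#'   (default 0.01, a few estimation quanta at a few hundred samples).
#' @return a `species_envelope`: selected variables, fitted distributions,
#'   threshold, verification scores (sensitivity, specificity, TSS) and the
#'   background seed.
#' @export
calibrate_envelope <- function(occurrences, bioclim,
                               candidates = bioclim_variable_names(),
                               background_seed = 1L, max_vars = 3L,
                               thresholds = seq(0.01, 0.99, by = 0.01),
                               min_presence = 30L, tss_tolerance = 0.01) {
  sp_name <- if ("species" %in% names(occurrences)) {
    u <- unique(occurrences$species)
    if (length(u) > 1L) stopf("calibrate one species at a time")
    u
  } else NA_character_
  candidates <- sort(intersect(candidates, bioclim$variables))
  if (length(candidates) < 2L) stopf("need at least 2 candidate variables")
  ny <- length(bioclim$lat); nx <- length(bioclim$lon)
  pres <- occurrence_cells(occurrences, bioclim)
  if (length(pres) < min_presence) {
    stopf("only %d presence cells; need at least %d", length(pres), min_presence)
  }
  V <- matrix(bioclim$values[, , candidates], ny * nx, length(candidates),
              dimnames = list(NULL, candidates))
  unmasked <- which(rowSums(is.na(V)) == 0L)
  pool <- setdiff(unmasked, pres)
  n_bg <- min(length(pres), length(pool))
  if (n_bg < min_presence) stopf("too few background cells available")
  bg <- with_seed(background_seed, sample(pool, n_bg))

  usable <- character(0)
  dists <- list()
  for (v in candidates) {
    xv <- V[pres, v]
    if (stats::sd(xv) == 0) {
      warning(sprintf("variable '%s' is constant over presences; excluded", v),
              call. = FALSE)
      next
    }
    dists[[v]] <- fit_envelope_dist(xv)
    usable <- c(usable, v)
  }
  if (length(usable) < 2L) stopf("fewer than 2 usable candidate variables")

  P_pres <- vapply(usable, function(v) envelope_pvalue(V[pres, v], dists[[v]]),
                   numeric(length(pres)))
  P_bg <- vapply(usable, function(v) envelope_pvalue(V[bg, v], dists[[v]]),
                 numeric(length(bg)))

  all_subsets <- list(); scans <- list()
  for (k in 2:min(max_vars, length(usable))) {
    for (s in utils::combn(usable, k, simplify = FALSE)) {
      cp <- conflate_rows(P_pres[, s, drop = FALSE])
      cb <- conflate_rows(P_bg[, s, drop = FALSE])
      all_subsets[[length(all_subsets) + 1L]] <- s
      scans[[length(scans) + 1L]] <- tss_scan(cp, cb, thresholds)
    }
  }
  tss_all <- vapply(scans, `[[`, numeric(1), "tss")
  # TSS is estimated on ~n presence + n background points, so differences of
  # a few 1/n quanta are sampling noise, not skill: subsets within
  # tss_tolerance of the maximum are tied, and ties resolve to fewer
  # variables, then to lexicographic enumeration order
  tied <- which(tss_all >= max(tss_all) - tss_tolerance)
  sizes <- lengths(all_subsets[tied])
  pick <- tied[sizes == min(sizes)][1]
  best <- c(scans[[pick]], list(variables = all_subsets[[pick]]))
  structure(list(species = sp_name, variables = best$variables,
                 dists = dists[best$variables], threshold = best$threshold,
                 sensitivity = best$sensitivity, specificity = best$specificity,
                 tss = best$tss, background_seed = background_seed,
                 n_presence = length(pres)),
            class = "species_envelope")
}

#' @export
print.species_envelope <- function(x, ...) {
  cat(sprintf("<species_envelope> %s: %s | TSS %.3f (sens %.3f, spec %.3f), threshold %.2f\n",
              x$species, paste(x$variables, collapse = " + "), x$tss,
              x$sensitivity, x$specificity, x$threshold))
  invisible(x)
}

#' Project occurrence probability onto a bioclim stack
#'
#' Per cell, the Fisher-conflated envelope probability of the cell's
#' selected-variable values. Cells whose values fall outside any variable's
#' extended presence support receive exactly 0 — projections are constrained
#' to the historic climate envelope by construction.
#'
#' @param env a [calibrate_envelope()] result.
#' @param bioclim a [bioclim_stack()] containing the envelope's variables.
#' @return matrix `[lat, lon]` of probabilities in `[0, 1]` (`NA` where
#'   masked).
#' @export
project_occurrence <- function(env, bioclim) {
  if (!all(env$variables %in% bioclim$variables)) {
    stopf("stack lacks envelope variables: %s",
          paste(setdiff(env$variables, bioclim$variables), collapse = ", "))
  }
  ny <- length(bioclim$lat); nx <- length(bioclim$lon)
  P <- vapply(env$variables,
              function(v) envelope_pvalue(as.vector(bioclim$values[, , v]), env$dists[[v]]),
              numeric(ny * nx))
  matrix(conflate_rows(P), ny, nx)
}

#' Ensemble mean of per-model probability fields
#'
#' @param fields list of probability matrices (one per model, same shape).
#' @return their arithmetic cellwise mean.
#' @export
ensemble_mean <- function(fields) {
  if (length(fields) < 1L) stopf("need at least one model field")
  Reduce(`+`, fields) / length(fields)
}

#' Serialize a species envelope to JSON
#'
#' Stores the selected variables, per-variable presence values, bandwidths
#' and supports, the threshold and the verification scores, for audit and
#' lossless reload.
#'
#' @param env a `species_envelope`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_envelope_json <- function(env, path) {
  obj <- list(species = env$species, variables = env$variables,
              threshold = env$threshold, sensitivity = env$sensitivity,
              specificity = env$specificity, tss = env$tss,
              background_seed = env$background_seed, n_presence = env$n_presence,
              dists = lapply(env$dists, function(d) {
                list(values = d$values, bw = d$bw, support = d$support,
                     median = d$median)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a species envelope written by [write_envelope_json()]
#'
#' @param path JSON path.
#' @return a `species_envelope`.
#' @export
read_envelope_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  dists <- lapply(obj$dists, function(d) {
    structure(list(values = as.numeric(d$values), bw = d$bw,
                   support = as.numeric(d$support), median = d$median),
              class = "envelope_dist")
  })
  structure(list(species = obj$species, variables = obj$variables,
                 dists = dists[obj$variables], threshold = obj$threshold,
                 sensitivity = obj$sensitivity, specificity = obj$specificity,
                 tss = obj$tss, background_seed = obj$background_seed,
                 n_presence = obj$n_presence),
            class = "species_envelope")
}
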