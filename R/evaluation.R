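#' Relative change of occurrence probability
#'
#' `delta_p = (p_future / p_historic - 1) x 100%` per cell, with cells
#' classified into exactly one of: `changed` (finite delta), `extinct`
#' (historically present, future 0 — delta pinned at -100), `expanded`
#' (absent historically, present in the future) or `absent` (absent in
#' both). "Zero" is `p <= zero_eps`: smoothed-kernel probabilities rarely
#' reach exact 0 inside the support.
#'
#' @param p_hist,p_fut aligned probability matrices.
#' @param zero_eps probability treated as zero (default 1e-3).
#' @return a `delta_p_map`: `delta` (%) and `class` matrices.
#' @export
delta_p <- function(p_hist, p_fut, zero_eps = 1e-3) {
  if (!identical(dim(p_hist), dim(p_fut))) stopf("fields are not aligned")
  if (any(p_hist < 0, na.rm = TRUE) || any(p_fut < 0, na.rm = TRUE)) {
    stopf("negative probabilities")
  }
  h0 <- p_hist <= zero_eps; f0 <- p_fut <= zero_eps
  cls <- matrix(NA_character_, nrow(p_hist), ncol(p_hist))
  cls[!h0 & !f0] <- "changed"
  cls[!h0 & f0] <- "extinct"
  cls[h0 & !f0] <- "expanded"
  cls[h0 & f0] <- "absent"
  dp <- matrix(NA_real_, nrow(p_hist), ncol(p_hist))
  ch <- which(cls == "changed")
  dp[ch] <- (p_fut[ch] / p_hist[ch] - 1) * 100
  dp[cls == "extinct"] <- -100
  structure(list(delta = dp, class = cls, zero_eps = zero_eps),
            class = "delta_p_map")
}

#' Distribution center and spatial extent of a projection
#'
#' Weighted mean of cell coordinates with weights equal to the occurrence
#' probability; zero-probability cells are excluded. The default
#' `"geometric"` method takes the weighted geometric mean in a strictly
#' positive frame (`lon + 180`, `lat + 90`) and shifts back — geometric
#' means of signed longitudes are ill-defined, so an `"arithmetic"` variant
#' is offered as well. The extent is the count of `p > 0` cells times the
#' cell area.
#'
#' @param p probability matrix `[lat, lon]`.
#' @param lon,lat cell-center coordinate vectors.
#' @param method `"geometric"` (default) or `"arithmetic"`.
#' @param cell_area area of one cell (any unit; default 1, extent = cell
#'   count).
#' @param zero_eps probability treated as zero.
#' @return a list: `lon`, `lat` of the center, `extent`, `n_cells`, `method`.
#' @export
distribution_center <- function(p, lon, lat, method = c("geometric", "arithmetic"),
                                cell_area = 1, zero_eps = 0) {
  method <- match.arg(method)
  w <- p
  w[is.na(w) | w <= zero_eps] <- 0
  if (sum(w) == 0) stopf("all-zero probability field: no distribution center")
  lon_m <- matrix(lon, nrow(p), ncol(p), byrow = TRUE)
  lat_m <- matrix(lat, nrow(p), ncol(p))
  if (method == "geometric") {
    clon <- exp(stats::weighted.mean(log(lon_m + 180), w)) - 180
    clat <- exp(stats::weighted.mean(log(lat_m + 90), w)) - 90
  } else {
    clon <- stats::weighted.mean(lon_m, w)
    clat <- stats::weighted.mean(lat_m, w)
  }
  n_cells <- sum(w > 0)
  list(lon = clon, lat = clat, extent = n_cells * cell_area,
       n_cells = n_cells, method = method)
}

#' Mean occurrence probability over occupied cells
#'
#' Area-weighted mean of `p` over the cells where the species is projected
#' to occur (`p > zero_eps`).
#'
#' @param p probability matrix.
#' @param area matrix of cell areas (default equal areas).
#' @param zero_eps probability treated as zero.
#' @return a scalar; 0 with a warning when no cell is occupied.
#' @export
mean_occurrence <- function(p, area = NULL, zero_eps = 0) {
  if (is.null(area)) area <- matrix(1, nrow(p), ncol(p))
  occ <- which(!is.na(p) & p > zero_eps)
  if (!length(occ)) {
    warning("no occupied cells; mean occurrence defined as 0", call. = FALSE)
    return(0)
  }
  stats::weighted.mean(p[occ], area[occ])
}

# stack a named list of probability matrices into [cell, species]
species_matrix <- function(fields) {
  sp <- sort(names(fields))
  M <- vapply(sp, function(s) as.vector(fields[[s]]), numeric(length(fields[[1]])))
  if (is.null(dim(M))) M <- matrix(M, nrow = 1, dimnames = list(NULL, sp))
  M
}

#' Locally dominant species
#'
#' Per cell, the species with the highest occurrence probability (ties go
#' to the alphabetically first species); cells where every species has
#' `p <= zero_eps` are labelled `NA` ("none").
#'
#' @param fields named list of probability matrices (ensemble means), one
#'   per species.
#' @param zero_eps probability treated as zero.
#' @return a list: `species` (character matrix) and `p` (the dominant
#'   probability matrix).
#' @export
dominant_species <- function(fields, zero_eps = 0) {
  M <- species_matrix(fields)
  sp <- colnames(M)
  dims <- dim(fields[[1]])
  M0 <- M; M0[is.na(M0)] <- -Inf
  idx <- max.col(M0, ties.method = "first")
  top <- M0[cbind(seq_len(nrow(M)), idx)]
  lab <- sp[idx]
  lab[!is.finite(top) | top <= zero_eps] <- NA_character_
  pv <- top
  pv[!is.finite(pv)] <- NA_real_
  list(species = matrix(lab, dims[1], dims[2]), p = matrix(pv, dims[1], dims[2]))
}

#' Dominance change maps
#'
#' Map A anchors on the historically dominant species: per cell, its
#' `delta_p` between the two periods (class `extinct` where it drops to 0).
#' Map B anchors on the future-dominant species, with classes
#' `newly_colonized` (future dominant absent historically) and `none` (no
#' species projected at all). Both come with spatial-share histograms of
#' `delta_p` binned in 10% steps, extinct/expanded tallied as separate bars.
#'
#' @param hist_fields,fut_fields named lists of per-species probability
#'   matrices for the two periods.
#' @param zero_eps probability treated as zero.
#' @return a list: `map_a`, `map_b` (each with `species`, `delta`, `class`
#'   matrices) and `hist_a`, `hist_b` (bin tables).
#' @export
dominance_change_maps <- function(hist_fields, fut_fields, zero_eps = 1e-3) {
  stopifnot(identical(sort(names(hist_fields)), sort(names(fut_fields))))
  dims <- dim(hist_fields[[1]])
  Mh <- species_matrix(hist_fields); Mf <- species_matrix(fut_fields)
  dh <- dominant_species(hist_fields, zero_eps)
  df <- dominant_species(fut_fields, zero_eps)

  cell_delta <- function(anchor_species) {
    n <- length(anchor_species)
    ph <- pf <- rep(NA_real_, n)
    has <- which(!is.na(anchor_species))
    col <- match(anchor_species[has], colnames(Mh))
    ph[has] <- Mh[cbind(has, col)]
    pf[has] <- Mf[cbind(has, col)]
    list(ph = ph, pf = pf)
  }

  classify <- function(anchor, ph, pf, future_anchored) {
    cls <- rep(NA_character_, length(anchor))
    dp <- rep(NA_real_, length(anchor))
    none <- is.na(anchor)
    cls[none] <- "none"
    h0 <- !none & ph <= zero_eps; f0 <- !none & pf <= zero_eps
    ch <- !none & !h0 & !f0
    dp[ch] <- (pf[ch] / ph[ch] - 1) * 100
    cls[ch] <- "changed"
    cls[!none & !h0 & f0] <- "extinct"
    dp[!none & !h0 & f0] <- -100
    cls[!none & h0 & !f0] <- if (future_anchored) "newly_colonized" else "expanded"
    cls[!none & h0 & f0] <- "absent"
    list(class = cls, delta = dp)
  }

  va <- cell_delta(as.vector(dh$species))
  ca <- classify(as.vector(dh$species), va$ph, va$pf, future_anchored = FALSE)
  vb <- cell_delta(as.vector(df$species))
  cb <- classify(as.vector(df$species), vb$ph, vb$pf, future_anchored = TRUE)

  bin10 <- function(cl) {
    dp <- cl$delta[cl$class == "changed"]
    dp <- dp[!is.na(dp)]
    brk <- seq(floor(min(c(dp, -100)) / 10) * 10, ceiling(max(c(dp, 0)) / 10) * 10, by = 10)
    h <- if (length(dp)) table(cut(dp, brk, include.lowest = TRUE)) else table(factor())
    special <- table(factor(cl$class, levels = c("extinct", "expanded",
                                                 "newly_colonized", "none")))
    list(bins = h, special = special)
  }

  list(map_a = list(species = dh$species,
                    delta = matrix(ca$delta, dims[1], dims[2]),
                    class = matrix(ca$class, dims[1], dims[2])),
       map_b = list(species = df$species,
                    delta = matrix(cb$delta, dims[1], dims[2]),
                    class = matrix(cb$class, dims[1], dims[2])),
       hist_a = bin10(ca), hist_b = bin10(cb))
}

#' Replacement tally of locally dominant species
#'
#' For every cell where a focal species is the historic dominant and goes
#' locally extinct (future `p <= zero_eps`), records the species dominating
#' that cell in the future (or `"none"`). Pairs below `min_count` cells are
#' suppressed from the report.
#'
#' @param hist_fields,fut_fields named lists of per-species probability
#'   matrices.
#' @param focal focal species names.
#' @param min_count suppress (focal, replacement) pairs with fewer cells.
#' @param zero_eps probability treated as zero.
#' @return data.frame `focal`, `replacement`, `cells`.
#' @export
replacement_tally <- function(hist_fields, fut_fields, focal,
                              min_count = 0L, zero_eps = 1e-3) {
  if (!all(focal %in% names(hist_fields))) stopf("focal species missing from the cube")
  dh <- dominant_species(hist_fields, zero_eps)
  df <- dominant_species(fut_fields, zero_eps)
  out <- list()
  for (f in focal) {
    fut_p <- as.vector(fut_fields[[f]])
    sel <- which(as.vector(dh$species) == f & !is.na(fut_p) & fut_p <= zero_eps)
    if (!length(sel)) next
    repl <- as.vector(df$species)[sel]
    repl[is.na(repl)] <- "none"
    tab <- table(repl)
    out[[f]] <- data.frame(focal = f, replacement = names(tab),
                           cells = as.integer(tab))
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(focal = character(), replacement = character(), cells = integer())
  }
  rownames(res) <- NULL
  res[res$cells >= min_count, , drop = FALSE]
}

#' Shannon diversity of a projected assemblage
#'
#' Per cell, `H' = -sum(pi_i log pi_i)` (natural log) over the species with
#' `p > 0`, where `pi_i` is species i's share of the summed occurrence
#' probabilities — so `H'` is invariant to rescaling all `p` by a constant
#' and bounded by `log(k)` for `k` species present. Cells with no species
#' get `H' = 0`.
#'
#' @param fields named list of per-species probability matrices.
#' @param zero_eps probability treated as zero.
#' @return a list: `h` (H' matrix) and `k` (species-count matrix).
#' @export
shannon_h <- function(fields, zero_eps = 0) {
  M <- species_matrix(fields)
  if (any(M < 0, na.rm = TRUE)) stopf("negative probabilities")
  dims <- dim(fields[[1]])
  M[is.na(M)] <- 0
  M[M <= zero_eps] <- 0
  tot <- rowSums(M)
  k <- rowSums(M > 0)
  h <- numeric(nrow(M))
  pos <- which(tot > 0)
  if (length(pos)) {
    pim <- M[pos, , drop = FALSE] / tot[pos]
    terms <- pim * log(pim)
    terms[pim == 0] <- 0
    h[pos] <- -rowSums(terms)
  }
  list(h = matrix(h, dims[1], dims[2]), k = matrix(k, dims[1], dims[2]))
}

#' Change in Shannon diversity between two periods
#'
#' `delta H' = H'_future - H'_historic` with cells classified as `changed`,
#' `disappeared` (all species lost: k falls to 0 from > 0), `colonized`
#' (k rises from 0) or `no_forest` (k = 0 in both).
#'
#' @param hist_fields,fut_fields named lists of per-species probability
#'   matrices.
#' @param zero_eps probability treated as zero.
#' @return a list: `h_hist`, `h_fut`, `delta`, `class` matrices.
#' @export
diversity_change <- function(hist_fields, fut_fields, zero_eps = 0) {
  sh <- shannon_h(hist_fields, zero_eps)
  sf <- shannon_h(fut_fields, zero_eps)
  cls <- matrix("changed", nrow(sh$h), ncol(sh$h))
  cls[sh$k > 0 & sf$k == 0] <- "disappeared"
  cls[sh$k == 0 & sf$k > 0] <- "colonized"
  cls[sh$k == 0 & sf$k == 0] <- "no_forest"
  list(h_hist = sh$h, h_fut = sf$h, delta = sf$h - sh$h, class = cls)
}

#' Percentual standard deviation across models
#'
#' `S_p = 100 x SD(p_j) / mean(p_j)` with the sample SD (divisor n - 1)
#' over the model ensemble at each cell; cells with zero mean are masked
#' (`NA`).
#'
#' @param fields list of per-model probability matrices (>= 2 models), or a
#'   numeric vector of per-model values for a single cell.
#' @return matrix (or scalar) of percentual SDs.
#' @export
percentual_sd <- function(fields) {
  if (is.numeric(fields)) fields <- lapply(fields, function(v) matrix(v, 1, 1))
  n <- length(fields)
  if (n < 2L) stopf("need at least 2 models")
  A <- vapply(fields, as.vector, numeric(length(fields[[1]])))
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  m <- rowMeans(A)
  s <- apply(A, 1, stats::sd)
  out <- ifelse(m > 0, s / m * 100, NA_real_)
  if (length(out) == 1L) out else matrix(out, nrow(fields[[1]]), ncol(fields[[1]]))
}

#' Two-way ANOVA uncertainty partition
#'
#' For a balanced model x scenario table of projected `p` at one cell,
#' partitions the total sum of squares into the two main effects and the
#' residual (which, with one observation per combination, is the
#' interaction), each expressed as a proportion of the total. A constant
#' response yields all-zero shares with `no_variance = TRUE`.
#'
#' @param tab numeric matrix, rows = models, columns = scenarios.
#' @return list `model`, `scenario`, `residual` (shares summing to 1) and
#'   `no_variance`.
#' @export
anova_partition <- function(tab) {
  tab <- as.matrix(tab)
  if (anyNA(tab)) stopf("unbalanced model x scenario table")
  n_m <- nrow(tab); n_s <- ncol(tab)
  if (n_m < 2L || n_s < 2L) stopf("need at least 2 models and 2 scenarios")
  g <- mean(tab)
  ss_tot <- sum((tab - g)^2)
  if (ss_tot < .Machine$double.eps) {
    return(list(model = 0, scenario = 0, residual = 0, no_variance = TRUE))
  }
  ss_m <- n_s * sum((rowMeans(tab) - g)^2)
  ss_s <- n_m * sum((colMeans(tab) - g)^2)
  ss_r <- ss_tot - ss_m - ss_s
  list(model = ss_m / ss_tot, scenario = ss_s / ss_tot,
       residual = max(ss_r, 0) / ss_tot, no_variance = FALSE)
}

#' Per-cell ANOVA partition maps
#'
#' Applies [anova_partition()] at every cell of a model x scenario set of
#' probability fields.
#'
#' @param fields nested list `[[model]][[scenario]]` of probability
#'   matrices.
#' @return list of matrices `model`, `scenario`, `residual`, plus a logical
#'   `no_variance` mask.
#' @export
anova_partition_maps <- function(fields) {
  models <- names(fields); scens <- names(fields[[1]])
  dims <- dim(fields[[1]][[1]])
  ncell <- prod(dims)
  A <- array(NA_real_, c(ncell, length(models), length(scens)))
  for (i in seq_along(models)) for (j in seq_along(scens)) {
    A[, i, j] <- as.vector(fields[[models[i]]][[scens[j]]])
  }
  out_m <- out_s <- out_r <- rep(NA_real_, ncell)
  novar <- rep(NA, ncell)
  for (c in seq_len(ncell)) {
    tab <- A[c, , ]
    if (anyNA(tab)) next
    a <- anova_partition(tab)
    out_m[c] <- a$model; out_s[c] <- a$scenario; out_r[c] <- a$residual
    novar[c] <- a$no_variance
  }
  list(model = matrix(out_m, dims[1], dims[2]),
       scenario = matrix(out_s, dims[1], dims[2]),
       residual = matrix(out_r, dims[1], dims[2]),
       no_variance = matrix(novar, dims[1], dims[2]))
}
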