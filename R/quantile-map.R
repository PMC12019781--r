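#' Fit an empirical quantile-mapping model
#'
#' For every cell and calendar month, stores paired empirical quantiles of
#' the model and observed series over the calibration window at a fixed
#' probability ladder (99 evenly spaced probabilities 0.01..0.99). Twelve
#' independent transfer functions per cell keep the mapping at monthly
#' resolution.
#'
#' @param observed a [climate_grid()] of the observed series.
#' @param model_historic a [climate_grid()] of the model series on the same
#'   grid.
#' @param calibration_years calendar years of the calibration window
#'   (>= 10 years).
#' @param probs probability ladder (default `seq(0.01, 0.99, by = 0.01)`).
#' @return a `quantile_map` object.
#' @export
fit_quantile_map <- function(observed, model_historic, calibration_years,
                             probs = seq(0.01, 0.99, by = 0.01)) {
  if (!identical(observed$variable, model_historic$variable)) {
    stopf("observed and model series must carry the same variable")
  }
  if (!isTRUE(all.equal(observed$lon, model_historic$lon)) ||
      !isTRUE(all.equal(observed$lat, model_historic$lat))) {
    stopf("observed and model series must share one grid")
  }
  if (length(unique(calibration_years)) < 10L) {
    stopf("calibration window must span at least 10 years")
  }
  obs <- subset_years(observed, calibration_years)
  mod <- subset_years(model_historic, calibration_years)
  ny <- length(obs$lat); nx <- length(obs$lon); np <- length(probs)
  # type-7 quantiles on row-sorted cell series, vectorised across cells
  row_quantiles <- function(X) {
    n <- ncol(X)
    S <- t(apply(X, 1, sort))
    h <- (n - 1) * probs + 1
    lo <- floor(h); g <- h - lo
    Q <- S[, lo, drop = FALSE] * rep(1 - g, each = nrow(X)) +
      S[, pmin(lo + 1, n), drop = FALSE] * rep(g, each = nrow(X))
    Q
  }
  q_obs <- q_mod <- array(NA_real_, c(ny, nx, 12L, np))
  for (m in 1:12) {
    so <- matrix(obs$values[, , obs$month == m, drop = FALSE], ny * nx)
    sm <- matrix(mod$values[, , mod$month == m, drop = FALSE], ny * nx)
    ok <- rowSums(is.na(so)) == 0L & rowSums(is.na(sm)) == 0L
    qo <- matrix(NA_real_, ny * nx, np); qm <- matrix(NA_real_, ny * nx, np)
    if (any(ok)) {
      qo[ok, ] <- row_quantiles(so[ok, , drop = FALSE])
      qm[ok, ] <- row_quantiles(sm[ok, , drop = FALSE])
    }
    q_obs[, , m, ] <- array(qo, c(ny, nx, np))
    q_mod[, , m, ] <- array(qm, c(ny, nx, np))
  }
  structure(list(variable = observed$variable, probs = probs,
                 q_obs = q_obs, q_mod = q_mod,
                 lon = observed$lon, lat = observed$lat,
                 calibration_years = range(calibration_years)),
            class = "quantile_map")
}

# map one cell/month vector through paired quantile tables
qmap_cell <- function(x, qm_mod, qm_obs, probs, variable) {
  np <- length(qm_mod)
  if (qm_mod[np] - qm_mod[1] < 1e-12) {
    # degenerate model table (e.g. an always-dry month): boundary convention
    if (variable == "temperature") return(x + (qm_obs[1] - qm_mod[1]))
    r <- if (qm_mod[1] > 1e-9) qm_obs[1] / qm_mod[1] else 1
    return(pmax(x * r, 0))
  }
  out <- numeric(length(x))
  lo <- x < qm_mod[1]; hi <- x > qm_mod[length(qm_mod)]
  mid <- !(lo | hi)
  if (any(mid)) {
    xm <- x[mid]
    i1 <- pmin(pmax(findInterval(xm, qm_mod), 1L), np - 1L)
    dq <- qm_mod[i1 + 1L] - qm_mod[i1]
    w <- ifelse(dq > 0, (xm - qm_mod[i1]) / dq, 0)
    p <- probs[i1] + w * (probs[i1 + 1L] - probs[i1])
    j1 <- pmin(pmax(findInterval(p, probs), 1L), np - 1L)
    w2 <- (p - probs[j1]) / (probs[j1 + 1L] - probs[j1])
    out[mid] <- qm_obs[j1] * (1 - w2) + qm_obs[j1 + 1L] * w2
  }
  if (variable == "temperature") {
    # constant additive correction beyond the calibrated range
    if (any(lo)) out[lo] <- x[lo] + (qm_obs[1] - qm_mod[1])
    if (any(hi)) out[hi] <- x[hi] + (qm_obs[length(qm_obs)] - qm_mod[length(qm_mod)])
  } else {
    # constant ratio beyond the calibrated range
    if (any(lo)) {
      r <- if (qm_mod[1] > 1e-9) qm_obs[1] / qm_mod[1] else 1
      out[lo] <- x[lo] * r
    }
    if (any(hi)) {
      r <- if (qm_mod[length(qm_mod)] > 1e-9) qm_obs[length(qm_obs)] / qm_mod[length(qm_mod)] else 1
      out[hi] <- x[hi] * r
    }
    out <- pmax(out, 0)
  }
  out
}

#' Apply a quantile-mapping model to a model series
#'
#' Each value is located in the model quantile table (linear interpolation
#' of its probability) and replaced by the observed table's value at that
#' probability. Beyond the calibrated range, temperature gets a constant
#' additive boundary correction and precipitation a constant ratio —
#' preserving projected trends without runaway extrapolation. Corrected
#' precipitation is floored at zero. The same transfer functions apply to
#' historic and future periods.
#'
#' @param model_series a [climate_grid()] on the quantile map's grid.
#' @param qm a `quantile_map` from [fit_quantile_map()].
#' @return a bias-corrected `climate_grid`.
#' @export
apply_quantile_map <- function(model_series, qm) {
  if (!identical(model_series$variable, qm$variable)) {
    stopf("variable mismatch between series and quantile map")
  }
  if (!isTRUE(all.equal(model_series$lon, qm$lon)) ||
      !isTRUE(all.equal(model_series$lat, qm$lat))) {
    stopf("grid mismatch between series and quantile map")
  }
  ny <- length(qm$lat); nx <- length(qm$lon)
  ncell <- ny * nx; np <- length(qm$probs)
  out <- array(NA_real_, dim(model_series$values))
  for (m in 1:12) {
    sel <- which(model_series$month == m)
    if (!length(sel)) next
    Vm <- matrix(model_series$values[, , sel, drop = FALSE], ncell, length(sel))
    Qm <- matrix(qm$q_mod[, , m, ], ncell, np)
    Qo <- matrix(qm$q_obs[, , m, ], ncell, np)
    Rm <- matrix(NA_real_, ncell, length(sel))
    for (r in which(!is.na(Qo[, 1]))) {
      Rm[r, ] <- qmap_cell(Vm[r, ], Qm[r, ], Qo[r, ], qm$probs, qm$variable)
    }
    out[, , sel] <- array(Rm, c(ny, nx, length(sel)))
  }
  climate_grid(out, model_series$variable, qm$lon, qm$lat,
               model_series$year, model_series$month)
}

#' Maximum ECDF distance between corrected and observed series
#'
#' Diagnostic for quantile-mapping quality: per cell and calendar month,
#' the Kolmogorov-Smirnov vertical distance between the empirical CDFs of
#' the corrected model series and the observed series over a common window;
#' returns the maximum over all cells/months.
#'
#' @param corrected,observed [climate_grid()]s on one grid.
#' @param years calendar years to compare over.
#' @return largest per-cell-month KS distance (a number in `[0, 1]`).
#' @export
max_ecdf_distance <- function(corrected, observed, years) {
  a <- subset_years(corrected, years); b <- subset_years(observed, years)
  ny <- length(a$lat); nx <- length(a$lon)
  worst <- 0
  for (m in 1:12) {
    av <- a$values[, , a$month == m, drop = FALSE]
    bv <- b$values[, , b$month == m, drop = FALSE]
    for (i in seq_len(ny)) for (j in seq_len(nx)) {
      x <- av[i, j, ]; y <- bv[i, j, ]
      if (anyNA(x) || anyNA(y)) next
      z <- sort(unique(c(x, y)))
      d <- max(abs(stats::ecdf(x)(z) - stats::ecdf(y)(z)))
      if (d > worst) worst <- d
    }
  }
  worst
}
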