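#' Basin-occupancy indicator series
#'
#' Treats each hill center as one sample of the collective variables at its
#' deposition time, maps it to the nearest grid node of the reference
#' surface and thence to its basin, and returns one binary occupancy series
#' per minimum. The series are the raw material for autocorrelation-based
#' error bars on free-energy differences. Samples are drawn from the biased
#' (progressively flattened) ensemble; no reweighting is applied.
#'
#' Centers falling outside a non-periodic grid range are clamped to the edge
#' node with a warning.
#'
#' @param hills a [read_hills()] object.
#' @param minima a precise-mode [find_minima()] result (supplies grid and
#'   basin assignment).
#' @return integer matrix, one row per hill and one 0/1 column per minimum
#'   (columns named by minima labels); each row sums to 1.
#' @export
occupancy_series <- function(hills, minima) {
  stopifnot(inherits(hills, "hills"), inherits(minima, "fes_minima"))
  if (is.null(minima$owner))
    stop("basin assignment required: use a precise-mode find_minima() result")
  f <- minima$fes
  d <- length(f$resolution)
  if (ncol(hills$centers) != d)
    stop("hills dimensionality does not match the reference surface")
  sp <- .fes_spacing(f)
  n <- length(hills$times)
  flat <- rep(0, n)
  strides <- cumprod(c(1, f$resolution[-d]))
  clamped <- FALSE
  for (j in seq_len(d)) {
    i <- round((hills$centers[, j] - f$lo[j]) / sp[j])
    if (f$cv$periodic[j]) {
      i <- i %% f$resolution[j]
    } else {
      out <- i < 0 | i > f$resolution[j] - 1
      if (any(out)) clamped <- TRUE
      i[i < 0] <- 0
      i[i > f$resolution[j] - 1] <- f$resolution[j] - 1
    }
    flat <- flat + i * strides[j]
  }
  if (clamped)
    warning("hill center(s) outside the grid range clamped to the edge")
  owner <- as.vector(minima$owner)[flat + 1]
  M <- nrow(minima$minima)
  occ <- matrix(0L, n, M, dimnames = list(NULL, minima$minima$label))
  occ[cbind(seq_len(n), owner)] <- 1L
  occ
}

#' Integrated autocorrelation statistics of a series
#'
#' Estimates the integrated autocorrelation time
#' `act = 1/2 + sum_k rho(k)` with the initial-positive-sequence truncation
#' rule: the sum over empirical autocorrelations stops at the first
#' non-positive pairwise sum `rho(2m-1) + rho(2m)` (a Geyer-style
#' estimator, robust for reversible-chain-like series). The effective
#' sample size is `n_eff = n / (2 act)` and the standard error of the mean
#' `se = sd * sqrt(1 / n_eff)`, never below the naive independent-sample
#' standard error (act is floored at 1/2).
#'
#' @param x numeric series (length >= 10).
#' @param maxlag largest lag considered; default `min(n - 1,
#'   max(100, 10 sqrt(n)))`.
#' @return An object of class `"series_stats"`: list with `n`, `mean`,
#'   `act`, `n_eff`, `se` and `zero_variance`. A constant series is flagged
#'   (`zero_variance = TRUE`, `act = NA`, `se = 0`).
#' @export
autocorr_stats <- function(x, maxlag = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("need at least 10 samples")
  m <- mean(x)
  s <- sd(x)
  if (s == 0) {
    return(structure(list(n = n, mean = m, act = NA_real_, n_eff = NA_real_,
                          se = 0, zero_variance = TRUE),
                     class = "series_stats"))
  }
  if (is.null(maxlag)) maxlag <- min(n - 1, max(100, floor(10 * sqrt(n))))
  rho <- as.vector(acf(x, lag.max = maxlag, plot = FALSE,
                       demean = TRUE)$acf)[-1]
  K <- 0L
  k <- 1L
  while (k <= length(rho)) {
    pair <- rho[k] + if (k + 1L <= length(rho)) rho[k + 1L] else 0
    if (pair <= 0) break
    K <- min(k + 1L, length(rho))
    k <- k + 2L
  }
  act <- max(0.5, 0.5 + sum(rho[seq_len(K)]))
  n_eff <- n / (2 * act)
  structure(list(n = n, mean = m, act = act, n_eff = n_eff,
                 se = s * sqrt(1 / n_eff), zero_variance = FALSE),
            class = "series_stats")
}

#' @export
print.series_stats <- function(x, ...) {
  if (x$zero_variance) {
    cat(sprintf("Series of %d samples, mean %.6g: zero variance (act not estimable)\n",
                x$n, x$mean))
  } else {
    cat(sprintf("Series of %d samples: mean %.6g, act %.3g, n_eff %.1f, se %.4g\n",
                x$n, x$mean, x$act, x$n_eff, x$se))
  }
  invisible(x)
}

#' Free-energy difference between two states with autocorrelation error
#'
#' Converts the mean occupancies of two basins into a free-energy
#' difference `dG = -kT log(p_a / p_b)` and propagates the
#' autocorrelation-corrected standard errors to first order:
#' `se(dG) = kT sqrt((se_a/p_a)^2 + (se_b/p_b)^2)`. Occupancies of 0 or 1
#' make the difference not estimable.
#'
#' @param stats_a,stats_b [autocorr_stats()] results for the two basins'
#'   occupancy series.
#' @param kT thermal energy, kJ/mol.
#' @return An object of class `"dg_error"`: list with `dg`, `se` (kJ/mol)
#'   and `estimable`.
#' @export
dg_error <- function(stats_a, stats_b, kT = 2.494339) {
  stopifnot(inherits(stats_a, "series_stats"), inherits(stats_b, "series_stats"))
  if (kT <= 0) stop("kT must be positive")
  pa <- stats_a$mean; pb <- stats_b$mean
  if (!(pa > 0 && pa < 1 && pb > 0 && pb < 1)) {
    return(structure(list(dg = NA_real_, se = NA_real_, estimable = FALSE),
                     class = "dg_error"))
  }
  structure(list(dg = -kT * log(pa / pb),
                 se = kT * sqrt((stats_a$se / pa)^2 + (stats_b$se / pb)^2),
                 estimable = TRUE),
            class = "dg_error")
}

#' @export
print.dg_error <- function(x, ...) {
  if (!x$estimable) {
    cat("Free-energy difference not estimable (empty or full occupancy)\n")
  } else {
    cat(sprintf("dG = %.4g +/- %.4g kJ/mol (1 se)\n", x$dg, x$se))
  }
  invisible(x)
}
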