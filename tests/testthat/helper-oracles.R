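# Shared fixtures and independent oracles.

# Build a hills object directly (bypassing file I/O) for small fixtures.
make_hills <- function(centers, widths, heights, times = NULL,
                       periodic = FALSE, lo = NA_real_, hi = NA_real_,
                       cv_names = NULL, biasf = NULL) {
  centers <- as.matrix(centers)
  d <- ncol(centers)
  widths <- matrix(widths, nrow(centers), d)
  if (is.null(times)) times <- seq_len(nrow(centers))
  if (is.null(cv_names)) cv_names <- paste0("cv", seq_len(d))
  colnames(centers) <- colnames(widths) <- cv_names
  structure(list(times = as.numeric(times), centers = centers,
                 widths = widths, heights = as.numeric(heights),
                 biasf = biasf,
                 cv = data.frame(name = cv_names,
                                 periodic = rep_len(periodic, d),
                                 lo = rep_len(lo, d), hi = rep_len(hi, d),
                                 stringsAsFactors = FALSE),
                 warnings = character()),
            class = "hills")
}

# Brute-force Gaussian sum with explicit periodic images (oracle for the
# minimum-image exact path; valid when sigma << period).
brute_gaussian_1d <- function(x, centers, sigma, heights, period = NULL,
                              n_images = 3) {
  v <- numeric(length(x))
  shifts <- if (is.null(period)) 0 else (-n_images:n_images) * period
  for (k in seq_along(centers)) {
    for (s in shifts) {
      v <- v + heights[k] * exp(-(x - centers[k] - s)^2 / (2 * sigma[k]^2))
    }
  }
  v
}

# Analytic free-energy difference of the tilted double well by quadrature,
# basins split at the barrier top.
double_well_dg <- function(spec) {
  U <- function(x) potential_energy(spec, cbind(x))
  xb <- optimize(function(x) -U(x), c(-0.5, 0.5))$minimum
  za <- integrate(function(x) exp(-U(x) / spec$kT), -4, xb)$value
  zb <- integrate(function(x) exp(-U(x) / spec$kT), xb, 4)$value
  list(dg = -spec$kT * log(zb / za), barrier = xb)
}

# Double-well ΔG measurement from a fitted minima set: merge basin
# populations by side of the barrier (metastable state = union of
# sub-basins on one side).
merged_dg <- function(minima, barrier, kT) {
  g <- minima$minima$g_population
  xs <- minima$minima[[minima$fes$cv$name[1]]]
  P <- exp(-g / kT)
  P <- P / sum(P)
  -kT * log(sum(P[xs > barrier]) / sum(P[xs < barrier]))
}

# 2D surface with one strict Gaussian well centered inside each cell of the
# default 8x8 coarse grid over [0, 1]^2.
cellwise_wells_fes <- function(resolution = 256, divisions = 8,
                               depth = 5, sigma = 0.015) {
  x <- seq(0, 1, length.out = resolution)
  cx <- (seq_len(divisions) - 0.5) / divisions
  gx <- sapply(cx, function(c) exp(-(x - c)^2 / (2 * sigma^2)))
  vals <- matrix(0, resolution, resolution)
  for (i in seq_len(divisions))
    for (j in seq_len(divisions))
      vals <- vals - depth * (gx[, i] %o% gx[, j])
  fes_grid(vals, c("x", "y"), lo = c(0, 0), hi = c(1, 1))
}
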