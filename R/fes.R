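#' Reconstruct a free energy surface from metadynamics hills
#'
#' Sums the deposited Gaussian bias potential V(s) on a regular grid over the
#' collective variables and returns its negative, F(s) = -V(s), as the free
#' energy surface estimate. Two summation paths are available:
#'
#' * `method = "exact"` evaluates the Gaussian of every hill at every grid
#'   node (minimum-image displacement on periodic CVs). Suitable for
#'   quantitative work.
#' * `method = "fast"` precomputes one Gaussian kernel sampled on the grid
#'   spacing, truncated where the exponent exceeds `cutoff`, and stamps it
#'   at the grid node nearest each hill center (with periodic wrap-around).
#'   Requires all hills of a CV to share one width (the common Plumed case);
#'   otherwise it refuses and directs you to the exact path.
#'
#' Hills are summed in a canonical order (sorted by time, then centers,
#' widths, heights), so the result is bit-identical under any permutation of
#' the input hills. Heights are used exactly as stored in the file: Plumed
#' already writes well-tempered heights pre-scaled so that plain summation
#' yields the free energy. For files holding unscaled heights set
#' `scale_biasfactor = TRUE` to apply the gamma/(gamma-1) factor.
#'
#' @param hills a [read_hills()] object.
#' @param resolution grid nodes per CV (recycled); default 256 for 1-2 CVs,
#'   64 for 3.
#' @param method `"fast"` (default) or `"exact"`.
#' @param range_lo,range_hi optional numeric vectors (length d) overriding
#'   the grid range. Defaults: the period bounds for periodic CVs, and the
#'   hill-center range padded by 3 mean widths for non-periodic CVs.
#' @param scale_biasfactor multiply heights by gamma/(gamma-1) (requires a
#'   `biasf` column). Default `FALSE`.
#' @param cutoff fast-path kernel truncation: the Gaussian exponent beyond
#'   which the kernel is zero. Default 6.25 (3.53 sigma).
#' @return An object of class `"fes"`: list with `values` (d-dimensional
#'   array, kJ/mol), `cv` (data frame `name`, `periodic`), `lo`, `hi`,
#'   `resolution`, `unit`.
#' @examples
#' sp <- sim_spec("double_well_1d", n_steps = 2000, seed = 1)
#' h <- simulate_metad(sp)$hills
#' f <- fes(h, resolution = 128, method = "exact")
#' print(f)
#' @export
fes <- function(hills, resolution = NULL, method = c("fast", "exact"),
                range_lo = NULL, range_hi = NULL, scale_biasfactor = FALSE,
                cutoff = 6.25) {
  stopifnot(inherits(hills, "hills"))
  method <- match.arg(method)
  d <- nrow(hills$cv)
  if (is.null(resolution)) resolution <- if (d <= 2) 256L else 64L
  resolution <- as.integer(rep_len(resolution, d))
  if (length(resolution) != d || any(resolution < 2))
    stop("resolution must give >= 2 nodes for each of the ", d, " CVs")

  rng <- .default_range(hills)
  if (!is.null(range_lo)) rng$lo <- rep_len(as.numeric(range_lo), d)
  if (!is.null(range_hi)) rng$hi <- rep_len(as.numeric(range_hi), d)
  if (any(rng$lo >= rng$hi)) stop("range_lo must be < range_hi")

  heights <- hills$heights
  if (scale_biasfactor) {
    if (is.null(hills$biasf))
      stop("scale_biasfactor = TRUE requires a biasf column")
    g <- hills$biasf
    heights <- heights * g / (g - 1)
  }

  # canonical accumulation order: permutation-invariant by construction
  ord <- do.call(order, c(list(hills$times),
                          lapply(seq_len(d), function(j) hills$centers[, j]),
                          lapply(seq_len(d), function(j) hills$widths[, j]),
                          list(heights)))
  centers <- hills$centers[ord, , drop = FALSE]
  widths <- hills$widths[ord, , drop = FALSE]
  heights <- heights[ord]
  periodic <- hills$cv$periodic

  if (method == "exact") {
    V <- cpp_sum_hills_exact(centers, widths, heights, resolution,
                             rng$lo, rng$hi, periodic)
  } else {
    sig <- numeric(d)
    for (j in seq_len(d)) {
      w <- widths[, j]
      sig[j] <- mean(w)
      if (max(abs(w - sig[j])) > 1e-6 * sig[j])
        stop("hill widths of CV '", hills$cv$name[j],
             "' are not constant; the fast path needs a single width per CV",
             " - use method = \"exact\"")
    }
    V <- cpp_sum_hills_fast(centers, sig, heights, resolution,
                            rng$lo, rng$hi, periodic, cutoff)
  }
  fes_grid(array(-V, dim = resolution), cv_names = hills$cv$name,
           lo = rng$lo, hi = rng$hi, periodic = periodic, unit = "kJ/mol")
}

.default_range <- function(hills) {
  d <- nrow(hills$cv)
  lo <- hi <- numeric(d)
  for (j in seq_len(d)) {
    if (hills$cv$periodic[j]) {
      lo[j] <- hills$cv$lo[j]; hi[j] <- hills$cv$hi[j]
    } else {
      pad <- 3 * mean(hills$widths[, j])
      lo[j] <- min(hills$centers[, j]) - pad
      hi[j] <- max(hills$centers[, j]) + pad
    }
  }
  list(lo = lo, hi = hi)
}

#' Construct a free energy surface from a grid of values
#'
#' Low-level constructor used by [fes()], [import_fes()] and by tests that
#' tabulate analytic surfaces. Grid nodes run from `lo` to `hi`; periodic
#' dimensions exclude the upper bound (spacing `(hi-lo)/r`), non-periodic
#' dimensions include both ends (spacing `(hi-lo)/(r-1)`).
#'
#' @param values numeric array (1-3 dimensions) of free-energy values.
#' @param cv_names character vector of CV names.
#' @param lo,hi numeric vectors: grid range per dimension.
#' @param periodic logical vector per dimension.
#' @param unit energy unit label, default `"kJ/mol"`.
#' @return an object of class `"fes"`.
#' @export
fes_grid <- function(values, cv_names, lo, hi, periodic = FALSE,
                     unit = "kJ/mol") {
  values <- as.array(values)
  d <- length(dim(values))
  stopifnot(d >= 1, d <= 3)
  periodic <- rep_len(as.logical(periodic), d)
  lo <- rep_len(as.numeric(lo), d); hi <- rep_len(as.numeric(hi), d)
  cv_names <- rep_len(as.character(cv_names), d)
  if (any(dim(values) < 2)) stop("each dimension needs >= 2 grid nodes")
  if (any(lo >= hi)) stop("lo must be < hi in every dimension")
  structure(list(values = values,
                 cv = data.frame(name = cv_names, periodic = periodic,
                                 stringsAsFactors = FALSE),
                 lo = lo, hi = hi, resolution = dim(values), unit = unit),
            class = "fes")
}

#' Grid node coordinates of a free energy surface
#'
#' @param fes a `"fes"` object.
#' @param dim_index which dimension (1-based).
#' @return numeric vector of node coordinates along that dimension.
#' @export
fes_nodes <- function(fes, dim_index) {
  r <- fes$resolution[dim_index]
  sp <- .fes_spacing(fes)[dim_index]
  fes$lo[dim_index] + (seq_len(r) - 1) * sp
}

.fes_spacing <- function(fes) {
  ifelse(fes$cv$periodic, (fes$hi - fes$lo) / fes$resolution,
         (fes$hi - fes$lo) / (fes$resolution - 1))
}

#' Shift a free energy surface so its global minimum is zero
#'
#' @param fes a `"fes"` object.
#' @return the normalized `"fes"` (idempotent).
#' @export
fes_normalize <- function(fes) {
  stopifnot(inherits(fes, "fes"))
  fes$values <- fes$values - min(fes$values)
  fes
}

#' Rescale a free energy surface by a scalar
#'
#' Multiplies all values by `factor`; the unit label is updated only when
#' the caller supplies one (e.g. `fes_scale(f, 0.239006, "kcal/mol")` to
#' convert kJ/mol to kcal/mol).
#'
#' @param fes a `"fes"` object.
#' @param factor scalar multiplier.
#' @param unit optional new unit label.
#' @return the rescaled `"fes"`.
#' @export
fes_scale <- function(fes, factor, unit = NULL) {
  stopifnot(inherits(fes, "fes"), is.numeric(factor), length(factor) == 1)
  fes$values <- fes$values * factor
  if (!is.null(unit)) fes$unit <- unit
  fes
}

.fes_compatible <- function(a, b) {
  for (attr in c("lo", "hi", "resolution")) {
    if (!isTRUE(all.equal(a[[attr]], b[[attr]], tolerance = 0,
                          check.attributes = FALSE)))
      stop("incompatible free energy surfaces: '", attr, "' differs")
  }
  if (!identical(a$cv$periodic, b$cv$periodic))
    stop("incompatible free energy surfaces: 'periodic' differs")
  if (!identical(a$cv$name, b$cv$name))
    stop("incompatible free energy surfaces: 'cv names' differ")
  if (!identical(a$unit, b$unit))
    stop("incompatible free energy surfaces: 'unit' differs")
  invisible(TRUE)
}

#' Arithmetic on free energy surfaces
#'
#' `+` and `-` combine two surfaces defined on the same grid (e.g. FES of
#' two hill subsets, or the difference of two systems); `*` and `/` with a
#' scalar rescale the values (see [fes_scale()] to also relabel the unit).
#'
#' @param e1,e2 `"fes"` objects or scalars as the operator admits.
#' @return a `"fes"` object.
#' @export
Ops.fes <- function(e1, e2) {
  if (missing(e2)) {  # unary
    if (.Generic == "-") { e1$values <- -e1$values; return(e1) }
    if (.Generic == "+") return(e1)
    stop("unary '", .Generic, "' not defined for fes objects")
  }
  if (inherits(e1, "fes") && inherits(e2, "fes")) {
    if (!(.Generic %in% c("+", "-")))
      stop("'", .Generic, "' not defined for two fes objects")
    .fes_compatible(e1, e2)
    e1$values <- get(.Generic)(e1$values, e2$values)
    return(e1)
  }
  if (inherits(e1, "fes") && is.numeric(e2) && length(e2) == 1) {
    if (!(.Generic %in% c("*", "/", "+", "-")))
      stop("'", .Generic, "' not defined for fes and scalar")
    e1$values <- get(.Generic)(e1$values, e2)
    return(e1)
  }
  if (is.numeric(e1) && length(e1) == 1 && inherits(e2, "fes")) {
    if (!(.Generic %in% c("*", "+")))
      stop("'", .Generic, "' not defined for scalar ", .Generic, " fes")
    e2$values <- get(.Generic)(e1, e2$values)
    return(e2)
  }
  stop("unsupported operand types for '", .Generic, "'")
}

#' Remove collective variables from a free energy surface
#'
#' Boltzmann-marginalizes the removed dimensions at thermal energy `kT`:
#' F'(s_keep) = -kT log sum_removed exp(-F/kT), computed with log-sum-exp
#' stabilization, then shifted so the minimum is zero. This is the standard
#' way to convert, say, a 2D surface to 1D for convergence comparisons.
#'
#' @param fes a `"fes"` object with d >= 2.
#' @param keep integer indices of the dimensions to keep (proper non-empty
#'   subset of `1:d`).
#' @param kT thermal energy in the surface's unit (default 2.494339 kJ/mol,
#'   i.e. 300 K).
#' @return a lower-dimensional, normalized `"fes"`.
#' @export
marginalize <- function(fes, keep, kT = 2.494339) {
  stopifnot(inherits(fes, "fes"))
  d <- length(fes$resolution)
  keep <- sort(unique(as.integer(keep)))
  if (!length(keep) || length(keep) >= d || any(keep < 1) || any(keep > d))
    stop("'keep' must be a non-empty proper subset of 1:", d)
  if (!is.numeric(kT) || kT <= 0) stop("kT must be a positive number")
  lw <- -fes$values / kT
  m <- apply(lw, keep, logsumexp)
  out <- fes_grid(array(-kT * m, dim = fes$resolution[keep]),
                  cv_names = fes$cv$name[keep], lo = fes$lo[keep],
                  hi = fes$hi[keep], periodic = fes$cv$periodic[keep],
                  unit = fes$unit)
  fes_normalize(out)
}

#' @export
print.fes <- function(x, ...) {
  d <- length(x$resolution)
  cat("Free energy surface: ", paste(x$resolution, collapse = " x "),
      " grid, ", d, " CV", if (d > 1) "s", " [", x$unit, "]\n", sep = "")
  for (j in seq_len(d))
    cat(sprintf("  %s: [%.6g, %.6g]%s\n", x$cv$name[j], x$lo[j], x$hi[j],
                if (x$cv$periodic[j]) " (periodic)" else ""))
  cat(sprintf("  values: min %.6g, max %.6g\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
summary.fes <- function(object, ...) {
  print(object)
  cat("Value quantiles:\n")
  print(stats::quantile(object$values))
  invisible(object)
}
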