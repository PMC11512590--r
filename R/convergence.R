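#' Per-minimum free energies along the simulation
#'
#' Diagnoses convergence by rebuilding the free energy surface from growing
#' prefixes of the hill list and evaluating the population-weighted free
#' energy of every metastable state at each checkpoint. The reference minima
#' and basin assignment are computed once from the full-simulation surface
#' and held fixed across checkpoints, so each state's series is well defined
#' even when early surfaces do not yet show all minima (a state not yet
#' explored simply appears at a high free energy). Each checkpoint row is
#' shifted so its own global minimum is at 0. Stable profiles over the late
#' checkpoints are one indication — not proof — of convergence.
#'
#' @param hills a [read_hills()] object.
#' @param n_checkpoints number of checkpoints; hill counts are
#'   `ceiling(n * k / n_checkpoints)` for k = 1..n_checkpoints (duplicates
#'   collapsed when there are fewer hills than checkpoints).
#' @param kT thermal energy, kJ/mol.
#' @param method summation path passed to [fes()] (`"fast"` or `"exact"`).
#' @param resolution grid resolution passed to [fes()].
#' @return An object of class `"convergence_profile"`: list with
#'   `checkpoints` (hill counts), `g` (checkpoint x minimum matrix of free
#'   energies, columns named by minima labels), `minima` (the reference
#'   [find_minima()] object) and `kT`.
#' @export
convergence_profile <- function(hills, n_checkpoints = 10, kT = 2.494339,
                                method = c("fast", "exact"),
                                resolution = NULL) {
  stopifnot(inherits(hills, "hills"))
  method <- match.arg(method)
  if (n_checkpoints < 1) stop("n_checkpoints must be >= 1")
  n <- length(hills$times)
  full <- fes(hills, resolution = resolution, method = method)
  minima <- find_minima(full, mode = "precise", kT = kT)
  ck <- unique(pmin(n, ceiling(n * seq_len(n_checkpoints) / n_checkpoints)))
  ck <- ck[ck >= 1]
  G <- matrix(NA_real_, length(ck), nrow(minima$minima),
              dimnames = list(NULL, minima$minima$label))
  for (i in seq_along(ck)) {
    fk <- fes(slice_hills(hills, 1, ck[i]), resolution = full$resolution,
              method = method, range_lo = full$lo, range_hi = full$hi)
    G[i, ] <- minima_free_energies(fk, minima, kT)
  }
  structure(list(checkpoints = ck, g = G, minima = minima, kT = kT),
            class = "convergence_profile")
}

#' Marginal free-energy profiles at successive simulation stages
#'
#' Builds the FES from growing prefixes of the hill list (equal fractions of
#' the run), removes the dimensions not in `keep` by Boltzmann
#' marginalization, and returns one normalized lower-dimensional surface per
#' stage, for overlay plotting: late-stage profiles that sit on top of each
#' other indicate a stable estimate.
#'
#' @param hills a [read_hills()] object with d >= 2 CVs.
#' @param keep dimension indices to keep (see [marginalize()]).
#' @param stages number of prefix stages (>= 1).
#' @param kT thermal energy, kJ/mol.
#' @param method,resolution passed to [fes()].
#' @return list of `"fes"` objects (one per stage, attribute `checkpoints`
#'   holds the hill counts), classed `"fes_marginals"`.
#' @export
marginal_evolution <- function(hills, keep, stages = 4, kT = 2.494339,
                               method = c("fast", "exact"),
                               resolution = NULL) {
  stopifnot(inherits(hills, "hills"))
  method <- match.arg(method)
  if (stages < 1) stop("stages must be >= 1")
  n <- length(hills$times)
  full <- fes(hills, resolution = resolution, method = method)
  ck <- unique(pmin(n, ceiling(n * seq_len(stages) / stages)))
  out <- lapply(ck, function(k) {
    fk <- fes(slice_hills(hills, 1, k), resolution = full$resolution,
              method = method, range_lo = full$lo, range_hi = full$hi)
    marginalize(fk, keep, kT)
  })
  attr(out, "checkpoints") <- ck
  class(out) <- "fes_marginals"
  out
}

#' Hill heights over simulation time
#'
#' In well-tempered metadynamics the deposited heights decay as a basin
#' fills, so this series is a quick visual convergence check.
#'
#' @param hills a [read_hills()] object.
#' @return data frame with columns `time` (ps) and `height` (kJ/mol).
#' @export
heights_series <- function(hills) {
  stopifnot(inherits(hills, "hills"))
  data.frame(time = hills$times, height = hills$heights)
}

#' Collective-variable values over simulation time
#'
#' @param hills a [read_hills()] object.
#' @return data frame with `time` (ps) and one column per CV (the hill
#'   centers, i.e. the CV values at deposition times).
#' @export
cv_series <- function(hills) {
  stopifnot(inherits(hills, "hills"))
  out <- data.frame(time = hills$times)
  for (j in seq_len(nrow(hills$cv)))
    out[[hills$cv$name[j]]] <- hills$centers[, j]
  out
}

#' @export
print.convergence_profile <- function(x, ...) {
  cat("Convergence profile: ", length(x$checkpoints), " checkpoints, ",
      ncol(x$g), " minima\n", sep = "")
  cat("Final free energies (kJ/mol):\n")
  print(round(x$g[nrow(x$g), ], 3))
  invisible(x)
}

#' @export
plot.convergence_profile <- function(x, xlab = "hills deposited",
                                     ylab = NULL, col = NULL, lty = 1,
                                     lwd = 2, ...) {
  if (is.null(ylab)) ylab <- paste0("free energy [", x$minima$fes$unit, "]")
  if (is.null(col)) col <- seq_len(ncol(x$g))
  graphics::matplot(x$checkpoints, x$g, type = "l", xlab = xlab, ylab = ylab,
                    col = col, lty = lty, lwd = lwd, ...)
  graphics::legend("topright", legend = colnames(x$g), col = col, lty = lty,
                   lwd = lwd, bty = "n")
  invisible(x)
}

#' @export
plot.fes_marginals <- function(x, xlab = NULL, ylab = NULL, col = NULL,
                               lwd = 2, ...) {
  if (length(x[[1]]$resolution) != 1)
    stop("overlay plotting supports 1D marginals")
  if (is.null(xlab)) xlab <- x[[1]]$cv$name[1]
  if (is.null(ylab)) ylab <- paste0("free energy [", x[[1]]$unit, "]")
  if (is.null(col)) col <- grDevices::hcl.colors(length(x), "Blues 3",
                                                 rev = TRUE)
  nodes <- fes_nodes(x[[1]], 1)
  ylim <- range(vapply(x, function(f) range(f$values), numeric(2)))
  graphics::plot(nodes, x[[1]]$values, type = "l", col = col[1], lwd = lwd,
                 xlab = xlab, ylab = ylab, ylim = ylim, ...)
  for (i in seq_along(x)[-1])
    graphics::lines(nodes, x[[i]]$values, col = col[i], lwd = lwd)
  ck <- attr(x, "checkpoints")
  graphics::legend("topright", legend = paste(ck, "hills"), col = col,
                   lwd = lwd, bty = "n")
  invisible(x)
}
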