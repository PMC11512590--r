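#' Specification of a synthetic metadynamics run
#'
#' Bundles the analytic model potential, the overdamped Langevin integration
#' settings and the hill-deposition settings of a synthetic run. The
#' built-in potentials (CV units are arbitrary; energies kJ/mol):
#'
#' * `double_well_1d`: U(x) = B (x^2 - 1)^2 + a x, a tilted double well with
#'   minima near x = +/- 1 (defaults B = 8, a = 1.5, so the x = -1 well is
#'   the global state and the analytic free-energy gap is a few kJ/mol).
#' * `four_well_2d`: U(x, y) = B ((x^2 - 1)^2 + (y^2 - 1)^2), four
#'   equivalent wells at (+/-1, +/-1) (default B = 15).
#' * `periodic_cosine_1d`: U(x) = A (1 - cos x) on the periodic domain
#'   from -pi to pi (default A = 5, a torsion-like 10 kJ/mol range).
#'
#' Defaults follow common practice for toy metadynamics benchmarks: kT at
#' 300 K, hill height 1 kJ/mol, deposition every 25 steps, well-tempered
#' bias factor 10.
#'
#' @param potential one of `"double_well_1d"`, `"four_well_2d"`,
#'   `"periodic_cosine_1d"`.
#' @param kT thermal energy, kJ/mol.
#' @param dt friction-scaled timestep, ps (per-potential defaults keep the
#'   Euler-Maruyama update stable against the stiffest curvature).
#' @param n_steps number of integration steps.
#' @param stride deposit one hill every `stride` steps.
#' @param height base hill height w, kJ/mol.
#' @param width hill width sigma per CV (per-potential default).
#' @param biasfactor well-tempered bias factor gamma (> 1), or `NULL` for
#'   standard (non-tempered) metadynamics.
#' @param seed RNG seed for [simulate_metad()].
#' @param params named numeric vector overriding the potential parameters.
#' @param s0 starting CV values (default: the global minimum).
#' @return an object of class `"sim_spec"`.
#' @export
sim_spec <- function(potential = c("double_well_1d", "four_well_2d",
                                   "periodic_cosine_1d"),
                     kT = 2.494339, dt = NULL, n_steps = 50000, stride = 25,
                     height = 1.0, width = NULL, biasfactor = 10, seed = 1,
                     params = NULL, s0 = NULL) {
  potential <- match.arg(potential)
  def <- switch(potential,
    double_well_1d = list(id = 1L, d = 1L, par = c(B = 8, a = 1.5),
                          dt = 0.001, width = 0.1, lo = -2, hi = 2,
                          periodic = FALSE, s0 = -1,
                          cv_names = "x"),
    four_well_2d = list(id = 2L, d = 2L, par = c(B = 15),
                        dt = 5e-4, width = c(0.15, 0.15), lo = c(-2, -2),
                        hi = c(2, 2), periodic = c(FALSE, FALSE),
                        s0 = c(-1, -1), cv_names = c("x", "y")),
    periodic_cosine_1d = list(id = 3L, d = 1L, par = c(A = 5),
                              dt = 0.005, width = 0.2, lo = -pi, hi = pi,
                              periodic = TRUE, s0 = 0, cv_names = "x"))
  if (!is.null(params)) def$par[names(params)] <- params
  if (is.null(dt)) dt <- def$dt
  if (is.null(width)) width <- def$width
  width <- rep_len(width, def$d)
  if (is.null(s0)) s0 <- def$s0
  stopifnot(kT > 0, dt > 0, n_steps >= 1, stride >= 1, height >= 0,
            all(width > 0), is.null(biasfactor) || biasfactor > 1)
  structure(list(potential = potential, id = def$id, d = def$d,
                 par = def$par, kT = kT, dt = dt, n_steps = as.integer(n_steps),
                 stride = as.integer(stride), height = height, width = width,
                 biasfactor = biasfactor, seed = seed,
                 lo = def$lo, hi = def$hi, periodic = def$periodic,
                 s0 = rep_len(s0, def$d), cv_names = def$cv_names),
            class = "sim_spec")
}

#' Run a synthetic metadynamics simulation
#'
#' Integrates overdamped Langevin dynamics (Euler-Maruyama) on
#' U(s) + V_bias(s, t), depositing a Gaussian hill every `stride` steps. In
#' well-tempered mode the deposited height is
#' w exp(-V_bias(s, t) / ((gamma - 1) kT)); the heights recorded in the
#' returned hills (and written to HILLS files) are pre-scaled by
#' gamma/(gamma - 1), the Plumed convention under which plain summation of
#' the recorded heights reconstructs -F directly. Periodic CVs use
#' minimum-image distances throughout. Runs are reproducible: identical
#' seeds give byte-identical HILLS files.
#'
#' @param spec a [sim_spec()] object.
#' @return list with `hills` (a `"hills"` object), `trajectory`
#'   (n_steps x d matrix of CV values) and `spec`.
#' @examples
#' run <- simulate_metad(sim_spec("double_well_1d", n_steps = 2000, seed = 7))
#' run$hills
#' @export
simulate_metad <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  res <- cpp_simulate(spec$id, unname(spec$par), spec$d, spec$kT, spec$dt,
                      spec$n_steps, spec$stride, spec$height, spec$width,
                      if (is.null(spec$biasfactor)) -1 else spec$biasfactor,
                      spec$s0, spec$lo, spec$hi, spec$periodic)
  n <- length(res$times)
  if (!n) stop("no hills deposited: increase n_steps or decrease stride")
  centers <- res$centers
  colnames(centers) <- spec$cv_names
  widths <- matrix(spec$width, n, spec$d, byrow = TRUE,
                   dimnames = list(NULL, spec$cv_names))
  hills <- structure(list(
    times = res$times, centers = centers, widths = widths,
    heights = res$heights,
    biasf = if (is.null(spec$biasfactor)) NULL else rep(spec$biasfactor, n),
    cv = data.frame(name = spec$cv_names, periodic = spec$periodic,
                    lo = ifelse(spec$periodic, spec$lo, NA_real_),
                    hi = ifelse(spec$periodic, spec$hi, NA_real_),
                    stringsAsFactors = FALSE),
    warnings = character()
  ), class = "hills")
  colnames(res$trajectory) <- spec$cv_names
  list(hills = hills, trajectory = res$trajectory, spec = spec)
}

#' Tabulate the analytic potential of a synthetic run as a surface
#'
#' Evaluates the model potential U on a regular grid over the potential's
#' reference range and normalizes it — the ground truth against which
#' reconstructed free energy surfaces can be compared.
#'
#' @param spec a [sim_spec()] object.
#' @param resolution grid nodes per CV.
#' @return a normalized `"fes"` object.
#' @export
analytic_fes <- function(spec, resolution = 256) {
  stopifnot(inherits(spec, "sim_spec"))
  resolution <- as.integer(rep_len(resolution, spec$d))
  f0 <- fes_grid(array(0, dim = pmax(resolution, 2)),
                 cv_names = spec$cv_names, lo = spec$lo, hi = spec$hi,
                 periodic = spec$periodic)
  nodes <- lapply(seq_len(spec$d), function(j) fes_nodes(f0, j))
  U <- potential_energy(spec, do.call(expand.grid, nodes))
  f0$values <- array(U, dim = resolution)
  fes_normalize(f0)
}

#' Evaluate the analytic model potential
#'
#' @param spec a [sim_spec()] object.
#' @param s numeric vector (one point), matrix or data frame of CV values.
#' @return numeric vector of potential energies, kJ/mol.
#' @export
potential_energy <- function(spec, s) {
  stopifnot(inherits(spec, "sim_spec"))
  s <- as.matrix(s)
  if (ncol(s) != spec$d && nrow(s) == spec$d) s <- t(s)
  p <- spec$par
  switch(spec$potential,
    double_well_1d = p[["B"]] * (s[, 1]^2 - 1)^2 + p[["a"]] * s[, 1],
    four_well_2d = p[["B"]] * ((s[, 1]^2 - 1)^2 + (s[, 2]^2 - 1)^2),
    periodic_cosine_1d = p[["A"]] * (1 - cos(s[, 1])))
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Synthetic metadynamics spec: ", x$potential, " (",
      x$d, "D)\n", sep = "")
  cat(sprintf("  kT %.4g kJ/mol, dt %.4g ps, %d steps, hill every %d steps\n",
              x$kT, x$dt, x$n_steps, x$stride))
  cat(sprintf("  hill height %.3g kJ/mol, width %s%s, seed %s\n",
              x$height, paste(format(x$width), collapse = ", "),
              if (is.null(x$biasfactor)) ", non-tempered"
              else paste0(", bias factor ", format(x$biasfactor)),
              format(x$seed)))
  invisible(x)
}
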