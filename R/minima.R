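# Neighborhood machinery shared by minima detection and basin assignment.
# Grids are addressed by 0-based flat indices (column-major, first dim
# fastest) internally; everything user-facing is 1-based.

# For every node: the minimum value over its Moore neighborhood (3^d - 1
# neighbors, periodic wrap on periodic dims, +Inf outside non-periodic
# edges), and the steepest-descent successor: the lexicographic (value,
# row-major index) minimum over the node itself and its neighbors. Sinks
# (successor == self) are the descent targets.
.grid_descent <- function(vals, r, periodic) {
  d <- length(r); N <- prod(r)
  v <- as.numeric(vals)
  idx0 <- 0:(N - 1)
  strides <- cumprod(c(1, r[-d]))
  coord <- matrix(0L, N, d)
  for (j in seq_len(d)) coord[, j] <- (idx0 %/% strides[j]) %% r[j]
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), d)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]

  best_val <- v; best_idx <- idx0
  min_nb <- rep(Inf, N)
  for (o in seq_len(nrow(offs))) {
    valid <- rep(TRUE, N)
    flat <- rep(0, N)
    for (j in seq_len(d)) {
      cj <- coord[, j] + offs[o, j]
      if (periodic[j]) {
        cj <- cj %% r[j]
      } else {
        valid <- valid & cj >= 0L & cj < r[j]
        cj[cj < 0L] <- 0L; cj[cj >= r[j]] <- r[j] - 1L
      }
      flat <- flat + cj * strides[j]
    }
    nv <- v[flat + 1]
    nv[!valid] <- Inf
    min_nb <- pmin(min_nb, nv)
    better <- (nv < best_val) | (nv == best_val & valid & flat < best_idx)
    best_val[better] <- nv[better]
    best_idx[better] <- flat[better]
  }
  # resolve ownership by pointer jumping (paths strictly decrease in
  # (value, index), so this terminates)
  own <- best_idx
  repeat {
    own2 <- best_idx[own + 1]
    if (identical(own2, own)) break
    own <- own2
  }
  list(strict = v < min_nb, owner0 = own, coord = coord, strides = strides,
       offs = offs)
}

.make_labels <- function(n) {
  lab <- character(n)
  for (i in seq_len(n)) {
    k <- i - 1L; s <- ""
    repeat {
      s <- paste0(LETTERS[k %% 26L + 1L], s)
      k <- k %/% 26L - 1L
      if (k < 0L) break
    }
    lab[i] <- s
  }
  lab
}

#' Locate free-energy minima and assign basins
#'
#' In `mode = "precise"` every grid node that is strictly lower than all of
#' its Moore neighbors (full 3^d - 1 neighborhood, periodic wrap on periodic
#' CVs, missing neighbors at non-periodic edges treated as +Inf) is a local
#' minimum; every node is then assigned to a minimum by steepest descent
#' (hop to the lowest neighbor, ties broken by smallest row-major index,
#' until a minimum is reached). The basin boundary mask marks nodes with a
#' face neighbor owned by a different minimum. Population-weighted free
#' energies of the basins are computed via [minima_free_energies()] and the
#' minima labelled A, B, C, ... in ascending population free energy (the
#' global state is A).
#'
#' In `mode = "grid"` the CV range is divided into a coarse grid of
#' `divisions` cells per CV (default 8, i.e. 8, 8 x 8 or 8 x 8 x 8 cells for
#' 1-3 CVs) and the lowest node of each cell is kept if it is a strict local
#' minimum of the full surface; duplicates found from adjacent cells are
#' collapsed. Up to `prod(divisions)` minima can be returned (64 for a 2D
#' surface at defaults). Grid mode returns no basin assignment, so minima
#' are labelled in ascending depth and `g_population` is `NA`.
#'
#' @param fes a `"fes"` object (normalized internally).
#' @param mode `"precise"` (default) or `"grid"`.
#' @param divisions coarse-grid cells per CV (grid mode), default 8.
#' @param kT thermal energy for the population weights, kJ/mol.
#' @return An object of class `"fes_minima"`: list with `minima` (data frame
#'   with `label`, one coordinate column per CV, `depth` — the FES value at
#'   the minimum node — and `g_population`), `owner` (integer array mapping
#'   every node to a minimum, precise mode), `boundary` (logical array,
#'   precise mode), the normalized `fes`, `mode` and `kT`. The grid indices
#'   of the minima are in `attr(x$minima, "grid_index")` (1-based).
#' @examples
#' x <- seq(-2, 2, length.out = 129)
#' f <- fes_grid((x^2 - 1)^2, "x", -2, 2)  # symmetric double well
#' m <- find_minima(f)
#' m$minima
#' @export
find_minima <- function(fes, mode = c("precise", "grid"), divisions = 8,
                        kT = 2.494339) {
  stopifnot(inherits(fes, "fes"))
  mode <- match.arg(mode)
  if (kT <= 0) stop("kT must be positive")
  fes <- fes_normalize(fes)
  r <- fes$resolution; d <- length(r)
  periodic <- fes$cv$periodic
  v <- as.numeric(fes$values)

  if (mode == "precise") {
    dsc <- .grid_descent(fes$values, r, periodic)
    sinks <- sort(unique(dsc$owner0))
    strict_sinks <- sinks[dsc$strict[sinks + 1]]
    if (!length(strict_sinks))
      stop("no strict minima on this surface (is it constant?)")
    own <- dsc$owner0
    if (length(strict_sinks) < length(sinks)) {
      # plateau sinks: merge each into the nearest strict minimum
      bad <- setdiff(sinks, strict_sinks)
      sc <- dsc$coord[strict_sinks + 1, , drop = FALSE]
      for (b in bad) {
        bc <- dsc$coord[b + 1, ]
        dd <- colSums((t(sc) - bc)^2)
        own[own == b] <- strict_sinks[which.min(dd)]
      }
    }
    min0 <- strict_sinks                      # 0-based flat indices
    owner_idx <- match(own, min0)             # minimum index per node
    g <- .basin_g(v, owner_idx, length(min0), kT)
    ord <- order(g, min0)
    min0 <- min0[ord]; g <- g[ord]
    owner_idx <- match(own, min0)
    labels <- .make_labels(length(min0))

    # face-neighbor boundary mask
    owner_arr <- array(owner_idx, dim = r)
    boundary <- array(FALSE, dim = r)
    for (j in seq_len(d)) {
      for (s in c(-1L, 1L)) {
        shifted <- .shift_array(owner_arr, j, s, periodic[j])
        boundary <- boundary | (!is.na(shifted) & shifted != owner_arr)
      }
    }
    tab <- .minima_table(fes, min0, labels, g)
    structure(list(minima = tab, owner = owner_arr, boundary = boundary,
                   fes = fes, mode = mode, kT = kT),
              class = "fes_minima")
  } else {
    divisions <- as.integer(rep_len(divisions, d))
    if (any(divisions < 1)) stop("divisions must be >= 1")
    if (any(r < divisions))
      stop("FES resolution must be >= divisions in every dimension")
    dsc <- .grid_descent(fes$values, r, periodic)  # for the strict-min test
    cell_lo <- lapply(seq_len(d), function(j)
      floor(r[j] * (0:(divisions[j] - 1)) / divisions[j]))
    cell_hi <- lapply(seq_len(d), function(j)
      floor(r[j] * (1:divisions[j]) / divisions[j]) - 1L)
    cells <- as.matrix(do.call(expand.grid,
                               lapply(divisions, function(k) seq_len(k))))
    found <- integer(0)
    strides <- dsc$strides
    for (ci in seq_len(nrow(cells))) {
      rngs <- lapply(seq_len(d), function(j) {
        cell_lo[[j]][cells[ci, j]]:cell_hi[[j]][cells[ci, j]]
      })
      nodes <- as.matrix(do.call(expand.grid, rngs))  # row-major-in-subset
      flat <- as.vector(nodes %*% strides)
      low <- flat[which.min(v[flat + 1])]
      if (dsc$strict[low + 1]) found <- c(found, low)
    }
    min0 <- sort(unique(found))
    depth <- v[min0 + 1]
    ord <- order(depth, min0)
    min0 <- min0[ord]
    labels <- .make_labels(length(min0))
    tab <- .minima_table(fes, min0, labels, rep(NA_real_, length(min0)))
    structure(list(minima = tab, owner = NULL, boundary = NULL,
                   fes = fes, mode = mode, kT = kT),
              class = "fes_minima")
  }
}

# shift an array by s along dim j; non-periodic vacated slots become NA
.shift_array <- function(a, j, s, periodic) {
  r <- dim(a); d <- length(r)
  idx <- seq_len(r[j]) - s
  if (periodic) {
    idx <- ((idx - 1L) %% r[j]) + 1L
  } else {
    idx[idx < 1L | idx > r[j]] <- NA_integer_
  }
  args <- rep(list(quote(expr = )), d)
  args[[j]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

.minima_table <- function(fes, min0, labels, g) {
  r <- fes$resolution; d <- length(r)
  strides <- cumprod(c(1, r[-d]))
  gi <- matrix(0L, length(min0), d)
  for (j in seq_len(d)) gi[, j] <- ((min0 %/% strides[j]) %% r[j]) + 1L
  tab <- data.frame(label = labels, stringsAsFactors = FALSE)
  for (j in seq_len(d)) tab[[fes$cv$name[j]]] <- fes_nodes(fes, j)[gi[, j]]
  tab$depth <- as.numeric(fes$values)[min0 + 1]
  tab$g_population <- g
  attr(tab, "grid_index") <- gi
  rownames(tab) <- NULL
  tab
}

# population free energies of basins: g_m = -kT log P_m, shifted to min 0
.basin_g <- function(v, owner_idx, M, kT) {
  lw <- -v / kT
  tot <- logsumexp(lw)
  g <- vapply(seq_len(M), function(m) {
    -kT * (logsumexp(lw[owner_idx == m]) - tot)
  }, numeric(1))
  g - min(g)
}

#' Population-weighted free energies of basins
#'
#' Converts a free energy surface plus a basin assignment into one free
#' energy per metastable state: every grid node contributes a Boltzmann
#' probability proportional to exp(-F/kT), the probabilities are summed per
#' basin, and the sums are converted back to free energies
#' g_m = -kT log P_m, shifted so the most populated state sits at 0. Because
#' whole basins are integrated, the result accounts for both the depth and
#' the width of each minimum: a wide shallow basin can outrank a narrow deep
#' one. Computed with log-sum-exp stabilization.
#'
#' The surface may be a different (e.g. partial-simulation) reconstruction
#' on the same grid as the one that defined `minima` — that is how
#' [convergence_profile()] tracks states over time.
#'
#' @param fes a `"fes"` object on the same grid as `minima$fes`.
#' @param minima a precise-mode [find_minima()] object (supplies the basin
#'   assignment).
#' @param kT thermal energy, kJ/mol.
#' @return named numeric vector of free energies (kJ/mol), one per minimum
#'   in the label order of `minima`, minimum value 0.
#' @export
minima_free_energies <- function(fes, minima, kT = minima$kT) {
  stopifnot(inherits(fes, "fes"), inherits(minima, "fes_minima"))
  if (is.null(minima$owner))
    stop("basin assignment required: use a precise-mode find_minima() result")
  if (!identical(dim(minima$owner), dim(fes$values)))
    stop("fes grid does not match the minima's basin assignment")
  if (kT <= 0) stop("kT must be positive")
  g <- .basin_g(as.numeric(fes$values), as.vector(minima$owner),
                nrow(minima$minima), kT)
  setNames(g, minima$minima$label)
}

#' @export
print.fes_minima <- function(x, digits = 4, ...) {
  cat("Free-energy minima (", x$mode, " mode): ", nrow(x$minima),
      " found\n", sep = "")
  print(format(x$minima, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.fes_minima <- function(object, ...) {
  print(object)
  if (!is.null(object$owner)) {
    vol <- table(object$owner)
    cat("Basin volumes (grid nodes):\n")
    print(setNames(as.integer(vol), object$minima$label))
  }
  invisible(object)
}
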