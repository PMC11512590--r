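dw1 <- function(res = 256) {
  x <- seq(-2, 2, length.out = res)
  fes_grid((x^2 - 1)^2, "x", -2, 2)
}

fourwell <- function(res) {
  x <- seq(-2, 2, length.out = res)
  fes_grid(outer((x^2 - 1)^2, (x^2 - 1)^2, `+`), c("x", "y"),
           c(-2, -2), c(2, 2))
}

test_that("the 1D double well yields two minima near +/-1 with the boundary at 0", {
  f <- dw1(256)
  m <- find_minima(f)
  expect_equal(nrow(m$minima), 2)
  expect_equal(sort(m$minima$x), c(-1, 1), tolerance = 4 / 255 + 1e-9)
  sp <- 4 / 255
  bx <- fes_nodes(f, 1)[which(m$boundary)]
  expect_true(length(bx) >= 1)
  expect_lt(min(abs(bx)), sp + 1e-12)
  # every node is owned, and each minimum owns its own node
  expect_false(anyNA(m$owner))
  gi <- attr(m$minima, "grid_index")
  expect_equal(as.vector(m$owner[gi]), seq_len(2))
})

test_that("a single-well surface gives one basin covering everything", {
  x <- seq(-1, 1, length.out = 101)
  f <- fes_grid(x^2, "x", -1, 1)
  m <- find_minima(f)
  expect_equal(nrow(m$minima), 1)
  expect_identical(m$minima$label, "A")
  expect_true(all(m$owner == 1))
  expect_false(any(m$boundary))
  expect_equal(m$minima$g_population, 0)
})

test_that("a constant surface has no strict minima", {
  f <- fes_grid(matrix(1, 16, 16), c("x", "y"), c(0, 0), c(1, 1))
  expect_error(find_minima(f), "no strict minima")
})

test_that("the separable four-well surface has exactly 4 minima at (+/-1, +/-1)", {
  for (res in c(64, 128, 256)) {
    m <- find_minima(fourwell(res))
    expect_equal(nrow(m$minima), 4)
    sp <- 4 / (res - 1)
    pts <- as.matrix(m$minima[, c("x", "y")])
    expect_equal(sort(abs(pts[, 1])), rep(1, 4), tolerance = sp + 1e-9)
    expect_equal(sort(abs(pts[, 2])), rep(1, 4), tolerance = sp + 1e-9)
    # boundaries run along the x = 0 and y = 0 node lines
    bidx <- which(m$boundary, arr.ind = TRUE)
    bx <- fes_nodes(m$fes, 1)[bidx[, 1]]
    by <- fes_nodes(m$fes, 2)[bidx[, 2]]
    expect_true(all(pmin(abs(bx), abs(by)) < sp + 1e-12))
  }
})

test_that("basin volumes are stable in resolution on the four-well surface", {
  v128 <- tabulate(find_minima(fourwell(128))$owner, 4) / 128^2
  v256 <- tabulate(find_minima(fourwell(256))$owner, 4) / 256^2
  expect_true(all(abs(v128 - v256) / v256 < 0.02))
})

test_that("coarse grid mode finds one minimum per cell on the 64-well fixture", {
  f <- cellwise_wells_fes(256)
  m <- find_minima(f, mode = "grid")
  expect_equal(nrow(m$minima), 64)
  expect_equal(anyDuplicated(m$minima$label), 0)
  expect_identical(m$minima$label[1], "A")
  expect_identical(m$minima$label[64], "BL")
  expect_true(all(is.na(m$minima$g_population)))
})

test_that("grid mode on a monotone ramp returns at most the corner minimum", {
  x <- seq(0, 1, length.out = 64)
  f <- fes_grid(outer(x, x, `+`), c("x", "y"), c(0, 0), c(1, 1))
  m <- find_minima(f, mode = "grid")
  expect_lte(nrow(m$minima), 1)
  if (nrow(m$minima) == 1)
    expect_equal(unlist(m$minima[1, c("x", "y")]), c(x = 0, y = 0))
})

test_that("grid-mode minima are a subset of precise-mode minima", {
  set.seed(11)
  # smooth random surface: sum of a few broad Gaussians
  x <- seq(0, 1, length.out = 128)
  vals <- matrix(0, 128, 128)
  for (k in 1:12) {
    cx <- runif(1); cy <- runif(1); a <- runif(1, -4, 1)
    vals <- vals + a * exp(-(outer((x - cx)^2, (x - cy)^2, `+`)) / (2 * 0.08^2))
  }
  f <- fes_grid(vals, c("x", "y"), c(0, 0), c(1, 1))
  mp <- find_minima(f, mode = "precise")
  mg <- find_minima(f, mode = "grid")
  expect_lte(nrow(mg$minima), nrow(mp$minima))
  expect_lte(nrow(mg$minima), 64)
  keyp <- apply(attr(mp$minima, "grid_index"), 1, paste, collapse = ",")
  keyg <- apply(attr(mg$minima, "grid_index"), 1, paste, collapse = ",")
  expect_true(all(keyg %in% keyp))
})

test_that("mirror-symmetric basins get equal population free energies", {
  # even resolution: node set symmetric about 0, no node on the barrier top
  m <- find_minima(dw1(256))
  expect_equal(nrow(m$minima), 2)
  expect_equal(m$minima$g_population, c(0, 0), tolerance = 1e-10)
})

test_that("population free energies match a fine-quadrature Boltzmann oracle", {
  kt <- 2.494339
  # well centers deliberately off the lattice symmetry so both are strict
  # minima of the discretized surface
  surf <- function(x) {
    -10 * exp(-(x - 1.01)^2 / (2 * 0.12^2)) -
      8 * exp(-(x + 1.02)^2 / (2 * 0.35^2))
  }
  res <- 256
  x <- seq(-2.5, 2.5, length.out = res)
  f <- fes_grid(surf(x), "x", -2.5, 2.5)
  m <- find_minima(f, kT = kt)
  expect_equal(nrow(m$minima), 2)
  # oracle: quadrature at 10x resolution, basins split at the interior maximum
  F0 <- min(surf(x))
  xb <- optimize(function(x) -surf(x), c(-0.8, 0.8))$minimum
  qa <- integrate(function(x) exp(-(surf(x) - F0) / kt), -2.5, xb,
                  subdivisions = 2560L)$value
  qb <- integrate(function(x) exp(-(surf(x) - F0) / kt), xb, 2.5,
                  subdivisions = 2560L)$value
  dg_oracle <- -kt * log(min(qa, qb) / max(qa, qb))
  dg_est <- max(m$minima$g_population)
  # agreement within one grid-spacing quadrature error
  expect_equal(dg_est, dg_oracle, tolerance = 5 / (res - 1))
  # the wide shallow basin (depth 8, sigma 0.35) outranks the narrow deep
  # one (depth 10, sigma 0.12) at this temperature: width matters
  expect_equal(m$minima$x[1], -1.02, tolerance = 0.05)
})

test_that("at tiny kT the population free-energy gap approaches the depth gap", {
  surf <- function(x) {
    -6 * exp(-(x - 1)^2 / (2 * 0.2^2)) - 4 * exp(-(x + 1)^2 / (2 * 0.2^2))
  }
  x <- seq(-2.5, 2.5, length.out = 512)
  m <- find_minima(fes_grid(surf(x), "x", -2.5, 2.5), kT = 1e-4)
  expect_equal(max(m$minima$g_population),
               abs(diff(range(m$minima$depth))), tolerance = 0.01)
})

test_that("labels are deterministic: ascending g in precise mode, depth with grid-index ties in grid mode", {
  surf <- function(x) {
    -5 * exp(-(x - 1.01)^2 / (2 * 0.2^2)) - 7 * exp(-(x + 1.02)^2 / (2 * 0.2^2))
  }
  x <- seq(-2.5, 2.5, length.out = 255)
  m <- find_minima(fes_grid(surf(x), "x", -2.5, 2.5))
  expect_identical(m$minima$label, c("A", "B"))
  expect_lt(m$minima$x[1], 0)  # the deeper, more populated well is A
  expect_true(!is.unsorted(m$minima$g_population))
  # grid mode orders by depth with row-major index as the tie-breaker
  mg <- find_minima(cellwise_wells_fes(128), mode = "grid")
  gi <- attr(mg$minima, "grid_index")
  flat <- (gi[, 2] - 1) * 128 + gi[, 1]
  expect_equal(order(mg$minima$depth, flat), seq_len(64))
})

test_that("minima_free_energies validates grids and recomputes at any kT", {
  m <- find_minima(dw1(128), kT = 2.494339)
  g <- minima_free_energies(m$fes, m)
  expect_equal(unname(g), m$minima$g_population)
  g2 <- minima_free_energies(m$fes, m, kT = 1.0)
  expect_equal(min(g2), 0)
  other <- fes_grid(matrix(0, 64, 64), c("x", "y"), c(0, 0), c(1, 1))
  expect_error(minima_free_energies(other, m), "match")
  mg <- find_minima(dw1(128), mode = "grid")
  expect_error(minima_free_energies(dw1(128), mg), "precise")
})
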