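test_that("a single hill centered on a grid node gives F = -h there", {
  h <- make_hills(cbind(0), 0.1, 2.5)
  f <- fes(h, resolution = 201, method = "exact",
           range_lo = -1, range_hi = 1)
  nodes <- fes_nodes(f, 1)
  i0 <- which.min(abs(nodes))
  expect_equal(nodes[i0], 0)
  expect_equal(f$values[i0], -2.5)
  expect_true(all(f$values >= -2.5))
})

test_that("summation is linear: coincident hills add, slices add", {
  h1 <- make_hills(cbind(0.3), 0.1, 1.7)
  h2 <- make_hills(rbind(0.3, 0.3), 0.1, c(1.7, 1.7), times = c(1, 2))
  f1 <- fes(h1, 101, "exact", range_lo = -1, range_hi = 1)
  f2 <- fes(h2, 101, "exact", range_lo = -1, range_hi = 1)
  expect_equal(f2$values, 2 * f1$values)

  set.seed(42)
  n <- 60
  h <- make_hills(cbind(runif(n, -1, 1)), 0.15, runif(n, 0.5, 1.5),
                  times = seq_len(n))
  fa <- fes(slice_hills(h, 1, 25), 101, "exact", range_lo = -1.5,
            range_hi = 1.5)
  fb <- fes(slice_hills(h, 26, n), 101, "exact", range_lo = -1.5,
            range_hi = 1.5)
  fall <- fes(h, 101, "exact", range_lo = -1.5, range_hi = 1.5)
  expect_equal((fa + fb)$values, fall$values, tolerance = 1e-9)
})

test_that("periodic summation matches a brute-force explicit-image sum", {
  h <- make_hills(cbind(-pi + 0.01), 0.3, 1.0, periodic = TRUE,
                  lo = -pi, hi = pi)
  f <- fes(h, 128, "exact")
  nodes <- fes_nodes(f, 1)
  oracle <- -brute_gaussian_1d(nodes, -pi + 0.01, 0.3, 1.0, period = 2 * pi)
  expect_equal(as.numeric(f$values), oracle, tolerance = 1e-10)
  # the wrapped tail is visible near +pi
  expect_lt(f$values[length(nodes)], -0.9)
})

test_that("exact and fast paths are bit-identical under hill permutation", {
  set.seed(7)
  n <- 80
  h <- make_hills(cbind(runif(n, -pi, pi)), 0.25, runif(n, 0.5, 1.5),
                  times = seq_len(n), periodic = TRUE, lo = -pi, hi = pi)
  perm <- sample(n)
  hp <- h
  hp$times <- h$times[perm]
  hp$centers <- h$centers[perm, , drop = FALSE]
  hp$widths <- h$widths[perm, , drop = FALSE]
  hp$heights <- h$heights[perm]
  expect_identical(fes(h, 128, "exact")$values, fes(hp, 128, "exact")$values)
  hc <- h; hc$widths[] <- 0.25
  hpc <- hp; hpc$widths[] <- 0.25
  expect_identical(fes(hc, 128, "fast")$values, fes(hpc, 128, "fast")$values)
})

test_that("fast path approximates exact within 1% of the hill height", {
  h <- make_hills(cbind(0.123), 0.1, 2.0)
  fe <- fes(h, 256, "exact", range_lo = -1, range_hi = 1)
  ff <- fes(h, 256, "fast", range_lo = -1, range_hi = 1)
  expect_lt(max(abs(fe$values - ff$values)), 0.01 * 2.0)
})

test_that("fast path refuses non-constant widths with a pointer to exact", {
  h <- make_hills(cbind(c(0, 0.5)), c(0.1, 0.2), c(1, 1))
  expect_error(fes(h, 64, "fast"), "exact")
})

test_that("default grid ranges follow periodicity and hill spread", {
  hp <- make_hills(cbind(c(-1, 2)), 0.3, c(1, 1), periodic = TRUE,
                   lo = -pi, hi = pi)
  fp <- fes(hp, 64)
  expect_equal(fp$lo, -pi); expect_equal(fp$hi, pi)
  hn <- make_hills(cbind(c(-1, 2)), 0.2, c(1, 1))
  fn <- fes(hn, 64)
  expect_equal(fn$lo, -1 - 0.6); expect_equal(fn$hi, 2 + 0.6)
})

test_that("normalize zeroes the minimum, is idempotent and commutes with scaling", {
  f <- fes_grid(matrix(5, 8, 8), c("x", "y"), c(0, 0), c(1, 1))
  expect_true(all(fes_normalize(f)$values == 0))
  set.seed(1)
  g <- fes_grid(matrix(rnorm(64), 8), c("x", "y"), c(0, 0), c(1, 1))
  gn <- fes_normalize(g)
  expect_equal(min(gn$values), 0)
  expect_equal(fes_normalize(gn), gn)
  expect_equal(fes_normalize(fes_scale(g, 3.7))$values,
               fes_scale(gn, 3.7)$values, tolerance = 1e-12)
})

test_that("surface algebra: subtraction, unit conversion, mismatch errors", {
  set.seed(2)
  a <- fes_grid(matrix(rnorm(64), 8), c("x", "y"), c(0, 0), c(1, 1))
  z <- a - a
  expect_true(all(z$values == 0))
  kcal <- fes_scale(a, 0.239006, unit = "kcal/mol")
  expect_equal(kcal$values, a$values * 0.239006)
  expect_identical(kcal$unit, "kcal/mol")
  b <- fes_grid(matrix(rnorm(81), 9), c("x", "y"), c(0, 0), c(1, 1))
  expect_error(a + b, "resolution")
  b2 <- fes_grid(matrix(rnorm(64), 8), c("x", "y"), c(0, 0), c(2, 1))
  expect_error(a - b2, "hi")
})

test_that("marginalization collapses separable surfaces to their 1D part", {
  x <- seq(-2, 2, length.out = 65)
  y <- seq(-1, 1, length.out = 33)
  fx <- (x^2 - 1)^2
  gy <- 3 * y^2
  f2 <- fes_grid(outer(fx, gy, `+`), c("x", "y"), c(-2, -1), c(2, 1))
  m <- marginalize(f2, keep = 1, kT = 2.494339)
  f1n <- fes_normalize(fes_grid(fx, "x", -2, 2))
  expect_equal(as.numeric(m$values), as.numeric(f1n$values),
               tolerance = 1e-9)
  expect_equal(m$cv$name, "x")

  const <- fes_grid(matrix(4, 16, 16), c("x", "y"), c(0, 0), c(1, 1))
  mc <- marginalize(const, keep = 2)
  expect_true(all(abs(mc$values) < 1e-12))
})

test_that("marginalization at tiny kT approaches the minimum over removed dims", {
  set.seed(3)
  vals <- matrix(runif(32 * 24, 0, 10), 32, 24)
  f <- fes_grid(vals, c("x", "y"), c(0, 0), c(1, 1))
  m <- marginalize(f, keep = 1, kT = 1e-4)
  oracle <- apply(vals, 1, min)
  oracle <- oracle - min(oracle)
  expect_equal(as.numeric(m$values), oracle, tolerance = 1e-2)
})

test_that("marginalize validates its arguments", {
  f <- fes_grid(matrix(0, 8, 8), c("x", "y"), c(0, 0), c(1, 1))
  expect_error(marginalize(f, integer(0)), "subset")
  expect_error(marginalize(f, 1:2), "subset")
  expect_error(marginalize(f, 1, kT = 0), "positive")
})
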