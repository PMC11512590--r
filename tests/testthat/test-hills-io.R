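test_that("a 2D well-tempered header is parsed with periodicity from SET lines", {
  f <- withr::local_tempfile()
  writeLines(c(
    "#! FIELDS time phi psi sigma_phi sigma_psi height biasf",
    "#! SET min_phi -pi",
    "#! SET max_phi pi",
    "0.5  -3.0 1.0  0.3 0.3  1.2 10",
    "1.0   3.3 1.1  0.3 0.3  1.1 10"
  ), f)
  h <- read_hills(f)
  expect_identical(h$cv$name, c("phi", "psi"))
  expect_identical(h$cv$periodic, c(TRUE, FALSE))
  expect_equal(h$cv$lo[1], -pi)
  expect_equal(h$cv$hi[1], pi)
  expect_equal(length(h$times), 2)
  expect_equal(h$biasf, c(10, 10))
  # centers of periodic CVs canonically wrapped into [-pi, pi)
  expect_true(all(h$centers[, "phi"] >= -pi & h$centers[, "phi"] < pi))
  expect_equal(unname(h$centers[2, "phi"]), 3.3 - 2 * pi)
})

test_that("a minimal single-row 1D file parses without biasfactor", {
  f <- withr::local_tempfile()
  writeLines(c("#! FIELDS time cv1 sigma_cv1 height", "0.5 1.0 0.1 1.2"), f)
  h <- read_hills(f)
  expect_equal(length(h$times), 1)
  expect_equal(nrow(h$cv), 1)
  expect_equal(h$heights, 1.2)
  expect_null(h$biasf)
  expect_false(h$cv$periodic)
})

test_that("parsing tolerates repeated whitespace, tabs, blank lines and restarts", {
  f <- withr::local_tempfile()
  writeLines(c(
    "#! FIELDS time x sigma_x height",
    "0.5\t  1.0   0.1\t1.2",
    "",
    "#! FIELDS time x sigma_x height",  # restart header mid-file
    "1.0 1.5    0.1 1.1",
    "   "
  ), f)
  h <- read_hills(f)
  expect_equal(h$times, c(0.5, 1.0))
  expect_equal(h$centers[, 1], c(1.0, 1.5), ignore_attr = TRUE)
})

test_that("extra columns are ignored with a warning; restart time overlap is flagged", {
  f <- withr::local_tempfile()
  writeLines(c(
    "#! FIELDS time x sigma_x height extra_col",
    "0.5 1.0 0.1 1.2 99",
    "0.4 1.1 0.1 1.2 99"
  ), f)
  expect_warning(h <- read_hills(f), "extra_col")
  expect_equal(ncol(h$centers), 1)
  expect_true(any(grepl("non-increasing", h$warnings)))
})

test_that("malformed files raise the specified errors", {
  f <- withr::local_tempfile()
  writeLines(c("0.5 1.0 0.1 1.2"), f)
  expect_error(read_hills(f), "FIELDS")
  writeLines(c("#! FIELDS time x sigma_x height", "0.5 1.0 0.1"), f)
  expect_error(read_hills(f), "line 2")
  writeLines(c("#! FIELDS time x sigma_x height"), f)
  expect_error(read_hills(f), "no data rows")
  expect_error(read_hills(file.path(tempdir(), "no-such-file")), "not found")
})

test_that("read/write round-trip preserves every field; second write is byte-identical", {
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  f3 <- withr::local_tempfile()
  writeLines(c(
    "#! FIELDS time phi x sigma_phi sigma_x height biasf",
    "#! SET min_phi -pi",
    "#! SET max_phi pi",
    "0.5 -1.234 0.77 0.35 0.21 1.2 15",
    "1.0  2.345 0.91 0.35 0.21 1.15 15",
    "1.5  3.0   1.02 0.35 0.21 1.1 15"
  ), f1)
  h <- read_hills(f1)
  write_hills(h, f2)
  h2 <- read_hills(f2)
  for (field in c("times", "heights", "biasf"))
    expect_equal(h2[[field]], h[[field]])
  expect_equal(h2$centers, h$centers)
  expect_equal(h2$widths, h$widths)
  expect_equal(h2$cv, h$cv)
  write_hills(h2, f3)
  expect_identical(readLines(f3), readLines(f2))
})

test_that("writing a 1D non-periodic set emits the expected header", {
  h <- make_hills(cbind(c(0.5, 0.7)), 0.1, c(1, 1), cv_names = "d1")
  f <- withr::local_tempfile()
  write_hills(h, f)
  expect_identical(readLines(f)[1], "#! FIELDS time d1 sigma_d1 height")
})

test_that("writing an empty hills set is refused", {
  h <- make_hills(cbind(0.5), 0.1, 1)
  h$times <- numeric(0); h$heights <- numeric(0)
  h$centers <- h$centers[0, , drop = FALSE]
  h$widths <- h$widths[0, , drop = FALSE]
  expect_error(write_hills(h, withr::local_tempfile()), "0 hills")
})

test_that("slice_hills keeps contiguous subsets and all metadata", {
  h <- make_hills(cbind(seq(-1, 1, length.out = 10)), 0.1, rep(1, 10),
                  periodic = TRUE, lo = -pi, hi = pi)
  n <- length(h$times)
  expect_equal(slice_hills(h, 1, n), h)
  s1 <- slice_hills(h, 1, 1)
  expect_equal(length(s1$times), 1)
  expect_equal(s1$cv, h$cv)
  s2 <- slice_hills(h, 4, 7)
  expect_equal(s2$centers[, 1], h$centers[4:7, 1], ignore_attr = TRUE)
  expect_error(slice_hills(h, 0, 5), "out of bounds")
  expect_error(slice_hills(h, 5, 11), "out of bounds")
  expect_error(slice_hills(h, 7, 6), "out of bounds")
})
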