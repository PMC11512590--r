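#' Read a Plumed-format HILLS file
#'
#' Parses the whitespace-separated HILLS dialect written by Plumed during a
#' metadynamics run: a `#! FIELDS ...` header naming the columns, optional
#' `#! SET min_<cv>` / `#! SET max_<cv>` lines declaring periodic collective
#' variables, then one row per deposited Gaussian hill. Collective-variable
#' columns are recognised as those paired with a `sigma_<cv>` width column;
#' any other column besides `time`, `height` and `biasf` is ignored with a
#' warning. Header blocks repeated mid-file (simulation restarts) are
#' skipped and the data concatenated; rows whose time does not increase are
#' kept and flagged in the object's `warnings` field.
#'
#' The tokens `pi` and `-pi` in SET lines are converted to +/- pi at double
#' precision.
#'
#' @param path path to a HILLS text file.
#' @return An object of class `"hills"`: a list with `times` (ps), `centers`
#'   and `widths` (n x d matrices, CV units), `heights` (kJ/mol), `biasf`
#'   (bias factors, or `NULL` when the file has no `biasf` column), `cv`
#'   (data frame with columns `name`, `periodic`, `lo`, `hi`) and
#'   `warnings` (character vector of parse notes).
#' @seealso [write_hills()], [slice_hills()], [fes()]
#' @export
read_hills <- function(path) {
  if (!file.exists(path)) stop("HILLS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("empty HILLS file: ", path)
  first <- lines[nonblank[1]]
  if (!grepl("^#!\\s+FIELDS\\b", first))
    stop("not a HILLS file (first non-blank line must start with '#! FIELDS'): ",
         path)

  fields <- strsplit(trimws(first), "\\s+")[[1]][-(1:2)]
  set_min <- set_max <- list()
  data_rows <- list(); data_lineno <- integer()
  in_first_header <- TRUE
  for (i in nonblank) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "#!")) {
      tok <- strsplit(ln, "\\s+")[[1]]
      if (length(tok) >= 4 && tok[2] == "SET" && in_first_header) {
        key <- tok[3]
        val <- .parse_pi(tok[4])
        if (startsWith(key, "min_")) set_min[[substring(key, 5)]] <- val
        if (startsWith(key, "max_")) set_max[[substring(key, 5)]] <- val
      }
      # repeated '#!' blocks after data (restarts) are skipped silently
      next
    }
    if (startsWith(ln, "#")) next
    in_first_header <- FALSE
    data_rows[[length(data_rows) + 1L]] <- ln
    data_lineno[length(data_rows)] <- i
  }
  if (!length(data_rows)) stop("HILLS file contains no data rows: ", path)

  cv_names <- fields[paste0("sigma_", fields) %in% fields]
  if (!length(cv_names))
    stop("no collective-variable columns (none paired with a sigma_ column)")
  if (length(cv_names) > 3)
    stop("only 1-3 collective variables are supported, found ",
         length(cv_names))
  known <- c("time", "height", "biasf", cv_names, paste0("sigma_", cv_names))
  extra <- setdiff(fields, known)
  warns <- character()
  if (length(extra)) {
    warns <- c(warns, paste0("ignored column(s): ",
                             paste(extra, collapse = ", ")))
    warning("ignored HILLS column(s): ", paste(extra, collapse = ", "))
  }

  ncol_expect <- length(fields)
  vals <- lapply(seq_along(data_rows), function(r) {
    tok <- strsplit(data_rows[[r]], "\\s+")[[1]]
    if (length(tok) != ncol_expect)
      stop("line ", data_lineno[r], ": expected ", ncol_expect,
           " columns, found ", length(tok))
    suppressWarnings(as.numeric(tok))
  })
  mat <- do.call(rbind, vals)
  colnames(mat) <- fields
  if (anyNA(mat)) stop("non-numeric value in HILLS data rows")

  n <- nrow(mat)
  d <- length(cv_names)
  periodic <- vapply(cv_names,
                     function(nm) !is.null(set_min[[nm]]) && !is.null(set_max[[nm]]),
                     logical(1))
  lo <- vapply(cv_names, function(nm)
    if (periodic[nm]) set_min[[nm]] else NA_real_, numeric(1))
  hi <- vapply(cv_names, function(nm)
    if (periodic[nm]) set_max[[nm]] else NA_real_, numeric(1))
  if (any(periodic & !(hi > lo), na.rm = TRUE))
    stop("periodic CV with max <= min in SET header")

  centers <- mat[, cv_names, drop = FALSE]
  widths <- mat[, paste0("sigma_", cv_names), drop = FALSE]
  colnames(widths) <- cv_names
  if (any(widths <= 0)) stop("all hill widths must be strictly positive")
  # canonical wrap of periodic centers into [lo, hi)
  for (j in which(periodic)) {
    per <- hi[j] - lo[j]
    centers[, j] <- lo[j] + (centers[, j] - lo[j]) %% per
  }
  times <- mat[, "time"]
  if (is.unsorted(times)) {
    warns <- c(warns, "non-increasing time values (restart overlap?) kept as-is")
  }

  structure(list(
    times = unname(times),
    centers = centers,
    widths = widths,
    heights = unname(mat[, "height"]),
    biasf = if ("biasf" %in% fields) unname(mat[, "biasf"]) else NULL,
    cv = data.frame(name = cv_names, periodic = unname(periodic),
                    lo = unname(lo), hi = unname(hi),
                    stringsAsFactors = FALSE),
    warnings = warns
  ), class = "hills")
}

.parse_pi <- function(tok) {
  tok <- gsub("−", "-", tok)  # unicode minus
  if (tok == "pi") return(pi)
  if (tok == "-pi") return(-pi)
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v)) stop("cannot parse SET value: ", tok)
  v
}

.fmt_num <- function(x) formatC(x, digits = 9, format = "g", width = 16)

.fmt_bound <- function(x) {
  if (isTRUE(all.equal(x, pi, tolerance = 0))) return("pi")
  if (isTRUE(all.equal(x, -pi, tolerance = 0))) return("-pi")
  formatC(x, digits = 9, format = "g")
}

#' Write a Plumed-format HILLS file
#'
#' Emits the `#! FIELDS` header, `#! SET min_/max_` lines for periodic CVs
#' and fixed-width numeric rows (9 significant digits, enough to survive a
#' read/write round-trip at printed precision). Period bounds equal to
#' +/- pi are written as the `pi` / `-pi` tokens, as Plumed does.
#'
#' @param hills a [read_hills()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path) {
  stopifnot(inherits(hills, "hills"))
  if (!length(hills$times)) stop("refusing to write a hills set with 0 hills")
  cvn <- hills$cv$name
  fields <- c("time", cvn, paste0("sigma_", cvn), "height",
              if (!is.null(hills$biasf)) "biasf")
  out <- paste("#! FIELDS", paste(fields, collapse = " "))
  for (j in which(hills$cv$periodic)) {
    out <- c(out,
             paste("#! SET", paste0("min_", cvn[j]), .fmt_bound(hills$cv$lo[j])),
             paste("#! SET", paste0("max_", cvn[j]), .fmt_bound(hills$cv$hi[j])))
  }
  body <- cbind(hills$times, hills$centers, hills$widths, hills$heights,
                hills$biasf)
  rows <- apply(body, 1L, function(r) paste(.fmt_num(r), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(out, rows), con)
  invisible(path)
}

#' Contiguous subset of a hills set
#'
#' Keeps hills `first` through `last` (1-based, inclusive), preserving all
#' CV metadata. Used to build prefix subsets for convergence checkpoints.
#'
#' @param hills a `"hills"` object.
#' @param first,last 1-based inclusive range of hill indices.
#' @return a `"hills"` object with `last - first + 1` hills.
#' @export
slice_hills <- function(hills, first, last) {
  stopifnot(inherits(hills, "hills"))
  n <- length(hills$times)
  if (!(first >= 1 && first <= last && last <= n))
    stop("index range out of bounds: [", first, ", ", last, "] with n = ", n)
  idx <- first:last
  out <- hills
  out$times <- hills$times[idx]
  out$centers <- hills$centers[idx, , drop = FALSE]
  out$widths <- hills$widths[idx, , drop = FALSE]
  out$heights <- hills$heights[idx]
  if (!is.null(hills$biasf)) out$biasf <- hills$biasf[idx]
  out
}

#' @export
print.hills <- function(x, ...) {
  d <- nrow(x$cv)
  cat("Metadynamics hills: ", length(x$times), " hills, ", d,
      " collective variable", if (d > 1) "s", "\n", sep = "")
  for (j in seq_len(d)) {
    cat("  ", x$cv$name[j],
        if (x$cv$periodic[j])
          sprintf(": periodic on [%.6g, %.6g]", x$cv$lo[j], x$cv$hi[j])
        else ": non-periodic", "\n", sep = "")
  }
  cat(sprintf("  time %.6g .. %.6g ps; heights %.4g .. %.4g kJ/mol\n",
              min(x$times), max(x$times), min(x$heights), max(x$heights)))
  if (!is.null(x$biasf))
    cat("  well-tempered, bias factor ", format(x$biasf[1]), "\n", sep = "")
  if (length(x$warnings))
    cat("  notes: ", paste(x$warnings, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.hills <- function(object, ...) {
  print(object)
  cat("Per-CV hill centers:\n")
  print(summary(object$centers))
  invisible(object)
}
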