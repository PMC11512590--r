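#' Letter color for optimal readability on a colored background
#'
#' Relative luminance of the background color with Rec. 709 coefficients
#' (0.2126 R + 0.7152 G + 0.0722 B on 0-1 channels): below 0.5 the label is
#' drawn white, otherwise black (a luminance of exactly 0.5 gives black).
#'
#' @param col background color(s), any form [grDevices::col2rgb()] accepts.
#' @return character vector of `"white"` / `"black"`.
#' @export
letter_color <- function(col) {
  rgb <- grDevices::col2rgb(col) / 255
  lum <- 0.2126 * rgb[1, ] + 0.7152 * rgb[2, ] + 0.0722 * rgb[3, ]
  unname(ifelse(lum < 0.5, "white", "black"))
}

#' Plot a free energy surface
#'
#' 1D surfaces are drawn as a line with minima letters; 2D surfaces as a
#' filled color map with solid contours at selected isovalues, dotted basin
#' boundaries and minima letters whose color adapts to the background
#' luminance (see [letter_color()]). Axis labels default to the CV names
#' carried over from the HILLS header. Inputs are never modified.
#'
#' @param x a `"fes"` object.
#' @param minima optional [find_minima()] result to overlay letters (and,
#'   in precise mode, basin boundaries).
#' @param palette palette name passed to [grDevices::hcl.colors()]
#'   (default `"viridis"`).
#' @param ncolors number of fill colors (2D).
#' @param levels contour isovalues (2D); default every 10 energy units.
#' @param xlab,ylab axis labels (default: CV names / energy unit).
#' @param show_boundary draw the dotted basin-boundary nodes (2D).
#' @param letter_cex letter size for minima labels.
#' @param ... passed to the underlying base-graphics call.
#' @return `x`, invisibly.
#' @export
plot.fes <- function(x, minima = NULL, palette = "viridis", ncolors = 128,
                     levels = NULL, xlab = NULL, ylab = NULL,
                     show_boundary = TRUE, letter_cex = 1.2, ...) {
  d <- length(x$resolution)
  if (d > 2) stop("plotting supports 1 or 2 CVs; marginalize first")
  if (is.null(xlab)) xlab <- x$cv$name[1]
  if (d == 1) {
    if (is.null(ylab)) ylab <- paste0("free energy [", x$unit, "]")
    graphics::plot(fes_nodes(x, 1), x$values, type = "l", lwd = 2,
                   xlab = xlab, ylab = ylab, ...)
    if (!is.null(minima)) {
      graphics::text(minima$minima[[x$cv$name[1]]], minima$minima$depth,
                     labels = minima$minima$label, pos = 3, font = 2,
                     cex = letter_cex, col = "black")
    }
  } else {
    if (is.null(ylab)) ylab <- x$cv$name[2]
    cols <- grDevices::hcl.colors(ncolors, palette)
    zlim <- range(x$values)
    nx <- fes_nodes(x, 1); ny <- fes_nodes(x, 2)
    graphics::image(nx, ny, x$values, col = cols, zlim = zlim,
                    xlab = xlab, ylab = ylab, useRaster = TRUE, ...)
    if (is.null(levels))
      levels <- seq(ceiling(zlim[1] / 10) * 10, zlim[2], by = 10)
    if (length(levels))
      graphics::contour(nx, ny, x$values, levels = levels, add = TRUE,
                        drawlabels = FALSE, col = "grey30")
    if (!is.null(minima)) {
      if (show_boundary && !is.null(minima$boundary)) {
        bidx <- which(minima$boundary, arr.ind = TRUE)
        graphics::points(nx[bidx[, 1]], ny[bidx[, 2]], pch = ".",
                         col = "grey15")
      }
      mt <- minima$minima
      bg <- cols[pmax(1, ceiling((mt$depth - zlim[1]) / diff(zlim) * ncolors))]
      graphics::text(mt[[x$cv$name[1]]], mt[[x$cv$name[2]]],
                     labels = mt$label, font = 2, cex = letter_cex,
                     col = letter_color(bg))
    }
  }
  invisible(x)
}

#' @export
plot.fes_minima <- function(x, ...) {
  plot.fes(x$fes, minima = x, ...)
}

#' Render a free energy surface to an image file
#'
#' Thin wrapper around [plot.fes()] that writes a PNG, SVG or PDF file
#' (chosen from the file extension). Rendering is deterministic: two calls
#' with identical inputs produce identical files.
#'
#' @param fes a `"fes"` object.
#' @param file output path ending in `.png`, `.svg` or `.pdf`.
#' @param minima optional [find_minima()] overlay.
#' @param width,height device size in pixels (png) or inches (svg/pdf).
#' @param dpi raster resolution for png output.
#' @param ... passed to [plot.fes()].
#' @return `file`, invisibly.
#' @export
plot_fes <- function(fes, file, minima = NULL, width = NULL, height = NULL,
                     dpi = 150, ...) {
  ext <- tolower(sub(".*\\.", "", basename(file)))
  switch(ext,
    png = grDevices::png(file, width = width %||% 1200,
                         height = height %||% 900, res = dpi,
                         type = "cairo"),
    svg = grDevices::svg(file, width = width %||% 8, height = height %||% 6),
    pdf = grDevices::pdf(file, width = width %||% 8, height = height %||% 6),
    stop("unsupported image format: .", ext))
  on.exit(grDevices::dev.off())
  plot.fes(fes, minima = minima, ...)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a free energy surface as a plain-text grid
#'
#' Header lines carry the CV names, periodicity, grid range, resolution and
#' energy unit; then one `coord... value` row per node, last dimension
#' fastest, values at 9 significant digits (enough for a lossless
#' export/import round-trip at printed precision).
#'
#' @param fes a `"fes"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [import_fes()]
#' @export
export_fes <- function(fes, path) {
  stopifnot(inherits(fes, "fes"))
  d <- length(fes$resolution)
  hdr <- c("# metafes free energy surface grid",
           paste("# cvs:", paste(fes$cv$name, collapse = " ")),
           paste("# periodic:", paste(as.integer(fes$cv$periodic),
                                      collapse = " ")),
           paste("# lo:", paste(formatC(fes$lo, digits = 17, format = "g"),
                                collapse = " ")),
           paste("# hi:", paste(formatC(fes$hi, digits = 17, format = "g"),
                                collapse = " ")),
           paste("# resolution:", paste(fes$resolution, collapse = " ")),
           paste("# unit:", fes$unit))
  nodes <- lapply(seq_len(d), function(j) fes_nodes(fes, j))
  # row order: last dimension fastest
  grid <- do.call(expand.grid, rev(nodes))[, rev(seq_len(d)), drop = FALSE]
  vals <- as.vector(aperm(fes$values, rev(seq_len(d))))
  rows <- cbind(as.matrix(grid), vals)
  lines <- apply(rows, 1L, function(r)
    paste(formatC(r, digits = 9, format = "g", width = 16), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, lines), con)
  invisible(path)
}

#' Import a free energy surface from a plain-text grid
#'
#' @param path a file written by [export_fes()].
#' @return a `"fes"` object.
#' @export
import_fes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("malformed FES grid file (missing header): ", path)
  hdr <- lines[startsWith(lines, "#")]
  get_field <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("malformed FES grid header: missing '", key, "'")
    strsplit(trimws(sub(paste0("^#\\s*", key, ":"), "", ln[1])), "\\s+")[[1]]
  }
  cvs <- get_field("cvs")
  periodic <- as.integer(get_field("periodic")) == 1L
  lo <- as.numeric(get_field("lo"))
  hi <- as.numeric(get_field("hi"))
  res <- as.integer(get_field("resolution"))
  unit <- paste(get_field("unit"), collapse = " ")
  d <- length(cvs)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) != prod(res))
    stop("malformed FES grid file: expected ", prod(res), " data rows, found ",
         length(body))
  vals <- vapply(strsplit(trimws(body), "\\s+"), function(tok) {
    if (length(tok) != d + 1) stop("malformed FES grid row")
    as.numeric(tok[d + 1])
  }, numeric(1))
  if (anyNA(vals)) stop("non-numeric value in FES grid file")
  # rows were written last-dimension-fastest
  a <- array(vals, dim = rev(res))
  a <- aperm(a, rev(seq_len(d)))
  fes_grid(a, cv_names = cvs, lo = lo, hi = hi, periodic = periodic,
           unit = unit)
}

#' Plot hill heights or CV trajectories from a hills set
#'
#' @param x a `"hills"` object.
#' @param what `"heights"` (hill heights vs time) or `"cv"` (CV values vs
#'   time, one panel per CV).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.hills <- function(x, what = c("heights", "cv"), ...) {
  what <- match.arg(what)
  if (what == "heights") {
    hs <- heights_series(x)
    graphics::plot(hs$time, hs$height, type = "l", xlab = "time [ps]",
                   ylab = "hill height [kJ/mol]", ...)
  } else {
    cs <- cv_series(x)
    d <- ncol(cs) - 1L
    old <- graphics::par(mfrow = c(d, 1))
    on.exit(graphics::par(old))
    for (j in seq_len(d)) {
      graphics::plot(cs$time, cs[[j + 1L]], type = "l", xlab = "time [ps]",
                     ylab = names(cs)[j + 1L], ...)
    }
  }
  invisible(x)
}
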