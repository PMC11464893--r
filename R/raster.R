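#' Lightweight single-band grid raster
#'
#' A minimal in-memory raster: a numeric matrix on a regular square grid
#' with an origin and pixel size in metres. Row 1 is the northern (top)
#' edge, column 1 the western edge, so the matrix prints the way the map
#' looks. All spatial products in this package are built on this type;
#' persistent output uses the plain-text ESRI ASCII grid format
#' (\code{\link{write_asc}}), which any GIS can ingest.
#'
#' @param values numeric matrix (row 1 = north).
#' @param xmin,ymin coordinates of the lower-left corner (m).
#' @param res pixel edge length (m); must be > 0.
#' @return an object of class \code{grid_raster}.
#' @export
grid_raster <- function(values, xmin = 0, ymin = 0, res = 30) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(res), length(res) == 1L, res > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, res = res),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<grid_raster> %d x %d pixels, res %g m, origin (%g, %g)\n",
    d[1], d[2], x$res, x$xmin, x$ymin
  ))
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat(sprintf("  values: min %.4g, median %.4g, max %.4g, NA %d\n",
                min(v), stats::median(v), max(v), sum(!is.finite(x$values))))
  }
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Pixel-centre coordinates of a grid raster
#'
#' @param r a \code{grid_raster}.
#' @return data.frame with columns \code{row}, \code{col}, \code{x}, \code{y}
#'   in matrix order (column-major).
#' @export
raster_coords <- function(r) {
  d <- dim(r$values)
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  data.frame(
    row = rows, col = cols,
    x = r$xmin + (cols - 0.5) * r$res,
    y = r$ymin + (d[1] - rows + 0.5) * r$res
  )
}

#' Row/column of the pixel containing each point
#'
#' Points on the outer boundary are snapped inward so that the full extent
#' is usable; points outside the extent yield NA.
#'
#' @param r a \code{grid_raster}.
#' @param x,y point coordinates (m).
#' @return data.frame with columns \code{row}, \code{col} (NA off-raster).
#' @export
cell_of <- function(r, x, y) {
  d <- dim(r$values)
  xmax <- r$xmin + d[2] * r$res
  ymax <- r$ymin + d[1] * r$res
  col <- floor((x - r$xmin) / r$res) + 1
  row <- d[1] - floor((y - r$ymin) / r$res)
  col[x == xmax] <- d[2]
  row[y == ymax] <- 1
  bad <- x < r$xmin | x > xmax | y < r$ymin | y > ymax
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations (nearest pixel)
#'
#' @inheritParams cell_of
#' @return numeric vector, NA for points off the raster.
#' @export
extract_at <- function(r, x, y) {
  rc <- cell_of(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- r$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster interchange. \code{NODATA_value} encodes NA.
#'
#' @param r a \code{grid_raster}.
#' @param path file path.
#' @param digits significant digits written.
#' @return \code{write_asc} returns \code{path} invisibly;
#'   \code{read_asc} returns a \code{grid_raster}.
#' @export
write_asc <- function(r, path, digits = 7) {
  d <- dim(r$values)
  v <- r$values
  v[!is.finite(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.6f", r$xmin),
    sprintf("yllcorner %.6f", r$ymin),
    sprintf("cellsize %.6f", r$res),
    "NODATA_value -9999"
  ), con)
  utils::write.table(signif(v, digits), con,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1])
  val <- as.numeric(kv[, 2])
  names(val) <- key
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  m[m == val[["nodata_value"]]] <- NA_real_
  stopifnot(nrow(m) == val[["nrows"]], ncol(m) == val[["ncols"]])
  grid_raster(m, xmin = val[["xllcorner"]], ymin = val[["yllcorner"]],
              res = val[["cellsize"]])
}

#' Global Moran's I of a raster band
#'
#' Rook (4-neighbour) contiguity, used to verify that generated fields
#' carry the intended spatial autocorrelation.
#'
#' @param m numeric matrix or \code{grid_raster}.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(m) {
  if (inherits(m, "grid_raster")) m <- m$values
  z <- m - mean(m)
  num <- sum(z[-1, ] * z[-nrow(z), ]) + sum(z[, -1] * z[, -ncol(z)])
  w <- (nrow(z) - 1) * ncol(z) + nrow(z) * (ncol(z) - 1) # each pair once
  n <- length(z)
  (n / (2 * w)) * (2 * num) / sum(z^2)
}
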