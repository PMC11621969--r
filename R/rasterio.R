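# Minimal in-memory raster container plus ESRI ASCII grid I/O. No raster
# package is assumed; the format is a plain-text header followed by rows of
# values from the top (north) row down.

#' Construct a raster layer
#'
#' @param values Numeric matrix, `values[i, j]` = row i from the *south*
#'   (so increasing row index is increasing latitude), column j from the
#'   west.
#' @param xll,yll Lower-left corner of the grid (degrees).
#' @param cell Cell size (degrees, square cells).
#' @param nodata Value marking missing cells (default -9999).
#' @return Object of class `flyway_raster`.
#' @export
flyway_raster <- function(values, xll, yll, cell, nodata = -9999) {
  stopifnot(is.matrix(values), cell > 0)
  structure(list(values = values, xll = xll, yll = yll, cell = cell,
                 nrow = nrow(values), ncol = ncol(values), nodata = nodata),
            class = "flyway_raster")
}

#' @export
print.flyway_raster <- function(x, ...) {
  cat(sprintf("flyway_raster: %d x %d cells of %g deg, origin (%g, %g)\n",
              x$nrow, x$ncol, x$cell, x$xll, x$yll))
  invisible(x)
}

#' Cell-centre coordinates of a raster
#' @param r A `flyway_raster`.
#' @return Data.frame `lon`, `lat`, `value` in column-major cell order.
#' @export
raster_cells <- function(r) {
  lon <- r$xll + (rep(seq_len(r$ncol), each = r$nrow) - 0.5) * r$cell
  lat <- r$yll + (rep(seq_len(r$nrow), times = r$ncol) - 0.5) * r$cell
  v <- as.vector(r$values)
  v[!is.na(v) & v == r$nodata] <- NA
  data.frame(lon = lon, lat = lat, value = v)
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param r A `flyway_raster`.
#' @param path Output file (.asc).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", r$ncol),
               sprintf("nrows %d", r$nrow),
               sprintf("xllcorner %.10g", r$xll),
               sprintf("yllcorner %.10g", r$yll),
               sprintf("cellsize %.10g", r$cell),
               sprintf("NODATA_value %.10g", r$nodata)), con)
  vals <- r$values
  vals[is.na(vals)] <- r$nodata
  # file rows run north to south
  for (i in rev(seq_len(r$nrow))) {
    writeLines(paste(format(vals[i, ], trim = TRUE, digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Input file.
#' @return A `flyway_raster`. `xllcenter`/`yllcenter` headers are converted
#'   to corner convention.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  ncol <- as.integer(hdr$ncols); nrow <- as.integer(hdr$nrows)
  cell <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cell / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cell / 2
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nrow * ncol) stop("raster body does not match header dimensions")
  m <- matrix(vals, nrow = nrow, ncol = ncol, byrow = TRUE)
  m <- m[rev(seq_len(nrow)), , drop = FALSE]  # back to south-up storage
  m[m == nodata] <- NA
  flyway_raster(m, xll = xll, yll = yll, cell = cell, nodata = nodata)
}
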