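#' Rectangular resistance / suitability raster
#'
#' A minimal in-memory grid: values stored as a matrix whose first row is
#' the TOP row of the map (ESRI ASCII order), with cell size in km and the
#' x/y of the lower-left corner. Resistance values must be strictly
#' positive where not nodata.
#'
#' @param values numeric matrix (row 1 = top of map).
#' @param cell_size cell edge length, km.
#' @param origin numeric length-2, (x, y) of the lower-left corner.
#' @param nodata logical matrix of the same shape, or NULL.
#' @param positive enforce strictly positive values (the resistance-surface
#'   invariant). General surfaces, e.g. interpolated residuals, may be
#'   negative and set this to FALSE.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size, origin = c(0, 0), nodata = NULL,
                        positive = TRUE) {
  values <- as.matrix(values)
  if (is.null(nodata)) nodata <- is.na(values)
  nodata <- nodata | is.na(values)
  if (!identical(dim(nodata), dim(values))) stop("nodata shape mismatch")
  if (positive && any(values[!nodata] <= 0))
    stop("raster values must be strictly positive where not nodata")
  stopifnot(length(origin) == 2, cell_size > 0)
  structure(list(values = values, n_rows = nrow(values), n_cols = ncol(values),
                 cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), nodata = nodata),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells of %.3g km, origin (%.3g, %.3g), %d nodata\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2],
              sum(x$nodata)))
  invisible(x)
}

# centers of all cells, row-major from the top-left cell
raster_cell_centers <- function(r) {
  xs <- r$origin[1] + (seq_len(r$n_cols) - 0.5) * r$cell_size
  ys <- r$origin[2] + (r$n_rows - seq_len(r$n_rows) + 0.5) * r$cell_size
  list(x = xs, y = ys)
}

# map planar points to (row, col); errors if off-grid
raster_locate <- function(r, x, y) {
  col <- floor((x - r$origin[1]) / r$cell_size) + 1L
  row <- r$n_rows - floor((y - r$origin[2]) / r$cell_size)
  off <- col < 1L | col > r$n_cols | row < 1L | row > r$n_rows
  if (any(off))
    stop(sprintf("point(s) off-grid: %s",
                 paste(sprintf("(%.3g, %.3g)", x[off], y[off]), collapse = ", ")))
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read an ESRI ASCII grid
#'
#' Header keys `ncols nrows xllcorner yllcorner cellsize NODATA_value`
#' followed by the values, top row first.
#'
#' @param path file path.
#' @return a [raster_grid()].
#' @export
read_raster_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- list(); i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing ASCII grid header keys: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop(sprintf("grid body has %d values, header promises %d x %d = %d",
                 length(vals), nr, nc, nr * nc))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- matrix(FALSE, nr, nc)
  if (!is.null(hdr$nodata_value)) {
    nodata <- m == hdr$nodata_value
    m[nodata] <- NA
  }
  # any surface may be stored in a grid file; resistance users validate
  # positivity at the point of use
  raster_grid(m, hdr$cellsize, c(hdr$xllcorner, hdr$yllcorner), nodata,
              positive = FALSE)
}

#' Write an ESRI ASCII grid
#' @param r a [raster_grid()].
#' @param path output file.
#' @param nodata_value numeric marker written for nodata cells.
#' @return `path`, invisibly.
#' @export
write_raster_grid <- function(r, path, nodata_value = -9999) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("ncols %d", r$n_cols),
               sprintf("nrows %d", r$n_rows),
               sprintf("xllcorner %.10g", r$origin[1]),
               sprintf("yllcorner %.10g", r$origin[2]),
               sprintf("cellsize %.10g", r$cell_size),
               sprintf("NODATA_value %.10g", nodata_value)), con)
  m <- r$values
  m[r$nodata] <- nodata_value
  utils::write.table(format(m, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Invert a habitat-suitability raster into a resistance surface
#'
#' resistance = 1 / max(suitability, floor); the floor keeps resistance
#' finite where predicted suitability approaches zero.
#'
#' @param r a [raster_grid()] of suitabilities in (0, 1].
#' @param floor minimum suitability before inversion.
#' @return a [raster_grid()] of resistances.
#' @export
suitability_to_resistance <- function(r, floor = 0.01) {
  stopifnot(inherits(r, "raster_grid"), floor > 0)
  v <- pmax(r$values, floor)
  v[r$nodata] <- NA
  raster_grid(v^-1, r$cell_size, r$origin, r$nodata)
}
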