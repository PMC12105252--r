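#' Gridded raster layer
#'
#' Lightweight single-band raster: a numeric matrix with row 1 at the northern
#' edge, an affine georeference given by the lower-left corner and a square
#' cell size, a CRS label (projected map units assumed) and a nodata sentinel.
#' Cell registration is cell-centre: the centre of cell (row, col) lies at
#' `xmin + (col - 0.5) * cellsize`, `ymin + (nrow - row + 0.5) * cellsize`.
#'
#' @param values numeric matrix (row 1 = north).
#' @param xmin,ymin coordinates of the lower-left corner of the grid.
#' @param cellsize side of a (square) cell in map units.
#' @param crs CRS label; purely informative, a projected CRS is assumed.
#' @param nodata sentinel written on export; internally missing cells are `NA`.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, xmin = 0, ymin = 0, cellsize = 1,
                        crs = "local-projected", nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid_raster: grid dimensions must be positive")
  if (!is.finite(cellsize) || cellsize <= 0)
    stop("grid_raster: cellsize must be > 0")
  structure(
    list(values = values, xmin = xmin, ymin = ymin,
         cellsize = cellsize, crs = crs, nodata = nodata),
    class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("grid_raster: %d x %d cells, cellsize %g (%s)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$crs))
  cat(sprintf("  extent: x [%g, %g]  y [%g, %g]\n",
              x$xmin, x$xmin + ncol(x$values) * x$cellsize,
              x$ymin, x$ymin + nrow(x$values) * x$cellsize))
  if (length(v))
    cat(sprintf("  values: min %.4g  mean %.4g  max %.4g  (%d valid cells)\n",
                min(v), mean(v), max(v), length(v)))
  else cat("  values: all missing\n")
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Raster values as a vector or matrix
#' @param r a `grid_raster`.
#' @param matrix return the matrix (default) or a plain vector.
#' @return numeric matrix or vector; missing cells are `NA`.
#' @export
rast_values <- function(r, matrix = TRUE) {
  stopifnot(inherits(r, "grid_raster"))
  if (matrix) r$values else as.vector(r$values)
}

#' Replace values keeping the georeference
#' @param r template `grid_raster`.
#' @param values matrix or vector of the same total length.
#' @return new `grid_raster`.
#' @export
rast_like <- function(r, values) {
  stopifnot(inherits(r, "grid_raster"))
  m <- matrix(as.double(values), nrow = nrow(r$values), ncol = ncol(r$values))
  grid_raster(m, r$xmin, r$ymin, r$cellsize, r$crs, r$nodata)
}

#' Check two rasters share grid geometry
#' @param a,b `grid_raster`s.
#' @param tol tolerance on origin/cellsize comparison.
#' @export
same_grid <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

stop_if_misaligned <- function(a, b, what = "rasters") {
  if (!same_grid(a, b)) stop(sprintf("%s are not on the same grid", what))
  invisible(TRUE)
}

#' Coordinates of cell centres
#' @param r a `grid_raster`.
#' @param cells optional vector of cell indices (column-major, as R matrices).
#' @return two-column matrix (x, y).
#' @export
cell_centers <- function(r, cells = NULL) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  if (is.null(cells)) cells <- seq_len(nr * nc)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  cbind(x = r$xmin + (col - 0.5) * r$cellsize,
        y = r$ymin + (nr - row + 0.5) * r$cellsize)
}

#' Cell index containing each point
#' @param r a `grid_raster`.
#' @param x,y point coordinates in map units.
#' @param strict error (rather than NA) for points outside the extent.
#' @return integer cell indices (column-major).
#' @export
cell_from_xy <- function(r, x, y, strict = TRUE) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((x - r$xmin) / r$cellsize) + 1L
  row <- nr - floor((y - r$ymin) / r$cellsize)
  # points sitting exactly on the top/right edge belong to the edge cell
  col[x == r$xmin + nc * r$cellsize] <- nc
  row[y == r$ymin + nr * r$cellsize] <- 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr | !is.finite(x) | !is.finite(y)
  if (any(bad)) {
    if (strict)
      stop(sprintf("points outside raster extent at indices: %s",
                   paste(which(bad), collapse = ", ")))
    col[bad] <- NA_integer_; row[bad] <- NA_integer_
  }
  as.integer((col - 1L) * nr + row)
}

# ---- stacks -----------------------------------------------------------------

#' Multi-layer raster stack
#'
#' A named list of `grid_raster` layers sharing one grid.
#' @param ... named `grid_raster` layers, or a single (named) list of them.
#' @return object of class `raster_stack`.
#' @export
raster_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1L]], "grid_raster"))
    layers <- layers[[1L]]
  if (!length(layers)) stop("raster_stack: no layers")
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- paste0("layer", seq_along(layers))
  for (l in layers) stopifnot(inherits(l, "grid_raster"))
  for (l in layers[-1L]) stop_if_misaligned(layers[[1L]], l, "stack layers")
  structure(layers, class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack: %d layers [%s], %d x %d cells\n", length(x),
              paste(names(x), collapse = ", "),
              nrow(x[[1L]]$values), ncol(x[[1L]]$values)))
  invisible(x)
}

#' Stack values as a cells-by-layers matrix
#' @param stack a `raster_stack`.
#' @return numeric matrix, one column per layer (column-major cell order).
#' @export
stack_matrix <- function(stack) {
  stopifnot(inherits(stack, "raster_stack"))
  n <- length(stack[[1L]]$values)
  m <- vapply(stack, function(l) as.vector(l$values), numeric(n))
  if (is.null(dim(m))) m <- matrix(m, nrow = n, dimnames = list(NULL, names(stack)))
  m
}

# ---- text raster I/O --------------------------------------------------------

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text, GDAL-readable format; values are written at full double
#' precision so a write/read round trip is exact.
#' @param r a `grid_raster`.
#' @param path output file path (conventionally `.asc`).
#' @export
write_ascii_grid <- function(r, path) {
  stopifnot(inherits(r, "grid_raster"))
  v <- r$values
  v[!is.finite(v)] <- r$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", ncol(v)),
    sprintf("NROWS %d", nrow(v)),
    sprintf("XLLCORNER %.17g", r$xmin),
    sprintf("YLLCORNER %.17g", r$ymin),
    sprintf("CELLSIZE %.17g", r$cellsize),
    sprintf("NODATA_VALUE %.17g", r$nodata)), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(sprintf("%.17g", v[i, ]), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file path.
#' @param crs CRS label to attach.
#' @return a `grid_raster`; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path, crs = "local-projected") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[toupper(parts[1L])]] <- as.numeric(parts[2L])
    i <- i + 1L
  }
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE")
  if (!all(need %in% names(hdr)))
    stop("read_ascii_grid: malformed header in ", path)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$NROWS, ncol = hdr$NCOLS, byrow = TRUE)
  nodata <- if (!is.null(hdr$NODATA_VALUE)) hdr$NODATA_VALUE else -9999
  m[m == nodata] <- NA_real_
  grid_raster(m, hdr$XLLCORNER, hdr$YLLCORNER, hdr$CELLSIZE, crs, nodata)
}

# ---- occurrences ------------------------------------------------------------

#' Point occurrence records
#' @param x,y coordinates in map units.
#' @param species species label (recycled).
#' @return data.frame of class `occurrence_set` with columns x, y, species.
#' @export
occurrence_set <- function(x, y, species = "sp") {
  stopifnot(length(x) == length(y))
  structure(data.frame(x = as.double(x), y = as.double(y),
                       species = rep_len(as.character(species), length(x)),
                       stringsAsFactors = FALSE),
            class = c("occurrence_set", "data.frame"))
}

#' Read/write occurrence CSV (columns x, y, species)
#' @param path CSV path.
#' @export
read_occurrences <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y", "species") %in% names(d)))
    stop("occurrence CSV must have columns x, y, species")
  occurrence_set(d$x, d$y, d$species)
}

#' @rdname read_occurrences
#' @param occ an `occurrence_set`.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}

#' Thin occurrences to one point per grid cell per species
#'
#' Retention is deterministic: points are ordered by (x, y) with a stable sort
#' and the first point in each occupied cell is kept.
#' @param occ an `occurrence_set`.
#' @param grid a `grid_raster` defining the cell tessellation.
#' @return thinned `occurrence_set`.
#' @export
thin_occurrences <- function(occ, grid) {
  stopifnot(inherits(grid, "grid_raster"))
  if (!nrow(occ)) return(occ)
  ord <- order(occ$x, occ$y, method = "radix")
  occ <- occ[ord, , drop = FALSE]
  cell <- cell_from_xy(grid, occ$x, occ$y)
  keep <- !duplicated(data.frame(cell = cell, species = occ$species))
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("occurrence_set", "data.frame"))
}

#' Extract stack values at points
#'
#' @param stack a `raster_stack`.
#' @param occ an `occurrence_set` (or data.frame with x, y).
#' @return data.frame: x, y, one column per layer, plus a logical `missing`
#'   column flagging rows that hit a nodata cell in any layer. Points outside
#'   the extent raise an error naming the offending rows.
#' @export
extract_at_points <- function(stack, occ) {
  stopifnot(inherits(stack, "raster_stack"))
  cells <- cell_from_xy(stack[[1L]], occ$x, occ$y, strict = TRUE)
  vals <- stack_matrix(stack)[cells, , drop = FALSE]
  colnames(vals) <- names(stack)
  out <- data.frame(x = occ$x, y = occ$y, vals, check.names = FALSE)
  out$missing <- apply(is.na(vals), 1L, any)
  out
}
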