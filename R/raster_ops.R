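#' Slope and aspect from a DEM (Horn's method)
#'
#' 3x3 Horn finite differences on a projected-CRS DEM. Slope is returned in
#' degrees (0-90); aspect is the downslope direction in degrees clockwise from
#' north, in [0, 360). Flat cells (zero gradient) get `NA` aspect. Edge cells
#' are handled by nearest-neighbour padding of the DEM.
#'
#' @param dem single-band `grid_raster` with elevation in the same linear
#'   units as the map coordinates.
#' @return list with `slope` and `aspect` rasters.
#' @export
slope_aspect <- function(dem) {
  stopifnot(inherits(dem, "grid_raster"))
  if (grepl("^(epsg:4326|longlat|geographic)$", tolower(dem$crs)))
    stop("slope_aspect: geographic (degree-unit) CRS needs a projected DEM")
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  # nearest-neighbour pad
  zp <- z[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  idx <- function(dr, dc) zp[seq_len(nr) + 1L + dr, seq_len(nc) + 1L + dc]
  a <- idx(-1L, -1L); b <- idx(-1L, 0L); cc <- idx(-1L, 1L)
  d <- idx(0L, -1L);                     f <- idx(0L, 1L)
  g <- idx(1L, -1L); h <- idx(1L, 0L);  i <- idx(1L, 1L)
  cs <- dem$cellsize
  gx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)   # east-positive
  gy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cs)   # north-positive
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
  aspect[gx == 0 & gy == 0] <- NA_real_
  aspect[is.na(slope)] <- NA_real_
  list(slope = rast_like(dem, slope), aspect = rast_like(dem, aspect))
}

#' Euclidean distance to the nearest feature cell
#'
#' Distances are measured cell centre to cell centre in map units; cells in
#' the feature mask get distance 0. Exact nearest-feature search, computed in
#' row chunks to bound memory.
#'
#' @param mask `grid_raster`: nonzero/TRUE cells are features.
#' @param grid optional template raster (defaults to the mask's grid).
#' @return `grid_raster` of distances.
#' @export
euclidean_distance <- function(mask, grid = NULL) {
  stopifnot(inherits(mask, "grid_raster"))
  if (is.null(grid)) grid <- mask else stop_if_misaligned(mask, grid)
  feat <- which(is.finite(mask$values) & mask$values != 0)
  if (!length(feat)) stop("euclidean_distance: empty feature mask")
  fxy <- cell_centers(mask, feat)
  n <- length(mask$values)
  out <- numeric(n)
  chunk <- max(1L, floor(4e6 / length(feat)))
  for (s in seq(1L, n, by = chunk)) {
    cells <- s:min(s + chunk - 1L, n)
    cxy <- cell_centers(mask, cells)
    d2 <- outer(cxy[, 1L], fxy[, 1L], "-")^2 + outer(cxy[, 2L], fxy[, 2L], "-")^2
    out[cells] <- sqrt(do.call(pmin, c(as.data.frame(d2), list(na.rm = FALSE))))
  }
  out[feat] <- 0
  rast_like(grid, out)
}

#' Resample a raster to a new cell size
#'
#' Output grid shares the lower-left corner; extent is covered by
#' `ceiling(extent / target_cell)` cells. `bilinear` interpolates between the
#' four enclosing cell centres (edge-clamped); `nearest` picks the containing
#' source cell and is the right choice for categorical layers.
#'
#' @param r a `grid_raster`.
#' @param target_cell output cell size (map units, > 0).
#' @param method "bilinear" or "nearest".
#' @return resampled `grid_raster`.
#' @export
resample_raster <- function(r, target_cell, method = c("bilinear", "nearest")) {
  stopifnot(inherits(r, "grid_raster"))
  if (!is.numeric(target_cell) || target_cell <= 0)
    stop("resample_raster: target_cell must be > 0")
  method <- match.arg(method)
  nr <- nrow(r$values); nc <- ncol(r$values)
  if (isTRUE(all.equal(target_cell, r$cellsize))) return(r)
  out_nc <- as.integer(ceiling(nc * r$cellsize / target_cell))
  out_nr <- as.integer(ceiling(nr * r$cellsize / target_cell))
  tmpl <- grid_raster(matrix(0, out_nr, out_nc), r$xmin, r$ymin,
                      target_cell, r$crs, r$nodata)
  xy <- cell_centers(tmpl)
  vals <- interpolate_at_xy(r, xy[, 1L], xy[, 2L], method)
  rast_like(tmpl, vals)
}

# bilinear / nearest interpolation at arbitrary coordinates (edge clamped)
interpolate_at_xy <- function(r, x, y, method = "bilinear") {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cellsize
  if (method == "nearest") {
    cells <- cell_from_xy(r, pmin(pmax(x, r$xmin), r$xmin + nc * cs),
                          pmin(pmax(y, r$ymin), r$ymin + nr * cs))
    return(r$values[cells])
  }
  # fractional position in units of cell centres
  fx <- (x - r$xmin) / cs - 0.5
  fy <- (r$ymin + nr * cs - y) / cs - 0.5   # row direction, 0 = top row centre
  fx <- pmin(pmax(fx, 0), nc - 1)
  fy <- pmin(pmax(fy, 0), nr - 1)
  c0 <- pmin(floor(fx), nc - 2 + (nc == 1)); c0 <- pmax(c0, 0)
  r0 <- pmin(floor(fy), nr - 2 + (nr == 1)); r0 <- pmax(r0, 0)
  tx <- fx - c0; ty <- fy - r0
  g <- function(rr, ccol) r$values[cbind(rr + 1L, ccol + 1L)]
  c1 <- pmin(c0 + 1, nc - 1); r1 <- pmin(r0 + 1, nr - 1)
  v00 <- g(r0, c0); v01 <- g(r0, c1); v10 <- g(r1, c0); v11 <- g(r1, c1)
  (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
}

#' Stepwise VIF screening of a predictor stack
#'
#' Iteratively removes the layer with the largest variance inflation factor
#' (VIF_j = 1 / (1 - R^2_j), from regressing layer j on all remaining layers)
#' until every remaining layer has VIF below `threshold`. Computed on a fixed-
#' seed random sample of valid cells; ties on the maximum VIF are broken by
#' layer name order.
#'
#' @param stack a `raster_stack` with at least two layers.
#' @param threshold drop layers while any VIF >= threshold (default 10).
#' @param max_cells sample size of valid cells used for the regressions.
#' @param seed RNG seed for the cell sample.
#' @return list: `retained` (layer names), `dropped` (in drop order),
#'   `vif` (final VIFs), `log` (data.frame of iterations).
#' @export
vif_screen <- function(stack, threshold = 10, max_cells = 10000, seed = 1L) {
  stopifnot(inherits(stack, "raster_stack"))
  if (length(stack) < 2L) stop("vif_screen: need at least two layers")
  m <- stack_matrix(stack)
  ok <- stats::complete.cases(m)
  m <- m[ok, , drop = FALSE]
  if (nrow(m) > max_cells) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    m <- m[sample.int(nrow(m), max_cells), , drop = FALSE]
  }
  keep <- colnames(m)
  dropped <- character(); log <- list()
  repeat {
    vifs <- vapply(keep, function(j) {
      others <- setdiff(keep, j)
      # collinear pairs legitimately produce a perfect fit here
      r2 <- suppressWarnings(
        summary(stats::lm(m[, j] ~ m[, others, drop = FALSE]))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1L))
    log[[length(log) + 1L]] <- data.frame(iteration = length(log) + 1L,
                                          layer = keep, vif = unname(vifs))
    worst <- max(vifs)
    if (worst < threshold || length(keep) == 1L) break
    # name-order tie break
    cand <- sort(keep[vifs == worst])[1L]
    dropped <- c(dropped, cand)
    keep <- setdiff(keep, cand)
  }
  list(retained = keep, dropped = dropped, vif = vifs,
       log = do.call(rbind, log))
}

#' Filter stream segments by Strahler order
#'
#' @param streams data.frame of stream segments with a `strahler` column
#'   (as produced by [generate_hydrology()]).
#' @param max_order keep segments with order <= max_order (default 3,
#'   the usual cut for small tributaries used by stream-breeding amphibians).
#' @return filtered data.frame.
#' @export
filter_streams <- function(streams, max_order = 3L) {
  if (is.null(streams$strahler))
    stop("filter_streams: segments carry no 'strahler' order attribute")
  streams[streams$strahler <= max_order, , drop = FALSE]
}

# ---- seeded RNG helpers -----------------------------------------------------

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
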