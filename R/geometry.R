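#' Simple planar geometry for ranges and barriers
#'
#' Polygons are two-column matrices of vertices (x, y), implicitly closed;
#' polylines are two-column matrices of consecutive vertices. Operations that
#' need polygon clipping assume convex polygons (all package-generated ranges
#' and buffers are convex).
#' @name geometry
NULL

#' Polygon area (shoelace)
#' @param poly two-column vertex matrix.
#' @return non-negative area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Polygon centroid
#' @param poly two-column vertex matrix.
#' @return c(x, y).
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- length(x); j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(c(mean(x), mean(y)))  # degenerate
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

#' Intersection of two convex polygons (Sutherland-Hodgman)
#' @param subject,clip convex polygons (two-column vertex matrices).
#' @return vertex matrix of the intersection, or NULL if empty.
#' @export
clip_convex <- function(subject, clip) {
  # orient clip counter-clockwise
  if (signed_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (k in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3L) return(NULL)
    a <- clip[k, ]; b <- clip[if (k == nc) 1L else k + 1L, ]
    inside <- function(p) (b[1L] - a[1L]) * (p[2L] - a[2L]) -
      (b[2L] - a[2L]) * (p[1L] - a[1L]) >= -1e-12
    inter <- function(p, q) {
      d1 <- c(q[1L] - p[1L], q[2L] - p[2L]); d2 <- c(b[1L] - a[1L], b[2L] - a[2L])
      den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
      t <- ((a[1L] - p[1L]) * d2[2L] - (a[2L] - p[2L]) * d2[1L]) / den
      p + t * d1
    }
    nxt <- list()
    n <- nrow(out)
    for (i in seq_len(n)) {
      p <- out[i, ]; q <- out[if (i == n) 1L else i + 1L, ]
      pin <- inside(p); qin <- inside(q)
      if (pin) nxt[[length(nxt) + 1L]] <- p
      if (xor(pin, qin)) nxt[[length(nxt) + 1L]] <- inter(p, q)
    }
    out <- if (length(nxt)) do.call(rbind, nxt) else NULL
  }
  if (!is.null(out) && polygon_area(out) < 1e-12) out <- NULL
  out
}

signed_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- length(x); j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Circular buffer polygon
#' @param center c(x, y).
#' @param radius buffer radius in map units.
#' @param n_vertices polygon resolution.
#' @return convex vertex matrix approximating the circle.
#' @export
buffer_circle <- function(center, radius, n_vertices = 64L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(center[1L] + radius * cos(th), center[2L] + radius * sin(th))
}

#' Point-in-polygon test (even-odd ray casting)
#' @param px,py point coordinates (vectors).
#' @param poly vertex matrix.
#' @return logical vector.
#' @export
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  vx <- poly[, 1L]; vy <- poly[, 2L]
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize polygons onto a grid
#' @param polys list of vertex matrices.
#' @param grid template `grid_raster`.
#' @return `grid_raster` mask (1 where a cell centre falls in any polygon).
#' @export
rasterize_polygons <- function(polys, grid) {
  xy <- cell_centers(grid)
  hit <- logical(nrow(xy))
  for (p in polys) hit <- hit | points_in_polygon(xy[, 1L], xy[, 2L], p)
  rast_like(grid, as.double(hit))
}

#' Rasterize polylines onto a grid
#'
#' Marks every cell whose interior is crossed, by sampling each segment at a
#' spacing of a third of a cell.
#' @param lines list of two-column vertex matrices (polylines).
#' @param grid template `grid_raster`.
#' @return `grid_raster` mask (1 on crossed cells).
#' @export
rasterize_lines <- function(lines, grid) {
  mask <- matrix(0, nrow(grid$values), ncol(grid$values))
  step <- grid$cellsize / 3
  for (ln in lines) {
    if (is.null(ln) || nrow(ln) < 2L) next
    for (s in seq_len(nrow(ln) - 1L)) {
      p <- ln[s, ]; q <- ln[s + 1L, ]
      len <- sqrt(sum((q - p)^2))
      t <- if (len == 0) 0 else seq(0, 1, by = step / len)
      t <- unique(c(t, 1))
      xs <- p[1L] + t * (q[1L] - p[1L]); ys <- p[2L] + t * (q[2L] - p[2L])
      cells <- cell_from_xy(grid, xs, ys, strict = FALSE)
      cells <- cells[!is.na(cells)]
      mask[cells] <- 1
    }
  }
  rast_like(grid, mask)
}

# ---- GeoJSON ---------------------------------------------------------------

#' Write polygons/polylines as GeoJSON
#' @param geoms named list of vertex matrices.
#' @param type "Polygon" or "LineString".
#' @param path output path.
#' @export
write_geojson <- function(geoms, type = c("Polygon", "LineString"), path) {
  type <- match.arg(type)
  feats <- lapply(names(geoms), function(nm) {
    m <- geoms[[nm]]
    coords <- lapply(seq_len(nrow(m)), function(i) c(m[i, 1L], m[i, 2L]))
    if (type == "Polygon") coords <- list(c(coords, coords[1L]))
    list(type = "Feature", properties = list(name = nm),
         geometry = list(type = type, coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons/polylines from GeoJSON written by [write_geojson()]
#' @param path GeoJSON path.
#' @return named list of vertex matrices.
#' @export
read_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  out <- list()
  for (f in g$features) {
    coords <- f$geometry$coordinates
    if (identical(f$geometry$type, "Polygon")) coords <- coords[[1L]]
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1L]], p[[2L]])))
    if (identical(f$geometry$type, "Polygon")) m <- m[-nrow(m), , drop = FALSE]
    out[[f$properties$name]] <- m
  }
  out
}
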