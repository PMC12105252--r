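#' Standardized Connectivity Change Index (SCCI)
#'
#' Cell-wise normalised difference of future vs current cumulative current:
#' `SCCI = (C_fut - C_cur) / (C_fut + C_cur)`, bounded in [-1, +1]; +1 is a
#' complete gain (no current now, current later), -1 a complete loss, 0
#' corridor maintenance. Cells with zero current in both maps are set to 0
#' (maintenance), not nodata.
#'
#' @param current,future non-negative current `grid_raster`s on one grid
#'   (or `current_map` objects).
#' @return `grid_raster` of SCCI values.
#' @export
scci <- function(current, future) {
  if (inherits(current, "current_map")) current <- current$current
  if (inherits(future, "current_map")) future <- future$current
  stop_if_misaligned(current, future, "current maps")
  cc <- current$values; cf <- future$values
  ok <- is.finite(cc) & is.finite(cf)
  if (any(cc[ok] < 0) || any(cf[ok] < 0))
    stop("scci: current inputs must be non-negative")
  s <- (cf - cc) / (cf + cc)
  s[ok & cc == 0 & cf == 0] <- 0
  rast_like(current, s)
}

#' Percent connectivity change within a range mask
#'
#' `100 * (mean_future - mean_current) / mean_current` over masked cells.
#' @param current,future current `grid_raster`s.
#' @param range_mask `grid_raster`: nonzero cells define the species range.
#' @return percent change (negative = decline).
#' @export
percent_connectivity_change <- function(current, future, range_mask) {
  if (inherits(current, "current_map")) current <- current$current
  if (inherits(future, "current_map")) future <- future$current
  stop_if_misaligned(current, future, "current maps")
  stop_if_misaligned(current, range_mask, "mask and current map")
  sel <- is.finite(range_mask$values) & range_mask$values != 0 &
    is.finite(current$values) & is.finite(future$values)
  if (!any(sel)) stop("percent_connectivity_change: empty mask")
  mc <- mean(current$values[sel]); mf <- mean(future$values[sel])
  if (mc == 0) stop("percent_connectivity_change: current mean is zero")
  100 * (mf - mc) / mc
}

#' Suitability-weighted centroid of a raster
#' @param r non-negative `grid_raster` with positive total weight.
#' @return c(x, y) in map units.
#' @export
weighted_centroid <- function(r) {
  v <- as.vector(r$values)
  ok <- is.finite(v)
  if (sum(v[ok]) <= 0) stop("weighted_centroid: total weight is zero")
  xy <- cell_centers(r)
  w <- v[ok] / sum(v[ok])
  c(x = sum(w * xy[ok, 1L]), y = sum(w * xy[ok, 2L]))
}

#' Centroid shift between two suitability rasters
#'
#' Euclidean distance and compass azimuth (degrees clockwise from grid
#' north, in [0, 360)) from the current to the future suitability-weighted
#' centroid.
#' @param current_sdm,future_sdm `grid_raster`s.
#' @return list of class `centroid_shift`: `from`, `to`, `distance`,
#'   `azimuth`.
#' @export
centroid_shift <- function(current_sdm, future_sdm) {
  a <- weighted_centroid(current_sdm)
  b <- weighted_centroid(future_sdm)
  d <- sqrt(sum((b - a)^2))
  az <- if (d == 0) 0 else (atan2(b[["x"]] - a[["x"]], b[["y"]] - a[["y"]]) *
                              180 / pi) %% 360
  structure(list(from = a, to = b, distance = d, azimuth = az),
            class = "centroid_shift")
}

#' Sympatry zone of two range polygons
#'
#' Intersection of the (convex) range polygons, its centroid, and a circular
#' buffer around the centroid sized to cover the whole contact area.
#' @param range_a,range_b convex range polygons (vertex matrices).
#' @param buffer_radius buffer radius in map units (e.g. 50e3 for 50 km on a
#'   metre grid).
#' @return list of class `sympatry_zone`: `intersection`, `area`,
#'   `centroid`, `buffer` polygon.
#' @export
sympatry_zone <- function(range_a, range_b, buffer_radius) {
  inter <- clip_convex(range_a, range_b)
  if (is.null(inter))
    stop("sympatry_zone: ranges do not overlap (no sympatry)")
  ctr <- polygon_centroid(inter)
  structure(list(intersection = inter, area = polygon_area(inter),
                 centroid = ctr,
                 buffer = buffer_circle(ctr, buffer_radius)),
            class = "sympatry_zone")
}

#' Average two species' SDMs inside a sympatry buffer
#'
#' Cell-wise arithmetic mean of the two suitability rasters, clipped to the
#' zone's buffer polygon (outside cells become nodata). A cell fully
#' suitable for one species and unsuitable for the other averages 0.5; a
#' cell suitable for both stays near 1 — the joint layer feeding the
#' hybridization-chance connectivity run.
#'
#' @param sdm_a,sdm_b aligned suitability `grid_raster`s in [0, 1].
#' @param zone a `sympatry_zone`.
#' @return `grid_raster`.
#' @export
average_sdms <- function(sdm_a, sdm_b, zone) {
  stop_if_misaligned(sdm_a, sdm_b, "SDM rasters")
  va <- sdm_a$values; vb <- sdm_b$values
  ok <- is.finite(va) & is.finite(vb)
  if (any(va[ok] < 0 | va[ok] > 1 | vb[ok] < 0 | vb[ok] > 1))
    stop("average_sdms: suitability values must lie in [0, 1]")
  avg <- (va + vb) / 2
  inb <- rasterize_polygons(list(zone$buffer), sdm_a)
  avg[inb$values == 0] <- NA_real_
  rast_like(sdm_a, avg)
}

#' Joint connectivity inside the hybridization zone
#'
#' Full downstream pipeline for the contact-zone assessment: average the two
#' SDMs within the sympatry buffer, burn barriers, apply the
#' negative-exponential resistance transform, and run pairwise current flow
#' using all occurrences of both species inside the buffer as focal nodes,
#' without distinguishing species.
#'
#' @param sdm_a,sdm_b suitability rasters in [0, 1].
#' @param zone a `sympatry_zone`.
#' @param occ_a,occ_b `occurrence_set`s of the two species.
#' @param roads,urban barrier geometries.
#' @param c resistance transform constant (default 4).
#' @param max_pairs optional pair cap passed to [solve_pairwise()].
#' @return a `current_map`.
#' @export
hybrid_connectivity <- function(sdm_a, sdm_b, zone, occ_a, occ_b,
                                roads = list(), urban = list(), c = 4,
                                max_pairs = NULL) {
  joint <- average_sdms(sdm_a, sdm_b, zone)
  joint <- burn_barriers(joint, roads, urban)
  res <- suitability_to_resistance(joint, c = c)
  graph <- build_grid_graph(res)
  occ <- rbind(data.frame(x = occ_a$x, y = occ_a$y),
               data.frame(x = occ_b$x, y = occ_b$y))
  inside <- points_in_polygon(occ$x, occ$y, zone$buffer)
  occ <- occ[inside, , drop = FALSE]
  if (nrow(occ) < 2L)
    stop("hybrid_connectivity: fewer than 2 occurrences inside the zone")
  nodes <- snap_nodes(graph, occ)
  solve_pairwise(graph, nodes, max_pairs = max_pairs)
}
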