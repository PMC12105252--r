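#' Configuration of a synthetic landscape
#'
#' Bundles the parameters of the generator: grid geometry, number of climate
#' layers, spatial autocorrelation range of the random fields (the *practical
#' range* of an exponential covariance: correlation falls to exp(-3) at that
#' distance, the usual geostatistical convention), a master seed, and
#' additive per-scenario climate shifts.
#'
#' @param grid_shape c(rows, cols), both positive.
#' @param cell_size cell side in map units.
#' @param n_climate_vars number of climate layers to simulate.
#' @param autocorr_range practical correlation range of the fields, map units.
#' @param seed master integer seed; identical config + seed gives
#'   bit-identical output.
#' @param scenario_deltas named list: scenario id -> numeric vector of
#'   per-variable additive shifts (length 1 or `n_climate_vars`).
#' @return list of class `landscape_config`.
#' @export
landscape_config <- function(grid_shape = c(100L, 100L), cell_size = 100,
                             n_climate_vars = 4L, autocorr_range = 2000,
                             seed = 42L, scenario_deltas = list()) {
  if (any(grid_shape < 1L)) stop("landscape_config: grid dimensions must be positive")
  if (autocorr_range <= 0) stop("landscape_config: autocorr_range must be > 0")
  if (cell_size <= 0) stop("landscape_config: cell_size must be > 0")
  structure(list(grid_shape = as.integer(grid_shape), cell_size = cell_size,
                 n_climate_vars = as.integer(n_climate_vars),
                 autocorr_range = autocorr_range, seed = as.integer(seed),
                 scenario_deltas = scenario_deltas),
            class = "landscape_config")
}

#' Stationary Gaussian random field with exponential covariance
#'
#' Circulant-embedding spectral simulation: the covariance
#' `C(h) = exp(-3 h / range)` is wrapped on an enlarged torus, its FFT gives
#' the spectral density, and filtered complex white noise is transformed back.
#' Mean 0, variance ~1.
#'
#' @param nrow,ncol grid dimensions.
#' @param range practical correlation range, in cell units.
#' @param seed integer seed.
#' @return numeric matrix.
#' @export
gaussian_field <- function(nrow, ncol, range, seed) {
  old <- local_seed(seed); on.exit(restore_seed(old))
  M <- stats::nextn(2L * nrow, 2L); N <- stats::nextn(2L * ncol, 2L)
  di <- pmin(0:(M - 1L), M - 0:(M - 1L))
  dj <- pmin(0:(N - 1L), N - 0:(N - 1L))
  h <- sqrt(outer(di^2, dj^2, "+"))
  C <- exp(-3 * h / range)
  lam <- Re(stats::fft(C))
  lam[lam < 0] <- 0              # clip tiny negative embedding eigenvalues
  Z <- matrix(stats::rnorm(M * N), M, N) + 1i * matrix(stats::rnorm(M * N), M, N)
  F <- stats::fft(sqrt(lam) * Z) / sqrt(M * N)
  Re(F)[seq_len(nrow), seq_len(ncol)]
}

#' Simulate multi-scenario climate predictor stacks
#'
#' Each climate layer is a smooth latitudinal + longitudinal gradient plus a
#' Gaussian random field with the configured correlation range. Future
#' scenarios add the configured per-variable deltas to the present layers, so
#' all scenarios share grid and CRS by construction.
#'
#' @param cfg a `landscape_config`.
#' @return named list of `raster_stack`s: `present` plus one per scenario id.
#' @export
generate_climate_stack <- function(cfg) {
  stopifnot(inherits(cfg, "landscape_config"))
  nr <- cfg$grid_shape[1L]; nc <- cfg$grid_shape[2L]
  range_cells <- cfg$autocorr_range / cfg$cell_size
  lat <- matrix(seq(1, 0, length.out = nr), nr, nc)          # north high
  lon <- matrix(seq(0, 1, length.out = nc), nr, nc, byrow = TRUE)
  layers <- list()
  for (v in seq_len(cfg$n_climate_vars)) {
    gf <- gaussian_field(nr, nc, range_cells, cfg$seed + 1000L * v)
    a <- cos(v); b <- sin(v)    # vary gradient orientation across variables
    layers[[paste0("clim", v)]] <-
      grid_raster(2 * (a * lat + b * lon) + gf,
                  cellsize = cfg$cell_size)
  }
  present <- raster_stack(layers)
  out <- list(present = present)
  for (sc in names(cfg$scenario_deltas)) {
    delta <- rep_len(cfg$scenario_deltas[[sc]], cfg$n_climate_vars)
    shifted <- lapply(seq_along(present), function(v)
      rast_like(present[[v]], present[[v]]$values + delta[v]))
    names(shifted) <- names(present)
    out[[sc]] <- raster_stack(shifted)
  }
  out
}

#' Simulate a DEM
#'
#' Regional tilt plus an autocorrelated roughness field, rescaled to the
#' requested relief.
#' @param cfg a `landscape_config`.
#' @param relief total elevation range, map (z) units.
#' @return `grid_raster`.
#' @export
generate_dem <- function(cfg, relief = 500) {
  nr <- cfg$grid_shape[1L]; nc <- cfg$grid_shape[2L]
  gf <- gaussian_field(nr, nc, cfg$autocorr_range / cfg$cell_size,
                       cfg$seed + 77L)
  ramp <- matrix(seq(1, 0, length.out = nr), nr, nc) +
    0.3 * matrix(seq(0, 1, length.out = nc), nr, nc, byrow = TRUE)
  z <- ramp + 0.6 * (gf - min(gf)) / max(1e-12, diff(range(gf)))
  z <- (z - min(z)) / diff(range(z)) * relief
  grid_raster(z, cellsize = cfg$cell_size)
}

# ---- hydrology --------------------------------------------------------------

#' Strahler stream order on a drainage tree
#'
#' Standard junction rule: a head segment has order 1; where tributaries
#' meet, the downstream order is the maximum tributary order, incremented by
#' one only if two or more tributaries share that maximum.
#'
#' @param downstream integer vector: `downstream[i]` is the index of the node
#'   directly downstream of node i, or `NA` for an outlet. Must be acyclic.
#' @return integer vector of Strahler orders per node.
#' @export
strahler_order <- function(downstream) {
  n <- length(downstream)
  ups <- vector("list", n)
  for (i in seq_len(n)) {
    d <- downstream[i]
    if (!is.na(d)) ups[[d]] <- c(ups[[d]], i)
  }
  order_out <- rep(NA_integer_, n)
  indeg <- lengths(ups)
  queue <- which(indeg == 0L)
  done <- 0L
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    up <- ups[[i]]
    if (!length(up)) order_out[i] <- 1L
    else {
      o <- order_out[up]
      mx <- max(o)
      order_out[i] <- if (sum(o == mx) >= 2L) mx + 1L else mx
    }
    done <- done + 1L
    d <- downstream[i]
    if (!is.na(d)) {
      indeg[d] <- indeg[d] - 1L
      if (indeg[d] == 0L) queue <- c(queue, d)
    }
  }
  if (done < n) stop("strahler_order: network contains a cycle")
  order_out
}

#' Simulate a stream network and water points from a DEM
#'
#' D8 steepest-descent flow routing, flow accumulation, stream delineation by
#' an accumulation threshold, Strahler ordering by the junction rule, and a
#' seeded scatter of standing-water points (pools/springs/troughs).
#'
#' @param cfg a `landscape_config`.
#' @param dem `grid_raster` on the config grid.
#' @param accum_threshold minimum number of upslope cells defining a stream.
#' @param water_density expected water points per cell.
#' @return list: `segments` data.frame (segment id, cell, x, y, strahler,
#'   downstream cell), `stream_mask` raster of per-cell Strahler order
#'   (NA off-stream), `water_points` data.frame (x, y).
#' @export
generate_hydrology <- function(cfg, dem, accum_threshold = 25L,
                               water_density = 0.003) {
  stopifnot(inherits(dem, "grid_raster"))
  z <- dem$values
  if (diff(range(z)) <= 0)
    stop("generate_hydrology: flat DEM gives a degenerate network")
  nr <- nrow(z); nc <- ncol(z); n <- nr * nc
  # D8 flow direction: steepest downhill neighbour (distance-weighted drop)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  dist <- sqrt(dr^2 + dc^2)
  row <- (seq_len(n) - 1L) %% nr + 1L
  col <- (seq_len(n) - 1L) %/% nr + 1L
  best_drop <- rep(0, n); flow_to <- rep(NA_integer_, n)
  for (k in seq_len(8L)) {
    rr <- row + dr[k]; cc <- col + dc[k]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    nb <- (cc - 1L) * nr + rr
    drop <- rep(-Inf, n)
    drop[ok] <- (z[seq_len(n)][ok] - z[nb[ok]]) / dist[k]
    upd <- ok & drop > best_drop + 1e-12
    best_drop[upd] <- drop[upd]
    flow_to[upd] <- nb[upd]
  }
  # accumulation: process cells from high to low elevation
  acc <- rep(1, n)
  for (i in order(z, decreasing = TRUE)) {
    d <- flow_to[i]
    if (!is.na(d)) acc[d] <- acc[d] + acc[i]
  }
  stream <- acc >= accum_threshold
  if (!any(stream))
    stop("generate_hydrology: no stream cells at this accumulation threshold")
  # drainage tree restricted to stream cells
  scells <- which(stream)
  idx <- match(seq_len(n), scells)           # cell -> stream node or NA
  down <- idx[flow_to[scells]]               # NA if downstream not a stream cell
  orders <- strahler_order(down)
  xy <- cell_centers(dem, scells)
  segments <- data.frame(cell = scells, x = xy[, 1L], y = xy[, 2L],
                         strahler = orders,
                         downstream_cell = ifelse(is.na(down), NA_integer_,
                                                  scells[down]))
  omask <- rep(NA_real_, n); omask[scells] <- orders
  # water points
  old <- local_seed(cfg$seed + 555L); on.exit(restore_seed(old))
  n_pts <- stats::rpois(1L, water_density * n)
  wp <- if (n_pts > 0) {
    cells <- sample.int(n, min(n_pts, n))
    wxy <- cell_centers(dem, cells)
    data.frame(x = wxy[, 1L], y = wxy[, 2L])
  } else data.frame(x = numeric(), y = numeric())
  list(segments = segments, stream_mask = rast_like(dem, omask),
       water_points = wp)
}

# ---- barriers ---------------------------------------------------------------

#' Simulate linear road barriers and urban polygons
#'
#' Roads are edge-to-edge polylines with jittered orientation; urban areas
#' are disjoint rectangles placed by rejection sampling.
#' @param cfg a `landscape_config`.
#' @param n_roads number of roads (0 allowed).
#' @param n_urban number of urban polygons.
#' @param urban_frac linear size of an urban patch as a fraction of extent.
#' @return list: `roads` (list of polylines), `urban` (list of polygons).
#' @export
generate_barriers <- function(cfg, n_roads = 2L, n_urban = 2L,
                              urban_frac = 0.08) {
  old <- local_seed(cfg$seed + 999L); on.exit(restore_seed(old))
  W <- cfg$grid_shape[2L] * cfg$cell_size
  H <- cfg$grid_shape[1L] * cfg$cell_size
  roads <- list()
  for (i in seq_len(n_roads)) {
    if (stats::runif(1) < 0.5) {        # west-east road
      y0 <- stats::runif(1, 0.15, 0.85) * H
      y1 <- y0 + stats::runif(1, -0.15, 0.15) * H
      roads[[paste0("road", i)]] <- cbind(c(0, W), c(y0, y1))
    } else {                            # south-north road
      x0 <- stats::runif(1, 0.15, 0.85) * W
      x1 <- x0 + stats::runif(1, -0.15, 0.15) * W
      roads[[paste0("road", i)]] <- cbind(c(x0, x1), c(0, H))
    }
  }
  urban <- list(); tries <- 0L
  while (length(urban) < n_urban && tries < 200L) {
    tries <- tries + 1L
    w <- urban_frac * W; h <- urban_frac * H
    x0 <- stats::runif(1, 0, W - w); y0 <- stats::runif(1, 0, H - h)
    cand <- cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
    overlaps <- any(vapply(urban, function(u)
      !is.null(clip_convex(cand, u)), logical(1L)))
    if (!overlaps) urban[[paste0("urban", length(urban) + 1L)]] <- cand
  }
  if (length(urban) < n_urban)
    warning("generate_barriers: placed only ", length(urban), " urban patches")
  list(roads = roads, urban = urban)
}

# ---- virtual species --------------------------------------------------------

#' Define a virtual species with known true suitability
#'
#' Truth combines a logistic response to two climate variables, an
#' exponential decay with distance to standing water, and a multiplicative
#' bonus in the preferred habitat class, so climatic, distance and
#' categorical predictor families all matter downstream.
#'
#' @param climate `raster_stack` of present climate (>= 2 layers).
#' @param dist_water `grid_raster` distance-to-water (map units), optional.
#' @param habitat `grid_raster` of integer habitat classes, optional.
#' @param coef logistic coefficients c(intercept, b1, b2) on the first two
#'   climate layers.
#' @param water_decay e-folding distance of the water term (map units).
#' @param habitat_class preferred class; `habitat_bonus` multiplies
#'   suitability outside it.
#' @param habitat_bonus factor in (0, 1] applied off the preferred class.
#' @param n_occurrences default occurrence count drawn by
#'   [sample_occurrences()] (default 128, a realistic count for a
#'   range-restricted amphibian).
#' @return list of class `virtual_species` with `true_suitability` raster.
#' @export
virtual_species <- function(climate, dist_water = NULL, habitat = NULL,
                            coef = c(-3, 2, -2), water_decay = 1500,
                            habitat_class = 1L, habitat_bonus = 0.6,
                            n_occurrences = 128L) {
  stopifnot(inherits(climate, "raster_stack"), length(climate) >= 2L)
  c1 <- climate[[1L]]$values; c2 <- climate[[2L]]$values
  eta <- coef[1L] + coef[2L] * c1 + coef[3L] * c2
  suit <- stats::plogis(eta)
  if (!is.null(dist_water)) {
    stop_if_misaligned(climate[[1L]], dist_water)
    suit <- suit * exp(-dist_water$values / water_decay)
  }
  if (!is.null(habitat)) {
    stop_if_misaligned(climate[[1L]], habitat)
    suit <- suit * ifelse(habitat$values == habitat_class, 1, habitat_bonus)
  }
  structure(list(true_suitability = rast_like(climate[[1L]], suit),
                 coef = coef, water_decay = water_decay,
                 habitat_class = habitat_class, habitat_bonus = habitat_bonus,
                 n_occurrences = as.integer(n_occurrences)),
            class = "virtual_species")
}

#' Sample occurrences proportionally to true suitability
#'
#' Cells are drawn without replacement with inclusion probability
#' proportional to true suitability (one point per cell, at the cell centre),
#' mirroring spatially thinned field data.
#'
#' @param vs a `virtual_species`.
#' @param seed integer seed.
#' @param n number of occurrences (defaults to `vs$n_occurrences`).
#' @param species species label.
#' @return an `occurrence_set` with exactly `n` rows.
#' @export
sample_occurrences <- function(vs, seed, n = vs$n_occurrences, species = "sp") {
  stopifnot(inherits(vs, "virtual_species"))
  suit <- as.vector(vs$true_suitability$values)
  pos <- which(is.finite(suit) & suit > 0)
  if (!length(pos)) stop("sample_occurrences: suitability is zero everywhere")
  if (length(pos) < n)
    stop(sprintf("sample_occurrences: only %d cells with positive suitability (< n = %d)",
                 length(pos), n))
  old <- local_seed(seed); on.exit(restore_seed(old))
  cells <- pos[sample.int(length(pos), n, prob = suit[pos])]
  xy <- cell_centers(vs$true_suitability, cells)
  occurrence_set(xy[, 1L], xy[, 2L], species)
}

#' Rectangular range polygon around a set of occurrences
#' @param occ an `occurrence_set`.
#' @param margin expansion margin in map units.
#' @return convex polygon (vertex matrix).
#' @export
range_polygon <- function(occ, margin = 0) {
  stopifnot(nrow(occ) > 0)
  x0 <- min(occ$x) - margin; x1 <- max(occ$x) + margin
  y0 <- min(occ$y) - margin; y1 <- max(occ$y) + margin
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}
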