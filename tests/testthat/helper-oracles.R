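# Independent reference implementations used as oracles. Each is written as
# plainly as possible (recursion, dense algebra, explicit loops) and stays
# independent of the package code paths it checks.

# Strahler order by direct recursion on upstream lists
oracle_strahler <- function(downstream) {
  n <- length(downstream)
  ups <- vector("list", n)
  for (i in seq_len(n)) if (!is.na(downstream[i]))
    ups[[downstream[i]]] <- c(ups[[downstream[i]]], i)
  rec <- function(i) {
    if (!length(ups[[i]])) return(1L)
    o <- vapply(ups[[i]], rec, integer(1L))
    m <- max(o)
    if (sum(o == m) >= 2L) m + 1L else m
  }
  vapply(seq_len(n), rec, integer(1L))
}

# node potentials for 1 A from s to t via dense Laplacian pseudoinverse
oracle_circuit_potentials <- function(n, edges, s, t) {
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]; g <- edges$conductance[k]
    L[i, j] <- L[i, j] - g; L[j, i] <- L[j, i] - g
    L[i, i] <- L[i, i] + g; L[j, j] <- L[j, j] + g
  }
  b <- numeric(n); b[s] <- 1; b[t] <- -1
  as.numeric(MASS::ginv(L) %*% b)
}

# per-node current (half sum of absolute incident edge currents, 1 A at foci)
oracle_node_current <- function(n, edges, v, s, t) {
  cur <- numeric(n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]
    ik <- abs(edges$conductance[k] * (v[i] - v[j]))
    cur[i] <- cur[i] + ik; cur[j] <- cur[j] + ik
  }
  cur <- cur / 2
  cur[c(s, t)] <- 1
  cur
}

# MESS by brute-force percentile per projection point
oracle_mess <- function(cal, proj) {
  vapply(seq_len(nrow(proj)), function(r) {
    min(vapply(seq_len(ncol(proj)), function(j) {
      x <- cal[, j]; p <- proj[r, j]
      f <- 100 * sum(x < p) / length(x)
      mn <- min(x); mx <- max(x)
      if (f == 0) (p - mn) / (mx - mn) * 100
      else if (f <= 50) 2 * f
      else if (f < 100) 2 * (100 - f)
      else (mx - p) / (mx - mn) * 100
    }, numeric(1L)))
  }, numeric(1L))
}

# continuous Boyce by an explicit window loop
oracle_boyce <- function(pres, bg, n_classes = 101L, window_frac = 0.1) {
  rng <- range(bg)
  w <- window_frac * diff(rng)
  mids <- seq(rng[1] + w / 2, rng[2] - w / 2, length.out = n_classes)
  pe <- mid_keep <- c()
  for (m in mids) {
    P <- sum(pres >= m - w / 2 & pres <= m + w / 2) / length(pres)
    E <- sum(bg >= m - w / 2 & bg <= m + w / 2) / length(bg)
    if (E > 0) { pe <- c(pe, P / E); mid_keep <- c(mid_keep, m) }
  }
  suppressWarnings(cor(pe, mid_keep, method = "spearman"))
}

# TSS by explicit confusion matrices over all observed thresholds
oracle_tss <- function(pred, lab) {
  best <- 0
  for (t in sort(unique(pred))) {
    tp <- sum(pred >= t & lab == 1); fn <- sum(pred < t & lab == 1)
    tn <- sum(pred < t & lab == 0); fp <- sum(pred >= t & lab == 0)
    best <- max(best, tp / (tp + fn) + tn / (tn + fp) - 1)
  }
  best
}

# all-pairs minimum distance to feature cells
oracle_distance <- function(mask) {
  feat <- which(mask$values != 0)
  fxy <- cell_centers(mask, feat)
  xy <- cell_centers(mask)
  out <- numeric(nrow(xy))
  for (i in seq_len(nrow(xy)))
    out[i] <- sqrt(min((xy[i, 1] - fxy[, 1])^2 + (xy[i, 2] - fxy[, 2])^2))
  rast_like(mask, out)
}

# exponential-variogram practical range fitted to directional correlations
oracle_variogram_range <- function(field, max_lag = 40L) {
  lags <- seq_len(min(max_lag, ncol(field) - 2L))
  emp <- vapply(lags, function(l)
    cor(as.vector(field[, seq_len(ncol(field) - l)]),
        as.vector(field[, seq_len(ncol(field) - l) + l])), numeric(1L))
  fit <- stats::nls(emp ~ exp(-3 * lags / rg), start = list(rg = max_lag / 3))
  unname(coef(fit)["rg"])
}

# small shared landscape used across test files
tiny_landscape <- function(seed = 11L, shape = c(40L, 40L)) {
  cfg <- landscape_config(grid_shape = shape, cell_size = 100,
                          n_climate_vars = 3L, autocorr_range = 1200,
                          seed = seed,
                          scenario_deltas = list(fut = c(0.8, -0.4, 0.2)))
  clim <- generate_climate_stack(cfg)
  dem <- generate_dem(cfg)
  list(cfg = cfg, clim = clim, dem = dem)
}
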