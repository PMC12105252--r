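#' Continuous Boyce index
#'
#' Presence-only evaluation: suitability is scanned with overlapping moving
#' windows; per window, P is the fraction of evaluation presences and E the
#' fraction of background cells whose prediction falls inside, and the index
#' is the Spearman rank correlation between the P/E ratio and the window
#' midpoint. Ranges from -1 (counter prediction) through 0 (no better than
#' chance) to +1 (optimal prediction).
#'
#' @param pred_presence predicted suitability at evaluation presences.
#' @param background predicted suitability over the background (all valid
#'   cells of the prediction raster).
#' @param n_classes number of moving windows (default 101).
#' @param window_frac window width as a fraction of the background prediction
#'   range (default 0.1).
#' @return Boyce index in [-1, 1].
#' @export
boyce_index <- function(pred_presence, background, n_classes = 101L,
                        window_frac = 0.1) {
  background <- background[is.finite(background)]
  pred_presence <- pred_presence[is.finite(pred_presence)]
  if (!length(pred_presence)) stop("boyce_index: no evaluation presences")
  rng <- range(background)
  if (diff(rng) <= 0)
    stop("boyce_index: constant predictions, index undefined")
  w <- window_frac * diff(rng)
  mids <- seq(rng[1L] + w / 2, rng[2L] - w / 2, length.out = n_classes)
  P <- E <- numeric(n_classes)
  for (k in seq_len(n_classes)) {
    lo <- mids[k] - w / 2; hi <- mids[k] + w / 2
    P[k] <- mean(pred_presence >= lo & pred_presence <= hi)
    E[k] <- mean(background >= lo & background <= hi)
  }
  ok <- E > 0
  if (sum(ok) < 2L)
    stop("boyce_index: fewer than two suitability classes with background support")
  ratio <- P[ok] / E[ok]
  suppressWarnings(stats::cor(ratio, mids[ok], method = "spearman"))
}

#' True Skill Statistic
#'
#' `max over thresholds t of sensitivity(t) + specificity(t) - 1`, with the
#' positive rule `prediction >= t`.
#' @param predictions numeric predictions.
#' @param labels 0/1 labels; both classes must be present.
#' @return TSS in [0, 1] (the threshold scan never does worse than 0).
#' @export
tss <- function(predictions, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("tss: both classes must be present")
  thr <- sort(unique(predictions))
  pos <- predictions[labels == 1L]; neg <- predictions[labels == 0L]
  best <- 0
  for (t in thr) {
    sens <- mean(pos >= t); spec <- mean(neg < t)
    best <- max(best, sens + spec - 1)
  }
  best
}

#' Moran's I correlogram of model residuals
#'
#' Binary-weight Moran's I per distance bin:
#' `I = (n / W) * sum_ij w_ij (r_i - rbar)(r_j - rbar) / sum_i (r_i - rbar)^2`
#' with `w_ij = 1` iff the pair distance falls in the bin. Under spatial
#' independence the expectation per bin is `-1/(n-1)`.
#'
#' @param residuals numeric residuals (observed - predicted).
#' @param coords two-column matrix of point coordinates.
#' @param bin_width bin width in map units.
#' @param max_dist largest distance considered.
#' @return data.frame of class `correlogram`: bin midpoint `dist`,
#'   `morans_i`, `n_pairs`.
#' @export
residual_correlogram <- function(residuals, coords, bin_width, max_dist) {
  n <- length(residuals)
  if (n < 3L) stop("residual_correlogram: need at least 3 points")
  if (stats::var(residuals) <= 0)
    stop("residual_correlogram: zero residual variance")
  d <- as.matrix(stats::dist(coords))
  r <- residuals - mean(residuals)
  denom <- sum(r^2)
  cross <- outer(r, r)
  breaks <- seq(0, max_dist, by = bin_width)
  if (breaks[length(breaks)] < max_dist) breaks <- c(breaks, max_dist)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  I <- np <- numeric(length(mids))
  ut <- upper.tri(d)
  for (k in seq_along(mids)) {
    sel <- ut & d > breaks[k] & d <= breaks[k + 1L]
    np[k] <- sum(sel)
    I[k] <- if (np[k] > 0) (n / (2 * np[k])) * 2 * sum(cross[sel]) / denom
    else NA_real_
  }
  structure(data.frame(dist = mids, morans_i = I, n_pairs = np),
            class = c("correlogram", "data.frame"))
}

#' Spatial autocorrelation range from residual correlograms
#'
#' The SAR proxy is the smallest bin midpoint `d*` such that `|I| < tol` at
#' `d*` and every larger bin, across all supplied correlograms (bins without
#' pairs are skipped). If Moran's I never stabilises below `tol`, the largest
#' bin midpoint is returned with a warning.
#'
#' @param correlograms a `correlogram` or list of them.
#' @param tol stability tolerance on |I| (default 0.05).
#' @return distance in map units.
#' @export
estimate_sar <- function(correlograms, tol = 0.05) {
  if (inherits(correlograms, "correlogram")) correlograms <- list(correlograms)
  if (!length(correlograms)) stop("estimate_sar: no correlograms supplied")
  mids <- correlograms[[1L]]$dist
  stable <- rep(TRUE, length(mids))
  for (cg in correlograms) {
    ok <- is.finite(cg$morans_i)
    stable <- stable & (!ok | abs(cg$morans_i) < tol)
  }
  # require stability from the bin onwards
  from_here <- rev(cumprod(rev(stable))) > 0
  if (!any(from_here)) {
    warning("estimate_sar: Moran's I never stabilises below tol; returning max distance")
    return(mids[length(mids)])
  }
  mids[which(from_here)[1L]]
}

#' Checkerboard spatial cross-validation folds
#'
#' Square blocks of side `block_size` anchored at the extent origin; a point
#' in block (i, j) goes to fold `1 + (i + j) mod 2`. Designed to be used with
#' a block size larger than the residual spatial autocorrelation range.
#'
#' @param pts data.frame with x, y.
#' @param block_size block side in map units.
#' @param origin c(x0, y0) anchor of the block lattice.
#' @return integer fold vector (1 or 2).
#' @export
checkerboard_folds <- function(pts, block_size, origin = c(0, 0)) {
  if (block_size <= 0) stop("checkerboard_folds: block_size must be > 0")
  bi <- floor((pts$x - origin[1L]) / block_size)
  bj <- floor((pts$y - origin[2L]) / block_size)
  fold <- as.integer((bi + bj) %% 2) + 1L
  if (length(unique(fold)) < 2L)
    stop("checkerboard_folds: one fold is empty; use a smaller block size")
  fold
}
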