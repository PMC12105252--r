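#' Fit a predictor-to-suitability transform from occurrence frequencies
#'
#' Compares the distribution of a predictor at occurrence localities against
#' its background distribution and turns the relative-frequency ratio into a
#' suitability score on [0, 1] (max-normalised).
#'
#' \describe{
#'   \item{categorical}{score(class) = occurrence frequency / background
#'     frequency, rescaled so the best class scores 1; classes absent from
#'     the background score 0 with a warning.}
#'   \item{decay}{binned frequency ratios fitted with `A * exp(-x / scale)`
#'     (distance-type predictors).}
#'   \item{gaussian}{binned ratios fitted with a Gaussian bump
#'     `A * exp(-(x - mu)^2 / (2 sigma^2))` (e.g. slope).}
#'   \item{gaussian_circular}{Gaussian in circular distance (degrees) to the
#'     circular mean of occurrence values (aspect; 0 and 360 coincide).}
#' }
#'
#' @param occ_values predictor values at occurrences (>= 30).
#' @param bg_values predictor values over the background.
#' @param kind transform family.
#' @param n_bins bins used for the continuous fits.
#' @return object of class `suitability_transform`.
#' @export
frequency_transform <- function(occ_values, bg_values,
                                kind = c("categorical", "decay", "gaussian",
                                         "gaussian_circular"),
                                n_bins = 12L) {
  kind <- match.arg(kind)
  occ_values <- occ_values[is.finite(occ_values)]
  bg_values <- bg_values[is.finite(bg_values)]
  if (length(occ_values) < 30L)
    stop("frequency_transform: need at least 30 occurrence values")
  if (kind == "categorical") {
    classes <- sort(unique(c(occ_values, bg_values)))
    occ_f <- table(factor(occ_values, levels = classes)) / length(occ_values)
    bg_f <- table(factor(bg_values, levels = classes)) / length(bg_values)
    score <- as.numeric(occ_f) / as.numeric(bg_f)
    if (any(!is.finite(score))) {
      warning("frequency_transform: class absent from background scored 0")
      score[!is.finite(score)] <- 0
    }
    score <- if (max(score) > 0) score / max(score) else score
    names(score) <- as.character(classes)
    return(structure(list(kind = kind, mapping = score),
                     class = "suitability_transform"))
  }
  x0 <- occ_values; b0 <- bg_values; center <- NULL
  if (kind == "gaussian_circular") {
    rad <- occ_values * pi / 180
    center <- (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
    circd <- function(v) { d <- abs((v - center) %% 360); pmin(d, 360 - d) }
    x0 <- circd(occ_values); b0 <- circd(bg_values)
  }
  breaks <- seq(min(b0), max(b0), length.out = n_bins + 1L)
  breaks[1L] <- breaks[1L] - 1e-9
  occ_h <- graphics::hist(x0, breaks = breaks, plot = FALSE)$counts / length(x0)
  bg_h <- graphics::hist(pmin(pmax(b0, breaks[1L]), breaks[n_bins + 1L]),
                         breaks = breaks, plot = FALSE)$counts / length(b0)
  mid <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  ok <- bg_h > 0
  ratio <- occ_h[ok] / bg_h[ok]; mid <- mid[ok]
  fit <- if (kind == "decay") {
    start <- list(A = max(ratio), s = max(stats::weighted.mean(mid, ratio), diff(range(mid)) / 10))
    minpack.lm::nlsLM(ratio ~ A * exp(-mid / s), start = start,
                      lower = c(A = 1e-9, s = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else if (kind == "gaussian_circular") {
    # the folded angular distance is centred at 0 by construction
    minpack.lm::nlsLM(ratio ~ A * exp(-mid^2 / (2 * sg^2)),
                      start = list(A = max(ratio), sg = diff(range(mid)) / 4),
                      lower = c(A = 1e-9, sg = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    start <- list(A = max(ratio), mu = mid[which.max(ratio)],
                  sg = diff(range(mid)) / 4)
    minpack.lm::nlsLM(ratio ~ A * exp(-(mid - mu)^2 / (2 * sg^2)),
                      start = start, lower = c(A = 1e-9, mu = -Inf, sg = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  params <- as.list(stats::coef(fit))
  if (kind == "gaussian_circular") params$mu <- 0
  structure(list(kind = kind, params = params, center = center),
            class = "suitability_transform")
}

#' Apply a suitability transform to a raster
#' @param tr a `suitability_transform`.
#' @param r predictor `grid_raster`.
#' @return `grid_raster` of scores in [0, 1]; nodata propagates.
#' @export
apply_transform <- function(tr, r) {
  stopifnot(inherits(tr, "suitability_transform"), inherits(r, "grid_raster"))
  v <- as.vector(r$values)
  out <- rep(NA_real_, length(v))
  ok <- is.finite(v)
  if (tr$kind == "categorical") {
    sc <- tr$mapping[as.character(v[ok])]
    sc[is.na(sc)] <- 0          # unseen class: no evidence of use
    out[ok] <- as.numeric(sc)
  } else {
    x <- v[ok]
    if (tr$kind == "gaussian_circular") {
      d <- abs((x - tr$center) %% 360); x <- pmin(d, 360 - d)
    }
    p <- tr$params
    raw <- if (tr$kind == "decay") exp(-x / p$s)
           else exp(-(x - if (tr$kind == "gaussian_circular") 0 else p$mu)^2 /
                      (2 * p$sg^2))
    out[ok] <- pmin(pmax(raw, 0), 1)
  }
  rast_like(r, out)
}

#' Weighted-overlay suitability
#'
#' Per-cell weighted arithmetic mean of aligned score layers (all on [0, 1],
#' including the climatic ensemble layer). Weights must sum to 1; nodata in
#' any layer propagates.
#'
#' @param layers named list of `grid_raster`s.
#' @param weights numeric weights matching `layers` (by name if named).
#' @return `grid_raster` in [0, 1].
#' @export
weighted_overlay <- function(layers, weights) {
  stopifnot(length(layers) == length(weights))
  if (!is.null(names(weights)) && !is.null(names(layers)))
    weights <- weights[names(layers)]
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weighted_overlay: weights must sum to 1")
  for (l in layers[-1L]) stop_if_misaligned(layers[[1L]], l, "overlay layers")
  acc <- 0
  for (i in seq_along(layers)) acc <- acc + weights[i] * layers[[i]]$values
  rast_like(layers[[1L]], acc)
}

#' Default fine-scale overlay weights
#'
#' Climate-ensemble-dominant, habitat-heavy weighting reflecting the target
#' taxon's reliance on forest cover and proximity to water; override freely.
#' @return named numeric vector summing to 1.
#' @export
default_overlay_weights <- function() {
  c(enm = 0.40, habitat = 0.20, dist_stream = 0.15, dist_water = 0.15,
    slope = 0.05, aspect = 0.05)
}

#' Re-run the overlay for a future scenario
#'
#' Identical transforms, weights and non-climatic layers; only the climatic
#' ensemble layer is swapped per scenario (fine-scale predictors have no
#' reliable future projections and are held fixed).
#'
#' @param scored_layers named list of transformed (non-climatic) score
#'   rasters used for the present-day overlay.
#' @param enm_future future ensemble suitability `grid_raster`.
#' @param weights the present-day weights (must include `enm`).
#' @return `grid_raster`.
#' @export
project_fine_future <- function(scored_layers, enm_future, weights) {
  stopifnot("enm" %in% names(weights))
  for (l in scored_layers) stop_if_misaligned(enm_future, l, "overlay layers")
  weighted_overlay(c(list(enm = enm_future), scored_layers), weights)
}

#' Continuous-Boyce validation of a final suitability raster
#'
#' Delegates to [boyce_index()] with the raster's valid cells as background
#' and the raster values at held-out occurrences as evaluation predictions.
#'
#' @param suitability final weighted `grid_raster`.
#' @param occ held-out `occurrence_set`.
#' @param ... passed to [boyce_index()].
#' @return Boyce index.
#' @export
validate_boyce <- function(suitability, occ, ...) {
  cells <- cell_from_xy(suitability, occ$x, occ$y)
  boyce_index(suitability$values[cells], as.vector(suitability$values), ...)
}
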