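#' Enumerate projection scenarios
#'
#' Cartesian product of projection years, emission pathways (SSPs) and
#' climate models (GCMs), in deterministic (year, ssp, gcm) order.
#'
#' @param years projection years (e.g. c(2030, 2050, 2070)).
#' @param ssps SSP labels (e.g. c("1.26", "2.45", "3.70", "5.85")).
#' @param gcms GCM labels.
#' @return data.frame with columns year, ssp, gcm and a `scenario_id`.
#' @export
enumerate_scenarios <- function(years, ssps, gcms) {
  if (!length(years) || !length(ssps) || !length(gcms))
    stop("enumerate_scenarios: empty component list")
  g <- expand.grid(gcm = gcms, ssp = ssps, year = years,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("year", "ssp", "gcm")]
  g <- g[order(match(g$year, years), match(g$ssp, ssps), match(g$gcm, gcms)), ]
  rownames(g) <- NULL
  g$scenario_id <- sprintf("%s_ssp%s_%s", g$year, g$ssp, g$gcm)
  g
}

#' Multivariate environmental similarity surface (MESS)
#'
#' Per variable with projection value `p` and calibration sample with
#' empirical percentile `f = 100 * mean(cal < p)`:
#' \itemize{
#'   \item `f = 0`: `(p - min) / (max - min) * 100` (negative below the min),
#'   \item `0 < f <= 50`: `2 f`,
#'   \item `50 <= f < 100`: `2 (100 - f)`,
#'   \item `f = 100`: `(max - p) / (max - min) * 100` (negative above the max).
#' }
#' The MESS value is the minimum over variables; negative values flag novel
#' (extrapolated) conditions.
#'
#' @param calibration matrix/data.frame of calibration values, one column per
#'   variable (typically the model's presence + pseudo-absence cells).
#' @param stack projection `raster_stack` with matching layer names.
#' @return list: `mess` raster (minimum similarity) and
#'   `most_dissimilar` raster of the argmin variable index.
#' @export
mess <- function(calibration, stack) {
  calibration <- as.matrix(calibration)
  vars <- colnames(calibration)
  if (is.null(vars)) {
    vars <- names(stack)[seq_len(ncol(calibration))]
    colnames(calibration) <- vars
  }
  stopifnot(all(vars %in% names(stack)))
  proj <- stack_matrix(stack)[, vars, drop = FALSE]
  sim <- matrix(NA_real_, nrow(proj), length(vars))
  for (j in seq_along(vars)) {
    cal <- sort(calibration[, j])
    if (cal[length(cal)] - cal[1L] <= 0)
      stop("mess: constant calibration values for variable ", vars[j])
    p <- proj[, j]
    f <- 100 * (findInterval(p, cal, left.open = TRUE)) / length(cal)
    mn <- cal[1L]; mx <- cal[length(cal)]
    s <- ifelse(f == 0, (p - mn) / (mx - mn) * 100,
         ifelse(f <= 50, 2 * f,
         ifelse(f < 100, 2 * (100 - f), (mx - p) / (mx - mn) * 100)))
    sim[, j] <- s
  }
  mins <- apply(sim, 1L, function(r) if (anyNA(r)) NA_real_ else min(r))
  amin <- apply(sim, 1L, function(r) if (anyNA(r)) NA_real_ else which.min(r))
  list(mess = rast_like(stack[[1L]], mins),
       most_dissimilar = rast_like(stack[[1L]], amin),
       variables = vars)
}

#' Dissimilarity-weighted multi-GCM averaging (MEDI-style)
#'
#' Combines per-GCM suitability projections into one surface per year x SSP,
#' down-weighting GCMs whose conditions are environmentally novel. Per cell,
#' each GCM's MESS value is rescaled by the global MESS range to a similarity
#' score `s_g` (plus a small epsilon), weights are `s_g / sum(s_g)` and the
#' output is the convex combination of the projections. With a degenerate
#' zero MESS range all GCMs weigh equally.
#'
#' @param projections list of suitability `grid_raster`s, one per GCM.
#' @param mess_rasters list of matching MESS `grid_raster`s.
#' @param eps stabilising constant (default 1e-6).
#' @return combined `grid_raster`.
#' @export
medi_combine <- function(projections, mess_rasters, eps = 1e-6) {
  if (length(projections) < 2L)
    stop("medi_combine: need at least two GCM projections")
  stopifnot(length(projections) == length(mess_rasters))
  for (p in projections[-1L]) stop_if_misaligned(projections[[1L]], p)
  for (m in mess_rasters) stop_if_misaligned(projections[[1L]], m)
  M <- vapply(mess_rasters, function(m) as.vector(m$values),
              numeric(length(projections[[1L]]$values)))
  P <- vapply(projections, function(p) as.vector(p$values),
              numeric(length(projections[[1L]]$values)))
  gmin <- min(M, na.rm = TRUE); gmax <- max(M, na.rm = TRUE)
  S <- if (gmax - gmin > 0) (M - gmin) / (gmax - gmin) + eps
       else matrix(1, nrow(M), ncol(M))
  W <- S / rowSums(S)
  rast_like(projections[[1L]], rowSums(W * P))
}

#' Project the ensemble across future scenarios
#'
#' For every scenario stack: predict the ensemble, compute MESS against the
#' calibration sample, then combine the GCM members of each year x SSP cell
#' of the scenario grid with [medi_combine()].
#'
#' @param ens an `sdm_ensemble` (or `enm_result`).
#' @param scenario_stacks named list `scenario_id -> raster_stack`, ids as
#'   produced by [enumerate_scenarios()].
#' @param scenarios data.frame from [enumerate_scenarios()].
#' @param calibration calibration sample matrix for MESS (presence +
#'   pseudo-absence predictor values).
#' @return list: `per_scenario` (suitability raster per scenario_id),
#'   `mess` (per scenario_id), `combined` (per year x SSP, MEDI-weighted).
#' @export
project_scenarios <- function(ens, scenario_stacks, scenarios, calibration) {
  if (inherits(ens, "enm_result")) ens <- ens$ensemble
  per <- list(); mss <- list()
  for (id in scenarios$scenario_id) {
    st <- scenario_stacks[[id]]
    if (is.null(st)) stop("project_scenarios: missing stack for ", id)
    per[[id]] <- predict_raster(ens, st)
    mss[[id]] <- mess(calibration, st)$mess
  }
  combined <- list()
  for (yr in unique(scenarios$year)) for (sp in unique(scenarios$ssp)) {
    ids <- scenarios$scenario_id[scenarios$year == yr & scenarios$ssp == sp]
    if (!length(ids)) next
    key <- sprintf("%s_ssp%s", yr, sp)
    combined[[key]] <- if (length(ids) == 1L) per[[ids]]
      else medi_combine(per[ids], mss[ids])
  }
  list(per_scenario = per, mess = mss, combined = combined)
}
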