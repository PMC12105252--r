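#' Surface range envelope of presence climates
#'
#' Per-variable rectilinear envelope spanning the empirical quantiles `q` and
#' `1 - q` (linear-interpolation, type 7) of presence-cell values; a cell is
#' inside the envelope iff it lies within the bounds for every variable.
#'
#' @param presences an `occurrence_set`.
#' @param stack climate `raster_stack`.
#' @param q tail quantile in (0, 0.5); default 0.025 (a 95% envelope).
#' @return object of class `sre_envelope` with `lower`/`upper` per variable.
#' @export
build_sre_envelope <- function(presences, stack, q = 0.025) {
  if (q < 0 || q >= 0.5) stop("build_sre_envelope: q must be in [0, 0.5)")
  if (nrow(presences) < 20L)
    stop("build_sre_envelope: need at least 20 presences for stable quantiles")
  vals <- extract_at_points(stack, presences)
  m <- as.matrix(vals[, names(stack), drop = FALSE])
  if (any(vals$missing)) m <- m[!vals$missing, , drop = FALSE]
  lower <- apply(m, 2L, stats::quantile, probs = q, type = 7, names = FALSE)
  upper <- apply(m, 2L, stats::quantile, probs = 1 - q, type = 7, names = FALSE)
  structure(list(lower = lower, upper = upper, q = q,
                 variables = names(stack)),
            class = "sre_envelope")
}

#' Which cells fall inside an SRE envelope
#' @param env an `sre_envelope`.
#' @param stack `raster_stack` with the envelope's variables.
#' @return logical vector over cells (NA where any layer is missing).
#' @export
sre_inside <- function(env, stack) {
  m <- stack_matrix(stack)[, env$variables, drop = FALSE]
  inside <- rep(TRUE, nrow(m))
  for (j in seq_along(env$variables))
    inside <- inside & m[, j] >= env$lower[j] & m[, j] <= env$upper[j]
  inside[!stats::complete.cases(m)] <- NA
  inside
}

#' Draw SRE-based pseudo-absence datasets
#'
#' Pseudo-absences are drawn uniformly, without duplicate cells within a set,
#' from cells whose climate lies outside the presence envelope in at least
#' one variable. Each replicate appends the (shared) presence rows with label
#' 1. Case weights give the two classes equal total weight: presences weigh 1
#' and each pseudo-absence weighs `n_presences / n`.
#'
#' @param env an `sre_envelope` built from the presences.
#' @param stack climate `raster_stack`.
#' @param presences the `occurrence_set` used to build `env`.
#' @param n pseudo-absences per set (default 1000).
#' @param n_sets number of replicate sets (default 10).
#' @param seed integer seed.
#' @return list of data.frames (class `pa_dataset`): columns x, y, label,
#'   weight, replicate.
#' @export
draw_pseudoabsences <- function(env, stack, presences, n = 1000L,
                                n_sets = 10L, seed = 42L) {
  inside <- sre_inside(env, stack)
  outside <- which(!is.na(inside) & !inside)
  if (length(outside) < n)
    stop(sprintf("draw_pseudoabsences: only %d cells outside the envelope (< n = %d)",
                 length(outside), n))
  old <- local_seed(seed); on.exit(restore_seed(old))
  n_pres <- nrow(presences)
  pres <- data.frame(x = presences$x, y = presences$y, label = 1L, weight = 1)
  lapply(seq_len(n_sets), function(rep_id) {
    cells <- outside[sample.int(length(outside), n)]
    xy <- cell_centers(stack[[1L]], cells)
    pa <- data.frame(x = xy[, 1L], y = xy[, 2L], label = 0L,
                     weight = n_pres / n)
    out <- rbind(pres, pa)
    out$replicate <- rep_id
    structure(out, class = c("pa_dataset", "data.frame"))
  })
}

#' Fit one niche-model learner
#'
#' Three families are supported, parameterised the way ensemble SDM studies
#' commonly fix them:
#' \describe{
#'   \item{glm}{binomial-logit GLM, quadratic polynomial in each predictor.}
#'   \item{gbm}{gradient-boosted trees (xgboost backend): 5000 trees,
#'     three-way interactions (depth 3), shrinkage 0.001, bag fraction 0.5,
#'     minimum 10 observations per terminal node.}
#'   \item{rf}{random forest: 500 classification trees, 2 candidate
#'     predictors per split, terminal node size 5; class weights mirror the
#'     case-weight scheme (the RF backend has no per-row weights).}
#' }
#' Constant predictors are dropped with a warning; a single-class dataset is
#' an error. Case weights are honoured by glm/gbm.
#'
#' @param data data.frame with columns `label`, `weight`, and predictors.
#' @param family "glm", "gbm" or "rf".
#' @param predictors character vector of predictor column names.
#' @param gbm_trees,rf_trees tree counts (defaults 5000 / 500).
#' @param seed seed for the stochastic learners.
#' @return object of class `sdm_fit`.
#' @export
fit_learner <- function(data, family = c("glm", "gbm", "rf"),
                        predictors = NULL, gbm_trees = 5000L,
                        rf_trees = 500L, seed = 42L) {
  family <- match.arg(family)
  if (is.null(predictors))
    predictors <- setdiff(names(data),
                          c("x", "y", "label", "weight", "replicate", "fold"))
  y <- as.integer(data$label)
  if (length(unique(y)) < 2L)
    stop("fit_learner: dataset contains a single class")
  w <- if (is.null(data$weight)) rep(1, nrow(data)) else data$weight
  keep <- predictors[vapply(predictors, function(p)
    stats::var(data[[p]]) > 0, logical(1L))]
  if (length(keep) < length(predictors))
    warning("fit_learner: dropping constant predictor(s): ",
            paste(setdiff(predictors, keep), collapse = ", "))
  if (!length(keep)) stop("fit_learner: no non-constant predictors")
  X <- as.matrix(data[, keep, drop = FALSE])
  old <- local_seed(seed); on.exit(restore_seed(old))
  model <- switch(family,
    glm = {
      df <- data.frame(label = y, data[, keep, drop = FALSE])
      rhs <- paste(sprintf("poly(%s, 2, raw = TRUE)", keep), collapse = " + ")
      suppressWarnings(stats::glm(stats::as.formula(paste("label ~", rhs)),
                                  family = stats::binomial(), data = df,
                                  weights = w))
    },
    gbm = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, weight = w)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.001,
                      max_depth = 3, subsample = 0.5, min_child_weight = 10,
                      nthread = 1),
        data = dtrain, nrounds = gbm_trees, verbose = 0)
    },
    rf = {
      cw <- c(`0` = 1 / sum(w[y == 0]), `1` = 1 / sum(w[y == 1]))
      randomForest::randomForest(x = data[, keep, drop = FALSE],
                                 y = factor(y, levels = c(0, 1)),
                                 ntree = rf_trees, mtry = min(2L, length(keep)),
                                 nodesize = 5,
                                 classwt = cw / sum(cw))
    })
  structure(list(family = family, model = model, predictors = keep),
            class = "sdm_fit")
}

#' Predict suitability from a fitted learner
#' @param object an `sdm_fit`.
#' @param newdata data.frame (or matrix) with the predictor columns.
#' @param ... unused.
#' @return numeric predictions in [0, 1]; NA rows propagate.
#' @export
predict.sdm_fit <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  X <- newdata[, object$predictors, drop = FALSE]
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  if (!any(ok)) return(out)
  out[ok] <- switch(object$family,
    glm = as.numeric(stats::predict(object$model, newdata = X[ok, , drop = FALSE],
                                    type = "response")),
    gbm = as.numeric(stats::predict(object$model,
                                    xgboost::xgb.DMatrix(as.matrix(X[ok, , drop = FALSE])))),
    rf  = as.numeric(stats::predict(object$model, X[ok, , drop = FALSE],
                                    type = "prob")[, "1"]))
  pmin(pmax(out, 0), 1)
}

#' Predict a suitability raster from a fitted model or ensemble
#' @param fit an `sdm_fit` or `sdm_ensemble`.
#' @param stack predictor `raster_stack`.
#' @return `grid_raster` of suitability in [0, 1].
#' @export
predict_raster <- function(fit, stack) {
  df <- as.data.frame(stack_matrix(stack))
  rast_like(stack[[1L]], stats::predict(fit, df))
}

#' Boyce-weighted ensemble of selected learners
#'
#' Members must pass both performance gates strictly (cross-validated Boyce
#' index above `boyce_min` and TSS above `tss_min`); ensemble weights are
#' proportional to each member's Boyce index and the ensemble prediction is
#' the weighted mean of member predictions.
#'
#' @param models list of `sdm_fit` objects, each carrying `$boyce` and
#'   `$tss` evaluation scores.
#' @param boyce_min,tss_min strict selection thresholds (defaults 0.7, 0.5).
#' @return object of class `sdm_ensemble`.
#' @export
build_ensemble <- function(models, boyce_min = 0.7, tss_min = 0.5) {
  scores <- data.frame(
    boyce = vapply(models, function(m) m$boyce %||% NA_real_, numeric(1L)),
    tss = vapply(models, function(m) m$tss %||% NA_real_, numeric(1L)))
  pass <- !is.na(scores$boyce) & !is.na(scores$tss) &
    scores$boyce > boyce_min & scores$tss > tss_min
  if (!any(pass))
    stop("build_ensemble: no model passes the gates; scores:\n",
         paste(utils::capture.output(print(scores)), collapse = "\n"))
  members <- models[pass]
  b <- scores$boyce[pass]
  structure(list(members = members, weights = b / sum(b),
                 scores = scores[pass, , drop = FALSE]),
            class = "sdm_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict.sdm_ensemble <- function(object, newdata, ...) {
  preds <- vapply(object$members, function(m) predict(m, newdata),
                  numeric(nrow(as.data.frame(newdata))))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  as.numeric(preds %*% object$weights)
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("sdm_ensemble: %d members\n", length(x$members)))
  for (i in seq_along(x$members))
    cat(sprintf("  %-4s  weight %.4f  Boyce %.3f  TSS %.3f\n",
                x$members[[i]]$family, x$weights[i],
                x$scores$boyce[i], x$scores$tss[i]))
  invisible(x)
}

#' Permutation variable importance of an ensemble
#'
#' For each variable, its values are permuted over the (sampled) prediction
#' cells and importance is `1 - cor(pred_original, pred_permuted)`, averaged
#' over permutations and normalised across variables to percentages summing
#' to 100.
#'
#' @param ens an `sdm_ensemble` (or `sdm_fit`).
#' @param stack predictor `raster_stack`.
#' @param n_perm permutations per variable (>= 1).
#' @param seed integer seed.
#' @param max_cells cell sample cap.
#' @return named numeric vector of percentages.
#' @export
variable_importance <- function(ens, stack, n_perm = 3L, seed = 42L,
                                max_cells = 5000L) {
  if (n_perm < 1L) stop("variable_importance: n_perm must be >= 1")
  m <- stack_matrix(stack)
  ok <- which(stats::complete.cases(m))
  old <- local_seed(seed); on.exit(restore_seed(old))
  if (length(ok) > max_cells) ok <- sort(sample(ok, max_cells))
  m <- m[ok, , drop = FALSE]
  base <- stats::predict(ens, as.data.frame(m))
  raw <- vapply(colnames(m), function(v) {
    mean(vapply(seq_len(n_perm), function(p) {
      mp <- m
      mp[, v] <- mp[sample.int(nrow(mp)), v]
      r <- suppressWarnings(stats::cor(base, stats::predict(ens, as.data.frame(mp))))
      if (is.na(r)) 1 else 1 - r
    }, numeric(1L)))
  }, numeric(1L))
  if (sum(raw) <= 0) return(raw * 0)
  100 * raw / sum(raw)
}

# ---- full ENM pipeline ------------------------------------------------------

#' Fit the full ensemble niche model for one species
#'
#' End-to-end climatic ENM: SRE envelope and pseudo-absence replicates,
#' checkerboard spatial cross-validation (block size from the residual
#' spatial autocorrelation range unless supplied), per-family x per-replicate
#' two-fold fitting with Boyce/TSS evaluation, strict member selection, a
#' Boyce-weighted ensemble refitted on the full datasets, and the present-day
#' ensemble suitability raster.
#'
#' @param presences thinned `occurrence_set`.
#' @param stack present-day climate `raster_stack` (post VIF screening).
#' @param families learner families to include.
#' @param n_pa pseudo-absences per replicate.
#' @param n_sets pseudo-absence replicates.
#' @param q SRE tail quantile.
#' @param block_size checkerboard block size; if NULL it is set from
#'   [estimate_sar()] on preliminary-model residuals (1.25 x SAR, at least
#'   2 cells).
#' @param boyce_min,tss_min member-selection gates.
#' @param gbm_trees boosted-trees rounds (default 5000).
#' @param seed master seed.
#' @return list of class `enm_result`: `ensemble`, `suitability` raster,
#'   `evaluations` data.frame, `block_size`, `sar`, `pa_sets`, `envelope`.
#' @export
fit_ensemble_enm <- function(presences, stack, families = c("glm", "gbm", "rf"),
                             n_pa = 1000L, n_sets = 10L, q = 0.025,
                             block_size = NULL, boyce_min = 0.7, tss_min = 0.5,
                             gbm_trees = 5000L, seed = 42L) {
  env <- build_sre_envelope(presences, stack, q)
  pa_sets <- draw_pseudoabsences(env, stack, presences, n = n_pa,
                                 n_sets = n_sets, seed = seed)
  sm <- stack_matrix(stack)
  get_pred <- function(d) {
    cells <- cell_from_xy(stack[[1L]], d$x, d$y)
    cbind(d, as.data.frame(sm[cells, , drop = FALSE]))
  }
  sar <- NA_real_
  if (is.null(block_size)) {
    # preliminary GLM per replicate (first 3): Moran correlogram of residuals
    r1 <- stack[[1L]]
    diag_len <- sqrt((ncol(r1$values) * r1$cellsize)^2 +
                       (nrow(r1$values) * r1$cellsize)^2)
    max_dist <- diag_len / 2
    cgs <- lapply(pa_sets[seq_len(min(3L, length(pa_sets)))], function(d) {
      dd <- get_pred(d)
      fit <- fit_learner(dd, "glm", predictors = names(stack), seed = seed)
      res <- dd$label - predict(fit, dd)
      # correlogram on a capped point sample to stay desk-scale
      idx <- if (nrow(dd) > 800L) sort(sample.int(nrow(dd), 800L)) else seq_len(nrow(dd))
      residual_correlogram(res[idx], cbind(dd$x, dd$y)[idx, , drop = FALSE],
                           bin_width = max_dist / 20, max_dist = max_dist)
    })
    sar <- estimate_sar(cgs)
    block_size <- max(1.25 * sar, 2 * r1$cellsize)
  }
  evals <- list(); full_fits <- list()
  for (fam in families) {
    for (d in pa_sets) {
      dd <- get_pred(d)
      fold <- checkerboard_folds(dd, block_size,
                                 origin = c(stack[[1L]]$xmin, stack[[1L]]$ymin))
      b <- t <- numeric(2L)
      for (k in 1:2) {
        tr <- dd[fold != k, , drop = FALSE]
        te <- dd[fold == k, , drop = FALSE]
        fit_k <- fit_learner(tr, fam, predictors = names(stack),
                             gbm_trees = gbm_trees, seed = seed + k)
        p_te <- predict(fit_k, te)
        bg <- predict(fit_k, as.data.frame(sm))
        b[k] <- tryCatch(boyce_index(p_te[te$label == 1L], bg),
                         error = function(e) NA_real_)
        t[k] <- tss(p_te, te$label)
      }
      full <- fit_learner(dd, fam, predictors = names(stack),
                          gbm_trees = gbm_trees, seed = seed)
      full$boyce <- mean(b, na.rm = TRUE)
      full$tss <- mean(t)
      full$replicate <- d$replicate[1L]
      full_fits[[length(full_fits) + 1L]] <- full
      evals[[length(evals) + 1L]] <-
        data.frame(family = fam, replicate = d$replicate[1L],
                   boyce = full$boyce, tss = full$tss)
    }
  }
  ens <- build_ensemble(full_fits, boyce_min, tss_min)
  structure(list(ensemble = ens, suitability = predict_raster(ens, stack),
                 evaluations = do.call(rbind, evals), block_size = block_size,
                 sar = sar, pa_sets = pa_sets, envelope = env),
            class = "enm_result")
}
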