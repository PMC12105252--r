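make_clim_stack <- function(n = 2000, nr = 40, nc = 50, seed = 90) {
  set.seed(seed)
  raster_stack(c1 = grid_raster(matrix(rnorm(nr * nc), nr, nc), cellsize = 10),
               c2 = grid_raster(matrix(rnorm(nr * nc), nr, nc), cellsize = 10))
}

test_that("SRE envelope bounds are the presence quantiles", {
  st <- make_clim_stack()
  cells <- seq(1, 2000, by = 20)
  xy <- cell_centers(st[[1]], cells)
  occ <- occurrence_set(xy[, 1], xy[, 2])
  vals <- extract_at_points(st, occ)
  env0 <- build_sre_envelope(occ, st, q = 0)
  expect_equal(unname(env0$lower), unname(apply(vals[, c("c1", "c2")], 2, min)))
  expect_equal(unname(env0$upper), unname(apply(vals[, c("c1", "c2")], 2, max)))
  # quantile formula on 1..100: q = 0.025 -> (3.475, 97.525), type 7
  v100 <- grid_raster(matrix(1:100 * 1.0, 10, 10), cellsize = 10)
  st100 <- raster_stack(v = v100)
  xy100 <- cell_centers(v100)
  occ100 <- occurrence_set(xy100[, 1], xy100[, 2])
  env <- build_sre_envelope(occ100, st100, q = 0.025)
  expect_equal(unname(env$lower), 3.475)
  expect_equal(unname(env$upper), 97.525)
  expect_error(build_sre_envelope(occ100[1:5, ], st100), "20 presences")
  expect_error(build_sre_envelope(occ100, st100, q = 0.7), "q must be")
})

test_that("pseudo-absences fall outside the envelope with equalising weights", {
  st <- make_clim_stack(seed = 91)
  # presences in the climatic core so plenty of cells lie outside the envelope
  m <- stack_matrix(st)
  core <- which(abs(m[, 1]) < 0.5 & abs(m[, 2]) < 0.5)
  xy <- cell_centers(st[[1]], core[seq_len(min(300L, length(core)))])
  occ <- occurrence_set(xy[, 1], xy[, 2])
  env <- build_sre_envelope(occ, st, q = 0.025)
  sets <- draw_pseudoabsences(env, st, occ, n = 400, n_sets = 3, seed = 7)
  expect_length(sets, 3L)
  inside <- sre_inside(env, st)
  for (d in sets) {
    pa <- d[d$label == 0, ]
    expect_equal(nrow(pa), 400L)
    cells <- cell_from_xy(st[[1]], pa$x, pa$y)
    expect_false(any(inside[cells]))
    expect_false(any(duplicated(cells)))
    # each pseudo-absence weighs n_pres / n
    expect_equal(unique(pa$weight), nrow(occ) / 400)
    expect_equal(sum(pa$weight), sum(d$weight[d$label == 1]))
    # presence rows identical across replicates
    expect_identical(d[d$label == 1, c("x", "y")], sets[[1]][sets[[1]]$label == 1, c("x", "y")])
  }
  expect_error(draw_pseudoabsences(env, st, occ, n = 10^6), "outside the envelope")
})

test_that("learners fit, respect weights, and reject degenerate inputs", {
  set.seed(95)
  n <- 300
  x <- c(runif(n, 1, 3), runif(n, -3, -1))   # perfectly separable in 1-D
  d <- data.frame(label = rep(1:0, each = n), weight = 1, p1 = x,
                  cst = 5)
  expect_warning(fit <- fit_learner(d, "glm"), "constant")
  p <- predict(fit, d)
  expect_true(all(p[d$label == 1] >= 0.99))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(fit_learner(d[d$label == 1, ], "glm", predictors = "p1"),
               "single class")
  # determinism: duplicated presence rows get identical predictions
  d2 <- rbind(d[1, ], d)
  expect_equal(predict(fit, d2)[1], predict(fit, d2)[2])
  for (fam in c("gbm", "rf")) {
    f <- fit_learner(d, fam, predictors = "p1", gbm_trees = 200L,
                     rf_trees = 100L, seed = 9)
    pf <- predict(f, d)
    expect_true(all(pf >= 0 & pf <= 1))
    expect_gt(mean(pf[d$label == 1]), mean(pf[d$label == 0]))
  }
})

test_that("an uninformative learner scores near-zero CV Boyce", {
  set.seed(96)
  st <- make_clim_stack(seed = 97)
  m <- stack_matrix(st)
  bs <- replicate(20, {
    cells <- sample(nrow(m), 120)
    te_cells <- sample(nrow(m), 120)
    d <- data.frame(label = rbinom(120, 1, 0.5), weight = 1,
                    c1 = m[cells, 1], c2 = m[cells, 2])
    if (length(unique(d$label)) < 2) return(NA_real_)
    f <- fit_learner(d, "glm")
    pres <- te_cells[seq_len(60)]
    tryCatch(boyce_index(predict(f, data.frame(c1 = m[pres, 1], c2 = m[pres, 2])),
                         predict(f, as.data.frame(m))),
             error = function(e) NA_real_)
  })
  expect_lt(abs(mean(bs, na.rm = TRUE)), 0.3)
})

test_that("ensemble weighting follows the Boyce index with strict gates", {
  mk <- function(b, t) structure(list(family = "glm", boyce = b, tss = t),
                                 class = "sdm_fit")
  ens <- build_ensemble(list(mk(0.8, 0.6), mk(0.9, 0.6)))
  expect_equal(ens$weights, c(0.8, 0.9) / 1.7, tolerance = 1e-9)
  expect_equal(round(ens$weights, 4), c(0.4706, 0.5294))
  one <- build_ensemble(list(mk(0.8, 0.6), mk(0.2, 0.6)))
  expect_equal(one$weights, 1)
  eq <- build_ensemble(list(mk(0.75, 0.6), mk(0.75, 0.55)))
  expect_equal(eq$weights, c(0.5, 0.5))
  # Boyce exactly at the threshold is excluded (strict inequality)
  expect_error(build_ensemble(list(mk(0.7, 0.9), mk(0.65, 0.9))), "no model")
  expect_error(build_ensemble(list(mk(0.9, 0.5))), "no model")
})

test_that("ensemble predictions are convex combinations of member predictions", {
  set.seed(98)
  n <- 200
  d <- data.frame(label = rbinom(n, 1, 0.5), weight = 1,
                  a = rnorm(n), b = rnorm(n))
  d$label[1:10] <- 1; d$label[11:20] <- 0
  m1 <- fit_learner(d, "glm"); m1$boyce <- 0.8; m1$tss <- 0.6
  m2 <- fit_learner(d, "rf", rf_trees = 50L); m2$boyce <- 0.9; m2$tss <- 0.6
  ens <- build_ensemble(list(m1, m2))
  newd <- data.frame(a = rnorm(50), b = rnorm(50))
  pe <- predict(ens, newd)
  p1 <- predict(m1, newd); p2 <- predict(m2, newd)
  expect_true(all(pe >= pmin(p1, p2) - 1e-12 & pe <= pmax(p1, p2) + 1e-12))
  expect_true(all(pe >= 0 & pe <= 1))
})

test_that("permutation importance isolates the informative variable", {
  set.seed(99)
  st <- make_clim_stack(seed = 99)
  m <- stack_matrix(st)
  cells <- sample(nrow(m), 400)
  d <- data.frame(label = rbinom(400, 1, plogis(3 * m[cells, 1])), weight = 1,
                  c1 = m[cells, 1], c2 = m[cells, 2])
  f <- fit_learner(d, "glm", predictors = "c1")
  f$boyce <- 0.9; f$tss <- 0.6
  ens <- build_ensemble(list(f))
  imp <- variable_importance(ens, st, n_perm = 3, seed = 5)
  expect_equal(sum(imp), 100)
  expect_equal(unname(imp["c1"]), 100)   # single-variable model
  expect_lt(unname(imp["c2"]), 2)
  # glm model truly driven by c1 only, but fitted on both: c2 still ~ 0
  f2 <- fit_learner(d, "glm")
  f2$boyce <- 0.9; f2$tss <- 0.6
  imp2 <- variable_importance(build_ensemble(list(f2)), st, n_perm = 3, seed = 5)
  expect_gt(unname(imp2["c1"]), 90)
  expect_error(variable_importance(ens, st, n_perm = 0), "n_perm")
})
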