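test_that("categorical transforms score classes by frequency ratio", {
  occ <- rep(1, 50)                         # all occurrences in class 1
  bg <- rep(1:3, c(50, 30, 20))
  tr <- frequency_transform(occ, bg, "categorical")
  expect_equal(unname(tr$mapping["1"]), 1)
  expect_equal(unname(tr$mapping["2"]), 0)
  # occurrence distribution equal to background -> flat scores
  occ2 <- rep(1:3, c(25, 15, 10))
  tr2 <- frequency_transform(occ2, bg, "categorical")
  expect_equal(unname(tr2$mapping), rep(1, 3), tolerance = 1e-12)
  # class absent from background scored 0, with a warning
  expect_warning(tr3 <- frequency_transform(c(rep(1, 40), rep(9, 10)), bg,
                                            "categorical"),
                 "absent")
  expect_equal(unname(tr3$mapping["9"]), 0)
})

test_that("decay transforms recover a known distance preference", {
  set.seed(130)
  bg <- runif(30000, 0, 2000)
  # occurrence density proportional to exp(-d / 300) against uniform background
  keep <- runif(30000) < exp(-bg / 300)
  occ <- bg[keep]
  tr <- frequency_transform(occ, bg, "decay", n_bins = 15)
  expect_lt(abs(tr$params$s - 300) / 300, 0.25)
  r <- grid_raster(matrix(c(0, 300, 900), 1, 3), cellsize = 10)
  sc <- apply_transform(tr, r)
  expect_equal(sc$values[1, 1], 1, tolerance = 1e-9)
  expect_true(all(diff(as.vector(sc$values)) < 0))
})

test_that("circular transforms treat 0 and 360 degrees as neighbours", {
  set.seed(131)
  # aspects wrapped around north: 350..360 and 0..10
  occ <- c(runif(40, 350, 360), runif(40, 0, 10))
  bg <- runif(5000, 0, 360)
  tr <- frequency_transform(occ, bg, "gaussian_circular")
  # wrap symmetry: equal angular offsets either side of the preferred
  # direction (close to north here) score identically
  ctr <- tr$center
  r <- grid_raster(matrix(c((ctr - 8) %% 360, (ctr + 8) %% 360, 90, 180), 1, 4))
  sc <- as.vector(apply_transform(tr, r)$values)
  expect_equal(sc[1], sc[2], tolerance = 1e-9)
  # preference decays away from the occupied sector
  expect_gt(sc[1], sc[3])
  expect_gt(sc[3], sc[4])
  expect_lt(sc[4], 0.05)
})

test_that("weighted overlay is an exact weighted mean with guarded weights", {
  g <- function(v) grid_raster(matrix(v, 2, 2))
  ls <- list(a = g(0.2), b = g(0.8))
  expect_equal(weighted_overlay(ls, c(a = 0.25, b = 0.75))$values,
               matrix(0.65, 2, 2))
  expect_equal(weighted_overlay(ls, c(a = 1, b = 0))$values, g(0.2)$values)
  same <- list(a = g(0.4), b = g(0.4), c = g(0.4))
  expect_equal(weighted_overlay(same, c(a = .2, b = .5, c = .3))$values,
               matrix(0.4, 2, 2))
  expect_error(weighted_overlay(ls, c(a = 0.5, b = 0.6)), "sum to 1")
  # nodata propagates
  na_l <- g(0.5); na_l$values[1, 1] <- NA
  out <- weighted_overlay(list(a = na_l, b = g(1)), c(a = 0.5, b = 0.5))
  expect_true(is.na(out$values[1, 1]))
})

test_that("overlay is monotone in any input layer", {
  set.seed(132)
  w <- c(a = 0.3, b = 0.45, c = 0.25)
  base <- lapply(1:3, function(i) grid_raster(matrix(runif(25), 5, 5)))
  names(base) <- names(w)
  out0 <- weighted_overlay(base, w)
  bumped <- base
  bumped$b$values[3, 3] <- bumped$b$values[3, 3] + 0.2
  out1 <- weighted_overlay(bumped, w)
  expect_true(all(out1$values >= out0$values))
})

test_that("future fine-scale projection swaps only the climatic layer", {
  set.seed(133)
  w <- c(enm = 0.4, habitat = 0.3, dist_stream = 0.3)
  fixed <- list(habitat = grid_raster(matrix(runif(16), 4, 4)),
                dist_stream = grid_raster(matrix(runif(16), 4, 4)))
  enm_now <- grid_raster(matrix(runif(16), 4, 4))
  now <- project_fine_future(fixed, enm_now, w)
  expect_equal(now$values,
               weighted_overlay(c(list(enm = enm_now), fixed), w)$values)
  # identical ENM layer -> identical output
  expect_equal(project_fine_future(fixed, enm_now, w)$values, now$values)
  # zero future ENM drops output by exactly w_enm * present contribution
  fut <- project_fine_future(fixed, rast_like(enm_now, 0), w)
  expect_equal(now$values - fut$values, 0.4 * enm_now$values, tolerance = 1e-12)
  # scenario batch: one output per scenario
  scen <- enumerate_scenarios(c(2030, 2050, 2070),
                              c("1.26", "2.45", "3.70", "5.85"),
                              c("g1", "g2"))
  outs <- lapply(seq_len(nrow(scen)), function(i)
    project_fine_future(fixed, enm_now, w))
  expect_length(outs, 24L)
})

test_that("Boyce validation of a truth raster on its own occurrences is high", {
  # larger grid so without-replacement sampling does not saturate the
  # high-suitability cells and flatten the P/E profile
  L <- tiny_landscape(seed = 19L, shape = c(70L, 70L))
  vs <- virtual_species(L$clim$present)
  suit <- vs$true_suitability
  occ <- sample_occurrences(vs, seed = 9L, n = 150L)
  expect_gt(validate_boyce(suit, occ), 0.7)
  # counter prediction flips the sign
  rev <- rast_like(suit, max(suit$values) - suit$values)
  expect_lt(validate_boyce(rev, occ), 0)
  # uniform occurrences carry no signal
  set.seed(10)
  bs <- replicate(20, {
    cells <- sample(length(suit$values), 200)
    xy <- cell_centers(suit, cells)
    validate_boyce(suit, occurrence_set(xy[, 1], xy[, 2]))
  })
  expect_lt(abs(mean(bs)), 0.3)
})

test_that("weighting fine-scale layers into the ENM improves truth recovery", {
  # truth built from the same families the overlay uses: climate logistic
  # down-weighted by distance-to-water decay and a habitat bonus. The
  # climatic ENM is *estimated* from the occurrences (climate only), so the
  # fitted water/habitat transforms carry signal the ENM cannot see.
  spearman <- function(a, b) suppressWarnings(cor(a, b, method = "spearman"))
  wins <- 0L
  for (seed in 1:10) {
    cfg <- landscape_config(grid_shape = c(35L, 35L), cell_size = 100,
                            n_climate_vars = 2L, autocorr_range = 900,
                            seed = 100L + seed)
    clim <- generate_climate_stack(cfg)
    wmask <- withr::with_seed(seed, {
      w <- rast_like(clim$present[[1]], 0)
      w$values[sample(length(w$values), 6)] <- 1
      w
    })
    dwat <- euclidean_distance(wmask)
    hab <- withr::with_seed(seed + 500L,
      rast_like(clim$present[[1]], matrix(rbinom(35 * 35, 1, 0.4), 35, 35)))
    vs <- virtual_species(clim$present, dist_water = dwat, habitat = hab,
                          water_decay = 1200, habitat_class = 1L,
                          habitat_bonus = 0.4)
    truth <- as.vector(vs$true_suitability$values)
    occ <- sample_occurrences(vs, seed = 200L + seed, n = 120L)
    # climate-only ENM estimated from the occurrences + random background
    m <- stack_matrix(clim$present)
    cells <- cell_from_xy(clim$present[[1]], occ$x, occ$y)
    bgc <- withr::with_seed(seed + 900L, sample(nrow(m), 300))
    d <- rbind(data.frame(label = 1L, weight = 1, m[cells, , drop = FALSE]),
               data.frame(label = 0L, weight = 120 / 300,
                          m[bgc, , drop = FALSE]))
    enm_fit <- fit_learner(d, "glm")
    enm_est <- predict_raster(enm_fit, clim$present)
    ex_w <- extract_at_points(raster_stack(d = dwat), occ)$d
    tr_w <- frequency_transform(ex_w, as.vector(dwat$values), "decay")
    ex_h <- extract_at_points(raster_stack(h = hab), occ)$h
    tr_h <- frequency_transform(ex_h, as.vector(hab$values), "categorical")
    overlay <- weighted_overlay(
      list(enm = enm_est, dist_water = apply_transform(tr_w, dwat),
           habitat = apply_transform(tr_h, hab)),
      c(enm = 0.5, dist_water = 0.3, habitat = 0.2))
    s_enm <- spearman(as.vector(enm_est$values), truth)
    s_ovl <- spearman(as.vector(overlay$values), truth)
    if (s_ovl >= s_enm) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
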