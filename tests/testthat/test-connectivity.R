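test_that("suitability normalisation and barrier burning behave as mosaics", {
  r <- grid_raster(matrix(c(10, 20, 30), 1, 3))
  expect_equal(as.vector(normalize_suitability(r)$values), c(0, 0.5, 1))
  unit <- grid_raster(matrix(c(0, 0.5, 1), 1, 3))
  expect_equal(normalize_suitability(unit)$values, unit$values)
  expect_error(normalize_suitability(grid_raster(matrix(2, 2, 2))), "constant")

  s <- grid_raster(matrix(1, 10, 10), cellsize = 10)
  expect_equal(burn_barriers(s)$values, s$values)       # empty set: identity
  road <- list(cbind(c(0, 100), c(55, 55)))             # full-row road
  b <- burn_barriers(s, roads = road)
  expect_true(all(b$values[5, ] == 0))
  expect_true(all(b$values[-5, ] == 1))
  urb <- list(cbind(c(20, 50, 50, 20), c(20, 20, 50, 50)))
  b2 <- burn_barriers(s, urban = urb)
  expect_equal(sum(b2$values == 0), 9)                  # 3x3 cell centres inside
})

test_that("negative-exponential resistance transform hits its endpoints", {
  h <- grid_raster(matrix(seq(0, 1, length.out = 1001), 1, 1001))
  r <- suitability_to_resistance(h, c = 4)
  v <- as.vector(r$values)
  expect_equal(v[1], 100)
  expect_equal(v[1001], 1)
  expect_true(all(diff(v) < 0))                         # strictly decreasing
  mid <- 100 - 99 * (1 - exp(-4 * 0.5)) / (1 - exp(-4))
  expect_equal(v[501], mid, tolerance = 1e-12)
  expect_error(suitability_to_resistance(grid_raster(matrix(1.2, 1, 1))),
               "0, 1")
})

test_that("grid-graph conductances follow the mean-resistance rule", {
  r <- grid_raster(matrix(c(2, 1, 4, 1), 2, 2))   # R[1,1]=2 R[2,1]=1 R[1,2]=4
  g <- build_grid_graph(r, 8)
  e <- g$edges
  pick <- function(i, j) e$conductance[(e$i == i & e$j == j) | (e$i == j & e$j == i)]
  expect_equal(pick(1, 3), 1 / 3)                  # rook R=(2,4) -> 1/mean = 1/3
  expect_equal(pick(1, 2), 1 / 1.5)                # R=(2,1)
  expect_equal(pick(1, 4), 1 / (1.5 * sqrt(2)))    # diagonal R=(2,1)
  expect_equal(pick(2, 3), 1 / (2.5 * sqrt(2)))    # anti-diagonal R=(1,4)
  runit <- grid_raster(matrix(1, 1, 2))
  expect_equal(build_grid_graph(runit, 4)$edges$conductance, 1)
  d24 <- build_grid_graph(grid_raster(matrix(c(2, 999, 999, 4), 2, 2)), 8)
  dg <- d24$edges[d24$edges$i == 1 & d24$edges$j == 4, "conductance"]
  expect_equal(dg, 1 / (3 * sqrt(2)), tolerance = 1e-12)
})

test_that("series, parallel and triangle circuits match closed forms", {
  # 1x3 uniform grid: middle cell carries the full ampere
  res <- grid_raster(matrix(1, 1, 3))
  g <- build_grid_graph(res, 4)
  cm <- solve_pairwise(g, c(1, 3))
  expect_equal(as.vector(cm$current$values), c(1, 1, 1), tolerance = 1e-10)
  expect_equal(cm$effective_resistance, 2, tolerance = 1e-10)
  # two-node single edge of conductance g -> R_eff = 1/g
  g2 <- make_graph(2, data.frame(i = 1, j = 2, conductance = 0.25))
  expect_equal(effective_resistance(g2, 1, 2), 4, tolerance = 1e-12)
  # two parallel 2-edge unit-resistance paths -> R_eff = 1
  g3 <- make_graph(4, data.frame(i = c(1, 3, 1, 4), j = c(3, 2, 4, 2),
                                 conductance = 1))
  expect_equal(effective_resistance(g3, 1, 2), 1, tolerance = 1e-12)
  # triangle of unit resistors -> 2/3 between any pair
  tri <- make_graph(3, data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                                  conductance = 1))
  for (p in list(c(1, 2), c(2, 3), c(1, 3)))
    expect_equal(effective_resistance(tri, p[1], p[2]), 2 / 3,
                 tolerance = 1e-12)
})

test_that("pairwise solutions match the dense pseudoinverse oracle", {
  skip_if_not_installed("MASS")
  set.seed(140)
  for (trial in 1:20) {
    nr <- sample(3:8, 1); nc <- sample(3:8, 1)
    R <- matrix(exp(rnorm(nr * nc, 1, 0.8)), nr, nc)
    res <- grid_raster(R)
    g <- build_grid_graph(res, sample(c(4L, 8L), 1))
    nodes <- sort(sample(g$n, sample(2:5, 1)))
    cm <- solve_pairwise(g, nodes)
    pairs <- combn(nodes, 2)
    cum <- numeric(g$n); eff <- numeric(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      v <- oracle_circuit_potentials(g$n, g$edges, pairs[1, k], pairs[2, k])
      cum <- cum + oracle_node_current(g$n, g$edges, v, pairs[1, k], pairs[2, k])
      eff[k] <- v[pairs[1, k]] - v[pairs[2, k]]
    }
    expect_equal(as.vector(cm$current$values)[g$cells], cum, tolerance = 1e-8)
    expect_equal(cm$effective_resistance, eff, tolerance = 1e-8)
  }
})

test_that("current is conserved and symmetric layouts give symmetric maps", {
  # Kirchhoff balance at non-focal nodes
  set.seed(141)
  res <- grid_raster(matrix(exp(rnorm(36, 1, 0.5)), 6, 6))
  g <- build_grid_graph(res, 8)
  nodes <- c(1, 36)
  cm <- solve_pairwise(g, nodes)
  # recompute potentials to check net flow directly
  v <- oracle_circuit_potentials(g$n, g$edges, 1, 36)
  net <- numeric(g$n)
  for (k in seq_len(nrow(g$edges))) {
    i <- g$edges$i[k]; j <- g$edges$j[k]
    f <- g$edges$conductance[k] * (v[i] - v[j])
    net[i] <- net[i] - f; net[j] <- net[j] + f
  }
  expect_lt(max(abs(net[-nodes])), 1e-8)
  expect_equal(net[1], -1, tolerance = 1e-8)
  expect_equal(net[36], 1, tolerance = 1e-8)
  # mirror-symmetric resistance grid -> mirror-symmetric current map
  Rm <- matrix(1, 5, 5); Rm[, 3] <- 5
  gs <- build_grid_graph(grid_raster(Rm), 4)
  cms <- solve_pairwise(gs, snap_nodes(gs, data.frame(x = c(0.5, 4.5), y = 2.5)))
  M <- cms$current$values
  expect_equal(M, M[5:1, ], tolerance = 1e-10)     # up-down mirror
  expect_equal(M, M[, 5:1], tolerance = 1e-10)     # left-right mirror
})

test_that("Rayleigh monotonicity and resistance scaling hold", {
  set.seed(142)
  R <- matrix(exp(rnorm(25, 1, 0.5)), 5, 5)
  g <- build_grid_graph(grid_raster(R), 8)
  base <- effective_resistance(g, 1, 25)
  # raising one cell's resistance never lowers effective resistance
  for (cell in c(7, 13, 19)) {
    R2 <- R; R2[cell] <- R2[cell] * 5
    g2 <- build_grid_graph(grid_raster(R2), 8)
    expect_gte(effective_resistance(g2, 1, 25), base - 1e-12)
  }
  # scaling all resistances by k scales R_eff by k, leaves currents unchanged
  k <- 3.7
  gk <- build_grid_graph(grid_raster(k * R), 8)
  expect_equal(effective_resistance(gk, 1, 25), k * base, tolerance = 1e-10)
  n1 <- solve_pairwise(g, c(1, 25))$current$values
  n2 <- solve_pairwise(gk, c(1, 25))$current$values
  expect_equal(n1, n2, tolerance = 1e-10)
})

test_that("focal nodes in different components are rejected by name", {
  R <- matrix(1, 3, 3); R[, 2] <- NA          # wall of nodata splits the grid
  g <- build_grid_graph(grid_raster(R), 4)
  expect_error(solve_pairwise(g, c(1, 4)), "components")
  g4 <- make_graph(4, data.frame(i = c(1, 3), j = c(2, 4), conductance = 1))
  expect_warning(r <- effective_resistance(g4, 1, 3), "disconnected")
  expect_equal(r, Inf)
})

test_that("pair budget subsampling and per-pair averaging stay consistent", {
  res <- grid_raster(matrix(1, 4, 4))
  g <- build_grid_graph(res, 8)
  full <- solve_pairwise(g, c(1, 6, 11, 16))
  expect_equal(full$n_pairs, 6L)
  capped <- solve_pairwise(g, c(1, 6, 11, 16), max_pairs = 3L)
  expect_equal(capped$n_pairs, 3L)
  avg <- solve_pairwise(g, c(1, 6, 11, 16), per_pair_mean = TRUE)
  expect_equal(avg$current$values * 6, full$current$values, tolerance = 1e-12)
})
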