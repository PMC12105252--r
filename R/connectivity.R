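#' Min-max normalise a suitability raster to [0, 1]
#' @param sdm `grid_raster`; must not be constant over valid cells.
#' @return `grid_raster` with valid values spanning [0, 1].
#' @export
normalize_suitability <- function(sdm) {
  v <- sdm$values
  rng <- range(v[is.finite(v)])
  if (diff(rng) <= 0) stop("normalize_suitability: constant raster")
  rast_like(sdm, (v - rng[1L]) / diff(rng))
}

#' Burn movement barriers into a suitability raster
#'
#' Cells crossed by roads or covered by urban polygons are set to
#' suitability 0 (hence maximum resistance after the transform), a mosaic
#' overwrite; all other cells are unchanged.
#'
#' @param suitability `grid_raster` in [0, 1].
#' @param roads list of polylines (two-column matrices), may be empty.
#' @param urban list of polygons, may be empty.
#' @return `grid_raster`.
#' @export
burn_barriers <- function(suitability, roads = list(), urban = list()) {
  v <- suitability$values
  if (length(roads)) {
    m <- rasterize_lines(roads, suitability)
    v[m$values != 0] <- 0
  }
  if (length(urban)) {
    m <- rasterize_polygons(urban, suitability)
    v[m$values != 0] <- 0
  }
  rast_like(suitability, v)
}

#' Negative-exponential suitability-to-resistance transform
#'
#' `R(h) = 100 - 99 * (1 - exp(-c h)) / (1 - exp(-c))`: a strictly decreasing
#' map from habitat suitability h in [0, 1] to movement resistance on
#' [1, 100], with R(0) = 100 and R(1) = 1. Larger `c` makes resistance drop
#' faster with suitability; c = 4 is the conventional choice for
#' habitat-specialist dispersal.
#'
#' @param h suitability `grid_raster` with values in [0, 1].
#' @param c transform constant (> 0), default 4.
#' @return resistance `grid_raster` on [1, 100].
#' @export
suitability_to_resistance <- function(h, c = 4) {
  stopifnot(c > 0)
  v <- h$values
  ok <- is.finite(v)
  if (any(v[ok] < 0 | v[ok] > 1))
    stop("suitability_to_resistance: suitability must lie in [0, 1]")
  rast_like(h, 100 - 99 * (1 - exp(-c * v)) / (1 - exp(-c)))
}

#' Build the weighted grid graph of a resistance surface
#'
#' One node per valid (non-NA) cell; edges join rook and (for
#' `neighborhood = 8`) diagonal neighbours with conductance
#' `1 / mean(R_i, R_j)`, diagonal conductances further divided by sqrt(2)
#' for the longer centre-to-centre distance.
#'
#' @param res resistance `grid_raster` (values > 0).
#' @param neighborhood 4 or 8 (default 8).
#' @return list of class `grid_graph`: `cells` (raster cell index per node),
#'   `edges` (data.frame i, j, conductance), `n`, plus the template raster.
#' @export
build_grid_graph <- function(res, neighborhood = 8L) {
  stopifnot(neighborhood %in% c(4L, 8L))
  R <- res$values
  nr <- nrow(R); nc <- ncol(R)
  valid <- is.finite(R)
  if (sum(valid) < 2L) stop("build_grid_graph: fewer than 2 valid cells")
  if (any(R[valid] <= 0)) stop("build_grid_graph: resistances must be > 0")
  node <- matrix(NA_integer_, nr, nc)
  node[valid] <- seq_len(sum(valid))
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (neighborhood == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  ei <- list(); ej <- list(); ec <- list()
  for (o in offs) {
    r0 <- seq_len(nr - abs(o[1L])) + max(0L, -o[1L]) * 0L
    rows <- if (o[1L] >= 0L) seq_len(nr - o[1L]) else seq_len(nr + o[1L]) - o[1L]
    cols <- if (o[2L] >= 0L) seq_len(nc - o[2L]) else seq_len(nc + o[2L]) - o[2L]
    a <- node[rows, cols, drop = FALSE]
    b <- node[rows + o[1L], cols + o[2L], drop = FALSE]
    Ra <- R[rows, cols, drop = FALSE]
    Rb <- R[rows + o[1L], cols + o[2L], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    cond <- 1 / ((Ra[ok] + Rb[ok]) / 2)
    if (sum(abs(o)) == 2L) cond <- cond / sqrt(2)
    ei[[length(ei) + 1L]] <- a[ok]; ej[[length(ej) + 1L]] <- b[ok]
    ec[[length(ec) + 1L]] <- cond
  }
  structure(list(cells = which(valid), n = sum(valid),
                 edges = data.frame(i = unlist(ei), j = unlist(ej),
                                    conductance = unlist(ec)),
                 template = rast_like(res, NA_real_)),
            class = "grid_graph")
}

#' Weighted graph from explicit edges (for small test circuits)
#' @param n node count.
#' @param edges data.frame i, j, conductance.
#' @return `grid_graph` without a raster template.
#' @export
make_graph <- function(n, edges) {
  structure(list(cells = seq_len(n), n = as.integer(n),
                 edges = edges, template = NULL),
            class = "grid_graph")
}

graph_laplacian <- function(graph) {
  e <- graph$edges
  A <- Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                            x = c(e$conductance, e$conductance),
                            dims = c(graph$n, graph$n))
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

graph_components <- function(graph) {
  # BFS over adjacency lists
  adj <- vector("list", graph$n)
  e <- graph$edges
  for (k in seq_len(nrow(e))) {
    adj[[e$i[k]]] <- c(adj[[e$i[k]]], e$j[k])
    adj[[e$j[k]]] <- c(adj[[e$j[k]]], e$i[k])
  }
  comp <- rep(NA_integer_, graph$n); cid <- 0L
  for (s in seq_len(graph$n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[is.na(comp[nb])]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp
}

#' Snap focal points to graph nodes
#'
#' Occurrences snap to their containing cell; coincident points collapse to
#' one node. Points on nodata (off-graph) cells are an error.
#' @param graph a `grid_graph` built from a raster.
#' @param occ `occurrence_set` or data.frame with x, y.
#' @return integer vector of unique node indices.
#' @export
snap_nodes <- function(graph, occ) {
  if (is.null(graph$template)) stop("snap_nodes: graph has no raster template")
  cells <- cell_from_xy(graph$template, occ$x, occ$y)
  node <- match(cells, graph$cells)
  if (anyNA(node))
    stop("snap_nodes: points on nodata/barrier-excluded cells at rows ",
         paste(which(is.na(node)), collapse = ", "))
  sort(unique(node))
}

#' Pairwise current-flow connectivity
#'
#' For every unordered pair of focal nodes, 1 A is injected at the source and
#' extracted at the destination; node potentials solve the graph Laplacian
#' system (sparse Cholesky, factorised once per graph). Per-cell current is
#' half the sum of absolute currents on incident edges (the full 1 A at the
#' two focal cells); the cumulative map sums over all pairs. Current is
#' conserved at every non-focal node to solver tolerance.
#'
#' @param graph a `grid_graph`.
#' @param nodes integer node indices (e.g. from [snap_nodes()]); all must lie
#'   in one connected component.
#' @param max_pairs optional cap: if the pair count exceeds it, a
#'   deterministic evenly spaced subsample of pairs is used.
#' @param per_pair_mean divide the cumulative map by the number of pairs
#'   (needed when comparing maps across node sets).
#' @return list of class `current_map`: `current` (raster if the graph has a
#'   template, else per-node vector), `n_pairs`, `nodes`,
#'   `effective_resistance` (per solved pair).
#' @export
solve_pairwise <- function(graph, nodes, max_pairs = NULL,
                           per_pair_mean = FALSE) {
  nodes <- sort(unique(as.integer(nodes)))
  if (length(nodes) < 2L) stop("solve_pairwise: need at least 2 focal nodes")
  comp <- graph_components(graph)
  if (length(unique(comp[nodes])) > 1L)
    stop("solve_pairwise: focal nodes fall in different components: ",
         paste(sprintf("node %d in component %d", nodes, comp[nodes]),
               collapse = "; "))
  keep <- which(comp == comp[nodes[1L]])
  remap <- match(seq_len(graph$n), keep)
  e <- graph$edges[comp[graph$edges$i] == comp[nodes[1L]], , drop = FALSE]
  sub <- make_graph(length(keep),
                    data.frame(i = remap[e$i], j = remap[e$j],
                               conductance = e$conductance))
  L <- graph_laplacian(sub)
  ns <- remap[nodes]
  ground <- ns[1L]
  Lr <- L[-ground, -ground, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lr), LDL = FALSE, perm = TRUE)
  solve_pot <- function(s, t) {
    b <- numeric(sub$n)
    b[s] <- b[s] + 1; b[t] <- b[t] - 1
    v <- numeric(sub$n)
    v[-ground] <- as.numeric(Matrix::solve(ch, b[-ground]))
    v
  }
  pairs <- utils::combn(ns, 2L)
  if (!is.null(max_pairs) && ncol(pairs) > max_pairs) {
    idx <- unique(round(seq(1L, ncol(pairs), length.out = max_pairs)))
    pairs <- pairs[, idx, drop = FALSE]
  }
  cum <- numeric(sub$n)
  eff <- numeric(ncol(pairs))
  ei <- sub$edges$i; ej <- sub$edges$j; g <- sub$edges$conductance
  for (k in seq_len(ncol(pairs))) {
    s <- pairs[1L, k]; t <- pairs[2L, k]
    v <- solve_pot(s, t)
    iedge <- abs(g * (v[ei] - v[ej]))
    node_cur <- numeric(sub$n)
    agg_i <- rowsum(iedge, ei); agg_j <- rowsum(iedge, ej)
    node_cur[as.integer(rownames(agg_i))] <- agg_i[, 1L]
    node_cur[as.integer(rownames(agg_j))] <-
      node_cur[as.integer(rownames(agg_j))] + agg_j[, 1L]
    node_cur <- node_cur / 2
    node_cur[c(s, t)] <- 1
    cum <- cum + node_cur
    eff[k] <- v[s] - v[t]
  }
  if (per_pair_mean) cum <- cum / ncol(pairs)
  out_nodes <- rep(NA_real_, graph$n)
  out_nodes[keep] <- cum
  current <- if (!is.null(graph$template)) {
    r <- graph$template
    v <- as.vector(r$values)
    v[graph$cells] <- out_nodes
    rast_like(r, v)
  } else out_nodes
  structure(list(current = current, n_pairs = ncol(pairs), nodes = nodes,
                 effective_resistance = eff),
            class = "current_map")
}

#' Effective resistance between two nodes
#'
#' Potential difference under a unit current injection; infinite (with a
#' warning) for disconnected nodes.
#' @param graph a `grid_graph`.
#' @param s,t node indices.
#' @return resistance in ohms.
#' @export
effective_resistance <- function(graph, s, t) {
  comp <- graph_components(graph)
  if (comp[s] != comp[t]) {
    warning("effective_resistance: nodes are disconnected")
    return(Inf)
  }
  solve_pairwise(graph, c(s, t))$effective_resistance[1L]
}
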