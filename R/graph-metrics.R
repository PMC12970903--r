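# Sparsity-thresholded binary graph topology.
#
# Weighted individual SCNs are binarized at each sparsity level K (fraction
# of strongest edges retained), global and nodal metrics are evaluated per
# K, and each metric is summarized across the grid by the trapezoidal area
# under the curve. Distances and betweenness are delegated to igraph; the
# clustering / path-length / efficiency conventions (exclusion of
# disconnected pairs, zero for isolated nodes) are implemented here.

#' Sparsity grid for network binarization
#'
#' @param k_min,k_max,step Grid bounds and spacing as edge-density
#'   fractions. Defaults (0.14, 0.50, 0.01; 37 levels) are the range within
#'   which thresholded covariance networks typically stay connected and
#'   small-world.
#' @return Object of class `sparsity_grid`: list with `k_min`, `k_max`,
#'   `step`, and the ordered `values`.
#' @export
sparsity_grid <- function(k_min = 0.14, k_max = 0.50, step = 0.01) {
  if (!(k_min > 0 && k_min < k_max && k_max < 1)) {
    stopf("need 0 < k_min < k_max < 1")
  }
  if (step <= 0) stopf("step must be > 0")
  values <- seq(k_min, k_max, by = step)
  structure(list(k_min = k_min, k_max = k_max, step = step, values = values),
            class = "sparsity_grid")
}

as_weight_matrix <- function(x) {
  if (inherits(x, "individual_scn") || inherits(x, "group_scn")) x$matrix
  else as.matrix(x)
}

#' Binarize a weighted network at sparsity K
#'
#' Retains the `round(K * n(n-1)/2)` edges of largest weight (absolute value
#' by default, signed value with `mode = "positive"`), rounding half away
#' from zero. Ties at the cutoff are broken by lexicographic (row, column)
#' order for determinism. Edge sets are nested across increasing K.
#'
#' @param scn An `individual_scn`, `group_scn`, or symmetric weight matrix.
#' @param k Sparsity in (0, 1).
#' @param mode `"absolute"` (rank by |weight|) or `"positive"` (signed).
#' @return Object of class `binary_network`: list with 0/1 `adjacency`
#'   (symmetric, zero diagonal), `k`, and `n_edges`.
#' @export
binarize <- function(scn, k, mode = c("absolute", "positive")) {
  mode <- match.arg(mode)
  w <- as_weight_matrix(scn)
  stopifnot(is_square_symmetric(w, tol = 1e-6))
  if (!(k > 0 && k < 1)) stopf("sparsity k must be in (0, 1)")
  n <- nrow(w)
  pairs <- which(upper.tri(w), arr.ind = TRUE)
  key <- if (mode == "absolute") abs(w[pairs]) else w[pairs]
  n_edges <- as.integer(round_half_up(k * n * (n - 1) / 2))
  if (n_edges < 1) stopf("sparsity k = %g yields zero edges for n = %d", k, n)
  n_edges <- min(n_edges, nrow(pairs))
  ord <- order(-key, pairs[, 1], pairs[, 2])
  keep <- pairs[ord[seq_len(n_edges)], , drop = FALSE]
  a <- matrix(0L, n, n, dimnames = dimnames(w))
  a[keep] <- 1L
  a[keep[, c(2, 1), drop = FALSE]] <- 1L
  structure(list(adjacency = a, k = k, n_edges = n_edges),
            class = "binary_network")
}

as_adjacency <- function(net) {
  if (inherits(net, "binary_network")) net$adjacency else as.matrix(net)
}

net_graph <- function(net) {
  igraph::graph_from_adjacency_matrix(as_adjacency(net), mode = "undirected",
                                      diag = FALSE)
}

#' Clustering coefficient (nodal and global)
#'
#' Per node: the fraction of its neighbor pairs that are themselves
#' connected, `2 * triangles / (degree * (degree - 1))`, defined as 0 for
#' degree < 2. Global Cp is the mean over all nodes.
#'
#' @param net A `binary_network` or 0/1 adjacency matrix.
#' @return List with `nodal` (per-node vector) and `global`.
#' @export
clustering_coefficient <- function(net) {
  a <- as_adjacency(net)
  d <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2
  nodal <- ifelse(d < 2, 0, 2 * tri / (d * (d - 1)))
  names(nodal) <- rownames(a)
  list(nodal = nodal, global = mean(nodal))
}

#' All-pairs shortest path lengths
#'
#' Unweighted breadth-first distances, expanded one hop at a time via
#' boolean matrix products (all sources simultaneously); unreachable pairs
#' are `Inf`.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @return Node x node distance matrix.
#' @export
shortest_path_lengths <- function(net) {
  a <- as_adjacency(net)
  n <- nrow(a)
  storage.mode(a) <- "double"
  d <- matrix(Inf, n, n, dimnames = dimnames(a))
  diag(d) <- 0
  reach <- a > 0
  d[reach] <- 1
  known <- reach | diag(TRUE, n)
  k <- 1
  while (any(reach)) {
    k <- k + 1
    reach <- (reach %*% a) > 0
    new <- reach & !known
    if (!any(new)) break
    d[new] <- k
    known <- known | new
  }
  d
}

#' Characteristic path length (nodal and global)
#'
#' Nodal Lp of node i is the mean shortest-path distance from i to the nodes
#' it can reach; unreachable pairs are excluded from every average rather
#' than assigned a surrogate distance (grid validation separately enforces
#' that networks stay essentially connected). A fully isolated node has
#' nodal Lp 0. Global Lp averages over all reachable ordered pairs.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @param dist Optional precomputed distance matrix.
#' @return List with `nodal`, `global`, and `n_unreachable_pairs` (ordered).
#' @export
characteristic_path_length <- function(net, dist = NULL) {
  d <- dist %||% shortest_path_lengths(net)
  diag(d) <- NA
  fin <- is.finite(d)
  nodal <- vapply(seq_len(nrow(d)), function(i) {
    di <- d[i, ][fin[i, ]]
    if (length(di) == 0) 0 else mean(di)
  }, numeric(1))
  names(nodal) <- rownames(d)
  vals <- d[fin]
  list(nodal = nodal,
       global = if (length(vals) == 0) 0 else mean(vals),
       n_unreachable_pairs = sum(!fin) - nrow(d))
}

#' Global efficiency (nodal and global)
#'
#' Mean inverse shortest-path distance, with `1/Inf = 0`, so disconnection
#' degrades efficiency smoothly instead of breaking the average.
#'
#' @inheritParams characteristic_path_length
#' @return List with `nodal` and `global`.
#' @export
global_efficiency <- function(net, dist = NULL) {
  d <- dist %||% shortest_path_lengths(net)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- NA
  nodal <- rowMeans(inv, na.rm = TRUE)
  names(nodal) <- rownames(d)
  list(nodal = nodal, global = mean(inv[!is.na(inv)]))
}

#' Local efficiency (nodal and global)
#'
#' Nodal local efficiency of node i is the global efficiency of the subgraph
#' induced on i's neighbors (0 with fewer than 2 neighbors); global Eloc is
#' the mean over nodes.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @return List with `nodal` and `global`.
#' @export
local_efficiency <- function(net) {
  a <- as_adjacency(net)
  storage.mode(a) <- "double"
  nodal <- vapply(seq_len(nrow(a)), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) return(0)
    sub <- a[nb, nb, drop = FALSE]
    inv <- 1 / shortest_path_lengths(sub)
    inv[!is.finite(inv)] <- 0
    sum(inv) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  names(nodal) <- rownames(a)
  list(nodal = nodal, global = mean(nodal))
}

#' Nodal degree and betweenness centrality
#'
#' Degree is the adjacency row sum. Betweenness is the unnormalized share of
#' shortest paths between other node pairs passing through each node, with
#' each unordered pair counted once.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @return List with per-node `degree` and `betweenness`.
#' @export
degree_and_betweenness <- function(net) {
  a <- as_adjacency(net)
  g <- net_graph(a)
  deg <- rowSums(a)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  names(btw) <- rownames(a)
  list(degree = deg, betweenness = btw)
}

#' Small-world index against degree-preserving random surrogates
#'
#' `sigma = (Cp / Cp_rand) / (Lp / Lp_rand)`, where the null values are
#' means over degree-preserving rewired surrogates (repeated random edge
#' swaps, `swap_factor * n_edges` attempts per surrogate). `sigma > 1`
#' indicates small-world organization. With `swap_factor = 0` the surrogate
#' is the network itself and sigma is exactly 1.
#'
#' @param net A `binary_network` or adjacency matrix with >= 1 edge.
#' @param n_random Number of surrogates (>= 1; default 100).
#' @param seed Integer seed for the rewiring stream.
#' @param swap_factor Edge-swap attempts per surrogate, as a multiple of the
#'   edge count (default 10).
#' @return List with `sigma` (NA with a flag when a null mean degenerates to
#'   0), `cp`, `lp`, `cp_rand`, `lp_rand`, and `valid`.
#' @export
small_world_index <- function(net, n_random = 100, seed = 1L,
                              swap_factor = 10) {
  a <- as_adjacency(net)
  if (sum(a) == 0) stopf("network has no edges")
  if (n_random < 1) stopf("n_random must be >= 1")
  cp <- clustering_coefficient(a)$global
  lp <- characteristic_path_length(a)$global
  g <- net_graph(a)
  n_edges <- igraph::ecount(g)
  stats_rand <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      gr <- if (swap_factor > 0) {
        igraph::rewire(g, igraph::keeping_degseq(
          niter = max(1, round(swap_factor * n_edges))))
      } else {
        g
      }
      ar <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
      c(clustering_coefficient(ar)$global,
        characteristic_path_length(ar)$global)
    }, numeric(2))
  })
  cp_rand <- mean(stats_rand[1, ])
  lp_rand <- mean(stats_rand[2, ])
  valid <- cp_rand > 0 && lp_rand > 0 && lp > 0
  sigma <- if (valid) (cp / cp_rand) / (lp / lp_rand) else NA_real_
  list(sigma = sigma, cp = cp, lp = lp,
       cp_rand = cp_rand, lp_rand = lp_rand, valid = valid)
}

#' Validate a sparsity grid on a cohort of networks
#'
#' For each sparsity level, reports the fraction of networks whose largest
#' connected component covers more than 90% of nodes and the fraction with
#' small-world index greater than 1, and flags levels failing either
#' criterion (connectivity in >90% of nodes for every network; sigma > 1 in
#' more than 95% of networks).
#'
#' @param scns List of `individual_scn` (or weight matrices).
#' @param grid A [sparsity_grid()].
#' @param n_random Surrogates per sigma evaluation (kept small by default:
#'   the criterion is a coarse screen).
#' @param seed Integer seed.
#' @param mode Binarization mode, see [binarize()].
#' @param sigma Set `FALSE` to skip the (relatively expensive) small-world
#'   screen and report connectivity only.
#' @return Data frame with one row per K: `k`, `frac_connected`,
#'   `frac_small_world`, `pass_connected`, `pass_small_world`, `flagged`.
#' @export
validate_sparsity_grid <- function(scns, grid, n_random = 10, seed = 1L,
                                   mode = "absolute", sigma = TRUE) {
  stopifnot(inherits(grid, "sparsity_grid"), length(scns) >= 1)
  rows <- lapply(seq_along(grid$values), function(gi) {
    k <- grid$values[gi]
    conn <- logical(length(scns))
    sw <- rep(NA, length(scns))
    for (si in seq_along(scns)) {
      net <- binarize(scns[[si]], k, mode)
      comp <- igraph::components(net_graph(net))
      conn[si] <- max(comp$csize) / nrow(net$adjacency) > 0.9
      if (isTRUE(sigma)) {
        sws <- small_world_index(net, n_random = n_random,
                                 seed = stage_seed(seed, "smallworld") +
                                   gi * 1000L + si)
        sw[si] <- isTRUE(sws$valid) && sws$sigma > 1
      }
    }
    data.frame(k = k,
               frac_connected = mean(conn),
               frac_small_world = if (isTRUE(sigma)) mean(sw) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pass_connected <- out$frac_connected >= 1
  out$pass_small_world <- if (isTRUE(sigma)) out$frac_small_world > 0.95
  else NA
  out$flagged <- !(out$pass_connected &
                     (is.na(out$pass_small_world) | out$pass_small_world))
  out
}

metric_names_global <- function() c("Cp", "Lp", "Eg", "Eloc")
metric_names_nodal <- function() {
  c("nodal_Cp", "nodal_Lp", "nodal_Eg", "nodal_Eloc", "degree", "betweenness")
}

# all requested metrics for one binary network, sharing the distance matrix
compute_net_metrics <- function(net, metrics) {
  a <- as_adjacency(net)
  out <- list()
  need_dist <- any(metrics %in% c("Lp", "Eg", "nodal_Lp", "nodal_Eg"))
  d <- if (need_dist) shortest_path_lengths(a) else NULL
  if (any(metrics %in% c("Cp", "nodal_Cp"))) {
    cc <- clustering_coefficient(a)
    out$Cp <- cc$global; out$nodal_Cp <- cc$nodal
  }
  if (any(metrics %in% c("Lp", "nodal_Lp"))) {
    lp <- characteristic_path_length(a, dist = d)
    out$Lp <- lp$global; out$nodal_Lp <- lp$nodal
  }
  if (any(metrics %in% c("Eg", "nodal_Eg"))) {
    eg <- global_efficiency(a, dist = d)
    out$Eg <- eg$global; out$nodal_Eg <- eg$nodal
  }
  if (any(metrics %in% c("Eloc", "nodal_Eloc"))) {
    el <- local_efficiency(a)
    out$Eloc <- el$global; out$nodal_Eloc <- el$nodal
  }
  if (any(metrics %in% c("degree", "betweenness"))) {
    db <- degree_and_betweenness(a)
    out$degree <- db$degree; out$betweenness <- db$betweenness
  }
  out[metrics]
}

#' Metric curves across the sparsity grid
#'
#' Binarizes a weighted network at every grid level and evaluates the
#' requested global and nodal metrics.
#'
#' @param scn An `individual_scn` (or weight matrix).
#' @param grid A [sparsity_grid()].
#' @param metrics Metric names among `Cp, Lp, Eg, Eloc` (global) and
#'   `nodal_Cp, nodal_Lp, nodal_Eg, nodal_Eloc, degree, betweenness`.
#' @param mode Binarization mode, see [binarize()].
#' @param subject_id Identifier attached to the rows.
#' @return Long data frame: `subject_id`, `metric`, `node` (`NA` for global
#'   metrics), `k`, `value`.
#' @export
metric_curves <- function(scn, grid,
                          metrics = c(metric_names_global(),
                                      metric_names_nodal()),
                          mode = "absolute",
                          subject_id = NA_character_) {
  stopifnot(inherits(grid, "sparsity_grid"))
  bad <- setdiff(metrics, c(metric_names_global(), metric_names_nodal()))
  if (length(bad) > 0) stopf("unknown metric(s): %s", paste(bad, collapse = ", "))
  rows <- lapply(grid$values, function(k) {
    net <- binarize(scn, k, mode)
    vals <- compute_net_metrics(net, metrics)
    labels <- rownames(net$adjacency) %||%
      sprintf("n%03d", seq_len(nrow(net$adjacency)))
    do.call(rbind, lapply(metrics, function(m) {
      v <- vals[[m]]
      if (length(v) == 1) {
        data.frame(subject_id = subject_id, metric = m, node = NA_character_,
                   k = k, value = as.numeric(v), stringsAsFactors = FALSE)
      } else {
        data.frame(subject_id = subject_id, metric = m, node = labels,
                   k = k, value = as.numeric(v), stringsAsFactors = FALSE)
      }
    }))
  })
  do.call(rbind, rows)
}

#' Trapezoidal area under a metric curve
#'
#' @param values Metric values, one per grid level.
#' @param grid A [sparsity_grid()] (or a numeric vector of K values).
#' @return The composite trapezoidal integral over K.
#' @export
auc_trapezoid <- function(values, grid) {
  k <- if (inherits(grid, "sparsity_grid")) grid$values else as.numeric(grid)
  if (length(values) != length(k)) {
    stopf("curve has %d values but grid has %d levels",
          length(values), length(k))
  }
  if (length(k) < 2) stopf("grid must have >= 2 levels")
  sum(diff(k) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' AUC summary of metric curves
#'
#' Collapses a long curve table (from [metric_curves()], possibly
#' row-bound across subjects) to one AUC per subject x metric x node.
#'
#' @param curves Long data frame with columns `subject_id`, `metric`,
#'   `node`, `k`, `value`.
#' @param grid A [sparsity_grid()]; curves must cover exactly its levels.
#' @return Data frame: `subject_id`, `metric`, `node`, `auc`.
#' @export
auc_table <- function(curves, grid) {
  stopifnot(all(c("subject_id", "metric", "node", "k", "value") %in%
                  names(curves)))
  node_key <- ifelse(is.na(curves$node), "<global>", curves$node)
  sid_key <- ifelse(is.na(curves$subject_id), "<none>", curves$subject_id)
  key <- paste(sid_key, curves$metric, node_key, sep = "\r")
  parts <- split(curves, key)
  rows <- lapply(parts, function(p) {
    p <- p[order(p$k), ]
    data.frame(subject_id = p$subject_id[1], metric = p$metric[1],
               node = p$node[1], auc = auc_trapezoid(p$value, grid),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
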