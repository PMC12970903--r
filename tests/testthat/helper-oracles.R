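# Independent brute-force oracles used to cross-check the package's graph
# metrics and statistics. These deliberately share no code with the
# implementation: Floyd-Warshall for distances, exhaustive triple
# enumeration for triangles, recursive shortest-path enumeration for
# betweenness, and a hand-written Benjamini-Hochberg step-up.

bf_floyd_warshall <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

bf_clustering <- function(a) {
  n <- nrow(a)
  nodal <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[v, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (a[nb[i], nb[j]] == 1) links <- links + 1
      }
    }
    nodal[v] <- 2 * links / (k * (k - 1))
  }
  list(nodal = nodal, global = mean(nodal))
}

bf_path_length <- function(a) {
  d <- bf_floyd_warshall(a)
  n <- nrow(a)
  nodal <- numeric(n)
  all_vals <- c()
  for (i in seq_len(n)) {
    di <- d[i, -i]
    fin <- di[is.finite(di)]
    nodal[i] <- if (length(fin) == 0) 0 else mean(fin)
    all_vals <- c(all_vals, fin)
  }
  list(nodal = nodal, global = if (length(all_vals) == 0) 0 else mean(all_vals))
}

bf_global_efficiency <- function(a) {
  d <- bf_floyd_warshall(a)
  n <- nrow(a)
  nodal <- numeric(n)
  total <- 0
  for (i in seq_len(n)) {
    inv <- 1 / d[i, -i]
    inv[!is.finite(inv)] <- 0
    nodal[i] <- mean(inv)
    total <- total + sum(inv)
  }
  list(nodal = nodal, global = total / (n * (n - 1)))
}

bf_local_efficiency <- function(a) {
  n <- nrow(a)
  nodal <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[v, ] == 1)
    if (length(nb) < 2) next
    nodal[v] <- bf_global_efficiency(a[nb, nb, drop = FALSE])$global
  }
  list(nodal = nodal, global = mean(nodal))
}

# all shortest paths between s and t, by recursive extension
bf_all_shortest_paths <- function(a, d, s, t) {
  if (!is.finite(d[s, t]) || s == t) return(list())
  if (d[s, t] == 1) return(list(c(s, t)))
  out <- list()
  for (u in which(a[s, ] == 1)) {
    if (d[u, t] == d[s, t] - 1) {
      for (p in bf_all_shortest_paths(a, d, u, t)) {
        out[[length(out) + 1]] <- c(s, p)
      }
    }
  }
  out
}

bf_betweenness <- function(a) {
  n <- nrow(a)
  d <- bf_floyd_warshall(a)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- bf_all_shortest_paths(a, d, s, t)
      if (length(paths) == 0) next
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(paths)
      }
    }
  }
  btw
}

bf_bh_adjust <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# explicit normal-equations least squares for residualization checks
bf_ols_residuals <- function(x, y) {
  beta <- solve(t(x) %*% x) %*% t(x) %*% y
  y - x %*% beta
}

random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(stats::runif(length(up)) < p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

ring_lattice <- function(n = 50, k = 4) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (off in seq_len(k / 2)) {
      j <- ((i - 1 + off) %% n) + 1
      a[i, j] <- 1L
      a[j, i] <- 1L
    }
  }
  a
}

make_small_cohort <- function(seed = 1, n_per_group = 20, n_regions = 16,
                              ...) {
  generate_cohort(cohort_config(n_per_group = n_per_group,
                                n_regions = n_regions, n_modules = 4,
                                seed = seed, ...))
}
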