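# Binarization, topology metrics against brute-force oracles, small-world
# surrogates, grid validation, and AUC summarization.

test_that("binarization keeps the strongest edges with deterministic ties", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.9; w[1, 3] <- 0.8; w[1, 4] <- 0.7
  w[2, 3] <- 0.3; w[2, 4] <- 0.2; w[3, 4] <- 0.1
  w <- w + t(w)
  net <- binarize(w, 0.5)
  expect_equal(net$n_edges, 3L)
  expect_equal(which(net$adjacency[upper.tri(net$adjacency)] == 1), c(1, 2, 4))
  expect_equal(unname(rowSums(net$adjacency)), c(3, 1, 1, 1))

  # all edges retained on a complete positive matrix
  full <- binarize(w + 1, 0.999)
  off <- full$adjacency[upper.tri(full$adjacency)]
  expect_true(all(off == 1))
  expect_true(all(diag(full$adjacency) == 0))

  # a strong negative edge wins under absolute ranking, loses under positive
  w2 <- matrix(0.3, 5, 5); diag(w2) <- 0
  w2[1, 2] <- w2[2, 1] <- -0.95
  neg <- binarize(w2, 0.1)
  expect_equal(neg$adjacency[1, 2], 1L)
  pos <- binarize(w2, 0.1, mode = "positive")
  expect_equal(pos$adjacency[1, 2], 0L)

  expect_error(binarize(w, 0.0001), "zero edges")
})

test_that("edge sets are nested across increasing sparsity", {
  set.seed(7)
  w <- matrix(rnorm(100), 10); w <- (w + t(w)) / 2; diag(w) <- 0
  ks <- seq(0.1, 0.9, by = 0.1)
  prev <- binarize(w, ks[1])$adjacency
  for (k in ks[-1]) {
    cur <- binarize(w, k)$adjacency
    expect_true(all(cur[prev == 1] == 1))
    prev <- cur
  }
})

test_that("closed-form graphs give the textbook metric values", {
  k3 <- matrix(1, 3, 3); diag(k3) <- 0
  expect_equal(clustering_coefficient(k3)$global, 1)
  expect_equal(characteristic_path_length(k3)$global, 1)
  expect_equal(global_efficiency(k3)$global, 1)

  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(clustering_coefficient(star)$global, 0)
  expect_equal(local_efficiency(star)$global, 0)
  db <- degree_and_betweenness(star)
  expect_equal(unname(db$degree), c(4, 1, 1, 1, 1))
  expect_equal(unname(db$betweenness), c(choose(4, 2), 0, 0, 0, 0))

  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1
  path3 <- path3 + t(path3)
  d <- shortest_path_lengths(path3)
  expect_equal(d[1, 3], 2)
  expect_equal(characteristic_path_length(path3)$global, 4 / 3)

  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(local_efficiency(k4)$global, 1)
  expect_equal(unname(degree_and_betweenness(k4)$betweenness), rep(0, 4))

  empty <- matrix(0, 4, 4)
  expect_equal(global_efficiency(empty)$global, 0)
})

test_that("disconnected structure is handled by exclusion, not penalties", {
  two_dyads <- matrix(0, 4, 4)
  two_dyads[1, 2] <- two_dyads[3, 4] <- 1
  two_dyads <- two_dyads + t(two_dyads)
  d <- shortest_path_lengths(two_dyads)
  expect_true(all(is.infinite(d[1:2, 3:4])))
  lp <- characteristic_path_length(two_dyads)
  expect_equal(lp$global, 1) # only the within-dyad pairs count
  expect_equal(lp$n_unreachable_pairs, 8)

  iso <- matrix(0, 4, 4); iso[1, 2] <- iso[2, 3] <- iso[3, 1] <- 1
  iso <- iso + t(iso) # triangle plus an isolated node
  lp2 <- characteristic_path_length(iso)
  expect_equal(unname(lp2$nodal[4]), 0)
  expect_equal(lp2$global, 1)
})

test_that("all metrics match brute-force oracles on random graphs", {
  set.seed(123)
  for (rep in 1:100) {
    n <- sample(4:8, 1)
    a <- random_adjacency(n, p = runif(1, 0.2, 0.8))
    expect_equal(shortest_path_lengths(a), bf_floyd_warshall(a),
                 ignore_attr = TRUE)
    cc <- clustering_coefficient(a); occ <- bf_clustering(a)
    expect_equal(unname(cc$nodal), occ$nodal, tolerance = 1e-12)
    expect_equal(cc$global, occ$global, tolerance = 1e-12)
    lp <- characteristic_path_length(a); olp <- bf_path_length(a)
    expect_equal(unname(lp$nodal), olp$nodal, tolerance = 1e-10)
    expect_equal(lp$global, olp$global, tolerance = 1e-10)
    eg <- global_efficiency(a); oeg <- bf_global_efficiency(a)
    expect_equal(unname(eg$nodal), oeg$nodal, tolerance = 1e-10)
    expect_equal(eg$global, oeg$global, tolerance = 1e-10)
    el <- local_efficiency(a); oel <- bf_local_efficiency(a)
    expect_equal(unname(el$nodal), oel$nodal, tolerance = 1e-10)
    expect_equal(el$global, oel$global, tolerance = 1e-10)
    db <- degree_and_betweenness(a)
    expect_equal(unname(db$degree), unname(rowSums(a)))
    expect_equal(unname(db$betweenness), bf_betweenness(a), tolerance = 1e-10)
  }
})

test_that("global metrics equal the mean of their nodal versions", {
  set.seed(9)
  for (rep in 1:20) {
    a <- random_adjacency(10, 0.3)
    expect_equal(clustering_coefficient(a)$global,
                 mean(clustering_coefficient(a)$nodal))
    expect_equal(local_efficiency(a)$global, mean(local_efficiency(a)$nodal))
  }
})

test_that("zero-swap surrogates give a small-world index of exactly 1", {
  a <- ring_lattice(20, 4)
  sw <- small_world_index(a, n_random = 3, seed = 1, swap_factor = 0)
  expect_equal(sw$sigma, 1)
  expect_true(sw$valid)
})

test_that("small-world index is deterministic given the seed", {
  a <- ring_lattice(30, 4)
  s1 <- small_world_index(a, n_random = 5, seed = 99)
  s2 <- small_world_index(a, n_random = 5, seed = 99)
  expect_identical(s1, s2)
})

test_that("sparsity grid validation reports and flags per level", {
  grid <- sparsity_grid(0.14, 0.2, 0.02)
  set.seed(5)
  scns <- replicate(3, {
    w <- matrix(runif(64, 0.2, 1), 8); w <- (w + t(w)) / 2; diag(w) <- 1
    w
  }, simplify = FALSE)
  rep_ok <- validate_sparsity_grid(scns, grid, sigma = FALSE)
  expect_equal(nrow(rep_ok), length(grid$values))
  expect_named(rep_ok, c("k", "frac_connected", "frac_small_world",
                         "pass_connected", "pass_small_world", "flagged"))

  # two 4-cliques with no bridge: low K cannot connect >90% of nodes
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- 0.9; w[5:8, 5:8] <- 0.9
  diag(w) <- 1
  rep_frag <- validate_sparsity_grid(list(w), sparsity_grid(0.2, 0.3, 0.05),
                                     sigma = FALSE)
  expect_true(all(rep_frag$frac_connected == 0))
  expect_true(all(rep_frag$flagged))
})

test_that("sparsity grid construction enforces its bounds", {
  g <- sparsity_grid()
  expect_length(g$values, 37)
  expect_equal(g$values[1], 0.14)
  expect_equal(g$values[37], 0.50)
  expect_error(sparsity_grid(0.5, 0.2), "k_min")
  expect_error(sparsity_grid(0.1, 0.4, step = -0.01), "step")
})

test_that("AUC follows closed forms and a per-interval trapezoid oracle", {
  grid <- sparsity_grid()
  expect_equal(auc_trapezoid(rep(2, 37), grid), 0.72, tolerance = 1e-12)
  lin <- seq(0, 1, length.out = 37)
  expect_equal(auc_trapezoid(lin, grid), 0.18, tolerance = 1e-12)
  set.seed(11)
  vals <- rnorm(37)
  oracle <- 0
  for (i in 1:36) {
    oracle <- oracle + (grid$values[i + 1] - grid$values[i]) *
      (vals[i] + vals[i + 1]) / 2
  }
  expect_equal(auc_trapezoid(vals, grid), oracle, tolerance = 1e-12)
  expect_error(auc_trapezoid(rep(1, 5), grid), "37")
})

test_that("metric curves and AUC tables are consistently shaped", {
  gen <- make_small_cohort(seed = 30, n_per_group = 6)
  parts <- build_individual_scns(gen$cohort)
  grid <- sparsity_grid(0.2, 0.3, 0.05)
  cur <- metric_curves(parts$scns[[1]], grid,
                       metrics = c("Cp", "nodal_Cp", "degree"),
                       subject_id = "s1")
  expect_equal(nrow(cur), length(grid$values) * (1 + 16 + 16))
  at <- auc_table(cur, grid)
  expect_equal(nrow(at), 1 + 16 + 16)
  cp_curve <- cur$value[cur$metric == "Cp"]
  expect_equal(at$auc[at$metric == "Cp" & is.na(at$node)],
               auc_trapezoid(cp_curve, grid))
  # constant-curve invariant: AUC = c * (k_max - k_min)
  const <- cur[cur$metric == "Cp", ]
  const$value <- 3
  expect_equal(auc_table(const, grid)$auc, 3 * (0.3 - 0.2))
  expect_error(metric_curves(parts$scns[[1]], grid, metrics = "bogus"),
               "unknown metric")
})
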