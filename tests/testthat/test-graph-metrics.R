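test_that("BFS distances match small known graphs and flag unreachable", {
  p3 <- make_net(c("1", "2", "3"), rbind(c("1", "2"), c("2", "3")))
  d <- shortest_path_lengths(p3)
  expect_equal(unname(d["1", "3"]), 2)
  expect_equal(unname(d["1", "2"]), 1)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  disc <- make_net(c("a", "b", "c"), rbind(c("a", "b")))
  expect_true(is.na(shortest_path_lengths(disc)["a", "c"]))
})

test_that("BFS distances equal the Floyd-Warshall oracle on random graphs", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(4:25, 1)
    adj <- random_adjacency(n, stats::runif(1, 0.1, 0.6))
    d <- bfs <- shortest_path_lengths(net_from_adjacency(adj))
    d[is.na(d)] <- Inf
    expect_equal(d, floyd_warshall(adj))
    # independent cross-check against igraph
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(unname(d), unname(igraph::distances(g)))
  }
})

test_that("global efficiency matches closed forms", {
  nodes <- c("1", "2", "3")
  complete <- make_net(nodes, t(utils::combn(nodes, 2)))
  expect_equal(global_efficiency(complete), 1)
  empty <- make_net(nodes, matrix(character(0), 0, 2))
  expect_equal(global_efficiency(empty), 0)
  p3 <- make_net(nodes, rbind(c("1", "2"), c("2", "3")))
  expect_equal(global_efficiency(p3), 5 / 6)
  expect_equal(cost_efficiency(p3, cost = 2 / 3), 5 / 6 - 2 / 3)
  expect_equal(cost_efficiency(complete, cost = 1), 0)
})

test_that("local efficiency matches closed forms", {
  k3 <- make_net(c("a", "b", "c"), t(utils::combn(c("a", "b", "c"), 2)))
  expect_equal(local_efficiency(k3), 1)
  c4 <- make_net(c("a", "b", "c", "d"),
                 rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("a", "d")))
  expect_equal(local_efficiency(c4), 0)
  empty <- make_net(c("a", "b"), matrix(character(0), 0, 2))
  expect_equal(local_efficiency(empty), 0)
})

test_that("efficiencies agree with brute-force oracles on random graphs", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(4:20, 1)
    adj <- random_adjacency(n, stats::runif(1, 0.15, 0.7))
    net <- net_from_adjacency(adj)
    expect_equal(global_efficiency(net), oracle_global_efficiency(adj))
    expect_equal(local_efficiency(net), oracle_local_efficiency(adj))
  }
})

test_that("global efficiency never decreases when an edge is added", {
  set.seed(15)
  for (i in 1:15) {
    adj <- random_adjacency(10, 0.3)
    miss <- which(upper.tri(adj) & !adj, arr.ind = TRUE)
    if (nrow(miss) == 0) next
    pick <- miss[sample(nrow(miss), 1), ]
    adj2 <- adj
    adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- TRUE
    expect_gte(global_efficiency(net_from_adjacency(adj2)),
               global_efficiency(net_from_adjacency(adj)))
  }
})

test_that("double-edge-swap randomization preserves the degree sequence", {
  set.seed(31)
  for (i in 1:10) {
    adj <- random_adjacency(12, 0.35)
    net <- net_from_adjacency(adj)
    if (net$n_edges < 2) next
    rr <- random_reference(net, seed = 100 + i)
    expect_equal(rr$n_edges, net$n_edges)
    deg <- function(nt) {
      table(factor(c(nt$edges$node1, nt$edges$node2), levels = nt$nodes))
    }
    expect_equal(deg(rr), deg(net))  # per-node degrees, not just sorted
    # no self-loops or duplicated edges
    expect_true(all(rr$edges$node1 != rr$edges$node2))
    expect_false(anyDuplicated(paste(rr$edges$node1, rr$edges$node2)) > 0)
  }
})

test_that("randomization is deterministic for a seed and inert on stars", {
  adj <- random_adjacency(10, 0.4)
  net <- net_from_adjacency(adj)
  r1 <- random_reference(net, seed = 5)
  r2 <- random_reference(net, seed = 5)
  expect_identical(r1$edges, r2$edges)
  # star graph: every swap would duplicate an edge, so nothing moves
  star <- make_net(c("h", letters[1:5]),
                   cbind(rep("h", 5), letters[1:5]))
  rs <- random_reference(star, seed = 1)
  expect_equal(attr(rs, "n_swaps"), 0L)
  expect_equal(rs$edges[, c("node1", "node2")],
               star$edges[order(star$edges$node1, star$edges$node2),
                          c("node1", "node2")])
})

test_that("the ring lattice adds edges in offset order", {
  c6 <- lattice_reference(6, 6)
  deg <- table(c(c6$edges$node1, c6$edges$node2))
  expect_true(all(deg == 2))
  expect_equal(global_efficiency(c6), 2 / 3)  # per-node sum 1+1+.5+.5+1/3
  c5 <- lattice_reference(5, 5)
  expect_true(all(table(c(c5$edges$node1, c5$edges$node2)) == 2))
  n <- 7
  full <- lattice_reference(n, n * (n - 1) / 2)
  expect_equal(global_efficiency(full), 1)
  expect_error(lattice_reference(4, 7), "exceeds")
  expect_identical(lattice_reference(8, 11)$edges,
                   lattice_reference(8, 11)$edges)
})

test_that("efficiency curves behave at the boundary and in between", {
  set.seed(19)
  x <- matrix(rnorm(30 * 120), 120, 30,
              dimnames = list(NULL, sprintf("n%02d", 1:30)))
  corr <- correlation_matrix(x)
  cv <- efficiency_curves(corr, cost_grid = c(0.3, 1), n_null = 3, seed = 2)
  expect_equal(cv$e_glob[2], 1)
  expect_equal(cv$ce[2], 0)
  expect_equal(cv$e_glob_rand[2], 1)  # complete graph admits no swap
  expect_equal(cv$e_glob_latt[2], 1)
  expect_equal(cv$ce, cv$e_glob - cv$cost)
  expect_true(all(cv$e_loc >= 0 & cv$e_loc <= 1))
  # an i.i.d.-noise network is statistically indistinguishable from its
  # degree-preserving randomization
  expect_lt(abs(cv$e_glob[1] - cv$e_glob_rand[1]), 0.05)
})

test_that("modular correlation structure yields a small-world range", {
  # deterministic block correlation matrix: 4 communities of 8 nodes
  n <- 32
  nodes <- sprintf("n%02d", 1:n)
  block <- rep(1:4, each = 8)
  r <- outer(block, block, function(a, b) ifelse(a == b, 0.6, 0.05))
  set.seed(23)
  jitter <- matrix(rnorm(n * n, 0, 0.01), n, n)
  jitter <- (jitter + t(jitter)) / 2
  r <- r + jitter
  diag(r) <- 1
  dimnames(r) <- list(nodes, nodes)
  cv <- efficiency_curves(r, cost_grid = seq(0.08, 0.4, by = 0.04),
                          n_null = 8, seed = 3)
  # strong local clustering relative to the degree-preserving null
  expect_true(any(cv$e_loc > cv$e_loc_rand))
  rng <- small_world_cost_range(cv)
  expect_gt(rng$n_costs, 0)
  expect_true(rng$cost_min >= 0.08 && rng$cost_max <= 0.4)
})

test_that("the small-world range handles the all-true and empty cases", {
  grid <- seq(0.1, 0.3, by = 0.05)
  curve <- tibble::tibble(
    cost = grid, e_glob = 0.5, e_loc = 0.6,
    ce = 0.5 - grid, e_glob_rand = 0.6, e_loc_rand = 0.4,
    e_glob_latt = 0.3
  )
  rng <- small_world_cost_range(curve)
  expect_equal(rng$cost_min, 0.1)
  expect_equal(rng$cost_max, 0.3)
  expect_equal(rng$n_costs, 5L)
  none <- curve
  none$e_loc_rand <- 0.9
  rng0 <- small_world_cost_range(none)
  expect_true(is.na(rng0$cost_min))
  expect_equal(rng0$n_costs, 0L)
  # the longest contiguous run wins
  mixed <- curve
  mixed$e_loc_rand <- c(0.9, 0.4, 0.4, 0.4, 0.9)
  rngm <- small_world_cost_range(mixed)
  expect_equal(rngm$cost_min, 0.15)
  expect_equal(rngm$cost_max, 0.25)
})

test_that("the smoothed cost-efficiency peak recovers an analytic maximum", {
  grid <- seq(0.1, 0.5, by = 0.05)
  ce <- -(grid - 0.3)^2
  pk <- smooth_and_peak(grid, ce)
  expect_equal(pk$peak_cost, 0.3, tolerance = 1e-3)
  # strictly increasing -> peak at the grid maximum
  expect_equal(smooth_and_peak(grid, grid)$peak_cost, 0.5)
  # constant -> smallest cost by the tie rule
  expect_equal(smooth_and_peak(grid, rep(0.2, length(grid)))$peak_cost, 0.1)
  expect_error(smooth_and_peak(c(0.1, 0.2, 0.3), c(1, 2, 3)),
               "at least 4")
})
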