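# Binary-graph metrics for cost-thresholded networks. All metrics operate
# on an undirected, unweighted adjacency matrix; network objects are
# converted on entry so the same code serves individual, group and null
# networks.

as_adjacency <- function(x) {
  if (inherits(x, "costnet_network") || inherits(x, "costnet_group_network")) {
    n <- length(x$nodes)
    adj <- matrix(FALSE, n, n, dimnames = list(x$nodes, x$nodes))
    if (nrow(x$edges) > 0) {
      i <- match(x$edges$node1, x$nodes)
      j <- match(x$edges$node2, x$nodes)
      adj[cbind(i, j)] <- TRUE
      adj[cbind(j, i)] <- TRUE
    }
    adj
  } else if (is.matrix(x)) {
    adj <- (x != 0)
    adj <- adj | t(adj)
    diag(adj) <- FALSE
    adj
  } else {
    stop("Cannot interpret object of class ", paste(class(x), collapse = "/"),
         " as a network.", call. = FALSE)
  }
}

# All-pairs unweighted distances by breadth-first frontier expansion,
# carried out for all sources at once with boolean matrix products.
# Unreachable pairs are Inf.
bfs_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  diag(d) <- 0
  if (n == 0) return(d)
  a_num <- adj * 1
  reach <- diag(n) > 0
  step <- 0L
  while (step < n) {
    step <- step + 1L
    nxt <- ((reach %*% a_num) > 0) | reach
    newly <- nxt & !reach
    if (!any(newly)) break
    d[newly] <- step
    reach <- nxt
  }
  d
}

#' Shortest path lengths between all node pairs
#'
#' Unweighted breadth-first distances (the path length is the number of
#' edges the path uses). Unreachable pairs are flagged `NA`.
#'
#' @param net A `costnet_network`, `costnet_group_network` or adjacency
#'   matrix.
#' @return Symmetric node-by-node matrix of integer distances, `NA` where
#'   no path exists, 0 on the diagonal.
#' @export
shortest_path_lengths <- function(net) {
  d <- bfs_distances(as_adjacency(net))
  d[is.infinite(d)] <- NA_real_
  d
}

#' Global efficiency of a binary network
#'
#' Mean over ordered node pairs of the inverse shortest path length, with
#' unreachable pairs contributing 0 (Latora-Marchiori convention) — an
#' index of how efficiently information can travel across the whole
#' network. 1 for a complete graph, 0 for an empty one.
#'
#' @inheritParams shortest_path_lengths
#' @return Value in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  adj <- as_adjacency(net)
  efficiency_from_adjacency(adj)
}

efficiency_from_adjacency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- bfs_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

#' Local efficiency of a binary network
#'
#' Mean over nodes of the global efficiency of the subgraph induced on
#' each node's neighbours; nodes with fewer than two neighbours
#' contribute 0. A clustering-like measure of fault tolerance.
#'
#' @inheritParams shortest_path_lengths
#' @return Value in \[0, 1\].
#' @export
local_efficiency <- function(net) {
  adj <- as_adjacency(net)
  n <- nrow(adj)
  if (n == 0) return(0)
  per_node <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    if (length(nb) < 2) return(0)
    efficiency_from_adjacency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(per_node)
}

#' Cost efficiency of a network
#'
#' Global efficiency minus wiring cost; its maximum over costs defines
#' the economical operating point of the network.
#'
#' @param net A `costnet_network` (its stored cost is used) or any
#'   network with `cost` supplied.
#' @param cost Wiring cost; defaults to `net$cost`.
#' @return `global_efficiency(net) - cost`.
#' @export
cost_efficiency <- function(net, cost = NULL) {
  cost <- cost %||% net$cost
  if (is.null(cost)) {
    stop("No wiring cost available for this network.", call. = FALSE)
  }
  global_efficiency(net) - cost
}

#' Degree-preserving random reference network
#'
#' Randomizes a network by repeated double-edge swaps — edges (a,b) and
#' (c,d) become (a,d) and (c,b) when this creates neither self-loops nor
#' multi-edges — preserving every node's degree exactly. The attempt
#' budget is bounded; if no (or not all) requested swaps are achievable
#' (a star graph admits none), the best-effort network is returned with
#' the realized swap and attempt counts in attributes `n_swaps` and
#' `n_attempts`.
#'
#' @param net A `costnet_network` or `costnet_group_network`.
#' @param seed Optional RNG seed; the caller's RNG state is restored.
#' @param swaps_per_edge Target successful swaps per edge (default 10).
#' @return A `costnet_network` with identical degree sequence and edge
#'   count (edge correlations are dropped).
#' @export
random_reference <- function(net, seed = NULL, swaps_per_edge = 10) {
  nodes <- net$nodes
  edges <- net$edges
  m <- nrow(edges)
  if (m < 2) {
    stop("Degree-preserving randomization needs at least 2 edges.",
         call. = FALSE)
  }
  adj <- as_adjacency(net)
  E <- cbind(match(edges$node1, nodes), match(edges$node2, nodes))
  target <- as.integer(swaps_per_edge * m)
  budget <- 20L * target
  swaps <- 0L
  attempts <- 0L
  with_local_seed(seed, {
    # draw edge pairs and orientation flips in batches; per-attempt RNG
    # calls dominate the runtime otherwise
    chunk <- 4096L
    pos <- chunk
    e1 <- e2 <- integer(0)
    flip <- logical(0)
    while (swaps < target && attempts < budget) {
      attempts <- attempts + 1L
      pos <- pos + 1L
      if (pos > chunk) {
        e1 <- sample.int(m, chunk, replace = TRUE)
        e2 <- sample.int(m, chunk, replace = TRUE)
        flip <- stats::runif(chunk) < 0.5
        pos <- 1L
      }
      i <- e1[pos]; j <- e2[pos]
      if (i == j) next
      a <- E[i, 1]; b <- E[i, 2]
      cc <- E[j, 1]; dd <- E[j, 2]
      if (flip[pos]) { tmp <- cc; cc <- dd; dd <- tmp }
      if (a == cc || a == dd || b == cc || b == dd) next
      if (adj[a, dd] || adj[cc, b]) next
      adj[a, b] <- adj[b, a] <- FALSE
      adj[cc, dd] <- adj[dd, cc] <- FALSE
      adj[a, dd] <- adj[dd, a] <- TRUE
      adj[cc, b] <- adj[b, cc] <- TRUE
      E[i, ] <- c(a, dd)
      E[j, ] <- c(cc, b)
      swaps <- swaps + 1L
    }
  })
  ce <- canonical_edge(nodes[E[, 1]], nodes[E[, 2]])
  out <- network_from_edges(
    nodes,
    tibble::tibble(node1 = ce$node1, node2 = ce$node2,
                   r = NA_real_)[order(ce$node1, ce$node2), ],
    cost = net$cost
  )
  attr(out, "n_swaps") <- swaps
  attr(out, "n_attempts") <- attempts
  out
}

#' Ring-lattice reference network
#'
#' Places nodes on a ring and adds edges in increasing neighbour-offset
#' order (all offset-1 edges around the ring, then offset-2, and so on)
#' until the requested edge count is reached — the regular-lattice
#' baseline for the small-world criterion. Deterministic.
#'
#' @param n_nodes Number of nodes.
#' @param n_edges Number of edges, at most `n(n-1)/2`.
#' @param nodes Optional node names (default `v1..vn`).
#' @return A `costnet_network`.
#' @examples
#' lattice_reference(6, 6)  # the 6-cycle
#' @export
lattice_reference <- function(n_nodes, n_edges, nodes = NULL) {
  n <- as.integer(n_nodes)
  max_m <- n * (n - 1) / 2
  if (n_edges > max_m) {
    stop("n_edges exceeds the ", max_m, " possible edges on ", n,
         " nodes.", call. = FALSE)
  }
  nodes <- nodes %||% sprintf("v%02d", seq_len(n))
  pairs <- matrix(0L, 0, 2)
  offset <- 1L
  while (nrow(pairs) < n_edges && offset <= n %/% 2) {
    i <- seq_len(n)
    j <- ((i + offset - 1L) %% n) + 1L
    new <- cbind(pmin(i, j), pmax(i, j))
    new <- unique(new)
    new <- new[order(new[, 1], new[, 2]), , drop = FALSE]
    pairs <- rbind(pairs, new)
    offset <- offset + 1L
  }
  pairs <- pairs[seq_len(n_edges), , drop = FALSE]
  network_from_edges(
    nodes,
    tibble::tibble(node1 = nodes[pairs[, 1]], node2 = nodes[pairs[, 2]],
                   r = NA_real_),
    cost = n_edges / max_m
  )
}

#' Efficiency curves over a grid of wiring costs
#'
#' Thresholds a correlation matrix at every cost of a grid and computes
#' the observed global efficiency, local efficiency and cost efficiency,
#' together with null means from degree-preserving random references and
#' the ring-lattice reference at matched cost — the inputs for the
#' small-world criterion and the cost-efficiency peak.
#'
#' @param corr Correlation matrix.
#' @param cost_grid Strictly increasing costs in (0, 1]; default
#'   0.01-0.50 in steps of 0.005.
#' @param n_null Random-reference realizations per cost (default 20).
#' @param seed Seed for the null ensemble (default 1).
#' @return Tibble of class `costnet_efficiency_curve` with columns
#'   `cost`, `e_glob`, `e_loc`, `ce`, `e_glob_rand`, `e_loc_rand`,
#'   `e_glob_latt`; attributes `n_null` and `seed`.
#' @export
efficiency_curves <- function(corr, cost_grid = seq(0.01, 0.5, by = 0.005),
                              n_null = 20, seed = 1L) {
  if (any(cost_grid <= 0) || any(cost_grid > 1)) {
    stop("cost_grid must lie in (0, 1].", call. = FALSE)
  }
  if (is.unsorted(cost_grid, strictly = TRUE)) {
    stop("cost_grid must be strictly increasing.", call. = FALSE)
  }
  rows <- purrr::map_dfr(seq_along(cost_grid), function(ci) {
    cost <- cost_grid[ci]
    net <- threshold_by_cost(corr, cost)
    eg <- global_efficiency(net)
    el <- local_efficiency(net)
    null_stats <- vapply(seq_len(n_null), function(b) {
      rr <- random_reference(net, seed = derive_seed(seed, ci * 1000 + b))
      c(global_efficiency(rr), local_efficiency(rr))
    }, numeric(2))
    latt <- lattice_reference(length(net$nodes), net$n_edges, net$nodes)
    tibble::tibble(
      cost = cost,
      e_glob = eg,
      e_loc = el,
      ce = eg - cost,
      e_glob_rand = mean(null_stats[1, ]),
      e_loc_rand = mean(null_stats[2, ]),
      e_glob_latt = global_efficiency(latt)
    )
  })
  structure(rows, n_null = n_null, seed = seed,
            class = c("costnet_efficiency_curve", class(rows)))
}

#' Average efficiency curves across subjects
#'
#' Element-wise mean of per-subject efficiency curves evaluated on the
#' same cost grid (the group-average curve on which the small-world range
#' and cost-efficiency peak are read off).
#'
#' @param curves List of `costnet_efficiency_curve` tibbles sharing a
#'   grid.
#' @return A `costnet_efficiency_curve` of the means.
#' @export
pool_efficiency_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  grid <- curves[[1]]$cost
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$cost, grid))) {
      stop("All curves must share the same cost grid.", call. = FALSE)
    }
  }
  cols <- c("e_glob", "e_loc", "ce", "e_glob_rand", "e_loc_rand",
            "e_glob_latt")
  out <- tibble::tibble(cost = grid)
  for (cl in cols) {
    out[[cl]] <- rowMeans(vapply(curves, function(cv) cv[[cl]],
                                 numeric(length(grid))))
  }
  structure(out, n_null = attr(curves[[1]], "n_null"),
            seed = attr(curves[[1]], "seed"),
            class = c("costnet_efficiency_curve", class(out)))
}

#' Cost range with the small-world property
#'
#' The small-world regime requires, at a given cost, that the observed
#' network is less globally efficient than its random reference but more
#' than the lattice, and more locally efficient than the random
#' reference. Returns the longest contiguous grid interval satisfying
#' all three strict inequalities (the first such interval on ties); an
#' empty range is signalled by `NA` bounds and `n_costs = 0`.
#'
#' @param curve A `costnet_efficiency_curve`.
#' @return One-row tibble with `cost_min`, `cost_max`, `n_costs`.
#' @export
small_world_cost_range <- function(curve) {
  ok <- curve$e_glob_rand > curve$e_glob &
    curve$e_glob > curve$e_glob_latt &
    curve$e_loc > curve$e_loc_rand
  if (!any(ok)) {
    return(tibble::tibble(cost_min = NA_real_, cost_max = NA_real_,
                          n_costs = 0L))
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  true_runs <- which(runs$values)
  best <- true_runs[which.max(runs$lengths[true_runs])]
  tibble::tibble(
    cost_min = curve$cost[starts[best]],
    cost_max = curve$cost[ends[best]],
    n_costs = as.integer(runs$lengths[best])
  )
}

#' Peak of a smoothed cost-efficiency curve
#'
#' Interpolates the (group-averaged) cost-efficiency samples with a
#' shape-preserving monotone piecewise-cubic Hermite spline
#' (Fritsch-Carlson), evaluates it on a 0.001-step grid spanning the
#' sampled costs, and returns the cost of the maximum (smallest cost on
#' ties).
#'
#' @param cost Cost grid (at least 4 points), or a
#'   `costnet_efficiency_curve` (then `ce` is taken from it).
#' @param ce Cost-efficiency samples matching `cost`.
#' @return Named list with `peak_cost` and `peak_ce`.
#' @export
smooth_and_peak <- function(cost, ce = NULL) {
  if (inherits(cost, "costnet_efficiency_curve") ||
      (is.data.frame(cost) && all(c("cost", "ce") %in% names(cost)))) {
    ce <- cost$ce
    cost <- cost$cost
  }
  if (length(cost) < 4) {
    stop("Need at least 4 grid points to smooth.", call. = FALSE)
  }
  f <- stats::splinefun(cost, ce, method = "monoH.FC")
  fine <- seq(min(cost), max(cost), by = 0.001)
  vals <- f(fine)
  # ties (to numerical precision) resolve to the smallest cost
  peak_at <- which(vals >= max(vals) - 1e-12)[1]
  list(peak_cost = fine[peak_at], peak_ce = vals[peak_at])
}
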