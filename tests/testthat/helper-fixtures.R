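# Shared fixtures and independent oracles for the test suite.

# --- graphs -----------------------------------------------------------------

# Build a costnet network from a character edge list.
make_net <- function(nodes, edges, cost = NULL) {
  edges <- tibble::tibble(node1 = edges[, 1], node2 = edges[, 2],
                          r = NA_real_)
  sw <- edges$node1 > edges$node2
  tmp <- edges$node1[sw]
  edges$node1[sw] <- edges$node2[sw]
  edges$node2[sw] <- tmp
  costnet:::network_from_edges(nodes, edges, cost = cost)
}

# Symmetric random adjacency matrix (Erdos-Renyi), named nodes.
random_adjacency <- function(n, p) {
  adj <- matrix(FALSE, n, n)
  adj[upper.tri(adj)] <- stats::runif(n * (n - 1) / 2) < p
  adj <- adj | t(adj)
  dimnames(adj) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  adj
}

net_from_adjacency <- function(adj) {
  idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  make_net(rownames(adj),
           cbind(rownames(adj)[idx[, 1]], rownames(adj)[idx[, 2]]))
}

# Independent all-pairs shortest-path oracle: Floyd-Warshall.
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  dimnames(d) <- dimnames(adj)
  d
}

# Independent efficiency oracles built on Floyd-Warshall.
oracle_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- floyd_warshall(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  per <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(per)
}

# Exact two-sided Wilcoxon rank-sum p by exhaustive enumeration of group
# assignments (no ties assumed).
oracle_wilcoxon_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  w_all <- apply(combs, 2, function(ix) {
    sum(rank(pooled)[ix]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Closed-form pooled-variance two-sample t and two-sided p.
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2,
       p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

# --- cohorts ----------------------------------------------------------------

# 12-ROI subset spanning all four communities, incl. striatal and
# thalamic nodes.
small_roi <- function() {
  roi <- costnet::roi_table()
  roi[roi$name %in% c("SMA1", "PreSMA1", "PMd1", "M1-1", "SOG1", "LG1",
                      "Cereb1", "DLPFC1", "VLPFC1", "Put1", "Thal1",
                      "Caudate1"), ]
}

no_planted_edges <- function() {
  tibble::tibble(node1 = character(), node2 = character(),
                 coupling = double(), attenuated = logical(),
                 driver = character())
}

# Zero-effect cohort configuration used for type-I calibration: the
# study's group sizes on a reduced node set with nothing planted.
zero_effect_config <- function(seed = 1L, n_per_group = c(HV = 14, PD = 12),
                               frames_per_run = 104) {
  costnet::sim_config(
    roi = small_roi(), n_per_group = n_per_group, n_runs = 1L,
    frames_per_run = frames_per_run,
    planted_edges = no_planted_edges(),
    activity_gain = 0, coupling_sd = 0,
    rt_model = list(intercept_ms = 900, beta_dlpfc_ms = 0,
                    beta_vlpfc_ms = 0, sd_ms = 60),
    seed = seed
  )
}

# Null edges (cross-community, population correlation zero) tested in
# calibration runs.
null_test_edges <- function() {
  tibble::tibble(node1 = c("SMA1", "DLPFC1", "PMd1", "M1-1"),
                 node2 = c("SOG1", "LG1", "VLPFC1", "Cereb1"))
}

# Small planted cohort for fast end-to-end tests (two planted edges on
# the reduced node set).
small_planted_config <- function(seed = 1L) {
  costnet::sim_config(
    roi = small_roi(), n_per_group = c(HV = 7, PD = 6), n_runs = 2L,
    frames_per_run = 104,
    planted_edges = tibble::tibble(
      node1 = c("DLPFC1", "PreSMA1", "Put1", "Caudate1"),
      node2 = c("SMA1", "SOG1", "VLPFC1", "PMd1"),
      coupling = 0.55,
      attenuated = c(TRUE, TRUE, TRUE, FALSE),
      driver = c("shared", "shared", "vlpfc", "dlpfc")
    ),
    seed = seed
  )
}
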