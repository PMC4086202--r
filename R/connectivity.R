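#' Pearson correlation matrix of a condition matrix
#'
#' Computes the symmetric node-by-node Pearson correlation matrix of ROI
#' time series, the substrate for all network construction.
#'
#' @param cond Frames-by-ROI matrix (at least 3 frames, no constant
#'   column).
#' @return A symmetric correlation matrix with unit diagonal, class
#'   `costnet_corr`, carrying the frame count in attribute `n_frames`.
#' @export
correlation_matrix <- function(cond) {
  cond <- unclass(cond)
  attr(cond, "condition") <- NULL
  attr(cond, "frames_dropped_per_block") <- NULL
  cond <- as.matrix(cond)
  if (nrow(cond) < 3) {
    stop("At least 3 frames are required for a correlation matrix.",
         call. = FALSE)
  }
  sds <- apply(cond, 2, stats::sd)
  if (any(sds == 0)) {
    stop("Constant time series for ROI(s): ",
         paste(colnames(cond)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(cond)
  diag(r) <- 1
  structure(r, n_frames = nrow(cond), class = c("costnet_corr", "matrix"))
}

#' Fisher z transform and its inverse
#'
#' `fisher_z()` maps a correlation r to `atanh(r)`, the
#' variance-stabilizing transform used for group statistics on edge
#' strengths; `inverse_fisher_z()` maps back with `tanh`.
#'
#' @param r Correlation value(s), `|r| < 1`.
#' @param z Fisher z value(s).
#' @return Numeric vector of the same length.
#' @examples
#' fisher_z(0.5)            # log(3) / 2
#' inverse_fisher_z(fisher_z(0.3))
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    stop("fisher_z requires |r| < 1.", call. = FALSE)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
inverse_fisher_z <- function(z) tanh(z)

# Upper-triangle edge table of a correlation matrix, ranked for
# cost-thresholding: largest signed r first, ties broken by lexicographic
# node-pair order. Anticorrelations are never preferred over positive
# correlations.
ranked_edges <- function(corr) {
  nodes <- colnames(corr)
  ut <- upper.tri(corr)
  idx <- which(ut, arr.ind = TRUE)
  tbl <- quick_tbl(
    node1 = nodes[idx[, 1]],
    node2 = nodes[idx[, 2]],
    r = corr[ut]
  )
  ce <- canonical_edge(tbl$node1, tbl$node2)
  tbl$node1 <- ce$node1
  tbl$node2 <- ce$node2
  tbl[order(-tbl$r, tbl$node1, tbl$node2), ]
}

#' Binarize a correlation matrix at a fixed wiring cost
#'
#' Retains the `K = round(cost * N(N-1)/2)` strongest edges by signed
#' Pearson r (positive correlations ranked first; rounding is
#' half-away-from-zero; ties at the cutoff break by lexicographic
#' node-pair order), producing an undirected, unweighted network whose
#' edge density is fixed rather than its correlation threshold. The
#' smallest retained correlation (the minimal correlation ratio) is
#' recorded.
#'
#' @param corr Correlation matrix (`costnet_corr` or plain symmetric
#'   matrix with dimnames).
#' @param cost Target fraction of retained edges, in (0, 1].
#' @return A `costnet_network`: list with `nodes`, `edges` (tibble
#'   `node1`, `node2`, `r`), `cost` (requested), `realized_cost`,
#'   `min_retained_r` and `n_edges`.
#' @examples
#' x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' net <- threshold_by_cost(correlation_matrix(x), cost = 2 / 3)
#' net$n_edges  # 2 of the 3 possible edges
#' @export
threshold_by_cost <- function(corr, cost) {
  if (cost <= 0 || cost > 1) {
    stop("cost must lie in (0, 1].", call. = FALSE)
  }
  nodes <- colnames(corr)
  n <- length(nodes)
  m <- n * (n - 1) / 2
  k <- round_half_up(cost * m)
  if (k < 1) {
    stop("cost ", cost, " retains zero edges for ", n, " nodes.",
         call. = FALSE)
  }
  edges <- ranked_edges(corr)[seq_len(k), ]
  structure(list(
    nodes = nodes,
    edges = edges,
    cost = cost,
    realized_cost = k / m,
    min_retained_r = min(edges$r),
    n_edges = as.integer(k)
  ), class = "costnet_network")
}

#' @export
print.costnet_network <- function(x, ...) {
  cat("<costnet_network> ", length(x$nodes), " nodes, ", x$n_edges,
      " edges (cost ", format(x$cost), ", min r ",
      format(round(x$min_retained_r, 3)), ")\n", sep = "")
  invisible(x)
}

# Build a network object directly from an edge table (internal; used by
# null models and readers).
network_from_edges <- function(nodes, edges, cost = NULL) {
  m <- length(nodes) * (length(nodes) - 1) / 2
  structure(list(
    nodes = nodes,
    edges = tibble::as_tibble(edges),
    cost = cost %||% (nrow(edges) / m),
    realized_cost = nrow(edges) / m,
    min_retained_r = if ("r" %in% names(edges) && nrow(edges) > 0) {
      suppressWarnings(min(edges$r))
    } else {
      NA_real_
    },
    n_edges = nrow(edges)
  ), class = "costnet_network")
}

#' Majority-vote group network
#'
#' Keeps an edge if it is present in strictly more than half of the
#' subjects' individual networks, recording per-edge support counts; the
#' resulting common network is the substrate of the group analyses.
#'
#' @param networks List of `costnet_network` objects sharing a node set.
#' @return A `costnet_group_network`: list with `nodes`, `edges` (tibble
#'   `node1`, `node2`, `support`), `group_size` and `threshold` (the
#'   minimal support kept, `floor(n/2) + 1`).
#' @export
group_common_network <- function(networks) {
  if (length(networks) == 0) {
    stop("Need at least one network.", call. = FALSE)
  }
  nodes <- networks[[1]]$nodes
  for (nt in networks) {
    if (!identical(sort(nt$nodes), sort(nodes))) {
      stop("All networks must share the same node set.", call. = FALSE)
    }
  }
  n_sub <- length(networks)
  keys <- unlist(lapply(networks, function(nt) {
    edge_key(nt$edges$node1, nt$edges$node2)
  }))
  support <- table(keys)
  thr <- floor(n_sub / 2) + 1L
  kept <- names(support)[support >= thr]
  parts <- strsplit(kept, "\r", fixed = TRUE)
  edges <- tibble::tibble(
    node1 = vapply(parts, `[`, "", 1),
    node2 = vapply(parts, `[`, "", 2),
    support = as.integer(support[kept])
  )
  edges <- edges[order(edges$node1, edges$node2), ]
  structure(list(
    nodes = nodes,
    edges = edges,
    group_size = n_sub,
    threshold = thr
  ), class = "costnet_group_network")
}

#' @export
print.costnet_group_network <- function(x, ...) {
  cat("<costnet_group_network> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges supported by > half of ", x$group_size,
      " subjects\n", sep = "")
  invisible(x)
}

#' Total connectivity of a group network
#'
#' Percentage of all possible node pairs retained as edges.
#'
#' @param g A `costnet_group_network` (or `costnet_network`).
#' @return A single percentage, `100 * |edges| / (N(N-1)/2)`.
#' @export
total_connectivity_percent <- function(g) {
  n <- length(g$nodes)
  n_edges <- if (!is.null(g$edges)) nrow(g$edges) else 0L
  100 * n_edges / (n * (n - 1) / 2)
}

#' Fisher-z edge strengths of every subject, in long form
#'
#' Collects each subject's Fisher-transformed correlation for a set of
#' edges into the tidy layout the group statistics consume.
#'
#' @param corrs Named list of per-subject correlation matrices.
#' @param subjects Tibble with columns `subject`, `group` (names matching
#'   `corrs`).
#' @param edges Tibble with columns `node1`, `node2`; `NULL` takes every
#'   node pair.
#' @return Tibble with columns `subject`, `group`, `node1`, `node2`, `z`.
#' @export
subject_edge_z <- function(corrs, subjects, edges = NULL) {
  if (is.null(edges)) {
    nodes <- colnames(corrs[[1]])
    idx <- which(upper.tri(corrs[[1]]), arr.ind = TRUE)
    ce <- canonical_edge(nodes[idx[, 1]], nodes[idx[, 2]])
    edges <- tibble::tibble(node1 = ce$node1, node2 = ce$node2)
  } else {
    ce <- canonical_edge(edges$node1, edges$node2)
    edges <- tibble::tibble(node1 = ce$node1, node2 = ce$node2)
  }
  idx <- cbind(edges$node1, edges$node2)
  z <- vapply(subjects$subject, function(s) {
    fisher_z(corrs[[s]][idx])
  }, numeric(nrow(edges)))
  z <- matrix(z, nrow = nrow(edges))
  n_e <- nrow(edges)
  tibble::tibble(
    subject = rep(subjects$subject, each = n_e),
    group = rep(subjects$group, each = n_e),
    node1 = rep.int(edges$node1, nrow(subjects)),
    node2 = rep.int(edges$node2, nrow(subjects)),
    z = as.vector(z)
  )
}
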