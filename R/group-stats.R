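# Edge-wise group statistics on Fisher-z connectivity strengths. The
# tests themselves are delegated to stats::t.test / cor.test /
# wilcox.test / p.adjust; this module owns the edge bookkeeping,
# direction labels, degeneracy flags and the DLPFC-exempt FDR policy.

new_edge_stats <- function(tbl, analysis) {
  tbl$analysis <- analysis
  structure(tbl, class = c("costnet_edge_stats", class(tbl)))
}

#' Edge-wise two-sample t-test between groups
#'
#' Compares each edge's Fisher-z connectivity strength between the two
#' groups with a two-sided two-sample t-test (pooled-variance Student by
#' default; `var_equal = FALSE` gives the Welch form for sensitivity
#' checks). Significance is flagged at `alpha` uncorrected, and the
#' direction of the difference is recorded. An edge with zero variance in
#' both groups is flagged degenerate (p undefined).
#'
#' @param edge_z Tibble with columns `subject`, `group`, `node1`,
#'   `node2`, `z` (from [subject_edge_z()]).
#' @param var_equal Pooled-variance t-test if `TRUE` (default).
#' @param alpha Uncorrected significance level (default 0.05).
#' @return A `costnet_edge_stats` tibble: `node1`, `node2`,
#'   `mean_z_group1`, `mean_z_group2`, `t`, `df`, `p`, `direction`
#'   (e.g. `"HV>PD"`), `significant`, `degenerate`; attribute `groups`
#'   holds the group labels in order.
#' @export
edgewise_group_ttest <- function(edge_z, var_equal = TRUE, alpha = 0.05) {
  groups <- unique(edge_z$group)
  if (length(groups) != 2) {
    stop("edge_z must contain exactly 2 groups, found: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  key <- edge_key(edge_z$node1, edge_z$node2)
  uk <- sort(unique(key))
  idx <- split(seq_along(key), key)[uk]
  is_g1 <- edge_z$group == groups[1]
  rows <- lapply(idx, function(i) {
    pooled_t_row(edge_z$z[i][is_g1[i]], edge_z$z[i][!is_g1[i]], var_equal)
  })
  parts <- strsplit(uk, "\r", fixed = TRUE)
  pull <- function(f) vapply(rows, `[[`, numeric(1), f)
  out <- quick_tbl(
    node1 = vapply(parts, `[`, "", 1),
    node2 = vapply(parts, `[`, "", 2),
    mean_z_group1 = pull("mean_z_group1"),
    mean_z_group2 = pull("mean_z_group2"),
    t = pull("t"),
    df = pull("df"),
    p = pull("p"),
    degenerate = vapply(rows, `[[`, logical(1), "degenerate")
  )
  out$direction <- ifelse(out$mean_z_group1 >= out$mean_z_group2,
                          paste0(groups[1], ">", groups[2]),
                          paste0(groups[2], ">", groups[1]))
  out$significant <- !is.na(out$p) & out$p < alpha
  out <- new_edge_stats(out, "group-diff")
  attr(out, "groups") <- groups
  out
}

pooled_t_row <- function(x, y, var_equal) {
  if (length(x) < 2 || length(y) < 2) {
    stop("Each group needs at least 2 subjects per edge.", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(list(mean_z_group1 = mean(x), mean_z_group2 = mean(y),
                t = NA_real_, df = NA_real_, p = NA_real_,
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(mean_z_group1 = mean(x), mean_z_group2 = mean(y),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Correlation between edge strength and subcortical activity
#'
#' Pearson correlation, across the subjects of one group, between each
#' edge's Fisher-z strength and each subcortical ROI's activity variable
#' — either the mean normalized task signal ([subcortical_activity_index()])
#' or surrogate contrast t-values. Two-sided p, flagged at `alpha`
#' uncorrected.
#'
#' @param edge_z Tibble `subject`, `node1`, `node2`, `z` for one group.
#' @param activity Tibble `subject`, `roi` plus one value column
#'   (`activity` or `t_value`).
#' @param alpha Significance level (default 0.05).
#' @return A `costnet_edge_stats` tibble: `node1`, `node2`, `roi`, `n`,
#'   `r`, `p`, `significant`, `degenerate`.
#' @export
edge_activity_correlation <- function(edge_z, activity, alpha = 0.05) {
  val_col <- setdiff(names(activity), c("subject", "roi"))[1]
  if (is.na(val_col)) {
    stop("activity must carry a value column besides subject and roi.",
         call. = FALSE)
  }
  common <- intersect(unique(edge_z$subject), unique(activity$subject))
  if (length(setdiff(unique(edge_z$subject), common)) > 0 ||
      length(setdiff(unique(activity$subject), common)) > 0) {
    stop("edge_z and activity must cover the same subjects.",
         call. = FALSE)
  }
  act_wide <- tidyr::pivot_wider(activity, names_from = "roi",
                                 values_from = dplyr::all_of(val_col))
  rois <- setdiff(names(act_wide), "subject")
  key <- edge_key(edge_z$node1, edge_z$node2)
  uk <- sort(unique(key))
  idx <- split(seq_along(key), key)[uk]
  n_e <- length(uk)
  n_r <- length(rois)
  r_v <- p_v <- rep(NA_real_, n_e * n_r)
  deg_v <- logical(n_e * n_r)
  for (e in seq_len(n_e)) {
    i <- idx[[e]]
    zv <- edge_z$z[i][match(act_wide$subject, edge_z$subject[i])]
    for (j in seq_len(n_r)) {
      pos <- (e - 1) * n_r + j
      av <- act_wide[[rois[j]]]
      if (stats::sd(zv) == 0 || stats::sd(av) == 0) {
        deg_v[pos] <- TRUE
      } else {
        ct <- stats::cor.test(zv, av)
        r_v[pos] <- unname(ct$estimate)
        p_v[pos] <- ct$p.value
      }
    }
  }
  parts <- strsplit(uk, "\r", fixed = TRUE)
  out <- quick_tbl(
    node1 = rep(vapply(parts, `[`, "", 1), each = n_r),
    node2 = rep(vapply(parts, `[`, "", 2), each = n_r),
    roi = rep.int(rois, n_e),
    n = rep.int(nrow(act_wide), n_e * n_r),
    r = r_v,
    p = p_v,
    degenerate = deg_v
  )
  out$significant <- !is.na(out$p) & out$p < alpha
  new_edge_stats(out, "activity-corr")
}

cor_row <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(n = length(x), r = NA_real_, p = NA_real_,
                degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y)
  list(n = length(x), r = unname(ct$estimate), p = ct$p.value,
       degenerate = FALSE)
}

#' Correlation between cortico-subcortical edge strength and response time
#'
#' Pearson correlation, across subjects of one group, between the
#' Fisher-z strength of each cortico-subcortical edge and the subject's
#' mean response time. Edges whose cortical node is in `dlpfc_nodes` are
#' tested at `alpha` uncorrected (a pre-specified directional
#' hypothesis); all other edges are Benjamini-Hochberg adjusted at
#' `alpha`.
#'
#' @param edge_z Tibble `subject`, `node1`, `node2`, `z` for one group;
#'   every edge must pair one cortical with one subcortical node.
#' @param rt Tibble `subject`, `rt_ms` (from [mean_rt()]).
#' @param roi ROI table (identifies the subcortical member of each edge).
#' @param dlpfc_nodes Cortical labels exempt from FDR correction
#'   (default `DLPFC1`-`DLPFC3`).
#' @param alpha Significance level (default 0.05).
#' @return A `costnet_edge_stats` tibble: `node1`, `node2`, `cortical`,
#'   `subcortical`, `n`, `r`, `p`, `p_adj` (`NA` for the uncorrected
#'   DLPFC rows), `significant`, `degenerate`.
#' @export
edge_rt_correlation <- function(edge_z, rt, roi,
                                dlpfc_nodes = c("DLPFC1", "DLPFC2", "DLPFC3"),
                                alpha = 0.05) {
  sc <- roi$name[roi$subcortical]
  rt <- rt[match(unique(edge_z$subject), rt$subject), ]
  if (anyNA(rt$rt_ms)) {
    stop("Response time missing for some subjects.", call. = FALSE)
  }
  key <- edge_key(edge_z$node1, edge_z$node2)
  uk <- sort(unique(key))
  idx <- split(seq_along(key), key)[uk]
  rows <- lapply(idx, function(i) {
    ord <- match(rt$subject, edge_z$subject[i])
    cor_row(edge_z$z[i][ord], rt$rt_ms)
  })
  parts <- strsplit(uk, "\r", fixed = TRUE)
  out <- quick_tbl(
    node1 = vapply(parts, `[`, "", 1),
    node2 = vapply(parts, `[`, "", 2),
    n = vapply(rows, `[[`, numeric(1), "n"),
    r = vapply(rows, `[[`, numeric(1), "r"),
    p = vapply(rows, `[[`, numeric(1), "p"),
    degenerate = vapply(rows, `[[`, logical(1), "degenerate")
  )
  is_sc1 <- out$node1 %in% sc
  is_sc2 <- out$node2 %in% sc
  if (any(is_sc1 == is_sc2)) {
    bad <- paste(out$node1[is_sc1 == is_sc2], out$node2[is_sc1 == is_sc2],
                 sep = "--")
    stop("Edges must pair one cortical with one subcortical node: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out$cortical <- ifelse(is_sc1, out$node2, out$node1)
  out$subcortical <- ifelse(is_sc1, out$node1, out$node2)
  uncorrected <- out$cortical %in% dlpfc_nodes
  out$p_adj <- NA_real_
  out$p_adj[!uncorrected] <- bh_fdr(out$p[!uncorrected])
  out$significant <- !is.na(out$p) &
    ifelse(uncorrected, out$p < alpha, out$p_adj < alpha)
  new_edge_stats(out, "rt-corr")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), as used for the
#' non-DLPFC response-time correlations.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_fdr(c(0.005, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-subject shortest path lengths from source nodes
#'
#' Collects, for every subject's individual network, the shortest path
#' length from each source node to every other node, in the tidy layout
#' [pathlength_group_comparison()] consumes.
#'
#' @param networks Named list of per-subject `costnet_network` objects.
#' @param subjects Tibble `subject`, `group`.
#' @param source_nodes Source node labels (e.g. the left/right primary
#'   motor cortex).
#' @return Tibble `subject`, `group`, `source`, `target`, `length`
#'   (`NA` when unreachable).
#' @export
subject_path_lengths <- function(networks, subjects, source_nodes) {
  parts <- lapply(seq_len(nrow(subjects)), function(k) {
    s <- subjects$subject[k]
    d <- shortest_path_lengths(networks[[s]])
    missing <- setdiff(source_nodes, rownames(d))
    if (length(missing) > 0) {
      stop("Source node(s) not in the network: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    src_v <- tgt_v <- character(0)
    len_v <- numeric(0)
    for (src in source_nodes) {
      targets <- setdiff(rownames(d), src)
      src_v <- c(src_v, rep.int(src, length(targets)))
      tgt_v <- c(tgt_v, targets)
      len_v <- c(len_v, d[src, targets])
    }
    quick_tbl(subject = rep.int(s, length(src_v)),
              group = rep.int(subjects$group[k], length(src_v)),
              source = src_v, target = tgt_v, length = len_v)
  })
  dplyr::bind_rows(parts)
}

#' Group comparison of path lengths from source nodes
#'
#' For each (source, target) pair, compares the distribution of
#' individual shortest path lengths between the two groups with a
#' two-sided Wilcoxon rank-sum test (exact when sample sizes permit and
#' there are no ties, normal approximation with tie correction
#' otherwise). Subjects whose pair is unreachable are excluded from that
#' pair's test and counted; a pair with fewer than 2 finite lengths in
#' either group is flagged untestable.
#'
#' @param path_lengths Tibble from [subject_path_lengths()].
#' @param alpha Significance level (default 0.05).
#' @return A `costnet_edge_stats` tibble: `source`, `target`,
#'   `mean_group1`, `sd_group1`, `n_group1`, `mean_group2`, `sd_group2`,
#'   `n_group2`, `n_excluded`, `p`, `significant`, `untestable`;
#'   attribute `groups`.
#' @export
pathlength_group_comparison <- function(path_lengths, alpha = 0.05) {
  groups <- unique(path_lengths$group)
  if (length(groups) != 2) {
    stop("path_lengths must contain exactly 2 groups.", call. = FALSE)
  }
  key <- paste(path_lengths$source, path_lengths$target, sep = "\r")
  uk <- sort(unique(key))
  idx <- split(seq_along(key), key)[uk]
  is_g1 <- path_lengths$group == groups[1]
  rows <- lapply(idx, function(i) {
    x <- path_lengths$length[i][is_g1[i]]
    y <- path_lengths$length[i][!is_g1[i]]
    xf <- x[is.finite(x)]
    yf <- y[is.finite(y)]
    untestable <- length(xf) < 2 || length(yf) < 2
    p <- if (untestable) {
      NA_real_
    } else {
      suppressWarnings(stats::wilcox.test(xf, yf)$p.value)
    }
    list(
      mean_group1 = if (length(xf)) mean(xf) else NA_real_,
      sd_group1 = if (length(xf) > 1) stats::sd(xf) else NA_real_,
      n_group1 = length(xf),
      mean_group2 = if (length(yf)) mean(yf) else NA_real_,
      sd_group2 = if (length(yf) > 1) stats::sd(yf) else NA_real_,
      n_group2 = length(yf),
      n_excluded = sum(!is.finite(x)) + sum(!is.finite(y)),
      p = p,
      untestable = untestable
    )
  })
  parts <- strsplit(uk, "\r", fixed = TRUE)
  pull_n <- function(f) vapply(rows, `[[`, numeric(1), f)
  out <- quick_tbl(
    source = vapply(parts, `[`, "", 1),
    target = vapply(parts, `[`, "", 2),
    mean_group1 = pull_n("mean_group1"),
    sd_group1 = pull_n("sd_group1"),
    n_group1 = as.integer(pull_n("n_group1")),
    mean_group2 = pull_n("mean_group2"),
    sd_group2 = pull_n("sd_group2"),
    n_group2 = as.integer(pull_n("n_group2")),
    n_excluded = as.integer(pull_n("n_excluded")),
    p = pull_n("p"),
    untestable = vapply(rows, `[[`, logical(1), "untestable")
  )
  out$significant <- !is.na(out$p) & out$p < alpha
  out <- new_edge_stats(out, "path-length")
  attr(out, "groups") <- groups
  out
}
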