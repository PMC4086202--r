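#' Run the full connectivity analysis on a cohort
#'
#' Sequences the whole method over a (simulated or assembled) two-group
#' cohort: run-wise global normalization, condition segmentation with
#' hemodynamic trimming, per-subject correlation matrices, fixed-cost
#' binarization, majority-vote group networks and total connectivity,
#' (optionally) efficiency curves with null models, the small-world cost
#' range and the smoothed cost-efficiency peak per group, edge-wise group
#' t-tests on the union common network, edge-activity correlations
#' (group 1 against mean subcortical signal, group 2 against surrogate
#' contrast t-values when available), cortico-subcortical edge-RT
#' correlations with the DLPFC-exempt FDR policy, and Wilcoxon
#' path-length comparisons from the primary motor nodes.
#'
#' @param cohort A `costnet_cohort` (see [simulate_cohort()],
#'   [read_cohort()]).
#' @param cost Wiring cost for the individual networks (default 0.28).
#' @param condition Task condition analysed (default `"SI"`).
#' @param trim_seconds Block-onset trim (default 10 s).
#' @param compute_curves Whether to compute efficiency curves (the
#'   costly stage; default `TRUE`).
#' @param cost_grid Cost grid for the curves (default 0.01-0.50 step
#'   0.005).
#' @param n_null Random-reference realizations per cost (default 20).
#' @param alpha Significance level for all edge statistics (default
#'   0.05).
#' @param dlpfc_nodes Cortical labels exempt from FDR in the RT analysis.
#' @param rt_nodes Cortical labels for the RT analysis; `NULL` derives
#'   them as the distinct cortical nodes of the significant
#'   group-difference edges.
#' @param source_nodes Sources for the path-length comparison; defaults
#'   to the motor nodes `M1-1`, `M1-2` when present.
#' @param var_equal Pooled-variance t-test if `TRUE` (default).
#' @param seed Seed for the null-model ensemble (default 1).
#' @return A list of class `costnet_analysis`; see [tidy()] and
#'   [glance()] methods, and [write_analysis()].
#' @export
analyze_cohort <- function(cohort, cost = 0.28, condition = "SI",
                           trim_seconds = 10, compute_curves = TRUE,
                           cost_grid = seq(0.01, 0.5, by = 0.005),
                           n_null = 20, alpha = 0.05,
                           dlpfc_nodes = c("DLPFC1", "DLPFC2", "DLPFC3"),
                           rt_nodes = NULL, source_nodes = NULL,
                           var_equal = TRUE, seed = 1L) {
  stopifnot(inherits(cohort, "costnet_cohort"))
  groups <- unique(cohort$subjects$group)
  if (length(groups) != 2) {
    stop("analyze_cohort expects exactly 2 groups.", call. = FALSE)
  }

  cond_mats <- run_stage("segmentation", cohort_condition_matrices(
    cohort, condition, trim_seconds))
  corrs <- run_stage("correlation", lapply(cond_mats, correlation_matrix))
  nets <- run_stage("thresholding", lapply(corrs, threshold_by_cost, cost = cost))

  by_group <- split(cohort$subjects$subject, cohort$subjects$group)[groups]
  group_nets <- lapply(by_group, function(subs) {
    group_common_network(nets[subs])
  })
  group_summary <- purrr::map_dfr(groups, function(g) {
    min_r <- vapply(nets[by_group[[g]]], `[[`, 0, "min_retained_r")
    tibble::tibble(
      group = g,
      n_subjects = length(by_group[[g]]),
      n_edges = nrow(group_nets[[g]]$edges),
      total_connectivity_pct = total_connectivity_percent(group_nets[[g]]),
      min_retained_r_mean = mean(min_r),
      min_retained_r_sd = stats::sd(min_r)
    )
  })

  curves <- small_world <- ce_peak <- NULL
  if (compute_curves) {
    subj_curves <- run_stage("efficiency curves", lapply(
      seq_along(corrs), function(i) {
        efficiency_curves(corrs[[i]], cost_grid, n_null,
                          seed = derive_seed(seed, i))
      }))
    names(subj_curves) <- names(corrs)
    curves <- lapply(by_group, function(subs) {
      pool_efficiency_curves(subj_curves[subs])
    })
    small_world <- purrr::map_dfr(groups, function(g) {
      dplyr::bind_cols(tibble::tibble(group = g),
                       small_world_cost_range(curves[[g]]))
    })
    ce_peak <- purrr::map_dfr(groups, function(g) {
      pk <- smooth_and_peak(curves[[g]])
      tibble::tibble(group = g, peak_cost = pk$peak_cost,
                     peak_ce = pk$peak_ce)
    })
  }

  union_edges <- dplyr::distinct(dplyr::bind_rows(
    group_nets[[1]]$edges[, c("node1", "node2")],
    group_nets[[2]]$edges[, c("node1", "node2")]
  ))
  edge_z_union <- subject_edge_z(corrs, cohort$subjects, union_edges)
  group_diff <- run_stage("group comparison", edgewise_group_ttest(
    edge_z_union, var_equal = var_equal, alpha = alpha))

  sig_g1 <- group_diff[group_diff$significant &
                         group_diff$direction == paste0(groups[1], ">",
                                                        groups[2]), ]

  activity_stats <- NULL
  if (nrow(sig_g1) > 0) {
    g1_subs <- by_group[[1]]
    act <- purrr::map_dfr(g1_subs, function(s) {
      dplyr::bind_cols(tibble::tibble(subject = s),
                       subcortical_activity_index(cond_mats[[s]], cohort$roi))
    })
    z_g1 <- edge_z_union[edge_z_union$group == groups[1] &
                           edge_key(edge_z_union$node1, edge_z_union$node2) %in%
                           edge_key(sig_g1$node1, sig_g1$node2), ]
    act_tab <- run_stage("activity correlation", edge_activity_correlation(
      z_g1[, c("subject", "node1", "node2", "z")], act, alpha = alpha))
    act_tab$group <- groups[1]
    act_tab$variable <- "mean_signal"
    activity_stats <- act_tab
    if (!is.null(cohort$surrogate_t) && nrow(cohort$surrogate_t) > 0) {
      g2_subs <- by_group[[2]]
      tsur <- cohort$surrogate_t[cohort$surrogate_t$subject %in% g2_subs, ]
      z_g2 <- edge_z_union[edge_z_union$group == groups[2] &
                             edge_key(edge_z_union$node1, edge_z_union$node2) %in%
                             edge_key(sig_g1$node1, sig_g1$node2), ]
      act_tab2 <- run_stage("activity correlation", edge_activity_correlation(
        z_g2[, c("subject", "node1", "node2", "z")], tsur, alpha = alpha))
      act_tab2$group <- groups[2]
      act_tab2$variable <- "surrogate_t"
      activity_stats <- dplyr::bind_rows(activity_stats, act_tab2)
    }
  }

  rt_stats <- NULL
  if (!is.null(cohort$events) && nrow(cohort$events) > 0) {
    rts <- run_stage("response times", mean_rt(cohort$events, condition))
    sc <- cohort$roi$name[cohort$roi$subcortical]
    if (is.null(rt_nodes)) {
      sig_nodes <- unique(c(
        group_diff$node1[group_diff$significant],
        group_diff$node2[group_diff$significant]
      ))
      rt_nodes <- setdiff(sig_nodes, sc)
      rt_nodes <- unique(c(rt_nodes, intersect(dlpfc_nodes, cohort$roi$name)))
    }
    if (length(rt_nodes) > 0 && length(sc) > 0) {
      pairs <- tidyr::expand_grid(node1 = rt_nodes, node2 = sc)
      z_pairs <- subject_edge_z(corrs, cohort$subjects, pairs)
      rt_stats <- purrr::map_dfr(groups, function(g) {
        zp <- z_pairs[z_pairs$group == g, c("subject", "node1", "node2", "z")]
        tab <- run_stage("RT correlation", edge_rt_correlation(
          zp, rts[rts$subject %in% by_group[[g]], ], cohort$roi,
          dlpfc_nodes = dlpfc_nodes, alpha = alpha))
        tab$group <- g
        tab
      })
    }
  }

  if (is.null(source_nodes)) {
    source_nodes <- intersect(c("M1-1", "M1-2"), cohort$roi$name)
  }
  path_stats <- NULL
  if (length(source_nodes) > 0) {
    pl <- subject_path_lengths(nets, cohort$subjects, source_nodes)
    path_stats <- run_stage("path-length comparison",
                            pathlength_group_comparison(pl, alpha = alpha))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("costnet")),
    groups = groups,
    n_subjects = as.integer(table(cohort$subjects$group)[groups]),
    cost = cost,
    condition = condition,
    trim_seconds = trim_seconds,
    frames_used = as.integer(vapply(cond_mats, nrow, 0L)[1]),
    cost_grid = if (compute_curves) range(cost_grid) else NULL,
    cost_grid_step = if (compute_curves && length(cost_grid) > 1) {
      cost_grid[2] - cost_grid[1]
    } else {
      NULL
    },
    n_null = if (compute_curves) n_null else NULL,
    alpha = alpha,
    dlpfc_nodes = dlpfc_nodes,
    rt_nodes = rt_nodes,
    source_nodes = source_nodes,
    var_equal = var_equal,
    seed = as.integer(seed)
  )

  structure(list(
    subjects = cohort$subjects,
    networks = nets,
    group_networks = group_nets,
    group_summary = group_summary,
    curves = curves,
    small_world = small_world,
    ce_peak = ce_peak,
    stats = list(group_diff = group_diff, activity = activity_stats,
                 rt = rt_stats, path_length = path_stats),
    manifest = manifest
  ), class = "costnet_analysis")
}

# Prefix stage names onto error messages so a pipeline abort names the
# stage that failed.
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("Pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' @export
print.costnet_analysis <- function(x, ...) {
  cat("<costnet_analysis>\n")
  print(x$group_summary)
  if (!is.null(x$ce_peak)) {
    cat("Cost-efficiency peaks:\n")
    print(x$ce_peak)
  }
  nsig <- sum(x$stats$group_diff$significant)
  cat(nsig, "edge(s) differ between groups at uncorrected p <",
      x$manifest$alpha, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the edge statistics of an analysis
#'
#' Binds all edge-level statistics tables (group differences, activity
#' correlations, RT correlations, path-length comparisons) into one long
#' tibble keyed by the `analysis` column.
#'
#' @param x A `costnet_analysis`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.costnet_analysis <- function(x, ...) {
  dplyr::bind_rows(lapply(x$stats, function(tb) {
    if (is.null(tb)) NULL else tibble::as_tibble(tb)
  }))
}

#' One-row summary of an analysis
#'
#' @param x A `costnet_analysis`.
#' @param ... Unused.
#' @return A one-row tibble: group sizes, total connectivity and minimal
#'   retained correlation per group, small-world range and
#'   cost-efficiency peak per group (when curves were computed), and the
#'   count of significant group-difference edges per direction.
#' @export
glance.costnet_analysis <- function(x, ...) {
  g <- x$group_summary$group
  out <- tibble::tibble(
    cost = x$manifest$cost,
    n_group1 = x$group_summary$n_subjects[1],
    n_group2 = x$group_summary$n_subjects[2],
    total_connectivity_pct_group1 = x$group_summary$total_connectivity_pct[1],
    total_connectivity_pct_group2 = x$group_summary$total_connectivity_pct[2],
    min_retained_r_group1 = x$group_summary$min_retained_r_mean[1],
    min_retained_r_group2 = x$group_summary$min_retained_r_mean[2]
  )
  gd <- x$stats$group_diff
  dir1 <- paste0(g[1], ">", g[2])
  out$n_sig_group1_gt_group2 <- sum(gd$significant & gd$direction == dir1)
  out$n_sig_group2_gt_group1 <- sum(gd$significant & gd$direction != dir1)
  if (!is.null(x$small_world)) {
    out$sw_cost_min_group1 <- x$small_world$cost_min[1]
    out$sw_cost_max_group1 <- x$small_world$cost_max[1]
    out$sw_cost_min_group2 <- x$small_world$cost_min[2]
    out$sw_cost_max_group2 <- x$small_world$cost_max[2]
    out$ce_peak_group1 <- x$ce_peak$peak_cost[1]
    out$ce_peak_group2 <- x$ce_peak$peak_cost[2]
  }
  out
}

#' Replicated simulation study: planted-effect recovery and calibration
#'
#' Simulates `n_replicates` cohorts from a configuration, analyses each
#' with the package's own pipeline stages, and reports per replicate
#' whether the planted effects were recovered: the attenuated edges'
#' group difference (majority of planted edges significant with the
#' group-1 > group-2 direction), the activity-coupling sign pattern
#' (median edge-activity correlation positive over striatal and negative
#' over thalamic ROIs in group 1), and the response-time sign pattern
#' (negative DLPFC-striatum and positive VLPFC-striatum edge-RT
#' correlation in group 1). Under a zero-effect configuration the
#' rejection-rate columns measure empirical type-I error instead.
#'
#' @param config A `costnet_sim_config`. For recovery runs it should
#'   plant effects; for calibration runs use a zero-effect configuration
#'   and supply `test_edges`.
#' @param n_replicates Number of simulated cohorts.
#' @param seed Master seed; each replicate derives its own.
#' @param alpha Significance level (default 0.05).
#' @param cost Wiring cost for the per-subject networks used in the
#'   Wilcoxon path-length stage (default 0.28).
#' @param trim_seconds Block-onset trim (default 10).
#' @param test_edges Tibble `node1`, `node2` of edges to test; defaults
#'   to the configuration's planted edges.
#' @param include Character subset of
#'   `c("ttest", "activity", "rt", "wilcoxon")` selecting the stages to
#'   run per replicate.
#' @return Tibble with one row per replicate: rejection rates per stage
#'   and the three recovery indicators (where applicable).
#' @export
run_simulation_study <- function(config, n_replicates, seed = 1L,
                                 alpha = 0.05, cost = 0.28,
                                 trim_seconds = 10, test_edges = NULL,
                                 include = c("ttest", "activity", "rt",
                                             "wilcoxon")) {
  stopifnot(inherits(config, "costnet_sim_config"), n_replicates >= 1)
  include <- match.arg(include, several.ok = TRUE)
  if (is.null(test_edges)) {
    test_edges <- config$planted_edges[, c("node1", "node2")]
  }
  if (nrow(test_edges) == 0) {
    stop("No edges to test: supply test_edges or plant edges in the ",
         "configuration.", call. = FALSE)
  }
  groups <- names(config$n_per_group)
  pe <- config$planted_edges
  striatal <- subcortical_rois(config$roi, "striatal")
  thalamic <- subcortical_rois(config$roi, "thalamic")

  purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
    cfg_r <- config
    cfg_r$seed <- as.integer(derive_seed(seed, rep_i) %% 2147483647)
    coh <- simulate_cohort(cfg_r)
    cond <- cohort_condition_matrices(coh, "SI", trim_seconds)
    corrs <- lapply(cond, correlation_matrix)
    row <- tibble::tibble(replicate = rep_i)

    if ("ttest" %in% include) {
      ez <- subject_edge_z(corrs, coh$subjects, test_edges)
      tt <- edgewise_group_ttest(ez, alpha = alpha)
      row$ttest_rejection_rate <- mean(tt$significant)
      atten <- pe[pe$attenuated, ]
      if (nrow(atten) > 0) {
        keys <- edge_key(atten$node1, atten$node2)
        tta <- tt[edge_key(tt$node1, tt$node2) %in% keys, ]
        hit <- tta$significant &
          tta$direction == paste0(groups[1], ">", groups[2])
        row$attenuation_hit_rate <- mean(hit)
        row$attenuation_detected <- mean(hit) > 0.5
      }
    }

    g1 <- coh$subjects$subject[coh$subjects$group == groups[1]]
    if ("activity" %in% include) {
      act <- purrr::map_dfr(g1, function(s) {
        dplyr::bind_cols(tibble::tibble(subject = s),
                         subcortical_activity_index(cond[[s]], coh$roi))
      })
      ez1 <- subject_edge_z(corrs, coh$subjects, test_edges)
      ez1 <- ez1[ez1$group == groups[1],
                 c("subject", "node1", "node2", "z")]
      ac <- edge_activity_correlation(ez1, act, alpha = alpha)
      row$activity_rejection_rate <- mean(ac$significant)
      if (nrow(pe) > 0) {
        shared <- pe[pe$driver == "shared", ]
        acs <- ac[edge_key(ac$node1, ac$node2) %in%
                    edge_key(shared$node1, shared$node2), ]
        r_str <- acs$r[acs$roi %in% striatal]
        r_tha <- acs$r[acs$roi %in% thalamic]
        row$activity_striatal_median_r <- stats::median(r_str)
        row$activity_thalamic_median_r <- stats::median(r_tha)
        row$activity_signs_recovered <-
          stats::median(r_str) > 0 && stats::median(r_tha) < 0
      }
    }

    if ("rt" %in% include) {
      rts <- mean_rt(coh$events, "SI")
      drivers <- pe[pe$driver %in% c("dlpfc", "vlpfc"), ]
      rt_edges <- if (nrow(drivers) > 0) {
        drivers[, c("node1", "node2")]
      } else {
        test_edges
      }
      ezr <- subject_edge_z(corrs, coh$subjects, rt_edges)
      ezr <- ezr[ezr$group == groups[1], ]
      rt1 <- rts[rts$subject %in% g1, ]
      ekey <- edge_key(ezr$node1, ezr$node2)
      uk <- sort(unique(ekey))
      stats_e <- vapply(uk, function(kk) {
        i <- which(ekey == kk)
        z <- ezr$z[i][match(rt1$subject, ezr$subject[i])]
        ct <- stats::cor.test(z, rt1$rt_ms)
        c(unname(ct$estimate), ct$p.value)
      }, numeric(2))
      parts <- strsplit(uk, "\r", fixed = TRUE)
      per_edge <- quick_tbl(
        node1 = vapply(parts, `[`, "", 1),
        node2 = vapply(parts, `[`, "", 2),
        r = stats_e[1, ],
        p = stats_e[2, ]
      )
      row$rt_rejection_rate <- mean(per_edge$p < alpha)
      if (nrow(drivers) > 0) {
        kd <- edge_key(drivers$node1[drivers$driver == "dlpfc"],
                       drivers$node2[drivers$driver == "dlpfc"])
        kv <- edge_key(drivers$node1[drivers$driver == "vlpfc"],
                       drivers$node2[drivers$driver == "vlpfc"])
        pk <- edge_key(per_edge$node1, per_edge$node2)
        r_d <- per_edge$r[pk %in% kd]
        r_v <- per_edge$r[pk %in% kv]
        row$rt_dlpfc_r <- if (length(r_d)) mean(r_d) else NA_real_
        row$rt_vlpfc_r <- if (length(r_v)) mean(r_v) else NA_real_
        row$rt_signs_recovered <- length(r_d) > 0 && length(r_v) > 0 &&
          all(r_d < 0) && all(r_v > 0)
      }
    }

    if ("wilcoxon" %in% include) {
      nets <- lapply(corrs, threshold_by_cost, cost = cost)
      src <- coh$roi$name[1]
      pl <- subject_path_lengths(nets, coh$subjects, src)
      pc <- pathlength_group_comparison(pl, alpha = alpha)
      testable <- !pc$untestable
      row$wilcoxon_rejection_rate <- if (any(testable)) {
        mean(pc$significant[testable])
      } else {
        NA_real_
      }
    }
    row
  })
}
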