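#' Plot efficiency curves against their null models
#'
#' Draws the observed global efficiency, local efficiency and cost
#' efficiency across wiring costs, with the degree-preserving random and
#' ring-lattice null means as dashed references — the visual check of
#' the small-world regime.
#'
#' @param object A `costnet_efficiency_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.costnet_efficiency_curve <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-"cost", names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(
      family = dplyr::case_when(
        .data$metric %in% c("e_glob", "e_glob_rand",
                            "e_glob_latt") ~ "global efficiency",
        .data$metric %in% c("e_loc", "e_loc_rand") ~ "local efficiency",
        TRUE ~ "cost efficiency"
      ),
      reference = .data$metric %in% c("e_glob_rand", "e_loc_rand",
                                      "e_glob_latt")
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cost, y = .data$value,
                                     colour = .data$metric,
                                     linetype = .data$reference)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~family, ncol = 1, scales = "free_y") +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(x = "wiring cost", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an edge-statistics table
#'
#' Effect size against evidence for every tested edge: the t statistic
#' (group differences) or correlation r (activity/RT analyses) on the x
#' axis and `-log10(p)` on the y axis, significant rows highlighted.
#'
#' @param object A `costnet_edge_stats` tibble.
#' @param alpha Reference significance level drawn as a horizontal line
#'   (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.costnet_edge_stats <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$effect <- if ("t" %in% names(df)) df$t else df$r
  xlab <- if ("t" %in% names(df)) "t statistic" else "Pearson r"
  df <- df[!is.na(df$p), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect,
                                   y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = xlab, y = expression(-log[10](p)),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Plot the group-average curves of an analysis
#'
#' @param object A `costnet_analysis` with computed curves.
#' @param ... Unused.
#' @return A ggplot object (curves faceted by group).
#' @export
autoplot.costnet_analysis <- function(object, ...) {
  if (is.null(object$curves)) {
    stop("This analysis was run without efficiency curves.", call. = FALSE)
  }
  long <- purrr::imap_dfr(object$curves, function(cv, g) {
    dplyr::bind_cols(tibble::tibble(group = g), tibble::as_tibble(cv))
  }) |>
    tidyr::pivot_longer(-c("cost", "group"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cost, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "wiring cost", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
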