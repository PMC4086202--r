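# Readers and writers for the package's tabular interchange formats.
# Everything is plain text: TSV for matrices and tables, JSON for
# manifests and ground truth, GraphML (via igraph) for networks.

#' Read and write frames-by-ROI time-series matrices as TSV
#'
#' One file per subject-run: a header row of ROI names, one row per
#' frame.
#'
#' @param path File path.
#' @param mat Frames-by-ROI matrix with column names.
#' @return `read_timeseries_tsv()` returns a numeric matrix;
#'   `write_timeseries_tsv()` returns `path` invisibly.
#' @export
read_timeseries_tsv <- function(path) {
  if (!file.exists(path)) {
    stop("Time-series file does not exist: ", path, call. = FALSE)
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double()), progress = FALSE)
  as.matrix(df)
}

#' @rdname read_timeseries_tsv
#' @export
write_timeseries_tsv <- function(mat, path) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(unclass(mat))), path,
                   progress = FALSE)
  invisible(path)
}

#' Write a correlation matrix as TSV with ROI name headers
#'
#' @param corr Correlation matrix with dimnames.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_corr_tsv <- function(corr, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(corr)))
  df <- dplyr::bind_cols(tibble::tibble(roi = colnames(corr)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_corr_tsv
#' @export
read_corr_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    roi = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$roi
  structure(m, class = c("costnet_corr", "matrix"))
}

#' Export a network as an edge-list TSV and, optionally, GraphML
#'
#' The edge list carries the node-name pair, the retained correlation
#' (and Fisher z) when known, and the support count for group networks.
#'
#' @param net A `costnet_network` or `costnet_group_network`.
#' @param path Output TSV path.
#' @param graphml Optional path for a GraphML export of the same
#'   network.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, graphml = NULL) {
  edges <- tibble::as_tibble(net$edges)
  if ("r" %in% names(edges)) {
    edges$z <- ifelse(abs(edges$r) < 1, atanh(edges$r), NA_real_)
  }
  readr::write_tsv(edges, path, progress = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = net$nodes)
    )
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}

#' Read a 4-D NIfTI volume for ROI extraction
#'
#' Thin wrapper around RNifti returning the array and the voxel-to-mm
#' affine in the 1-based convention [extract_roi_timeseries()] expects.
#'
#' @param path NIfTI file path.
#' @return List with `volume` (4-D array) and `affine` (4x4 matrix).
#' @export
read_nifti_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("Reading NIfTI volumes requires the RNifti package.",
         call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  aff0 <- RNifti::xform(img)  # maps 0-based voxel indices to mm
  aff <- aff0
  aff[1:3, 4] <- aff0[1:3, 4] - aff0[1:3, 1:3] %*% rep(1, 3)
  list(volume = unclass(img), affine = aff)
}

#' Write a simulated volume fixture to NIfTI
#'
#' @param fixture List from [simulate_volume_fixture()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(fixture, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("Writing NIfTI volumes requires the RNifti package.",
         call. = FALSE)
  }
  aff <- fixture$affine
  aff0 <- aff
  aff0[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% rep(1, 3)
  img <- RNifti::asNifti(fixture$volume)
  img <- RNifti::`sform<-`(img, structure(aff0, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a simulated cohort to a directory of plain-text files
#'
#' Lays a cohort out as the file set [run_pipeline()] reads: the ROI
#' table, a subjects table, the task schedule, one time-series TSV per
#' subject-run (`<subject>_run<r>.tsv`), the button-press events, the
#' surrogate t-values (if any), and the planted ground truth as JSON.
#'
#' @param cohort A `costnet_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
  readr::write_tsv(cohort$roi, file.path(dir, "roi_table.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$subjects, file.path(dir, "subjects.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$schedule, file.path(dir, "schedule.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$events, file.path(dir, "events.tsv"),
                   progress = FALSE)
  if (!is.null(cohort$surrogate_t) && nrow(cohort$surrogate_t) > 0) {
    readr::write_tsv(cohort$surrogate_t,
                     file.path(dir, "surrogate_t.tsv"), progress = FALSE)
  }
  for (s in names(cohort$runs)) {
    for (r in seq_along(cohort$runs[[s]])) {
      write_timeseries_tsv(
        cohort$runs[[s]][[r]],
        file.path(dir, "timeseries", sprintf("%s_run%d.tsv", s, r))
      )
    }
  }
  meta <- list(tr_seconds = cohort$tr_seconds)
  if (!is.null(cohort$truth)) {
    meta$planted_effects <- planted_truth_report(cohort$truth)
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `costnet_cohort` (with `truth = NULL`; the planted-effect
#'   report, if present, is attached as attribute `planted_effects`).
#' @export
read_cohort <- function(dir) {
  need <- c("roi_table.tsv", "subjects.tsv", "schedule.tsv", "events.tsv",
            "meta.json")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      stop("Cohort directory is missing ", f, ": ", file.path(dir, f),
           call. = FALSE)
    }
  }
  roi <- roi_table(file.path(dir, "roi_table.tsv"))
  subjects <- readr::read_tsv(file.path(dir, "subjects.tsv"),
                              col_types = "cc", progress = FALSE)
  schedule <- readr::read_tsv(file.path(dir, "schedule.tsv"),
                              col_types = "iic", progress = FALSE)
  events <- readr::read_tsv(file.path(dir, "events.tsv"),
                            col_types = readr::cols(
                              subject = readr::col_character(),
                              condition = readr::col_character(),
                              .default = readr::col_double()),
                            progress = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  tpath <- file.path(dir, "surrogate_t.tsv")
  surrogate_t <- if (file.exists(tpath)) {
    readr::read_tsv(tpath, col_types = "ccd", progress = FALSE)
  } else {
    NULL
  }
  n_runs <- length(unique(schedule$run))
  runs <- lapply(subjects$subject, function(s) {
    lapply(seq_len(n_runs), function(r) {
      read_timeseries_tsv(
        file.path(dir, "timeseries", sprintf("%s_run%d.tsv", s, r)))
    })
  })
  names(runs) <- subjects$subject
  out <- structure(list(
    roi = roi, subjects = subjects, runs = runs, schedule = schedule,
    tr_seconds = meta$tr_seconds, events = events,
    surrogate_t = surrogate_t, truth = NULL
  ), class = "costnet_cohort")
  if (!is.null(meta$planted_effects)) {
    attr(out, "planted_effects") <- tibble::as_tibble(meta$planted_effects)
  }
  out
}

#' Write all tables of an analysis to a run directory
#'
#' Emits the group summary, every edge-statistics table, the pooled
#' efficiency curves, the group networks (edge-list TSV and GraphML) and
#' a JSON manifest of all parameters and seeds. Re-running the pipeline
#' from the same inputs and manifest reproduces the tables byte for
#' byte.
#'
#' @param analysis A `costnet_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(analysis$group_summary,
                   file.path(dir, "group_summary.tsv"), progress = FALSE)
  for (nm in names(analysis$stats)) {
    tb <- analysis$stats[[nm]]
    if (!is.null(tb)) {
      readr::write_tsv(tibble::as_tibble(tb),
                       file.path(dir, paste0(nm, ".tsv")),
                       progress = FALSE)
    }
  }
  if (!is.null(analysis$curves)) {
    curves <- purrr::imap_dfr(analysis$curves, function(cv, g) {
      dplyr::bind_cols(tibble::tibble(group = g), tibble::as_tibble(cv))
    })
    readr::write_tsv(curves, file.path(dir, "efficiency_curves.tsv"),
                     progress = FALSE)
    readr::write_tsv(analysis$small_world,
                     file.path(dir, "small_world_range.tsv"),
                     progress = FALSE)
    readr::write_tsv(analysis$ce_peak, file.path(dir, "ce_peak.tsv"),
                     progress = FALSE)
  }
  for (g in names(analysis$group_networks)) {
    write_edge_list(
      analysis$group_networks[[g]],
      file.path(dir, sprintf("group_network_%s.tsv", g)),
      graphml = file.path(dir, sprintf("group_network_%s.graphml", g))
    )
  }
  jsonlite::write_json(analysis$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Run the full pipeline from a configuration
#'
#' Reads a cohort from disk, runs [analyze_cohort()], and writes all
#' result tables and a manifest to the output directory. The
#' configuration is a list (or YAML file) with elements `cohort_dir`,
#' `out_dir`, and any of the [analyze_cohort()] parameters (`cost`,
#' `condition`, `trim_seconds`, `compute_curves`, `cost_grid_min/max/step`,
#' `n_null`, `alpha`, `dlpfc_nodes`, `rt_nodes`, `source_nodes`,
#' `var_equal`, `seed`). Outputs are deterministic given the inputs,
#' configuration and seed.
#'
#' @param config List or path to a YAML file.
#' @return The `costnet_analysis`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("Configuration file does not exist: ", config, call. = FALSE)
    }
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("Reading YAML configuration requires the yaml package.",
           call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$cohort_dir)) {
    stop("Configuration must name a cohort_dir.", call. = FALSE)
  }
  if (!dir.exists(config$cohort_dir)) {
    stop("Cohort directory does not exist: ", config$cohort_dir,
         call. = FALSE)
  }
  cohort <- run_stage("cohort input", read_cohort(config$cohort_dir))
  grid <- seq(config$cost_grid_min %||% 0.01,
              config$cost_grid_max %||% 0.5,
              by = config$cost_grid_step %||% 0.005)
  analysis <- analyze_cohort(
    cohort,
    cost = config$cost %||% 0.28,
    condition = config$condition %||% "SI",
    trim_seconds = config$trim_seconds %||% 10,
    compute_curves = config$compute_curves %||% TRUE,
    cost_grid = grid,
    n_null = config$n_null %||% 20,
    alpha = config$alpha %||% 0.05,
    dlpfc_nodes = config$dlpfc_nodes %||% c("DLPFC1", "DLPFC2", "DLPFC3"),
    rt_nodes = config$rt_nodes,
    source_nodes = config$source_nodes,
    var_equal = config$var_equal %||% TRUE,
    seed = config$seed %||% 1L
  )
  if (!is.null(config$out_dir)) {
    write_analysis(analysis, config$out_dir)
  }
  invisible(analysis)
}
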