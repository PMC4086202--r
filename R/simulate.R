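#' Configuration for a synthetic task-fMRI cohort
#'
#' Defines the geometry and planted statistical structure of a simulated
#' two-group finger-movement cohort. Each ROI time series is generated from
#' a unit-variance latent factor model
#' \deqn{x_i(t) = a\, f_{c(i)}(t) + \sum_{e \ni i} b_{e}\, g_e(t) +
#'   \sqrt{1 - a^2 - \sum_e b_e^2}\, \epsilon_i(t)}
#' where \eqn{f_c} is the latent signal of ROI \eqn{i}'s community,
#' \eqn{g_e} the shared signal of a planted edge, and \eqn{a =
#' \sqrt{\rho}} with \eqn{\rho} the within-community correlation. Under
#' this model the population correlation of a planted edge is
#' \eqn{a_i a_j [c(i) = c(j)] + b_e^2} in closed form, which the tests use
#' as an independent oracle.
#'
#' Per-subject coupling scalars multiply the planted loadings: a shared
#' scalar drives the attenuated cortico-cortical edges and the subcortical
#' activity offsets, while two independent scalars drive the
#' DLPFC-striatum and VLPFC-striatum edges and the subject's mean
#' response time. Group-2 subjects have the attenuated edges' loadings
#' multiplied by `attenuation`.
#'
#' @param roi ROI table ([roi_table()] by default).
#' @param n_per_group Named integer vector of group sizes; names are the
#'   group labels. Default `c(HV = 14, PD = 12)`.
#' @param n_runs Runs per subject (default 4).
#' @param frames_per_run Frames per run (default 146).
#' @param tr_seconds Repetition time in seconds (default 3.5).
#' @param base_coupling Within-community population correlation
#'   \eqn{\rho \in [0, 1]} (default 0.25).
#' @param planted_edges Tibble of planted edges with columns `node1`,
#'   `node2`, `coupling` (base loading \eqn{b_0}), `attenuated` (logical)
#'   and `driver` (`"shared"`, `"dlpfc"` or `"vlpfc"`). `NULL` uses the
#'   default six-edge set; a zero-row tibble plants nothing.
#' @param attenuation Multiplier in \eqn{[0, 1]} applied to attenuated
#'   edges' loadings in group 2 (default 0.5; 1 means no group effect).
#' @param coupling_sd Between-subject SD of the coupling scalars
#'   (default 0.2; scalars are truncated to `1 ± 2.5 * coupling_sd` and
#'   kept positive).
#' @param activity_gain Offset (latent-signal units) added to subcortical
#'   ROIs during SI frames, scaled by the subject's shared coupling
#'   scalar; positive for striatal ROIs, negative for thalamic ones
#'   (default 1).
#' @param t_surrogate List `(t0, gain, sd)` for the per-subject surrogate
#'   subcortical t-values, generated as `t0 + gain * (shared - 1) + noise`.
#' @param rt_model List `(intercept_ms, beta_dlpfc_ms, beta_vlpfc_ms,
#'   sd_ms)`: the subject's mean inter-press interval is
#'   `intercept + beta_dlpfc * (u_d - 1) + beta_vlpfc * (u_v - 1) + noise`
#'   with `u_d`, `u_v` the DLPFC/VLPFC coupling scalars. Defaults plant a
#'   negative DLPFC slope and a positive VLPFC slope.
#' @param press_interval_sd_ms Within-subject SD of simulated inter-press
#'   intervals (default 50 ms).
#' @param schedule Optional schedule tibble (`run`, `frame`, `condition`);
#'   `NULL` builds the default interleaved block design via
#'   [make_schedule()].
#' @param seed Master RNG seed (default 1); per-subject seeds are derived
#'   deterministically from it.
#' @return A list of class `costnet_sim_config`.
#' @seealso [simulate_cohort()], [planted_truth_report()]
#' @export
sim_config <- function(roi = roi_table(),
                       n_per_group = c(HV = 14L, PD = 12L),
                       n_runs = 4L,
                       frames_per_run = 146L,
                       tr_seconds = 3.5,
                       base_coupling = 0.25,
                       planted_edges = NULL,
                       attenuation = 0.5,
                       coupling_sd = 0.2,
                       activity_gain = 1,
                       t_surrogate = list(t0 = 3, gain = 2, sd = 0.8),
                       rt_model = list(intercept_ms = 900,
                                       beta_dlpfc_ms = -500,
                                       beta_vlpfc_ms = 500,
                                       sd_ms = 60),
                       press_interval_sd_ms = 50,
                       schedule = NULL,
                       seed = 1L) {
  validate_roi_table(roi)
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 1L),
            n_runs >= 1L, frames_per_run >= 1L, tr_seconds > 0)
  if (is.null(names(n_per_group)) || any(names(n_per_group) == "")) {
    names(n_per_group) <- c("group1", "group2")
  }
  if (base_coupling < 0 || base_coupling > 1) {
    stop("base_coupling must lie in [0, 1].", call. = FALSE)
  }
  if (attenuation < 0 || attenuation > 1) {
    stop("attenuation multiplier must lie in [0, 1].", call. = FALSE)
  }
  if (is.null(planted_edges)) planted_edges <- default_planted_edges()
  planted_edges <- tibble::as_tibble(planted_edges)
  if (nrow(planted_edges) > 0) {
    needed <- c("node1", "node2", "coupling", "attenuated", "driver")
    miss <- setdiff(needed, names(planted_edges))
    if (length(miss) > 0) {
      stop("planted_edges is missing columns: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    unknown <- setdiff(c(planted_edges$node1, planted_edges$node2), roi$name)
    if (length(unknown) > 0) {
      stop("planted_edges reference ROIs absent from the ROI table: ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    }
    ce <- canonical_edge(planted_edges$node1, planted_edges$node2)
    planted_edges$node1 <- ce$node1
    planted_edges$node2 <- ce$node2
    if (anyDuplicated(edge_key(planted_edges$node1, planted_edges$node2))) {
      stop("planted_edges contains duplicated node pairs.", call. = FALSE)
    }
  }
  if (is.null(schedule)) {
    schedule <- make_schedule(frames_per_run, n_runs)
  }
  cfg <- structure(list(
    roi = roi,
    community = roi_community(roi$name),
    n_per_group = n_per_group,
    n_runs = as.integer(n_runs),
    frames_per_run = as.integer(frames_per_run),
    tr_seconds = tr_seconds,
    base_coupling = base_coupling,
    planted_edges = planted_edges,
    attenuation = attenuation,
    coupling_sd = coupling_sd,
    activity_gain = activity_gain,
    t_surrogate = t_surrogate,
    rt_model = rt_model,
    press_interval_sd_ms = press_interval_sd_ms,
    schedule = schedule,
    seed = as.integer(seed)
  ), class = "costnet_sim_config")
  validate_variance_budget(cfg)
  cfg
}

# Default planted-edge set: five node-disjoint attenuated edges drawn from
# the dorsal-motor/prefrontal/visual blocks plus two response-time-driving
# cortico-striatal edges (the VLPFC-striatal edge is also attenuated).
default_planted_edges <- function() {
  tibble::tribble(
    ~node1,    ~node2,   ~coupling, ~attenuated, ~driver,
    "DLPFC1",  "PreSMA1", 0.55,      TRUE,        "shared",
    "M1-1",    "PreSMA2", 0.55,      TRUE,        "shared",
    "DLPFC3",  "SOG1",    0.55,      TRUE,        "shared",
    "IPL5",    "SMA1",    0.55,      TRUE,        "shared",
    "Put1",    "VLPFC3",  0.55,      TRUE,        "vlpfc",
    "DLPFC2",  "Put2",    0.55,      FALSE,       "dlpfc"
  )
}

# Upper truncation point of the coupling scalars.
coupling_upper <- function(cfg) 1 + 2.5 * cfg$coupling_sd

# Reject configurations whose implied latent covariance cannot be realized:
# in the unit-variance factor model a ROI's community loading plus planted
# loadings must leave non-negative residual variance at the maximal
# coupling scalar.
validate_variance_budget <- function(cfg) {
  a2 <- cfg$base_coupling
  smax <- coupling_upper(cfg)
  if (nrow(cfg$planted_edges) == 0) {
    if (a2 > 1) stop("base_coupling exceeds unit variance.", call. = FALSE)
    return(invisible(cfg))
  }
  nodes <- c(cfg$planted_edges$node1, cfg$planted_edges$node2)
  b2max <- tapply((rep(cfg$planted_edges$coupling, 2) * smax)^2, nodes, sum)
  total <- a2 + b2max
  bad <- names(total)[total > 1 + 1e-12]
  if (length(bad) > 0) {
    stop("Implied covariance is not positive semi-definite: variance ",
         "budget exceeded at ROI(s) ", paste(bad, collapse = ", "),
         " (community loading + planted couplings > unit variance).",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Build an interleaved block-design task schedule
#'
#' Each run opens with rest, then cycles task blocks (SI, ET, CTL by
#' default, each appearing `n_cycles` times) separated by rest; frames
#' left over after even division go to rest at the end of the run.
#'
#' @param frames_per_run Frames in each run.
#' @param n_runs Number of runs.
#' @param conditions Task condition labels cycled over blocks.
#' @param n_cycles Times each condition appears per run (default 2).
#' @param rest_frames Rest frames before each block (default 2).
#' @return Tibble with columns `run`, `frame`, `condition` (task labels or
#'   `"rest"`).
#' @export
make_schedule <- function(frames_per_run, n_runs = 1L,
                          conditions = c("SI", "ET", "CTL"),
                          n_cycles = 2L, rest_frames = 2L) {
  n_blocks <- length(conditions) * n_cycles
  task_total <- frames_per_run - rest_frames * (n_blocks + 1)
  if (task_total < n_blocks) {
    stop("frames_per_run too small for ", n_blocks, " task blocks with ",
         rest_frames, " rest frames each.", call. = FALSE)
  }
  block_len <- task_total %/% n_blocks
  labels <- rep(rep(conditions, n_cycles), each = 1L)
  per_run <- c(rep("rest", rest_frames),
               unlist(lapply(labels, function(cnd) {
                 c(rep(cnd, block_len), rep("rest", rest_frames))
               })))
  per_run <- c(per_run, rep("rest", frames_per_run - length(per_run)))
  tibble::tibble(
    run = rep(seq_len(n_runs), each = frames_per_run),
    frame = rep(seq_len(frames_per_run), times = n_runs),
    condition = rep(per_run, times = n_runs)
  )
}

#' Simulate a two-group cohort of ROI time series
#'
#' Generates per-subject, per-run ROI time-series matrices from the latent
#' factor model in [sim_config()], together with button-press event times,
#' surrogate subcortical t-values, and the ground truth of every planted
#' effect. Deterministic for a fixed config seed; each subject's draws use
#' a seed derived from the master seed, so cohorts are reproducible and
#' subjects independent.
#'
#' @param config A `costnet_sim_config`.
#' @return A list of class `costnet_cohort` with elements `roi`,
#'   `subjects` (tibble `subject`, `group`), `runs` (named list: subject ->
#'   list of frames-by-ROI matrices on a raw BOLD-like scale), `schedule`,
#'   `tr_seconds`, `events` (tibble `subject`, `run`, `block`,
#'   `condition`, `time_ms`), `surrogate_t` (tibble `subject`, `roi`,
#'   `t_value`) and `truth` (the `GroundTruth`, see
#'   [planted_truth_report()]).
#' @examples
#' cfg <- sim_config(n_per_group = c(A = 3, B = 3), n_runs = 1,
#'                   frames_per_run = 60, seed = 7)
#' coh <- simulate_cohort(cfg)
#' dim(coh$runs[[1]][[1]])
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "costnet_sim_config"))
  validate_variance_budget(config)
  cfg <- config
  roi_names <- cfg$roi$name
  n_roi <- length(roi_names)
  comm <- cfg$community
  comm_levels <- sort(unique(comm))
  comm_idx <- match(comm, comm_levels)
  a <- sqrt(cfg$base_coupling)
  pe <- cfg$planted_edges
  n_edge <- nrow(pe)

  groups <- rep(names(cfg$n_per_group), cfg$n_per_group)
  n_sub <- length(groups)
  subjects <- tibble::tibble(
    subject = sprintf("sub%02d", seq_len(n_sub)),
    group = groups
  )

  striatal <- subcortical_rois(cfg$roi, "striatal")
  thalamic <- subcortical_rois(cfg$roi, "thalamic")
  act_sign <- stats::setNames(rep(0, n_roi), roi_names)
  act_sign[striatal] <- 1
  act_sign[thalamic] <- -1

  lo <- max(0.05, 1 - 2.5 * cfg$coupling_sd)
  hi <- coupling_upper(cfg)
  draw_scalar <- function() {
    if (cfg$coupling_sd == 0) return(1)
    min(max(stats::rnorm(1, 1, cfg$coupling_sd), lo), hi)
  }

  runs <- vector("list", n_sub)
  events <- vector("list", n_sub)
  tvals <- vector("list", n_sub)
  couplings <- vector("list", n_sub)
  params <- vector("list", n_sub)

  for (k in seq_len(n_sub)) {
    sub_id <- subjects$subject[k]
    grp <- subjects$group[k]
    is_g2 <- grp == names(cfg$n_per_group)[2]
    runs_k <- events_k <- NULL
    with_local_seed(derive_seed(cfg$seed, k), {
      s_shared <- draw_scalar()
      u_dlpfc <- draw_scalar()
      u_vlpfc <- draw_scalar()
      driver_val <- c(shared = s_shared, dlpfc = u_dlpfc, vlpfc = u_vlpfc)

      if (n_edge > 0) {
        mult <- ifelse(is_g2 & pe$attenuated, cfg$attenuation, 1)
        b_k <- pe$coupling * driver_val[pe$driver] * mult
      } else {
        b_k <- numeric(0)
      }

      # Loading matrix: community factors then planted-edge factors.
      L <- matrix(0, n_roi, length(comm_levels) + n_edge,
                  dimnames = list(roi_names, NULL))
      L[cbind(seq_len(n_roi), comm_idx)] <- a
      if (n_edge > 0) {
        for (e in seq_len(n_edge)) {
          L[pe$node1[e], length(comm_levels) + e] <- b_k[e]
          L[pe$node2[e], length(comm_levels) + e] <- b_k[e]
        }
      }
      resid_var <- 1 - rowSums(L^2)
      if (any(resid_var < -1e-12)) {
        stop("Implied covariance is not positive semi-definite at ROI(s) ",
             paste(roi_names[resid_var < -1e-12], collapse = ", "),
             call. = FALSE)
      }
      resid_sd <- sqrt(pmax(resid_var, 0))

      runs_k <- lapply(seq_len(cfg$n_runs), function(r) {
        fr <- cfg$frames_per_run
        Z <- matrix(stats::rnorm(fr * ncol(L)), fr, ncol(L))
        X <- Z %*% t(L) +
          matrix(stats::rnorm(fr * n_roi), fr, n_roi) *
            rep(resid_sd, each = fr)
        sched_r <- cfg$schedule[cfg$schedule$run == r, ]
        si <- which(sched_r$condition == "SI")
        if (length(si) > 0 && cfg$activity_gain != 0) {
          X[si, ] <- X[si, ] +
            rep(act_sign * cfg$activity_gain * s_shared, each = length(si))
        }
        colnames(X) <- roi_names
        1000 + 20 * X  # raw BOLD-like intensity scale
      })

      rt_k <- cfg$rt_model$intercept_ms +
        cfg$rt_model$beta_dlpfc_ms * (u_dlpfc - 1) +
        cfg$rt_model$beta_vlpfc_ms * (u_vlpfc - 1) +
        stats::rnorm(1, 0, cfg$rt_model$sd_ms)
      rt_k <- max(rt_k, 300)

      events_k <- simulate_events(cfg, sub_id, rt_k)

      subcort <- cfg$roi$name[cfg$roi$subcortical]
      tv <- quick_tbl(
        subject = rep.int(sub_id, length(subcort)),
        roi = subcort,
        t_value = cfg$t_surrogate$t0 +
          cfg$t_surrogate$gain * (s_shared - 1) +
          stats::rnorm(length(subcort), 0, cfg$t_surrogate$sd)
      )

      cpl <- quick_tbl(
        subject = rep.int(sub_id, n_edge),
        group = rep.int(grp, n_edge),
        node1 = pe$node1, node2 = pe$node2,
        coupling = b_k,
        attenuated = pe$attenuated,
        driver = pe$driver,
        implied_r = b_k^2 +
          ifelse(comm[match(pe$node1, roi_names)] ==
                   comm[match(pe$node2, roi_names)],
                 cfg$base_coupling, 0)
      )

      runs[[k]] <- runs_k
      events[[k]] <- events_k
      tvals[[k]] <- tv
      couplings[[k]] <- cpl
      params[[k]] <- quick_tbl(
        subject = sub_id, group = grp,
        s_shared = s_shared, s_dlpfc = u_dlpfc, s_vlpfc = u_vlpfc,
        rt_true_ms = rt_k
      )
    })
  }

  names(runs) <- subjects$subject
  truth <- structure(list(
    edges = pe,
    subject_couplings = dplyr::bind_rows(couplings),
    subject_params = dplyr::bind_rows(params),
    rt_model = cfg$rt_model,
    activity = tibble::tibble(
      roi = roi_names[act_sign != 0],
      sign = unname(act_sign[act_sign != 0]),
      gain = unname(cfg$activity_gain * act_sign[act_sign != 0])
    ),
    attenuation = cfg$attenuation,
    base_coupling = cfg$base_coupling,
    seed = cfg$seed
  ), class = "costnet_ground_truth")

  structure(list(
    roi = cfg$roi,
    subjects = subjects,
    runs = runs,
    schedule = cfg$schedule,
    tr_seconds = cfg$tr_seconds,
    events = dplyr::bind_rows(events),
    surrogate_t = dplyr::bind_rows(tvals),
    truth = truth,
    config = cfg
  ), class = "costnet_cohort")
}

# Button-press events: within each SI/ET/CTL block, press times are a
# cumulative sum of i.i.d. truncated-normal inter-press intervals around
# the subject's model-implied mean RT.
simulate_events <- function(cfg, sub_id, rt_ms) {
  sched <- cfg$schedule
  run_v <- integer(0); block_v <- integer(0)
  cond_v <- character(0); time_v <- numeric(0)
  for (r in unique(sched$run)) {
    sr <- sched[sched$run == r, ]
    blk <- rle(sr$condition)
    ends <- cumsum(blk$lengths)
    starts <- ends - blk$lengths + 1
    bi <- 0L
    for (j in seq_along(blk$values)) {
      cnd <- blk$values[j]
      if (cnd == "rest") next
      bi <- bi + 1L
      block_start_ms <- (sr$frame[starts[j]] - 1) * cfg$tr_seconds * 1000
      block_len_ms <- blk$lengths[j] * cfg$tr_seconds * 1000
      n_press <- max(2L, min(10L, floor(block_len_ms / (rt_ms + 200))))
      iv <- pmax(stats::rnorm(n_press, rt_ms, cfg$press_interval_sd_ms), 150)
      times <- block_start_ms + 200 + cumsum(c(0, iv[-1]))
      run_v <- c(run_v, rep.int(r, n_press))
      block_v <- c(block_v, rep.int(bi, n_press))
      cond_v <- c(cond_v, rep.int(cnd, n_press))
      time_v <- c(time_v, times)
    }
  }
  quick_tbl(subject = rep.int(sub_id, length(time_v)), run = run_v,
            block = block_v, condition = cond_v, time_ms = time_v)
}

#' Summarize the planted effects of a simulated cohort
#'
#' Produces a machine-readable table of every effect the generator
#' planted: one row per planted edge (population correlation per group and
#' the implied Fisher-z group difference at the mean coupling scalar), one
#' row per subcortical ROI's activity-coupling gain, and one row per
#' response-time slope.
#'
#' @param truth A `costnet_ground_truth`, from `simulate_cohort()$truth`.
#' @return Tibble with columns `type` (`"edge"`, `"activity_gain"`,
#'   `"rt_slope"`), `name`, `node1`, `node2`, `attenuated`, `group1`,
#'   `group2` and `effect` (z difference for edges, signed gain for
#'   activity, slope in ms for RT).
#' @export
planted_truth_report <- function(truth) {
  stopifnot(inherits(truth, "costnet_ground_truth"))
  pe <- truth$edges
  rows <- list()
  if (nrow(pe) > 0) {
    same_comm <- vapply(seq_len(nrow(pe)), function(e) {
      roi_community(pe$node1[e]) == roi_community(pe$node2[e])
    }, logical(1))
    r1 <- pe$coupling^2 + ifelse(same_comm, truth$base_coupling, 0)
    mult <- ifelse(pe$attenuated, truth$attenuation, 1)
    r2 <- (pe$coupling * mult)^2 + ifelse(same_comm, truth$base_coupling, 0)
    rows$edges <- tibble::tibble(
      type = "edge",
      name = paste(pe$node1, pe$node2, sep = "--"),
      node1 = pe$node1, node2 = pe$node2,
      attenuated = pe$attenuated,
      group1 = unname(r1), group2 = unname(r2),
      effect = unname(atanh(r1) - atanh(r2))
    )
  }
  if (nrow(truth$activity) > 0) {
    rows$activity <- tibble::tibble(
      type = "activity_gain",
      name = truth$activity$roi,
      node1 = NA_character_, node2 = NA_character_,
      attenuated = NA,
      group1 = NA_real_, group2 = NA_real_,
      effect = truth$activity$gain
    )
  }
  rows$rt <- tibble::tibble(
    type = "rt_slope",
    name = c("dlpfc_striatum", "vlpfc_striatum"),
    node1 = NA_character_, node2 = NA_character_,
    attenuated = NA,
    group1 = NA_real_, group2 = NA_real_,
    effect = c(truth$rt_model$beta_dlpfc_ms, truth$rt_model$beta_vlpfc_ms)
  )
  dplyr::bind_rows(rows)
}

#' Simulate a small 4-D volume with known ROI signals
#'
#' Builds a 4-D array (x, y, z, frame) in which each ROI contributes a
#' known time series to the 27 voxels of a 3x3x3 cube centred on its peak,
#' on top of white background noise, together with the voxel-to-mm affine
#' and the peak table. Exercises the ROI-cube extraction path end to end:
#' with `noise_sd = 0`, [extract_roi_timeseries()] recovers `signals`
#' exactly.
#'
#' @param peaks ROI-table-like tibble (`name`, `x`, `y`, `z` in mm).
#' @param frames Number of frames.
#' @param seed RNG seed.
#' @param voxel_mm Isotropic voxel size in mm (default 3).
#' @param signals Optional frames-by-ROI matrix of planted cube signals;
#'   default draws a smooth random series per ROI offset by its index.
#' @param noise_sd Background white-noise SD (default 0.5).
#' @param margin_voxels Empty voxels padded around the bounding box of the
#'   peaks (default 3; must be >= 1 so cubes fit).
#' @return List with `volume` (4-D array), `affine` (4x4 matrix mapping
#'   1-based voxel indices to mm), `peaks` and `signals`.
#' @export
simulate_volume_fixture <- function(peaks, frames, seed = 1L,
                                    voxel_mm = 3, signals = NULL,
                                    noise_sd = 0.5, margin_voxels = 3L) {
  stopifnot(frames >= 1, voxel_mm > 0, margin_voxels >= 1)
  n_roi <- nrow(peaks)
  origin <- c(min(peaks$x), min(peaks$y), min(peaks$z)) -
    margin_voxels * voxel_mm
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- origin - voxel_mm  # voxel (1,1,1) centre sits at origin
  vox <- t(apply(cbind(peaks$x, peaks$y, peaks$z), 1, function(mm) {
    round(solve(affine, c(mm, 1))[1:3])
  }))
  dims <- apply(vox, 2, max) + margin_voxels
  # Cube collisions: two rounded peaks closer than 3 voxels on every axis.
  if (n_roi > 1) {
    pair <- utils::combn(n_roi, 2)
    clash <- apply(pair, 2, function(p) {
      all(abs(vox[p[1], ] - vox[p[2], ]) < 3)
    })
    if (any(clash)) {
      bad <- apply(pair[, clash, drop = FALSE], 2, function(p) {
        paste(peaks$name[p], collapse = "/")
      })
      stop("ROI cubes overlap in the fixture grid: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (any(vox < 2) || any(t(vox) > dims - 1)) {
    bad <- peaks$name[apply(vox, 1, function(v) any(v < 2) ||
                              any(v > dims - 1))]
    stop("ROI cube(s) would leave the volume: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  with_local_seed(seed, {
    if (is.null(signals)) {
      signals <- vapply(seq_len(n_roi), function(k) {
        stats::filter(stats::rnorm(frames), rep(1 / 3, 3),
                      circular = TRUE) + k
      }, numeric(frames))
      signals <- matrix(signals, nrow = frames)
    }
    stopifnot(nrow(signals) == frames, ncol(signals) == n_roi)
    colnames(signals) <- peaks$name
    vol <- array(stats::rnorm(prod(dims) * frames, 0, noise_sd),
                 dim = c(dims, frames))
    for (k in seq_len(n_roi)) {
      xs <- vox[k, 1] + (-1:1); ys <- vox[k, 2] + (-1:1)
      zs <- vox[k, 3] + (-1:1)
      for (t in seq_len(frames)) {
        vol[xs, ys, zs, t] <- vol[xs, ys, zs, t] + signals[t, k]
      }
    }
    list(volume = vol, affine = affine, peaks = tibble::as_tibble(peaks),
         signals = signals)
  })
}
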