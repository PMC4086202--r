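#' Extract ROI cube time series from a 4-D volume
#'
#' For each ROI peak, maps its mm coordinate to the nearest voxel through
#' the inverse affine and averages the 27 voxels of the 3x3x3 cube centred
#' there, at every frame. The cube is 3x3x3 voxels regardless of voxel
#' anisotropy.
#'
#' @param volume 4-D numeric array (x, y, z, frame).
#' @param affine 4x4 matrix mapping 1-based voxel indices `(i, j, k, 1)`
#'   to mm coordinates.
#' @param roi ROI table with columns `name`, `x`, `y`, `z` (mm).
#' @return Frames-by-ROI numeric matrix with ROI names as column names.
#' @seealso [simulate_volume_fixture()] for a self-validating fixture.
#' @export
extract_roi_timeseries <- function(volume, affine, roi) {
  stopifnot(length(dim(volume)) == 4, all(dim(affine) == c(4, 4)))
  inv <- tryCatch(solve(affine), error = function(e) {
    stop("Affine matrix is not invertible.", call. = FALSE)
  })
  dims <- dim(volume)[1:3]
  frames <- dim(volume)[4]
  out <- matrix(NA_real_, frames, nrow(roi),
                dimnames = list(NULL, roi$name))
  for (k in seq_len(nrow(roi))) {
    v <- round(inv %*% c(roi$x[k], roi$y[k], roi$z[k], 1))[1:3]
    if (any(v < 2) || any(v > dims - 1)) {
      stop("ROI cube lies (partly) outside the volume: ", roi$name[k],
           call. = FALSE)
    }
    cube <- volume[v[1] + (-1:1), v[2] + (-1:1), v[3] + (-1:1), ,
                   drop = FALSE]
    out[, k] <- apply(cube, 4, mean)
  }
  out
}

#' Globally normalize one run of ROI time series
#'
#' Z-scores a frames-by-ROI matrix against the pooled mean and pooled
#' sample standard deviation of all its entries (every frame of every
#' ROI), so relative amplitude differences between ROIs within the run
#' are preserved.
#'
#' @param run Frames-by-ROI numeric matrix.
#' @return Matrix of the same shape with pooled mean 0 and pooled sample
#'   SD 1.
#' @export
normalize_run <- function(run) {
  run <- as.matrix(run)
  mu <- mean(run)
  sd_ <- stats::sd(as.vector(run))
  if (!is.finite(sd_) || sd_ == 0) {
    stop("Cannot normalize a constant run (pooled SD is zero).",
         call. = FALSE)
  }
  (run - mu) / sd_
}

#' Concatenate one condition's frames across blocks and runs
#'
#' Restricts normalized runs to a single task condition, dropping the
#' first `ceil(trim_seconds / tr_seconds)` frames of every contiguous
#' same-condition block to discount the hemodynamic delay, then
#' concatenates surviving frames in temporal order across blocks and
#' runs. A block shorter than the trim contributes zero frames (with a
#' warning), it is not an error.
#'
#' @param runs List of frames-by-ROI matrices, one per run, already
#'   normalized.
#' @param schedule Tibble (`run`, `frame`, `condition`) covering every
#'   frame of every run.
#' @param condition Condition label to keep (e.g. `"SI"`).
#' @param tr_seconds Repetition time in seconds.
#' @param trim_seconds Seconds discarded at each block onset (default 10).
#' @return A frames-by-ROI matrix (class `costnet_condition_matrix`) with
#'   attributes `condition` and `frames_dropped_per_block`.
#' @examples
#' sched <- make_schedule(30, 1)
#' runs <- list(matrix(rnorm(30 * 4), 30, 4,
#'                     dimnames = list(NULL, paste0("r", 1:4))))
#' si <- segment_and_concatenate(runs, sched, "SI", tr_seconds = 3.5)
#' @export
segment_and_concatenate <- function(runs, schedule, condition,
                                    tr_seconds, trim_seconds = 10) {
  stopifnot(is.list(runs), tr_seconds > 0, trim_seconds >= 0)
  if (!condition %in% schedule$condition) {
    stop("Condition '", condition, "' does not occur in the schedule.",
         call. = FALSE)
  }
  n_drop <- as.integer(ceiling(trim_seconds / tr_seconds))
  run_ids <- sort(unique(schedule$run))
  if (length(runs) != length(run_ids)) {
    stop("Schedule describes ", length(run_ids), " run(s) but ",
         length(runs), " matrices were supplied.", call. = FALSE)
  }
  pieces <- list()
  n_short <- 0L
  for (ri in seq_along(run_ids)) {
    sched_r <- schedule[schedule$run == run_ids[ri], ]
    sched_r <- sched_r[order(sched_r$frame), ]
    mat <- as.matrix(runs[[ri]])
    if (nrow(mat) != nrow(sched_r)) {
      stop("Run ", run_ids[ri], " has ", nrow(mat), " frames but the ",
           "schedule covers ", nrow(sched_r), ".", call. = FALSE)
    }
    blk <- rle(sched_r$condition)
    ends <- cumsum(blk$lengths)
    starts <- ends - blk$lengths + 1
    for (j in which(blk$values == condition)) {
      keep <- (starts[j] + n_drop):ends[j]
      if (starts[j] + n_drop > ends[j]) {
        n_short <- n_short + 1L
        next
      }
      pieces[[length(pieces) + 1L]] <- mat[keep, , drop = FALSE]
    }
  }
  if (n_short > 0) {
    warning(n_short, " block(s) of condition '", condition,
            "' shorter than the trim contributed zero frames.",
            call. = FALSE)
  }
  out <- if (length(pieces) > 0) {
    do.call(rbind, pieces)
  } else {
    mat0 <- as.matrix(runs[[1]])
    mat0[0, , drop = FALSE]
  }
  structure(out, condition = condition,
            frames_dropped_per_block = n_drop,
            class = c("costnet_condition_matrix", class(out)))
}

#' Mean normalized signal of the subcortical ROIs
#'
#' Averages each subcortical ROI's normalized time series over all
#' retained frames of a condition matrix; used as a per-subject index of
#' regional activity during the task.
#'
#' @param cond Condition matrix from [segment_and_concatenate()].
#' @param roi ROI table with a `subcortical` flag.
#' @return Tibble with columns `roi` and `activity`, one row per
#'   subcortical ROI.
#' @export
subcortical_activity_index <- function(cond, roi) {
  if (nrow(cond) == 0) {
    stop("Condition matrix has zero frames; cannot compute an activity ",
         "index.", call. = FALSE)
  }
  sc <- roi$name[roi$subcortical]
  missing <- setdiff(sc, colnames(cond))
  if (length(missing) > 0) {
    stop("Subcortical ROI(s) absent from the condition matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(roi = sc,
                 activity = unname(colMeans(cond[, sc, drop = FALSE])))
}

#' Mean inter-press response time per subject
#'
#' The response time is the interval between the onsets of successive
#' button presses. Intervals are computed within each run (and block, if
#' an events table carries a `block` column), never across block
#' boundaries, pooled over hands and runs, and averaged per subject.
#'
#' @param events Tibble with columns `subject`, `run`, `condition`,
#'   `time_ms` and optionally `block`.
#' @param condition Condition whose presses to use (default `"SI"`).
#' @return Tibble with columns `subject`, `rt_ms` (mean interval) and
#'   `n_intervals`.
#' @examples
#' ev <- tibble::tibble(subject = "s1", run = 1, condition = "SI",
#'                      time_ms = c(0, 500, 1200))
#' mean_rt(ev)  # mean of 500 and 700 = 600 ms
#' @export
mean_rt <- function(events, condition = "SI") {
  ev <- events[events$condition == condition, , drop = FALSE]
  if (nrow(ev) == 0) {
    stop("No presses for condition '", condition, "'.", call. = FALSE)
  }
  key <- if ("block" %in% names(ev)) {
    paste(ev$subject, ev$run, ev$block, sep = "\r")
  } else {
    paste(ev$subject, ev$run, sep = "\r")
  }
  o <- order(key, ev$time_ms)
  key <- key[o]
  tm <- ev$time_ms[o]
  subj <- ev$subject[o]
  n <- length(tm)
  same <- key[-1] == key[-n]
  iv <- diff(tm)[same]
  iv_subj <- subj[-1][same]
  rt <- tapply(iv, iv_subj, mean)
  bad <- setdiff(unique(ev$subject), names(rt))
  if (length(bad) > 0) {
    stop("Fewer than 2 presses for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  quick_tbl(subject = names(rt), rt_ms = as.numeric(rt),
            n_intervals = as.integer(table(iv_subj)[names(rt)]))
}

#' Per-subject SI condition matrices for a whole cohort
#'
#' Convenience wrapper running [normalize_run()] and
#' [segment_and_concatenate()] for every subject of a simulated or
#' assembled cohort.
#'
#' @param cohort A `costnet_cohort`.
#' @param condition Condition label (default `"SI"`).
#' @param trim_seconds Block-onset trim in seconds (default 10).
#' @return Named list of condition matrices, one per subject.
#' @export
cohort_condition_matrices <- function(cohort, condition = "SI",
                                      trim_seconds = 10) {
  stopifnot(inherits(cohort, "costnet_cohort"))
  lapply(cohort$runs, function(runs_k) {
    segment_and_concatenate(lapply(runs_k, normalize_run),
                            cohort$schedule, condition,
                            cohort$tr_seconds, trim_seconds)
  })
}
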