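#' Region-of-interest table for the finger-movement network
#'
#' The 62-node registry used throughout the package: ROI name, peak
#' coordinate in ICBM 152 mm space, the activation contrast the peak came
#' from, and a flag marking the 10 subcortical nodes (caudate, putamen,
#' ventral striatum and thalamus). Each ROI acts as one network node; its
#' time series is the mean over a 27-voxel cube centred on the peak.
#'
#' @param path Optional path to a tab-separated ROI table with columns
#'   `name`, `x`, `y`, `z`, `category`, `subcortical`. Defaults to the
#'   packaged 62-region table.
#' @return A tibble with one row per node and columns `name` (unique
#'   label), `x`, `y`, `z` (mm), `category` (contrast of origin) and
#'   `subcortical` (logical).
#' @examples
#' roi <- roi_table()
#' sum(roi$subcortical)  # 10 subcortical nodes
#' @export
roi_table <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "roi_table.tsv", package = "costnet", mustWork = TRUE)
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      name = readr::col_character(),
      x = readr::col_double(),
      y = readr::col_double(),
      z = readr::col_double(),
      category = readr::col_character(),
      subcortical = readr::col_logical()
    ),
    progress = FALSE
  )
  validate_roi_table(tbl)
  tbl
}

validate_roi_table <- function(tbl) {
  required <- c("name", "x", "y", "z", "category", "subcortical")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("ROI table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tbl$name)) {
    stop("ROI names must be unique; duplicated: ",
         paste(unique(tbl$name[duplicated(tbl$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(tbl$x) & is.finite(tbl$y) & is.finite(tbl$z))) {
    stop("ROI coordinates must be finite.", call. = FALSE)
  }
  invisible(tbl)
}

#' Assign ROIs to functional communities by name
#'
#' Maps each ROI label onto one of four broad functional communities used
#' as the modular blocks of the synthetic covariance: `dorsal_motor`
#' (SMA, pre-SMA, dorsal premotor, M1, parietal, posterior insula),
#' `ventral_visual` (occipital, lingual, fusiform, lateral occipital,
#' cerebellum), `prefrontal` (DLPFC, VLPFC, anterior PFC, anterior
#' insula) and `subcortical` (striatum and thalamus).
#'
#' @param names Character vector of ROI labels.
#' @return Character vector of community labels, same length as `names`.
#' @export
roi_community <- function(names) {
  out <- rep(NA_character_, length(names))
  out[grepl("^(SMA|PreSMA|PMd|M1|IPL|InsPost)", names)] <- "dorsal_motor"
  out[grepl("^(SOG|MOG|LG|FG|LOA|Cereb)", names)] <- "ventral_visual"
  out[grepl("^(DLPFC|VLPFC|APFC|INS[0-9])", names)] <- "prefrontal"
  out[grepl("^(Put|Thal|Caudate|VS)", names)] <- "subcortical"
  if (anyNA(out)) {
    stop("No community mapping for ROI(s): ",
         paste(names[is.na(out)], collapse = ", "), call. = FALSE)
  }
  out
}

#' Names of the subcortical ROIs
#'
#' @param roi ROI table as returned by [roi_table()].
#' @param which `"all"` (default), `"striatal"` (caudate, putamen, ventral
#'   striatum) or `"thalamic"`.
#' @return Character vector of ROI names.
#' @export
subcortical_rois <- function(roi, which = c("all", "striatal", "thalamic")) {
  which <- match.arg(which)
  nm <- roi$name[roi$subcortical]
  switch(which,
    all = nm,
    striatal = nm[grepl("^(Put|Caudate|VS)", nm)],
    thalamic = nm[grepl("^Thal", nm)]
  )
}
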