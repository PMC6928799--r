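#' Pipeline configuration
#'
#' Collects every tunable threshold of the detection pipeline with its
#' default. `read_traysow_config()` loads overrides from a YAML file whose
#' keys match the argument names.
#'
#' @param min_vproj Frame-gate vertical-projection threshold (px).
#' @param min_hproj Tilt-estimation horizontal-projection threshold (px).
#' @param tilt_roi Tilt ROI `c(x, y, w, h)`.
#' @param angle_formula `"arctan"` or `"legacy"`, see [slope_to_angle()].
#' @param hsl_thresholds Class hue thresholds, see [hsl_thresholds()].
#' @param n_row_groups,n_col_groups Gridline counts expected along rows
#'   and columns (cells + 1).
#' @param roi_rows,roi_cols Cell rows/columns of the detection region.
#' @param min_contour_area Impurity filter threshold (px).
#' @param gate_grad_threshold,tilt_grad_threshold Segment-detector
#'   sensitivities for the gate and the tilt estimator.
#' @return A named list of class `traysow_config`.
#' @export
traysow_config <- function(min_vproj = 100, min_hproj = 45,
                           tilt_roi = c(70, 70, 800, 500),
                           angle_formula = "arctan",
                           hsl_thresholds = traysow::hsl_thresholds(),
                           n_row_groups = 11L, n_col_groups = 14L,
                           roi_rows = 10L, roi_cols = 13L,
                           min_contour_area = 30,
                           gate_grad_threshold = 0.10,
                           tilt_grad_threshold = 0.04) {
  structure(list(min_vproj = min_vproj, min_hproj = min_hproj,
                 tilt_roi = tilt_roi, angle_formula = angle_formula,
                 hsl_thresholds = hsl_thresholds,
                 n_row_groups = as.integer(n_row_groups),
                 n_col_groups = as.integer(n_col_groups),
                 roi_rows = as.integer(roi_rows),
                 roi_cols = as.integer(roi_cols),
                 min_contour_area = min_contour_area,
                 gate_grad_threshold = gate_grad_threshold,
                 tilt_grad_threshold = tilt_grad_threshold),
            class = "traysow_config")
}

#' @rdname traysow_config
#' @param path YAML file with a subset of the configuration keys.
#' @export
read_traysow_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(traysow_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(vals$hsl_thresholds)) {
    vals$hsl_thresholds <- hsl_thresholds(
      grid = unlist(vals$hsl_thresholds$grid),
      seed = unlist(vals$hsl_thresholds$seed))
  }
  do.call(traysow_config, vals)
}

#' Process one frame through the full detection pipeline
#'
#' Gate -> tilt correction -> HSL segmentation -> gridline localisation ->
#' ROI split -> contour filtering -> missing rate (and seed count when a
#' trained counter is supplied). Only the first valid frame of a tray
#' transit produces a report; edge frames and repeats are skipped with
#' their verdict, and frames whose grid cannot be located are skipped as
#' `unreadable`.
#'
#' @param frame RGB array `[y, x, 3]`.
#' @param config A [traysow_config()].
#' @param state Gate state carried across consecutive frames.
#' @param counter Optional trained [seed_counter] for seed counting.
#' @param frame_index Index recorded in the report.
#' @return List with `state` and either `report` (a `tray_report`) or
#'   `skipped` (the verdict string).
#' @export
process_frame <- function(frame, config = traysow_config(),
                          state = gate_state(), counter = NULL,
                          frame_index = NA_integer_) {
  cls <- classify_frame(frame, state, min_vproj = config$min_vproj,
                        grad_threshold = config$gate_grad_threshold)
  state <- cls$state
  if (cls$verdict != "valid_first") {
    return(list(state = state, skipped = cls$verdict))
  }
  corrected <- correct_tilt(frame, roi = config$tilt_roi,
                            min_hproj = config$min_hproj,
                            grad_threshold = config$tilt_grad_threshold,
                            formula = config$angle_formula)
  seg <- segment_classes(corrected$frame, config$hsl_thresholds)
  grid_bin <- preprocess_grid(seg$grid)
  roi <- tryCatch({
    rows_prof <- projection_profile(grid_bin, "rows")
    cols_prof <- projection_profile(grid_bin, "columns")
    coords <- grid_coordinates(
      locate_gridlines(rows_prof, config$n_row_groups),
      locate_gridlines(cols_prof, config$n_col_groups))
    select_roi(coords, config$roi_rows, config$roi_cols)
  }, traysow_unreadable = function(e) e, error = function(e) {
    unreadable_frame(conditionMessage(e))
  })
  if (inherits(roi, "condition")) {
    return(list(state = state, skipped = "unreadable"))
  }
  seed_bin <- preprocess_grid(seg$seed)
  pieces <- split_into_pieces(seed_bin, roi)
  contours <- lapply(pieces, find_and_filter_contours,
                     min_area = config$min_contour_area)
  m <- count_empty_cells(contours)
  N <- length(pieces)
  report <- structure(list(
    frame_index = frame_index,
    N = N, m = m,
    missing_rate = missing_rate(m, N),
    seed_count = if (is.null(counter)) NA_integer_ else count_seeds(contours, counter),
    tilt_deg = corrected$estimate$theta_deg
  ), class = "tray_report")
  list(state = state, report = report)
}

#' Process a frame sequence
#'
#' Runs [process_frame()] over a list of in-memory frames or a vector of
#' image paths, carrying the gate state across frames.
#'
#' @param frames List of RGB arrays, or character vector of PNG/JPEG
#'   paths.
#' @inheritParams process_frame
#' @return List with `reports` (one per valid first frame) and `verdicts`
#'   (one per input frame).
#' @export
process_frames <- function(frames, config = traysow_config(), counter = NULL) {
  state <- gate_state()
  reports <- list()
  verdicts <- character(length(frames))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (is.character(fr)) {
      if (!file.exists(fr)) stop("cannot read frame: ", fr)
      fr <- read_frame(fr)
    }
    res <- process_frame(fr, config, state, counter, frame_index = i)
    state <- res$state
    if (!is.null(res$report)) {
      reports[[length(reports) + 1]] <- res$report
      verdicts[i] <- "valid_first"
    } else {
      verdicts[i] <- res$skipped
    }
  }
  list(reports = reports, verdicts = verdicts)
}

#' Pool consecutive detections
#'
#' Groups consecutive tray reports (three by default, pooling 390 cells,
#' close to the 406 cells of a whole tray) and pools their empty-cell
#' counts, missing rate and seed counts. A trailing incomplete group is
#' kept and flagged `partial`.
#'
#' @param reports List of `tray_report`s.
#' @param group_size Reports per group.
#' @return Data frame with one row per group: `group`, `n_reports`, `N`,
#'   `m`, `missing_rate`, `seed_count`, `partial`.
#' @export
aggregate_detections <- function(reports, group_size = 3L) {
  stopifnot(group_size >= 1)
  if (!length(reports)) {
    return(data.frame(group = integer(0), n_reports = integer(0),
                      N = integer(0), m = integer(0),
                      missing_rate = numeric(0), seed_count = integer(0),
                      partial = logical(0)))
  }
  g <- (seq_along(reports) - 1L) %/% group_size + 1L
  out <- lapply(split(reports, g), function(grp) {
    N <- sum(vapply(grp, `[[`, numeric(1), "N"))
    m <- sum(vapply(grp, `[[`, numeric(1), "m"))
    sc <- vapply(grp, `[[`, numeric(1), "seed_count")
    data.frame(n_reports = length(grp), N = N, m = m,
               missing_rate = missing_rate(m, N),
               seed_count = if (anyNA(sc)) NA_real_ else sum(sc),
               partial = length(grp) < group_size)
  })
  res <- do.call(rbind, out)
  res <- cbind(group = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Relative detection error
#'
#' `delta = |v_sys - v| / v * 100`, the magnitude of the system-vs-manual
#' relative error, computed on unrounded values.
#'
#' @param v_sys System-measured value.
#' @param v Manual reference value.
#' @return Relative error in percent.
#' @export
#' @examples
#' relative_error(11, 10)  # 10
relative_error <- function(v_sys, v) {
  if (v == 0) {
    if (v_sys == 0) return(0)
    stop("reference value is 0 while the system value is not")
  }
  abs(v_sys - v) / v * 100
}

#' Average detection accuracy from relative errors
#'
#' @param deltas Non-empty numeric vector of relative errors in percent.
#' @return List with `mean_error` and `accuracy = 100 - mean_error`.
#' @export
accuracy_from_errors <- function(deltas) {
  if (!length(deltas)) stop("no relative errors supplied")
  me <- mean(deltas)
  list(mean_error = me, accuracy = 100 - me)
}

#' Write a detection report as deterministic JSON
#'
#' Per-frame verdicts, per-tray results (rates rounded to two decimals at
#' this presentation layer only) and per-group aggregates. Identical
#' inputs produce byte-identical files.
#'
#' @param result A [process_frames()] result.
#' @param path Output JSON path.
#' @param group_size Reports per aggregate group.
#' @return `path`, invisibly.
#' @export
write_tray_report <- function(result, path, group_size = 3L) {
  trays <- lapply(result$reports, function(r) {
    list(frame_index = r$frame_index, N = r$N, m = r$m,
         missing_rate = round2(r$missing_rate),
         seed_count = r$seed_count,
         tilt_deg = round(r$tilt_deg, 3))
  })
  agg <- aggregate_detections(result$reports, group_size)
  agg$missing_rate <- round2(agg$missing_rate)
  jsonlite::write_json(
    list(verdicts = result$verdicts, trays = trays, groups = agg),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
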