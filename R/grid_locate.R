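#' Preprocess a segmented class image into a clean binary image
#'
#' Grayscale conversion, Otsu binarisation and one 3 x 3 morphological
#' opening, removing isolated speckle while preserving gridlines and seed
#' blobs. An all-black input has no threshold and stays all black.
#'
#' @param grid_image Masked RGB array or grayscale matrix (a
#'   [segment_classes()] output).
#' @return Binary matrix (0/1).
#' @export
preprocess_grid <- function(grid_image) {
  g <- to_gray(grid_image)
  if (max(g) <= 0 || max(g) == min(g)) return(matrix(0, nrow(g), ncol(g)))
  thr <- EBImage::otsu(EBImage::Image(t(g)), range = c(0, max(g)))
  bin <- (g > thr) * 1
  EBImage::opening(bin, EBImage::makeBrush(3, "box"))
}

#' Projection profile of a binary image
#'
#' Sums binary pixel values along each row (`axis = "rows"`) or column
#' (`axis = "columns"`). Gridlines appear as sharp local maxima of the
#' profile.
#'
#' @param binary_image Binary matrix (0/1).
#' @param axis `"rows"` or `"columns"`.
#' @return Data frame with `index` (0-based row/column coordinate) and
#'   `pixel_sum`.
#' @export
projection_profile <- function(binary_image, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(binary_image))
  s <- if (axis == "rows") rowSums(binary_image != 0) else colSums(binary_image != 0)
  data.frame(index = seq_along(s) - 1L, pixel_sum = as.numeric(s))
}

#' Locate gridlines from a projection profile
#'
#' Splits the profile into `n_groups` contiguous equal-length blocks (the
#' last block absorbs the remainder) and returns, per block, the
#' coordinate of the maximum pixel sum. Ties are broken toward the block's
#' central index (then toward the smaller index), deterministically.
#'
#' @param profile Data frame from [projection_profile()].
#' @param n_groups Number of gridlines expected (blocks to split into).
#' @return Integer vector of 0-based gridline coordinates, one per block.
#' @export
locate_gridlines <- function(profile, n_groups) {
  n <- nrow(profile)
  if (is.null(n) || n == 0) stop("empty projection profile")
  if (n_groups < 1) stop("n_groups must be >= 1")
  if (n < n_groups) stop("profile shorter than the number of groups")
  base <- n %/% n_groups
  out <- integer(n_groups)
  for (i in seq_len(n_groups)) {
    from <- (i - 1L) * base + 1L
    to <- if (i == n_groups) n else i * base
    s <- profile$pixel_sum[from:to]
    cand <- which(s == max(s))
    centre <- (1 + length(s)) / 2
    pick <- cand[order(abs(cand - centre), cand)][1]
    out[i] <- profile$index[from + pick - 1L]
  }
  out
}

#' Gridline coordinate pair
#'
#' Bundles the sorted y-coordinates of horizontal gridlines and
#' x-coordinates of vertical gridlines. Coordinates must be strictly
#' increasing; on a well-formed tray consecutive gaps stay within 25% of
#' the median gap, and a violation marks the frame unreadable.
#'
#' @param row_lines,col_lines Integer vectors of 0-based coordinates.
#' @param check_gaps If `TRUE`, enforce the gap-regularity sanity check.
#' @return An object of class `grid_coordinates`.
#' @export
grid_coordinates <- function(row_lines, col_lines, check_gaps = TRUE) {
  for (v in list(row_lines, col_lines)) {
    if (length(v) < 2 || any(diff(v) <= 0)) {
      stop("gridline coordinates must be strictly increasing")
    }
  }
  if (check_gaps) {
    for (v in list(row_lines, col_lines)) {
      gaps <- diff(v)
      med <- stats::median(gaps)
      if (any(abs(gaps - med) > 0.25 * med)) {
        stop(unreadable_frame("irregular gridline spacing"))
      }
    }
  }
  structure(list(row_lines = as.numeric(row_lines),
                 col_lines = as.numeric(col_lines)),
            class = "grid_coordinates")
}

unreadable_frame <- function(msg) {
  structure(class = c("traysow_unreadable", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Select the 10 x 13-cell region of interest
#'
#' The detection region spans the first `rows + 1` horizontal and
#' `cols + 1` vertical gridlines. A frame without enough located gridlines
#' is flagged unreadable (condition class `traysow_unreadable`) so the
#' pipeline can skip it.
#'
#' @param coords A [grid_coordinates()] object.
#' @param rows,cols Cell rows and columns of the detection region.
#' @return List with the retained `row_lines`, `col_lines` and the ROI
#'   rectangle `rect = c(x0, y0, x1, y1)`.
#' @export
select_roi <- function(coords, rows = 10, cols = 13) {
  stopifnot(inherits(coords, "grid_coordinates"))
  if (length(coords$row_lines) < rows + 1 || length(coords$col_lines) < cols + 1) {
    stop(unreadable_frame(sprintf(
      "need %d row and %d column gridlines, found %d and %d",
      rows + 1, cols + 1, length(coords$row_lines), length(coords$col_lines))))
  }
  rl <- coords$row_lines[seq_len(rows + 1)]
  cl <- coords$col_lines[seq_len(cols + 1)]
  list(row_lines = rl, col_lines = cl,
       rect = c(x0 = cl[1], y0 = rl[1], x1 = cl[cols + 1], y1 = rl[rows + 1]))
}
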