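#' Split the seed binary image into per-cell pieces
#'
#' Cuts the preprocessed seed binary image along the located gridline
#' coordinates into one piece per cell. Piece `(r, c)` spans the half-open
#' pixel ranges `[row_lines[r], row_lines[r+1])` x
#' `[col_lines[c], col_lines[c+1])`, so the pieces tile the ROI without
#' overlap.
#'
#' @param seed_binary Binary matrix (0/1), full-frame.
#' @param roi ROI from [select_roi()] (retained gridline coordinates).
#' @return List of pieces, each a list with 0-based `row`, `col` and the
#'   binary `mask`.
#' @export
split_into_pieces <- function(seed_binary, roi) {
  stopifnot(is.matrix(seed_binary), !is.null(roi$row_lines), !is.null(roi$col_lines))
  rl <- as.integer(round(roi$row_lines)); cl <- as.integer(round(roi$col_lines))
  if (max(rl) > nrow(seed_binary) || max(cl) > ncol(seed_binary)) {
    stop("gridline coordinates exceed the seed image")
  }
  pieces <- vector("list", (length(rl) - 1) * (length(cl) - 1))
  i <- 0L
  for (r in seq_len(length(rl) - 1)) {
    for (c in seq_len(length(cl) - 1)) {
      i <- i + 1L
      pieces[[i]] <- list(
        row = r - 1L, col = c - 1L,
        mask = seed_binary[(rl[r] + 1):rl[r + 1], (cl[c] + 1):cl[c + 1],
                           drop = FALSE])
    }
  }
  pieces
}

# (area, perimeter, shape factor) per labelled component. Area is the
# pixel count; perimeter is the chain length of the traced outer boundary
# (unit steps 1, diagonal steps sqrt(2)), the arc-length convention of
# polygonal contour tracing.
contour_features <- function(labels) {
  n <- max(labels)
  if (n == 0) {
    return(data.frame(area = numeric(0), perimeter = numeric(0),
                      shape_factor = numeric(0)))
  }
  areas <- tabulate(labels[labels > 0], n)
  # ocontour needs EBImage's [x, y] layout; labels are [y, x]
  oc <- EBImage::ocontour(EBImage::Image(t(labels)))
  per <- vapply(seq_len(n), function(i) {
    p <- oc[[i]]
    if (is.null(p) || nrow(p) < 2) return(4)   # single pixel: unit square
    d <- rbind(diff(p), p[1, ] - p[nrow(p), ])
    sum(sqrt(rowSums(d^2)))
  }, numeric(1))
  data.frame(area = areas, perimeter = per,
             shape_factor = shape_factor(per, areas))
}

#' Find contours in a piece and filter out impurities
#'
#' Labels 8-connected components of the binary piece, removes contours
#' whose area is below `min_area` pixels (impurity blobs; a contour of
#' exactly `min_area` is kept) and measures (area, perimeter, shape
#' factor) for the survivors.
#'
#' @param piece A piece from [split_into_pieces()] or a binary matrix.
#' @param min_area Minimum contour area in pixels.
#' @return Data frame with `area`, `perimeter` and `shape_factor`, one row
#'   per surviving contour.
#' @export
find_and_filter_contours <- function(piece, min_area = 30) {
  mask <- if (is.list(piece)) piece$mask else piece
  stopifnot(is.matrix(mask))
  if (!any(mask != 0)) {
    return(data.frame(area = numeric(0), perimeter = numeric(0),
                      shape_factor = numeric(0)))
  }
  feats <- contour_features(label8((mask != 0) * 1))
  feats[feats$area >= min_area, , drop = FALSE]
}

#' Count empty cells
#'
#' A cell is empty when its piece contains no contour after impurity
#' filtering.
#'
#' @param piece_contours List of contour data frames, one per piece (the
#'   result of [find_and_filter_contours()] over all pieces).
#' @return Integer count of empty cells.
#' @export
count_empty_cells <- function(piece_contours) {
  sum(vapply(piece_contours, nrow, integer(1)) == 0L)
}

#' Missing rate of a tray
#'
#' The headline seeding-quality statistic: the percentage of cells that
#' received no seed, `100 * m / N`.
#'
#' @param m Number of empty cells.
#' @param N Total number of cells.
#' @return Missing rate in percent (full precision; round at reporting).
#' @export
#' @examples
#' missing_rate(10, 390)  # 2.5641...
missing_rate <- function(m, N) {
  if (N <= 0) stop("N must be positive")
  if (m < 0 || m > N) stop("m must lie in [0, N]")
  100 * m / N
}

#' Shape factor of a contour
#'
#' `F = C^2 / (4 pi A)`: 1 for a perfect circle, growing with elongation
#' or with the merging of touching seeds into one contour — the feature
#' that lets a small network count seeds per contour.
#'
#' @param C Contour perimeter in pixels.
#' @param A Contour area in pixels squared.
#' @return Dimensionless shape factor.
#' @export
#' @examples
#' shape_factor(2 * pi, pi)    # circle of radius 1 -> 1
#' shape_factor(4, 1)          # unit square -> 4 / pi
shape_factor <- function(C, A) {
  if (any(A <= 0)) stop("contour area must be positive")
  C^2 / (4 * pi * A)
}

#' Total predicted seeds over all pieces
#'
#' Sums the per-contour predictions of the counting network over every
#' surviving contour in every piece.
#'
#' @param piece_contours List of contour data frames.
#' @param counter Trained [seed_counter] from [bp_train()].
#' @return Integer total seed count.
#' @export
count_seeds <- function(piece_contours, counter) {
  all_feats <- do.call(rbind, piece_contours)
  if (is.null(all_feats) || !nrow(all_feats)) return(0L)
  sum(bp_forward(all_feats, counter))
}
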