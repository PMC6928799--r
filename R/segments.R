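#' Detect straight line segments in a grayscale image
#'
#' A light-weight segment detector used both for tray-edge gating and for
#' tilt estimation. The image is Gaussian-smoothed, central-difference
#' gradients are thresholded, edge pixels are split by dominant gradient
#' orientation (so crossing gridlines do not merge), and each elongated
#' connected component is fitted with a straight segment by principal-axis
#' regression. The contract is that a rendered straight edge of length L
#' comes back as one or more collinear segments covering at least 0.8 L.
#'
#' @param gray_image Numeric matrix `[y, x]` with values in `[0, 1]`.
#' @param grad_threshold Gradient magnitude (per pixel, on the `[0, 1]`
#'   intensity scale) below which pixels are not edge candidates. The
#'   default suits high-contrast tray-edge bands; tilt estimation uses a
#'   lower value to pick up the fainter grid edges.
#' @param orientation Restrict to edges of one orientation: `"horizontal"`
#'   keeps near-horizontal edges (vertical gradient dominant), `"vertical"`
#'   the converse, `"any"` both.
#' @param min_component_px Minimum edge pixels per component.
#' @param min_elongation Minimum principal-axis standard-deviation ratio;
#'   rejects isotropic noise blobs.
#' @param smooth_sigma Gaussian pre-smoothing standard deviation.
#' @return Data frame of segments with columns `x1, y1, x2, y2` (0-based
#'   pixel coordinates, origin top-left).
#' @export
detect_line_segments <- function(gray_image, grad_threshold = 0.10,
                                 orientation = c("any", "horizontal", "vertical"),
                                 min_component_px = 15L, min_elongation = 5,
                                 smooth_sigma = 1) {
  orientation <- match.arg(orientation)
  empty <- data.frame(x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0))
  if (!is.matrix(gray_image) || !length(gray_image)) return(empty)
  if (nrow(gray_image) < 5 || ncol(gray_image) < 5) return(empty)
  g <- EBImage::gblur(gray_image, sigma = smooth_sigma)
  H <- nrow(g); W <- ncol(g)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (g[, 3:W] - g[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (g[3:H, ] - g[1:(H - 2), ]) / 2
  agx <- abs(gx); agy <- abs(gy)
  edge <- pmax(agx, agy) > grad_threshold
  masks <- switch(orientation,
                  horizontal = list(h = edge & (agy >= agx)),
                  vertical = list(v = edge & (agx > agy)),
                  any = list(h = edge & (agy >= agx), v = edge & (agx > agy)))
  # bridge 1-2 px gaps along the edge direction so a fragmented low-contrast
  # edge chain labels as one component
  bridge <- list(h = matrix(1, 1, 5), v = matrix(1, 5, 1))
  segs <- list()
  for (mi in seq_along(masks)) {
    m <- masks[[mi]]
    if (!any(m)) next
    m <- EBImage::closing(m * 1, bridge[[names(masks)[mi]]])
    lab <- label8(m)
    n <- max(lab)
    if (n == 0) next
    idx <- which(lab > 0, arr.ind = TRUE)
    ord <- order(lab[lab > 0])
    pts <- idx[ord, , drop = FALSE]
    sizes <- tabulate(lab[lab > 0], n)
    stops <- cumsum(sizes)
    starts <- c(1, head(stops, -1) + 1)
    for (i in seq_len(n)) {
      if (sizes[i] < min_component_px) next
      y <- pts[starts[i]:stops[i], 1] - 1
      x <- pts[starts[i]:stops[i], 2] - 1
      mx <- mean(x); my <- mean(y)
      cv <- stats::cov(cbind(x, y))
      ev <- eigen(cv, symmetric = TRUE)
      s1 <- sqrt(max(ev$values[1], 0)); s2 <- sqrt(max(ev$values[2], 0))
      if (s1 < (min_elongation * max(s2, 0.3))) next
      v <- ev$vectors[, 1]
      t <- (x - mx) * v[1] + (y - my) * v[2]
      segs[[length(segs) + 1]] <- data.frame(
        x1 = mx + min(t) * v[1], y1 = my + min(t) * v[2],
        x2 = mx + max(t) * v[1], y2 = my + max(t) * v[2])
    }
  }
  if (!length(segs)) return(empty)
  do.call(rbind, segs)
}

#' Projection-length filters for line segments
#'
#' `filter_by_vertical_projection()` keeps segments whose vertical extent
#' `|y2 - y1|` strictly exceeds `min_vproj` (tray beginning/end bands
#' project long vertical edges, seed and soil contours do not).
#' `filter_by_horizontal_projection()` keeps segments whose horizontal
#' extent `|x2 - x1|` is at least `min_hproj` (near-horizontal grid edges
#' used for tilt estimation).
#'
#' @param segments Data frame with columns `x1, y1, x2, y2`.
#' @param min_vproj,min_hproj Projection thresholds in pixels.
#' @return The filtered data frame.
#' @export
filter_by_vertical_projection <- function(segments, min_vproj = 100) {
  if (!nrow(segments)) return(segments)
  segments[abs(segments$y2 - segments$y1) > min_vproj, , drop = FALSE]
}

#' @rdname filter_by_vertical_projection
#' @export
filter_by_horizontal_projection <- function(segments, min_hproj = 45) {
  if (!nrow(segments)) return(segments)
  segments[abs(segments$x2 - segments$x1) >= min_hproj, , drop = FALSE]
}

#' Frame gate: one detection per tray transit
#'
#' A frame is invalid while a tray beginning/end band is in view (any line
#' segment surviving the vertical-projection filter). The first edge-free
#' frame after an invalid frame — or at stream start — is the single valid
#' detection for that tray; later edge-free frames are repeats.
#'
#' @return `gate_state()` returns a fresh state (phase `awaiting_tray`).
#' @export
gate_state <- function() {
  structure(list(phase = "awaiting_tray", detections_emitted = 0L),
            class = "gate_state")
}

#' @rdname gate_state
#' @param frame RGB array or grayscale matrix.
#' @param state A `gate_state` object.
#' @param min_vproj Vertical-projection threshold in pixels.
#' @param grad_threshold Edge-detector sensitivity, see
#'   [detect_line_segments()].
#' @return `classify_frame()` returns a list with `verdict` (one of
#'   `"invalid_edge"`, `"valid_first"`, `"valid_repeat"`) and the updated
#'   `state`.
#' @export
classify_frame <- function(frame, state = gate_state(), min_vproj = 100,
                           grad_threshold = 0.10) {
  stopifnot(inherits(state, "gate_state"))
  segs <- detect_line_segments(to_gray(frame), grad_threshold = grad_threshold)
  survivors <- filter_by_vertical_projection(segs, min_vproj)
  if (nrow(survivors)) {
    state$phase <- "awaiting_tray"
    return(list(verdict = "invalid_edge", state = state))
  }
  if (state$phase == "awaiting_tray") {
    state$phase <- "tray_in_view"
    state$detections_emitted <- state$detections_emitted + 1L
    list(verdict = "valid_first", state = state)
  } else {
    list(verdict = "valid_repeat", state = state)
  }
}
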