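#' Tilt estimation and affine rotation correction
#'
#' Frames captured on the moving belt are slightly oblique. The tilt angle
#' is estimated from the slopes of near-horizontal grid edges inside a
#' fixed region of interest and removed by rotating the frame about its
#' centre.
#'
#' @name tilt_correct
NULL

#' Crop the tilt-estimation region of interest
#'
#' @param frame RGB array or grayscale matrix.
#' @param roi `c(x, y, w, h)` in pixels, 0-based top-left corner. The
#'   default covers the tray interior of a 960 x 720 frame while avoiding
#'   its borders.
#' @return Grayscale matrix of the cropped region. A ROI reaching past the
#'   frame is clipped with a warning.
#' @export
extract_tilt_roi <- function(frame, roi = c(70, 70, 800, 500)) {
  g <- to_gray(frame)
  H <- nrow(g); W <- ncol(g)
  x0 <- roi[1]; y0 <- roi[2]; w <- roi[3]; h <- roi[4]
  stopifnot(w > 0, h > 0, x0 < W, y0 < H)
  if (x0 < 0 || y0 < 0 || x0 + w > W || y0 + h > H) {
    warning("tilt ROI exceeds frame bounds; clipping")
    x0 <- max(x0, 0); y0 <- max(y0, 0)
    w <- min(w, W - x0); h <- min(h, H - y0)
  }
  g[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)]
}

#' Slope of a line segment
#'
#' `k = (y2 - y1) / (x2 - x1)` in image coordinates (y downward). Vertical
#' segments have no slope and return `NA`, which callers drop from the
#' slope pool.
#'
#' @param seg One-row data frame or list with `x1, y1, x2, y2`.
#' @return Numeric slope, or `NA` for a vertical segment.
#' @export
segment_slope <- function(seg) {
  dx <- seg$x2 - seg$x1
  if (dx == 0) return(NA_real_)
  (seg$y2 - seg$y1) / dx
}

#' Trimmed mean slope
#'
#' Averages segment slopes after removing exactly one maximum and one
#' minimum instance, damping the influence of a single miss-detected
#' segment. With fewer than 3 slopes the plain mean is used with a
#' warning; an empty pool yields 0 (no rotation).
#'
#' @param slopes Numeric vector of slopes (`NA`s are dropped).
#' @return The trimmed mean `K`.
#' @export
trimmed_mean_slope <- function(slopes) {
  slopes <- slopes[is.finite(slopes)]
  n <- length(slopes)
  if (n == 0) {
    warning("no usable slopes; assuming no tilt")
    return(0)
  }
  if (n < 3) {
    warning("fewer than 3 slopes; falling back to the plain mean")
    return(mean(slopes))
  }
  (sum(slopes) - max(slopes) - min(slopes)) / (n - 2)
}

#' Convert a mean slope to a tilt angle
#'
#' The geometric relation is `theta = arctan(K)` (radians), the default.
#' `formula = "legacy"` applies the small-angle degree-style scaling
#' `theta = K * pi / 180`, retained for fidelity comparisons; the two agree
#' only to first order for very small slopes.
#'
#' @param K Mean slope from [trimmed_mean_slope()].
#' @param formula `"arctan"` (default) or `"legacy"`.
#' @return Tilt angle in radians.
#' @export
slope_to_angle <- function(K, formula = c("arctan", "legacy")) {
  formula <- match.arg(formula)
  stopifnot(is.finite(K))
  if (formula == "arctan") atan(K) else K * pi / 180
}

#' Rotation about the image centre as a 2 x 3 affine matrix
#'
#' Builds the affine matrix that rotates image content by `theta` radians
#' (positive = counter-clockwise on screen, y-down coordinates) about the
#' frame centre `(width/2, height/2)`:
#' `A = [[a, b, (1-a)cx - b cy], [-b, a, b cx + (1-a)cy]]` with
#' `a = cos(theta)`, `b = sin(theta)`. The centre is a fixed point of the
#' map.
#'
#' @param theta Rotation angle in radians.
#' @param width,height Frame size in pixels.
#' @return An object of class `rotation_spec` with fields `centre_x`,
#'   `centre_y`, `alpha`, `beta` and the matrix `A`.
#' @export
rotation_matrix <- function(theta, width, height) {
  stopifnot(width > 0, height > 0)
  cx <- width / 2; cy <- height / 2
  a <- cos(theta); b <- sin(theta)
  A <- matrix(c(a, b, (1 - a) * cx - b * cy,
                -b, a, b * cx + (1 - a) * cy),
              nrow = 2, byrow = TRUE)
  structure(list(centre_x = cx, centre_y = cy, alpha = a, beta = b, A = A),
            class = "rotation_spec")
}

#' Rotate an image with an affine transformation
#'
#' Applies the forward map `dst = A [x, y, 1]'` by inverse-mapping each
#' output pixel into the source and sampling bilinearly. Output dimensions
#' equal input dimensions; pixels falling outside the source are filled
#' with `fill` (scalar or per-channel), by default a neutral soil-like
#' gray so that frame corners do not create phantom contours downstream.
#'
#' @param frame RGB array `[y, x, 3]` or grayscale matrix.
#' @param spec A `rotation_spec` from [rotation_matrix()].
#' @param fill Fill value(s) in `[0, 1]`.
#' @return Image of the same shape as `frame`.
#' @export
rotate_image <- function(frame, spec, fill = 0.5) {
  stopifnot(inherits(spec, "rotation_spec"))
  gray <- is.matrix(frame)
  H <- if (gray) nrow(frame) else dim(frame)[1]
  W <- if (gray) ncol(frame) else dim(frame)[2]
  A <- rbind(spec$A, c(0, 0, 1))
  Ainv <- solve(A)
  xs <- rep(0:(W - 1), each = H)
  ys <- rep(0:(H - 1), times = W)
  sx <- Ainv[1, 1] * xs + Ainv[1, 2] * ys + Ainv[1, 3]
  sy <- Ainv[2, 1] * xs + Ainv[2, 2] * ys + Ainv[2, 3]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  valid <- x0 >= 0 & y0 >= 0 & x0 <= W - 2 & y0 <= H - 2
  # border pixels sampled exactly on the last row/column stay valid
  edge <- (x0 == W - 1 & fx < 1e-9 & y0 >= 0 & y0 <= H - 1) |
          (y0 == H - 1 & fy < 1e-9 & x0 >= 0 & x0 <= W - 1)
  valid <- valid | (edge & x0 >= 0 & y0 >= 0 & x0 <= W - 1 & y0 <= H - 1)
  xc0 <- clamp(x0, 0, W - 1); yc0 <- clamp(y0, 0, H - 1)
  xc1 <- clamp(x0 + 1, 0, W - 1); yc1 <- clamp(y0 + 1, 0, H - 1)
  i00 <- yc0 + 1 + H * xc0; i10 <- yc0 + 1 + H * xc1
  i01 <- yc1 + 1 + H * xc0; i11 <- yc1 + 1 + H * xc1
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy; w11 <- fx * fy
  sample_ch <- function(ch, f) {
    v <- w00 * ch[i00] + w10 * ch[i10] + w01 * ch[i01] + w11 * ch[i11]
    v[!valid] <- f
    matrix(v, H, W)
  }
  if (gray) return(sample_ch(frame, fill[1]))
  fill <- rep(fill, length.out = 3)
  out <- array(0, dim = dim(frame))
  for (k in 1:3) out[, , k] <- sample_ch(frame[, , k], fill[k])
  out
}

#' Estimate the tilt angle of a tray frame
#'
#' Detects near-horizontal grid-edge segments inside the tilt ROI, filters
#' them by horizontal projected length, forms the trimmed mean of their
#' slopes and converts it to an angle.
#'
#' @param frame RGB array or grayscale matrix.
#' @param roi Tilt ROI, see [extract_tilt_roi()].
#' @param min_hproj Horizontal-projection threshold in pixels.
#' @param grad_threshold Detector sensitivity for the faint grid edges.
#' @param formula Angle formula, see [slope_to_angle()].
#' @return A list of class `tilt_estimate` with `slopes`, trimmed mean
#'   `K`, `theta` (radians), `theta_deg` and `n` (slopes used).
#' @export
estimate_tilt <- function(frame, roi = c(70, 70, 800, 500), min_hproj = 45,
                          grad_threshold = 0.04,
                          formula = c("arctan", "legacy")) {
  sub <- extract_tilt_roi(frame, roi)
  segs <- detect_line_segments(sub, grad_threshold = grad_threshold,
                               orientation = "horizontal")
  segs <- filter_by_horizontal_projection(segs, min_hproj)
  slopes <- if (nrow(segs)) {
    vapply(seq_len(nrow(segs)), function(i) segment_slope(segs[i, ]),
           numeric(1))
  } else {
    numeric(0)
  }
  K <- trimmed_mean_slope(slopes)
  theta <- slope_to_angle(K, formula)
  structure(list(slopes = slopes, K = K, theta = theta,
                 theta_deg = theta * 180 / pi,
                 n = sum(is.finite(slopes))),
            class = "tilt_estimate")
}

#' Correct the tilt of a frame
#'
#' Convenience wrapper: estimates the tilt and rotates the frame about its
#' centre so that gridlines become axis-aligned.
#'
#' @inheritParams estimate_tilt
#' @param fill Fill for out-of-frame pixels, see [rotate_image()].
#' @return List with the corrected `frame` and the `tilt_estimate`.
#' @export
correct_tilt <- function(frame, roi = c(70, 70, 800, 500), min_hproj = 45,
                         grad_threshold = 0.04,
                         formula = c("arctan", "legacy"), fill = 0.5) {
  est <- estimate_tilt(frame, roi, min_hproj, grad_threshold, formula)
  H <- if (is.matrix(frame)) nrow(frame) else dim(frame)[1]
  W <- if (is.matrix(frame)) ncol(frame) else dim(frame)[2]
  out <- if (abs(est$theta) > 1e-9) {
    rotate_image(frame, rotation_matrix(est$theta, W, H), fill = fill)
  } else {
    frame
  }
  list(frame = out, estimate = est)
}
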