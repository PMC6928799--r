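#' Specification of a synthetic pot-tray frame
#'
#' Describes one rendered frame of the visible 10 x 13-cell region of a
#' sown pot tray: geometry, ground-truth tilt, per-cell seed counts,
#' seed-coloured impurity blobs, an optional tray-edge band, and the
#' per-class H/S/L sampling ranges. Rendering is fully deterministic given
#' `rng_seed`.
#'
#' Per-class colours are sampled inside the hue bands that the fixed
#' thresholds of [hsl_thresholds()] assume (grid hue in (3, 30), seed hue
#' in (70, 168), soil between the two), with a safety margin so that 8-bit
#' RGB quantisation cannot push a pixel across a threshold.
#'
#' @param rows,cols Visible cell rows and columns.
#' @param cell_size_px Cell edge length in pixels.
#' @param gridline_width_px Gridline thickness in pixels (>= 3 so that a
#'   3 x 3 morphological opening preserves the lines).
#' @param tilt_deg Ground-truth tilt angle in degrees (positive = gridlines
#'   slope downward to the right).
#' @param seed_counts Optional `rows x cols` integer matrix of seeds per
#'   cell; if `NULL`, counts are sampled from `count_probs` with a fraction
#'   `empty_frac` of empty cells.
#' @param empty_frac Expected fraction of empty cells when sampling counts.
#' @param count_probs Probabilities of 1, 2 or 3 seeds in a non-empty cell.
#' @param impurity_count Number of seed-coloured soil impurity blobs.
#' @param edge_band If `TRUE`, a dark near-vertical tray beginning/end band
#'   crosses the frame.
#' @param frame_w,frame_h Frame size in pixels.
#' @param class_colors Per-class H/S/L sampling ranges (half-degree hue
#'   scale, S and L in `[0, 255]`).
#' @param rng_seed Integer seed controlling all randomness in the render.
#' @return An object of class `tray_spec`.
#' @export
tray_spec <- function(rows = 10L, cols = 13L, cell_size_px = 64L,
                      gridline_width_px = 3L, tilt_deg = 0,
                      seed_counts = NULL, empty_frac = 0.02,
                      count_probs = c(0.35, 0.45, 0.2),
                      impurity_count = 3L, edge_band = FALSE,
                      frame_w = 960L, frame_h = 720L,
                      class_colors = tray_class_colors(),
                      rng_seed = 1L) {
  stopifnot(rows >= 1L, cols >= 1L, cell_size_px >= 8L, gridline_width_px >= 3L)
  pitch <- cell_size_px + gridline_width_px
  grid_w <- cols * pitch + gridline_width_px
  grid_h <- rows * pitch + gridline_width_px
  if (grid_w > frame_w || grid_h > frame_h) {
    stop(sprintf("frame %dx%d too small for %dx%d cells at %d px",
                 frame_w, frame_h, rows, cols, cell_size_px))
  }
  if (!is.null(seed_counts)) {
    seed_counts <- as.matrix(seed_counts)
    stopifnot(identical(dim(seed_counts), c(as.integer(rows), as.integer(cols))),
              all(seed_counts >= 0))
  }
  gr <- class_colors$grid$h; se <- class_colors$seed$h
  if (gr[1] < se[2] && se[1] < gr[2]) stop("seed and grid hue ranges must not intersect")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 cell_size_px = as.integer(cell_size_px),
                 gridline_width_px = as.integer(gridline_width_px),
                 tilt_deg = tilt_deg, seed_counts = seed_counts,
                 empty_frac = empty_frac, count_probs = count_probs,
                 impurity_count = as.integer(impurity_count),
                 edge_band = isTRUE(edge_band),
                 frame_w = as.integer(frame_w), frame_h = as.integer(frame_h),
                 class_colors = class_colors, rng_seed = as.integer(rng_seed)),
            class = "tray_spec")
}

#' @rdname tray_spec
#' @export
tray_class_colors <- function() {
  list(grid = list(h = c(8, 25), s = c(30, 70), l = c(166, 173)),
       soil = list(h = c(33, 64), s = c(18, 27), l = c(116, 144)),
       seed = list(h = c(85, 150), s = c(20, 29), l = c(178, 200)),
       band = list(h = c(5, 40), s = c(5, 15), l = c(12, 25)))
}

# Sample one H/S/L colour range into an n x 3 RGB matrix in [0, 1].
sample_class_rgb <- function(n, rng) {
  hsl_to_rgb(runif(n, rng$h[1], rng$h[2]),
             runif(n, rng$s[1], rng$s[2]),
             runif(n, rng$l[1], rng$l[2]))
}

# Rasterize an ellipse into a logical matrix the size of `mask`.
ellipse_pixels <- function(dim_yx, cx, cy, a, b, phi) {
  r <- ceiling(max(a, b))
  ys <- max(1, floor(cy - r + 1)):min(dim_yx[1], ceiling(cy + r + 1))
  xs <- max(1, floor(cx - r + 1)):min(dim_yx[2], ceiling(cx + r + 1))
  if (!length(ys) || !length(xs)) return(NULL)
  dx <- outer(rep(1, length(ys)), xs - 1 - cx)
  dy <- outer(ys - 1 - cy, rep(1, length(xs)))
  u <- (dx * cos(phi) + dy * sin(phi)) / a
  v <- (-dx * sin(phi) + dy * cos(phi)) / b
  inside <- which(u * u + v * v <= 1, arr.ind = TRUE)
  if (!nrow(inside)) return(NULL)
  cbind(y = ys[inside[, 1]], x = xs[inside[, 2]])
}

# Radius of an ellipse (semi-axes a, b, orientation phi) along direction ang.
ellipse_radius_along <- function(a, b, phi, ang) {
  1 / sqrt((cos(ang - phi) / a)^2 + (sin(ang - phi) / b)^2)
}

# Draw a touching cluster of `k` elliptical seeds centred near (cx, cy),
# keeping all pixels within `bound_r` of the centre. Seeds form a chain:
# each is placed in shallow overlap with the previous one, at a contact
# distance scaled by the two directional radii so that the overlap depth
# is consistent regardless of orientation. Returns a logical mask.
draw_seed_cluster <- function(dim_yx, cx, cy, k, bound_r,
                              area_range = c(125, 175)) {
  mask <- matrix(FALSE, dim_yx[1], dim_yx[2])
  ell <- matrix(NA_real_, k, 5)   # ex, ey, a, b, phi
  for (i in seq_len(k)) {
    A <- runif(1, area_range[1], area_range[2])
    q <- runif(1, 1.7, 2.1)
    ab <- A / pi
    a <- sqrt(ab * q); b <- sqrt(ab / q)
    phi <- runif(1, 0, pi)
    if (i == 1) {
      ex <- cx + runif(1, -3, 3); ey <- cy + runif(1, -3, 3)
    } else {
      ok <- FALSE
      for (try in 1:25) {
        j <- i - 1L   # chain topology: each seed touches the previous one
        ang <- runif(1, 0, 2 * pi)
        d <- runif(1, 0.8, 0.9) *
          (ellipse_radius_along(ell[j, 3], ell[j, 4], ell[j, 5], ang) +
           ellipse_radius_along(a, b, phi, ang))
        ex <- ell[j, 1] + d * cos(ang)
        ey <- ell[j, 2] + d * sin(ang)
        if ((ex - cx)^2 + (ey - cy)^2 <= (bound_r - a)^2) { ok <- TRUE; break }
      }
      if (!ok) { ex <- cx; ey <- cy }   # collapse onto the centre as last resort
    }
    ell[i, ] <- c(ex, ey, a, b, phi)
    px <- ellipse_pixels(dim_yx, ex, ey, a, b, phi)
    if (!is.null(px)) mask[px] <- TRUE
  }
  mask
}

#' Render a synthetic pot-tray frame with exact ground truth
#'
#' Paints textured soil, a rectangular gridline lattice, elliptical seed
#' clusters in non-empty cells, small seed-coloured impurities and an
#' optional tray-edge band, then rotates the scene by the ground-truth tilt
#' angle (bilinear resampling, soil-mean fill). Identical specs render
#' byte-identical frames.
#'
#' @param spec A [tray_spec()].
#' @return A list with `frame` (RGB array `[y, x, 3]`) and `truth`, a
#'   `tray_truth` list carrying `tilt_deg`, nominal (post-correction)
#'   `row_lines`/`col_lines` pixel coordinates, `seeds_per_cell`,
#'   `empty_cells` (0-based row/col data frame), `total_seeds`, the
#'   nominal binary `seed_mask` and `grid_mask`, and impurity placements.
#' @export
render_tray <- function(spec) {
  stopifnot(inherits(spec, "tray_spec"))
  with_seed(spec$rng_seed, {
    W <- spec$frame_w; H <- spec$frame_h
    gw <- spec$gridline_width_px; cell <- spec$cell_size_px
    pitch <- cell + gw
    grid_w <- spec$cols * pitch + gw
    grid_h <- spec$rows * pitch + gw
    ox <- (W - grid_w) %/% 2L
    oy <- (H - grid_h) %/% 2L
    cc <- spec$class_colors

    frame <- array(0, dim = c(H, W, 3))
    soil <- sample_class_rgb(H * W, cc$soil)
    for (k in 1:3) frame[, , k] <- matrix(soil[, k], H, W)
    soil_mean <- colMeans(soil)

    # gridline lattice (0-based line start coordinates)
    col_starts <- ox + (0:spec$cols) * pitch
    row_starts <- oy + (0:spec$rows) * pitch
    grid_mask <- matrix(FALSE, H, W)
    gx <- as.vector(outer(1:gw, col_starts, `+`))      # 1-based columns
    gy <- as.vector(outer(1:gw, row_starts, `+`))
    span_x <- (ox + 1):(ox + grid_w)
    span_y <- (oy + 1):(oy + grid_h)
    grid_mask[span_y, gx] <- TRUE
    grid_mask[gy, span_x] <- TRUE
    gcol <- sample_class_rgb(sum(grid_mask), cc$grid)
    for (k in 1:3) { ch <- frame[, , k]; ch[grid_mask] <- gcol[, k]; frame[, , k] <- ch }

    # per-cell seed counts
    counts <- spec$seed_counts
    if (is.null(counts)) {
      n <- spec$rows * spec$cols
      nonempty <- runif(n) >= spec$empty_frac
      k <- sample.int(3L, n, replace = TRUE, prob = spec$count_probs)
      counts <- matrix(ifelse(nonempty, k, 0L), spec$rows, spec$cols)
    }

    seed_mask <- matrix(FALSE, H, W)
    bound_r <- cell / 2 - gw - 2
    for (r in seq_len(spec$rows)) {
      for (cl in seq_len(spec$cols)) {
        k <- counts[r, cl]
        if (k == 0) next
        cx <- col_starts[cl] + gw + cell / 2
        cy <- row_starts[r] + gw + cell / 2
        seed_mask <- seed_mask |
          draw_seed_cluster(c(H, W), cx, cy, k, bound_r)
      }
    }

    # soil impurities: seed-coloured blobs, mostly under the 30-px filter
    imp <- data.frame(x = numeric(0), y = numeric(0), area = numeric(0))
    if (spec$impurity_count > 0) {
      for (i in seq_len(spec$impurity_count)) {
        A <- if (runif(1) < 0.8) runif(1, 5, 29) else runif(1, 30, 60)
        q <- runif(1, 1.2, 2)
        a <- sqrt(A / pi * q); b <- sqrt(A / pi / q)
        ix <- runif(1, ox + 5, ox + grid_w - 5)
        iy <- runif(1, oy + 5, oy + grid_h - 5)
        px <- ellipse_pixels(c(H, W), ix, iy, a, b, runif(1, 0, pi))
        if (!is.null(px)) seed_mask[px] <- TRUE
        imp <- rbind(imp, data.frame(x = ix, y = iy, area = A))
      }
    }
    scol <- sample_class_rgb(sum(seed_mask), cc$seed)
    for (k in 1:3) { ch <- frame[, , k]; ch[seed_mask] <- scol[, k]; frame[, , k] <- ch }

    # tray beginning/end band: dark, high-contrast, spans the frame height
    if (spec$edge_band) {
      bx0 <- round(runif(1, 40, W - 100))
      bcol <- sample_class_rgb(H * 60, cc$band)
      for (k in 1:3) {
        frame[, (bx0 + 1):(bx0 + 60), k] <- matrix(bcol[, k], H, 60)
      }
    }

    if (spec$tilt_deg != 0) {
      rs <- rotation_matrix(-spec$tilt_deg * pi / 180, W, H)
      frame <- rotate_image(frame, rs, fill = soil_mean)
    }

    truth <- structure(list(
      tilt_deg = spec$tilt_deg,
      row_lines = row_starts + (gw - 1) / 2,
      col_lines = col_starts + (gw - 1) / 2,
      seeds_per_cell = counts,
      empty_cells = {
        e <- which(counts == 0, arr.ind = TRUE)
        data.frame(row = e[, 1] - 1L, col = e[, 2] - 1L)
      },
      total_seeds = sum(counts),
      seed_mask = seed_mask * 1,
      grid_mask = grid_mask * 1,
      impurities = imp,
      origin = c(x = ox, y = oy)
    ), class = "tray_truth")
    list(frame = frame, truth = truth)
  })
}

#' Synthetic contour-feature training samples
#'
#' Renders touching clusters of 1..k synthetic seeds, applies the same
#' morphological opening used by the detection pipeline, and measures
#' (area, perimeter, shape factor) of the merged contour. Class `i` blobs
#' contain `i` seeds; feature clouds of adjacent classes overlap because
#' individual seed sizes vary.
#'
#' @param class_counts Samples per class; class label = position. Defaults
#'   to the 2280/1216/822/620/586 split of a production training set.
#' @param rng_seed Integer seed; fixed seed gives an identical dataset.
#' @return Data frame with `area`, `perimeter`, `shape_factor`, `label`.
#' @export
make_contour_samples <- function(class_counts = c(2280, 1216, 822, 620, 586),
                                 rng_seed = 1L) {
  stopifnot(all(class_counts >= 0))
  with_seed(rng_seed, {
    total <- sum(class_counts)
    out <- data.frame(area = numeric(total), perimeter = numeric(total),
                      shape_factor = numeric(total), label = integer(total))
    dim_yx <- c(120L, 120L)
    kernel <- EBImage::makeBrush(3, "box")
    row <- 0L
    for (lab in seq_along(class_counts)) {
      for (s in seq_len(class_counts[lab])) {
        repeat {
          m <- draw_seed_cluster(dim_yx, 60, 60, lab, bound_r = 52)
          m <- EBImage::opening(m * 1, kernel)
          labs <- label8(m)
          if (max(labs) == 0) next
          feats <- contour_features(labs)
          feats <- feats[which.max(feats$area), ]   # largest component
          if (max(labs) == 1 || lab == 1) break
        }
        row <- row + 1L
        out$area[row] <- feats$area
        out$perimeter[row] <- feats$perimeter
        out$shape_factor[row] <- feats$shape_factor
        out$label[row] <- lab
      }
    }
    out
  })
}

#' Read and write frames and ground-truth sidecars
#'
#' `write_tray()` saves a rendered frame as PNG together with a JSON
#' ground-truth sidecar (`tilt_deg`, gridline coordinates, seeds per cell);
#' `read_frame()` loads a PNG/JPEG into the package's `[y, x, 3]` array
#' layout.
#'
#' @param frame RGB array `[y, x, 3]`.
#' @param truth A `tray_truth` object (optional).
#' @param path Output PNG path; the sidecar replaces the extension by
#'   `.json`.
#' @return `read_frame()` returns an RGB array; `write_tray()` returns
#'   `path` invisibly.
#' @export
write_tray <- function(frame, truth = NULL, path) {
  EBImage::writeImage(EBImage::Image(aperm(frame, c(2, 1, 3)),
                                     colormode = "Color"), path)
  if (!is.null(truth)) {
    side <- sub("\\.[^.]+$", ".json", path)
    jsonlite::write_json(list(tilt_deg = truth$tilt_deg,
                              row_lines = truth$row_lines,
                              col_lines = truth$col_lines,
                              seeds_per_cell = truth$seeds_per_cell,
                              total_seeds = truth$total_seeds),
                         side, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_tray
#' @export
read_frame <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2L) {
    g <- t(as.array(img))
    return(array(rep(g, 3), dim = c(dim(g), 3)))
  }
  aperm(as.array(img)[, , 1:3], c(2, 1, 3))
}
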