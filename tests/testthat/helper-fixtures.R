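# Shared fixtures, built once per test run and cached.

.fixtures <- new.env()

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Flat (tilt 0, impurity-free) tray with full ground truth.
flat_tray <- function() {
  fixture("flat_tray", render_tray(tray_spec(tilt_deg = 0, rng_seed = 7,
                                             impurity_count = 0)))
}

# Small contour-feature training set and a counter trained on it.
small_samples <- function() {
  fixture("small_samples",
          make_contour_samples(c(120, 80, 60, 50, 40), rng_seed = 7))
}

small_counter <- function() {
  fixture("small_counter", bp_train(small_samples(), rng_seed = 3))
}

# Small frames for exercising the gate state machine cheaply.
small_clean_frame <- function() {
  fixture("small_clean_frame",
          render_tray(tray_spec(rows = 2, cols = 3, cell_size_px = 40,
                                frame_w = 240, frame_h = 200,
                                rng_seed = 5))$frame)
}

small_edge_frame <- function() {
  fixture("small_edge_frame",
          render_tray(tray_spec(rows = 2, cols = 3, cell_size_px = 40,
                                frame_w = 240, frame_h = 200,
                                edge_band = TRUE, rng_seed = 6))$frame)
}

# Independent brute-force oracle for gridline localisation: explicit loops,
# same block and tie-break conventions as the documented contract.
oracle_locate <- function(profile, n_groups) {
  n <- nrow(profile)
  base <- floor(n / n_groups)
  res <- integer(0)
  for (i in 1:n_groups) {
    lo <- (i - 1) * base + 1
    hi <- if (i == n_groups) n else i * base
    best <- NA; best_d <- Inf
    centre <- (lo + hi) / 2
    mx <- -Inf
    for (j in lo:hi) mx <- max(mx, profile$pixel_sum[j])
    for (j in lo:hi) {
      if (profile$pixel_sum[j] == mx) {
        d <- abs(j - centre)
        if (d < best_d - 1e-12) { best <- j; best_d <- d }
      }
    }
    res <- c(res, profile$index[best])
  }
  res
}

# Rasterize one ellipse as a binary matrix (for contour-feature checks).
raster_ellipse <- function(a, b, dim = 101) {
  c0 <- (dim + 1) / 2
  xy <- expand.grid(y = 1:dim, x = 1:dim)
  matrix(as.numeric(((xy$x - c0) / a)^2 + ((xy$y - c0) / b)^2 <= 1), dim, dim)
}
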